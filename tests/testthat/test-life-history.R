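# synthetic CDS built from explicit codon choices
codon_gene <- function(codons) paste(codons, collapse = "")

test_that("codon-usage bias sits at its baseline under identical usage", {
  # background and highly expressed set are the very same genes, so
  # every within-amino-acid frequency matches the background exactly
  gene <- codon_gene(rep(c("CTG", "CTA", "AAA", "AAG", "GGC", "GAT"), 20))
  genes <- c(gene, gene)
  cub <- codon_usage_bias(genes, genes, min_genes = 1L)
  expect_equal(cub$statistic, cub$baseline, tolerance = 1e-12)
  expect_false(cub$low_confidence)
})

test_that("skewed synonymous usage scores above the no-bias baseline", {
  # background: Leu codons uniform; highly expressed: only CTG
  set.seed(5)
  leu <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  background <- vapply(1:20, function(i) {
    codon_gene(sample(leu, 60, replace = TRUE))
  }, "")
  skewed <- codon_gene(rep("CTG", 60))
  cub <- codon_usage_bias(skewed, background)
  expect_gt(cub$statistic, cub$baseline)
  expect_true(cub$low_confidence)  # single gene < default threshold

  expect_error(codon_usage_bias(character(0L), background), "empty")
  expect_error(codon_usage_bias("AC", background), "codon")
  # trailing partial codons are trimmed, not fatal
  trimmed <- codon_usage_bias(paste0(skewed, "AC"), background)
  expect_equal(trimmed$statistic, cub$statistic)
})

test_that("composition features hit analytic values on homopolymer input", {
  g <- genome_record("gc", c(c1 = strrep("GC", 500)))
  ps <- protein_set("gc", c(p1 = strrep("A", 100)),
                    cds = c(p1 = strrep("GCA", 100)))
  feats <- extract_ogt_features(g, ps)
  expect_equal(unname(feats[["genome_gc"]]), 1)
  expect_equal(unname(feats[["aa_A"]]), 1)
  expect_equal(unname(feats[["frac_ivywrel"]]), 0)
  expect_equal(unname(feats[["orf_nt_a"]]), 1 / 3)
  # proteome-only input restricts to protein-derived features
  pp <- protein_set("p", c(p1 = "MKKLLE"))
  fo <- extract_ogt_features(NULL, pp)
  expect_false("genome_gc" %in% names(fo))
  expect_true("aa_K" %in% names(fo))
})

test_that("composition features equal an independent single-pass count", {
  set.seed(9)
  orfs <- c(pA = random_protein(80L, seed = 51),
            pB = random_protein(90L, seed = 52))
  tg <- make_toy_genome(orfs, "feat", seed = 53)
  ps <- predict_orfs(tg$genome)
  feats <- extract_ogt_features(tg$genome, ps)
  # oracle: direct character tally of the genome string
  chars <- strsplit(paste(tg$genome$sequence, collapse = ""), "")[[1L]]
  expect_equal(unname(feats[["genome_gc"]]),
               mean(chars %in% c("G", "C")))
  aa_chars <- strsplit(paste(ps$proteins, collapse = ""), "")[[1L]]
  expect_equal(unname(feats[["aa_L"]]), mean(aa_chars == "L"))
  # gene order does not matter
  ps_rev <- protein_set("feat", rev(ps$proteins), cds = rev(ps$cds))
  expect_equal(extract_ogt_features(tg$genome, ps_rev)[names(feats)],
               feats)
})

test_that("linear model files parse and predict as a plain dot product", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("#traitguilds-model v1", "#response: demo",
               "#transform: identity", "#units: hours",
               "feature\tweight", "(intercept)\t1", "f1\t2"), tmp)
  model <- read_linear_model(tmp)
  expect_equal(predict_from_linear_model(c(f1 = 1), model), 3,
               ignore_attr = TRUE)
  # zero slopes give the intercept everywhere
  model0 <- model
  model0$coefficients[] <- 0
  expect_equal(predict_from_linear_model(c(f1 = 99), model0), 1,
               ignore_attr = TRUE)
  expect_error(predict_from_linear_model(c(other = 1), model), "missing")

  # random spec vs independent dot product
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:6, 1L)
    w <- rnorm(k)
    names(w) <- sprintf("f%d", 1:k)
    x <- rnorm(k)
    names(x) <- names(w)
    spec <- structure(list(coefficients = w, intercept = rnorm(1),
                           transform = "identity", units = "u",
                           meta = list()),
                      class = "linear_model_spec")
    expect_equal(as.numeric(predict_from_linear_model(x, spec)),
                 spec$intercept + sum(w * x), tolerance = 1e-12)
  }

  # log transform back-transforms through exp
  spec <- structure(list(coefficients = c(f1 = 1), intercept = 0,
                         transform = "log", units = "hours",
                         meta = list()), class = "linear_model_spec")
  expect_equal(as.numeric(predict_from_linear_model(c(f1 = 2), spec)),
               exp(2))
})

test_that("packaged synthetic models drive genome-level predictions", {
  fx <- pipeline_fixture()
  g01 <- read_genome_fasta(file.path(fx$genome_dir, "g01.fa"))
  proteins <- predict_orfs(g01)
  manifest <- read_hmm_manifest(fx$manifest_file)
  hits <- filter_hits(scan_proteins(proteins, fx$hmm_library), manifest)
  models <- example_model_files()
  # the toy manifest has no ribosomal hits, so the trait is refused
  expect_error(life_history_traits(g01, proteins, hits, manifest,
                                   models[["growth"]], models[["ogt"]]),
               "ribosomal")
  # with the planted nosZ protein relabelled as a ribosomal model the
  # prediction path runs end to end
  manifest2 <- manifest
  manifest2$hmm_name[manifest2$hmm_name == "nosZ"] <- "rpsZ"
  hits2 <- hits
  hits2$hmm_name[hits2$hmm_name == "nosZ"] <- "rpsZ"
  lh <- life_history_traits(g01, proteins, hits2, manifest2,
                            models[["growth"]], models[["ogt"]],
                            min_ribosomal = 1L)
  expect_true(is.finite(lh[["doubling_time_h"]]))
  expect_gt(lh[["doubling_time_h"]], 0)  # log-scale model exponentiates
  expect_true(is.finite(lh[["ogt_celsius"]]))
  expect_false(attr(lh, "low_confidence"))
})
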