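test_that("genome records validate sequences and sizes", {
  g <- genome_record("g", c(c1 = "ACGTACGT"))
  expect_identical(g$size_bp, 8L)
  expect_error(genome_record("g", ""), "empty")
  expect_error(genome_record("g", "ACGX!"), "non-nucleotide")
  expect_error(genome_record("g", c(c1 = "ACGT"), size_bp = 99),
               "disagrees")
})

test_that("planted ORFs are recovered by the gene caller", {
  orfs <- c(pA = random_protein(160L, seed = 21),
            pB = random_protein(190L, seed = 22),
            pC = random_protein(220L, seed = 23))
  tg <- make_toy_genome(orfs, "orftest", seed = 31)
  ps <- predict_orfs(tg$genome)
  expect_gte(length(ps$proteins), 3L)
  for (nm in names(tg$expected$proteins)) {
    planted <- substring(tg$expected$proteins[[nm]], 2L)  # allow start swap
    expect_true(any(grepl(planted, ps$proteins, fixed = TRUE)),
                info = nm)
  }
  # nucleotide CDS travel along with the proteins
  expect_identical(names(ps$cds), names(ps$proteins))
  # cached second call is identical
  expect_identical(predict_orfs(tg$genome), ps)
  # proteome-only genomes cannot be ORF-called
  expect_error(predict_orfs(genome_record("p_only")), "no nucleotide")
})

test_that("hmmsearch separates true family members from decoys", {
  lib <- make_toy_hmm_library(c("famX", "famY"), seed = 7)
  queries <- protein_set("gQ", c(
    trueX = lib$seeds[["famX"]],
    trueY = lib$seeds[["famY"]],
    decoy1 = random_protein(120L, seed = 71),
    decoy2 = paste(rev(strsplit(lib$seeds[["famX"]], "")[[1L]]),
                   collapse = "")))
  hits <- scan_proteins(queries, lib$library)
  xhit <- hits[hits$hmm_name == "famX", ]
  expect_true("trueX" %in% xhit$protein_id)
  true_score <- xhit$bitscore[xhit$protein_id == "trueX"]
  other <- hits$bitscore[hits$protein_id %in% c("decoy1", "decoy2")]
  if (length(other) > 0L) expect_true(all(other < true_score))
  expect_error(scan_proteins(queries, tempfile()), "not found")
  bad <- tempfile()
  writeLines("not a profile", bad)
  expect_error(scan_proteins(queries, bad), "malformed|HMMER")
  expect_error(scan_proteins(protein_set("e", setNames(character(0L),
                                                       character(0L))),
                             lib$library), "empty")
})

test_that("trusted-cutoff filtering keeps best hits at or above cutoff", {
  m <- hmm_manifest(c("mA", "mB", "mC"), c(50, 60, NA))
  hits <- data.frame(
    genome_id = "g1",
    protein_id = c("p1", "p1", "p2", "p3", "p4"),
    hmm_name = c("mA", "mA", "mA", "mB", "mB"),
    bitscore = c(60, 55, 49.9, 60, 70),
    evalue = 1e-10)
  kept <- filter_hits(hits, m)
  # boundary: 49.9 < 50 removed; dedup keeps the 60-bit hit for p1/mA
  expect_identical(nrow(kept), 3L)
  expect_equal(kept$bitscore[kept$protein_id == "p1"], 60)
  expect_false("p2" %in% kept$protein_id)
  # score equal to the cutoff passes
  eq <- hits[1, ]
  eq$bitscore <- 50
  expect_identical(nrow(filter_hits(eq, m)), 1L)

  # missing-cutoff policy: reject by default, pass-through on request
  mc <- hits[1, ]
  mc$hmm_name <- "mC"
  expect_error(filter_hits(mc, m), "without a trusted cutoff")
  expect_warning(kept <- filter_hits(mc, m, missing_cutoff = "pass"),
                 "unfiltered")
  expect_identical(nrow(kept), 1L)
  expect_error(filter_hits(transform(hits, hmm_name = "ghost"), m),
               "absent from the manifest")
})

test_that("filtering equals a brute-force pass over random labelled hits", {
  set.seed(404)
  m <- hmm_manifest(c("mA", "mB"), c(40, 55))
  for (rep in 1:50) {
    n <- sample(5:40, 1L)
    hits <- data.frame(
      genome_id = sample(c("g1", "g2"), n, replace = TRUE),
      protein_id = sample(sprintf("p%d", 1:8), n, replace = TRUE),
      hmm_name = sample(c("mA", "mB"), n, replace = TRUE),
      bitscore = round(runif(n, 20, 80), 1),
      evalue = 1e-5)
    kept <- filter_hits(hits, m)
    cutoff <- c(mA = 40, mB = 55)
    # brute force: best score per (genome, protein, model), then cutoff
    want <- 0L
    for (key in unique(paste(hits$genome_id, hits$protein_id,
                             hits$hmm_name))) {
      sub <- hits[paste(hits$genome_id, hits$protein_id,
                        hits$hmm_name) == key, ]
      if (max(sub$bitscore) >= cutoff[[sub$hmm_name[[1L]]]]) {
        want <- want + 1L
      }
    }
    expect_identical(nrow(kept), want)
    expect_true(all(kept$bitscore >= cutoff[kept$hmm_name]))
  }
})

test_that("count tables count distinct proteins and respect cutoff monotonicity", {
  m <- hmm_manifest(c("nosZ", "nirK"), c(50, 50))
  hits <- data.frame(
    genome_id = c("G", "G", "G", "G", "H"),
    protein_id = c("p1", "p2", "p3", "p1", "q1"),
    hmm_name = c("nosZ", "nosZ", "nosZ", "nirK", "nirK"),
    bitscore = c(60, 70, 80, 55, 90),
    evalue = 1e-8)
  tab <- count_table(filter_hits(hits, m), c("G", "H", "Z"),
                     models = c("nosZ", "nirK"))
  expect_identical(unname(tab["G", "nosZ"]), 3L)
  # one protein counts once per model it hits
  expect_identical(unname(tab["G", "nirK"]), 1L)
  # genome with no hits is an all-zero row
  expect_true(all(tab["Z", ] == 0L))
  expect_identical(presence_matrix(tab), unclass(tab) > 0L)

  # raising a cutoff never increases any count
  m2 <- hmm_manifest(c("nosZ", "nirK"), c(75, 50))
  tab2 <- count_table(filter_hits(hits, m2), c("G", "H", "Z"),
                      models = c("nosZ", "nirK"))
  expect_true(all(unclass(tab2) <= unclass(tab)))

  # identical inputs give identical tables
  tab3 <- count_table(filter_hits(hits, m), c("G", "H", "Z"),
                      models = c("nosZ", "nirK"))
  expect_identical(tab3, tab)
})

test_that("fixture genomes yield the planted copy numbers end to end", {
  fx <- pipeline_fixture()
  g05 <- read_genome_fasta(file.path(fx$genome_dir, "g05.fa"))
  proteins <- predict_orfs(g05)
  hits <- scan_proteins(proteins, fx$hmm_library)
  manifest <- read_hmm_manifest(fx$manifest_file)
  kept <- filter_hits(hits, manifest)
  tab <- count_table(kept, list(g05), models = manifest$hmm_name)
  expect_identical(unname(tab["g05", "nosZ"]), 3L)
  expect_identical(unname(tab["g05", "amtB"]), 1L)
  expect_identical(unname(tab["g05", "narG"]), 0L)
})
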