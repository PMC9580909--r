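#' @title Life-history traits from genome-wide signatures
#'
#' @description
#' Two composite traits are predicted from genome-wide signals rather
#' than from individual marker genes:
#'
#' * **minimum doubling time** (hours), from the codon-usage bias of
#'   ribosomal protein genes relative to the genome-wide background --
#'   highly expressed genes in fast growers show strong synonymous
#'   codon preference;
#' * **optimal growth temperature** (deg C), from compositional
#'   features of the genome, its ORFs and the translated proteome.
#'
#' Both predictions go through pluggable multiple-linear-regression
#' model files ([read_linear_model()]); the package authors make no
#' claim about coefficient values, which are supplied by the user or by
#' the packaged synthetic examples.
#'
#' The codon-usage-bias statistic is MILC (Measure Independent of
#' Length and Composition; Supek & Vlahovicek 2005): for a gene with
#' `L` codons, `MILC = sum_a M_a / L - C` with
#' `M_a = 2 * sum_{c in a} O_c * ln(f_c / e_c)` (observed within-amino-
#' acid codon frequencies `f` against background expectation `e`) and
#' small-sample correction `C = sum_a (r_a - 1)/L - 0.5` over amino
#' acids present in the gene (`r_a` = number of synonymous codons).
#' The reported statistic is the mean MILC of the highly expressed set
#' against the genome-wide background; its no-bias baseline for a gene
#' whose usage equals the background exactly is `-C`.
#'
#' @name life_history
NULL

# per-amino-acid synonymous codon families of the standard genetic code
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

codon_counts <- function(genes) {
  fams <- codon_families()
  codons <- unlist(fams, use.names = FALSE)
  counts <- stats::setNames(rep(0, length(codons)), codons)
  for (g in genes) {
    g <- toupper(g)
    L <- nchar(g) %/% 3L
    if (L < 1L) stop("gene shorter than one codon", call. = FALSE)
    cods <- substring(g, 3L * seq_len(L) - 2L, 3L * seq_len(L))
    tab <- table(cods)
    keep <- intersect(names(tab), codons)
    counts[keep] <- counts[keep] + as.numeric(tab[keep])
  }
  counts
}

# background within-amino-acid codon frequencies; exact (no floor), so
# a gene whose usage equals the background scores exactly zero
# divergence. Families absent from the background get uniform
# frequencies.
background_frequencies <- function(bg_counts) {
  fams <- codon_families()
  e <- bg_counts
  attr(e, "family_n") <- vapply(fams, function(fam) sum(bg_counts[fam]),
                                numeric(1L))
  for (fam in fams) {
    n <- sum(bg_counts[fam])
    e[fam] <- if (n == 0) 1 / length(fam) else bg_counts[fam] / n
  }
  e
}

milc_gene <- function(gene, e) {
  fams <- codon_families()
  fam_n <- attr(e, "family_n")
  o <- codon_counts(list(gene))
  L <- sum(o)
  m <- 0
  corr_df <- 0
  for (fam in names(fams)) {
    codons <- fams[[fam]]
    n_a <- sum(o[codons])
    if (n_a == 0) next
    f <- o[codons] / n_a
    e_fam <- e[codons]
    nz <- o[codons] > 0
    # codon observed in the gene but never in the background: fall
    # back to a half-count expectation instead of a zero divisor
    starved <- nz & e_fam == 0
    if (any(starved)) e_fam[starved] <- 0.5 / max(1, fam_n[[fam]])
    m <- m + 2 * sum(o[codons][nz] * log(f[nz] / e_fam[nz]))
    corr_df <- corr_df + (length(codons) - 1L)
  }
  m / L - (corr_df / L - 0.5)
}

#' Codon-usage bias of highly expressed genes vs genome background
#'
#' @param highly_expressed Character vector of nucleotide coding
#'   sequences (typically ribosomal protein genes). Trailing partial
#'   codons are trimmed.
#' @param background Character vector of nucleotide coding sequences
#'   (typically all genes of the genome).
#' @param min_genes Minimum number of highly expressed genes below
#'   which the result is flagged low-confidence (default 10).
#' @return List of class `"codon_usage_features"`: `statistic` (mean
#'   MILC), `per_gene` MILC values, `n_genes`, `baseline` (the exact
#'   no-bias value, averaged over the gene set) and `low_confidence`.
#' @export
codon_usage_bias <- function(highly_expressed, background,
                             min_genes = 10L) {
  if (length(highly_expressed) == 0L || length(background) == 0L) {
    stop("empty gene set", call. = FALSE)
  }
  trim <- function(x) {
    x <- toupper(x)
    substr(x, 1L, 3L * (nchar(x) %/% 3L))
  }
  highly_expressed <- trim(highly_expressed)
  background <- trim(background)
  if (any(nchar(highly_expressed) < 3L) || any(nchar(background) < 3L)) {
    stop("gene shorter than one codon after trimming", call. = FALSE)
  }
  e <- background_frequencies(codon_counts(background))
  per_gene <- vapply(highly_expressed, milc_gene, numeric(1L), e)
  baseline <- vapply(highly_expressed, function(g) {
    o <- codon_counts(list(g))
    fams <- codon_families()
    L <- sum(o)
    corr_df <- sum(vapply(fams, function(fam) {
      if (sum(o[fam]) > 0) length(fam) - 1L else 0L
    }, numeric(1L)))
    -(corr_df / L - 0.5)
  }, numeric(1L))
  structure(list(statistic = mean(per_gene),
                 per_gene = unname(per_gene),
                 n_genes = length(highly_expressed),
                 baseline = mean(baseline),
                 low_confidence = length(highly_expressed) < min_genes),
            class = "codon_usage_features")
}

#' Identify ribosomal-protein gene models in a manifest
#'
#' @param manifest An `"hmm_manifest"`.
#' @param pattern Regular expression on model names; the default
#'   matches standard large/small-subunit ribosomal protein gene
#'   symbols.
#' @return Character vector of model names.
#' @export
ribosomal_models <- function(manifest, pattern = "^(rpl|rps|rpm)") {
  manifest$hmm_name[grepl(pattern, manifest$hmm_name)]
}

# ---- compositional features for growth-temperature models ------------------

#' Compositional features of a genome and its proteome
#'
#' Deterministic, gene-order-invariant features used by optimal-growth-
#' temperature regression models: genome G+C fraction; ORF nucleotide
#' fractions (`orf_nt_a` etc.) and G+C; proteome amino-acid fractions
#' (`aa_A` ... `aa_Y`), the IVYWREL fraction (a classic thermophily
#' correlate) and the charged-residue (DEKR) fraction. Proteome-only
#' input yields only the protein-derived subset; the regression model
#' used downstream must then restrict itself to those features.
#'
#' @param genome A `"genome_record"` (may lack sequence for
#'   proteome-only input).
#' @param proteins A `"protein_set"`; ORF nucleotide features use its
#'   `cds` component when present.
#' @return Named numeric vector of features.
#' @export
extract_ogt_features <- function(genome = NULL, proteins) {
  stopifnot(inherits(proteins, "protein_set"))
  feats <- numeric(0L)
  letter_fracs <- function(seqs, alphabet, prefix) {
    all <- paste(toupper(seqs), collapse = "")
    if (nchar(all) == 0L) stop("empty sequence set", call. = FALSE)
    chars <- strsplit(all, "")[[1L]]
    tab <- table(factor(chars, levels = alphabet))
    stats::setNames(as.numeric(tab) / length(chars),
                    paste0(prefix, tolower(alphabet)))
  }
  if (!is.null(genome) && !is.null(genome$sequence)) {
    nt <- letter_fracs(genome$sequence, c("A", "C", "G", "T"), "genome_nt_")
    feats <- c(feats, genome_gc = unname(nt[["genome_nt_c"]] +
                                           nt[["genome_nt_g"]]), nt)
  }
  if (!is.null(proteins$cds)) {
    nt <- letter_fracs(proteins$cds, c("A", "C", "G", "T"), "orf_nt_")
    feats <- c(feats, orf_gc = unname(nt[["orf_nt_c"]] +
                                        nt[["orf_nt_g"]]), nt)
  }
  aa_alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  aa <- letter_fracs(proteins$proteins, aa_alpha, "aa_")
  names(aa) <- paste0("aa_", aa_alpha)
  ivywrel <- sum(aa[paste0("aa_", c("I", "V", "Y", "W", "R", "E", "L"))])
  charged <- sum(aa[paste0("aa_", c("D", "E", "K", "R"))])
  c(feats, aa, frac_ivywrel = ivywrel, frac_charged = charged)
}

# ---- pluggable linear models -----------------------------------------------

#' Read / apply a plain-text linear model file
#'
#' Model files are tab-separated `feature` / `weight` pairs with a
#' metadata header of `#key: value` lines after the
#' `#traitguilds-model v1` first line. Recognised keys: `response`,
#' `transform` (`identity` or `log` -- the model predicts on the log
#' scale and predictions are exponentiated), `units`, `statistic`,
#' `provenance`. The intercept is the `(intercept)` row.
#'
#' @param path Model file path.
#' @return A `"linear_model_spec"`: list with `coefficients` (named,
#'   excluding intercept), `intercept`, `transform`, `units`, `meta`.
#' @export
read_linear_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#traitguilds-model")) {
    stop("'", path, "' is not a model file (missing '#traitguilds-model' header)",
         call. = FALSE)
  }
  meta_lines <- grep("^#", lines[-1L], value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ml))[[1L]]
    if (length(kv) == 3L) meta[[kv[[2L]]]] <- kv[[3L]]
  }
  body <- lines[-1L][!startsWith(lines[-1L], "#")]
  df <- utils::read.delim(text = body)
  stopifnot(all(c("feature", "weight") %in% names(df)))
  ic <- df$feature == "(intercept)"
  transform <- if (is.null(meta$transform)) "identity" else meta$transform
  if (!transform %in% c("identity", "log")) {
    stop("unknown transform '", transform, "' in ", path, call. = FALSE)
  }
  structure(list(
    coefficients = stats::setNames(as.numeric(df$weight[!ic]),
                                   df$feature[!ic]),
    intercept = if (any(ic)) as.numeric(df$weight[ic][[1L]]) else 0,
    transform = transform,
    units = if (is.null(meta$units)) NA_character_ else meta$units,
    meta = meta), class = "linear_model_spec")
}

#' @rdname read_linear_model
#' @param features Named numeric feature vector; must cover every model
#'   coefficient.
#' @param model A `"linear_model_spec"`.
#' @return `predict_from_linear_model()` returns the predicted value
#'   (back-transformed), with attribute `units`.
#' @export
predict_from_linear_model <- function(features, model) {
  stopifnot(inherits(model, "linear_model_spec"))
  need <- names(model$coefficients)
  missing <- setdiff(need, names(features))
  if (length(missing) > 0L) {
    stop("features missing for model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept +
    sum(model$coefficients * as.numeric(features[need]))
  value <- switch(model$transform, identity = eta, log = exp(eta))
  attr(value, "units") <- model$units
  value
}

#' Packaged synthetic life-history model files
#'
#' Paths to the example model files shipped with the package. Their
#' coefficients are synthetic illustrations (see the file headers);
#' substitute your own trained model files for real predictions.
#'
#' @return Named character vector with elements `growth` and `ogt`.
#' @export
example_model_files <- function() {
  dir <- system.file("extdata", "models", package = "traitguilds",
                     mustWork = TRUE)
  c(growth = file.path(dir, "synthetic_growth_model.tsv"),
    ogt = file.path(dir, "synthetic_ogt_model.tsv"))
}

#' Predict life-history traits for one genome
#'
#' Ribosomal protein genes are located through the retained HMM hits to
#' the manifest's ribosomal models; their codon-usage bias feeds the
#' growth model, and compositional features feed the growth-temperature
#' model.
#'
#' @param genome A `"genome_record"`.
#' @param proteins A `"protein_set"` with `cds` sequences.
#' @param hits Filtered hit data frame ([filter_hits()]).
#' @param manifest An `"hmm_manifest"`.
#' @param growth_model,ogt_model `"linear_model_spec"` objects (or
#'   paths).
#' @param min_ribosomal Minimum ribosomal genes for a confident
#'   codon-usage estimate.
#' @return Named numeric vector `c(doubling_time_h, ogt_celsius)` with
#'   attribute `low_confidence`.
#' @export
life_history_traits <- function(genome, proteins, hits, manifest,
                                growth_model, ogt_model,
                                min_ribosomal = 10L) {
  if (is.character(growth_model)) growth_model <- read_linear_model(growth_model)
  if (is.character(ogt_model)) ogt_model <- read_linear_model(ogt_model)
  if (is.null(proteins$cds)) {
    stop("protein set lacks nucleotide CDS; codon usage needs them",
         call. = FALSE)
  }
  ribo <- ribosomal_models(manifest)
  ribo_prot <- unique(hits$protein_id[hits$genome_id == proteins$genome_id &
                                        hits$hmm_name %in% ribo])
  ribo_prot <- intersect(ribo_prot, names(proteins$cds))
  if (length(ribo_prot) == 0L) {
    stop("no ribosomal protein genes found for ", proteins$genome_id,
         call. = FALSE)
  }
  cub <- codon_usage_bias(proteins$cds[ribo_prot], proteins$cds,
                          min_genes = min_ribosomal)
  feats <- c(extract_ogt_features(genome, proteins),
             cub_milc = cub$statistic,
             n_ribosomal = cub$n_genes)
  out <- c(doubling_time_h = as.numeric(
             predict_from_linear_model(feats, growth_model)),
           ogt_celsius = as.numeric(
             predict_from_linear_model(feats, ogt_model)))
  attr(out, "low_confidence") <- cub$low_confidence
  out
}
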