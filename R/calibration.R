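#' @title Trusted-cutoff calibration by F-score maximisation
#'
#' @description
#' Every profile HMM gets a per-model trusted bit-score cutoff chosen on
#' a labelled benchmark: sequences known to belong to the family
#' (positives) and sequences known not to (negatives) are scored with
#' `hmmsearch`, precision/recall/F are computed at every observed score,
#' and the smallest score that maximises the F-score becomes the trusted
#' cutoff. Negatives that the search engine never reported (below its
#' reporting floor) are accounted for through `n_negatives_total`, so
#' false-positive rates use the full negative set.
#'
#' @name hmm_calibration
NULL

#' Labelled bit-score set for one model
#'
#' @param model Model name.
#' @param positive_scores Bit scores of true-positive sequences (at
#'   least one).
#' @param negative_scores Bit scores of reported true-negative
#'   sequences; negatives the engine did not report are implicitly below
#'   every threshold.
#' @param n_negatives_total Total number of negatives scanned; defaults
#'   to `length(negative_scores)`.
#' @return A `"labeled_score_set"`.
#' @export
labeled_score_set <- function(model, positive_scores,
                              negative_scores = numeric(0L),
                              n_negatives_total = length(negative_scores)) {
  positive_scores <- as.numeric(positive_scores)
  negative_scores <- as.numeric(negative_scores)
  if (length(positive_scores) == 0L || anyNA(positive_scores)) {
    stop("need at least one positive score (no NAs)", call. = FALSE)
  }
  if (n_negatives_total < length(negative_scores)) {
    stop("n_negatives_total < number of reported negative scores",
         call. = FALSE)
  }
  structure(list(model = model, positive_scores = positive_scores,
                 negative_scores = negative_scores,
                 n_negatives_total = as.integer(n_negatives_total)),
            class = "labeled_score_set")
}

#' Read a labelled score file
#'
#' @param path Tab-separated file with columns `sequence_id`, `label`
#'   (`pos`/`neg`) and `bitscore` (`.` for a scanned-but-unreported
#'   negative).
#' @param model Model name; defaults to the file name without
#'   extension.
#' @return A `"labeled_score_set"`.
#' @export
read_score_set <- function(path, model = NULL) {
  if (is.null(model)) model <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("sequence_id", "label", "bitscore") %in% names(df)))
  if (!all(df$label %in% c("pos", "neg"))) {
    stop("labels must be 'pos' or 'neg' in ", path, call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(ifelse(df$bitscore == ".",
                                              NA, df$bitscore)))
  pos <- score[df$label == "pos"]
  if (anyNA(pos)) stop("positives must all have scores in ", path,
                       call. = FALSE)
  neg_all <- df$label == "neg"
  neg <- score[neg_all & !is.na(score)]
  labeled_score_set(model, pos, neg, n_negatives_total = sum(neg_all))
}

#' Precision/recall/F curve over observed score thresholds
#'
#' Candidate thresholds are the observed score values (F is piecewise
#' constant between them). At threshold `t`: `TP = #positives >= t`,
#' `FP = #reported negatives >= t`, `FN = #positives < t`,
#' `TN = n_negatives_total - FP`. Precision is undefined when
#' `TP + FP = 0` (returned as `NA`, excluded from cutoff selection).
#'
#' @param scores A `"labeled_score_set"`.
#' @return Data frame of class `"threshold_curve"` with columns
#'   `threshold`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f`,
#'   `fpr`, sorted by increasing threshold; attribute `model`.
#' @export
threshold_metrics <- function(scores) {
  stopifnot(inherits(scores, "labeled_score_set"))
  pos <- scores$positive_scores
  neg <- scores$negative_scores
  n_neg <- scores$n_negatives_total
  thresholds <- sort(unique(c(pos, neg)))
  tp <- vapply(thresholds, function(t) sum(pos >= t), numeric(1L))
  fp <- vapply(thresholds, function(t) sum(neg >= t), numeric(1L))
  fn <- length(pos) - tp
  tn <- n_neg - fp
  precision <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  recall <- tp / length(pos)
  f <- ifelse(is.na(precision) | precision + recall == 0, NA_real_,
              2 * precision * recall / (precision + recall))
  f[!is.na(precision) & precision + recall == 0] <- 0
  fpr <- if (n_neg > 0L) fp / n_neg else rep(0, length(fp))
  out <- data.frame(threshold = thresholds, tp = tp, fp = fp, fn = fn,
                    tn = tn, precision = precision, recall = recall,
                    f = f, fpr = fpr)
  attr(out, "model") <- scores$model
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Select the trusted cutoff from a threshold curve
#'
#' The trusted cutoff is the smallest threshold that maximises the
#' F-score. Thresholds where precision is undefined (`TP + FP = 0`) are
#' excluded from the argmax. If no threshold attains a positive,
#' defined F, the model is reported as uncalibratable.
#'
#' @param curve A `"threshold_curve"`.
#' @return A `"trusted_cutoff"`: list with `model`, `cutoff`, `f`,
#'   `sensitivity`, `fpr` and logical `calibratable`.
#' @export
select_trusted_cutoff <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"), nrow(curve) > 0L)
  model <- attr(curve, "model")
  ok <- !is.na(curve$f)
  if (!any(ok) || max(curve$f[ok]) <= 0) {
    return(structure(list(model = model, cutoff = NA_real_, f = NA_real_,
                          sensitivity = NA_real_, fpr = NA_real_,
                          calibratable = FALSE),
                     class = "trusted_cutoff"))
  }
  fmax <- max(curve$f[ok])
  # exact rational ties in F can differ by an ulp depending on the
  # evaluation route; treat scores within 1e-9 of the max as tied so
  # the smallest tied threshold wins, as the selection rule requires
  at_max <- which(ok & curve$f >= fmax - 1e-9)
  best <- at_max[which.min(curve$threshold[at_max])]
  structure(list(model = model, cutoff = curve$threshold[[best]],
                 f = curve$f[[best]], sensitivity = curve$recall[[best]],
                 fpr = curve$fpr[[best]], calibratable = TRUE),
            class = "trusted_cutoff")
}

#' @export
print.trusted_cutoff <- function(x, ...) {
  if (x$calibratable) {
    cat(sprintf("<trusted cutoff> %s: %.2f bits (F=%.3f, sens=%.3f, FPR=%.3g)\n",
                x$model, x$cutoff, x$f, x$sensitivity, x$fpr))
  } else {
    cat(sprintf("<trusted cutoff> %s: uncalibratable\n", x$model))
  }
  invisible(x)
}

#' Summarise calibration performance across models
#'
#' @param cutoffs List of `"trusted_cutoff"` objects.
#' @param sensitivity_min,f_min Aggregate thresholds reported as the
#'   fraction of calibratable models meeting them.
#' @return List with `table` (per-model data frame: `hmm_name`,
#'   `trusted_cutoff`, `f`, `sensitivity`, `fpr`, `calibratable`) and
#'   `aggregate` (named fractions `frac_sensitivity_ge`, `frac_f_ge`,
#'   plus the thresholds used and model counts).
#' @export
summarize_performance <- function(cutoffs, sensitivity_min = 0.75,
                                  f_min = 0.8) {
  if (length(cutoffs) == 0L) {
    tab <- data.frame(hmm_name = character(0L),
                      trusted_cutoff = numeric(0L), f = numeric(0L),
                      sensitivity = numeric(0L), fpr = numeric(0L),
                      calibratable = logical(0L))
    return(list(table = tab,
                aggregate = list(n_models = 0L, n_calibratable = 0L,
                                 sensitivity_min = sensitivity_min,
                                 f_min = f_min,
                                 frac_sensitivity_ge = NA_real_,
                                 frac_f_ge = NA_real_)))
  }
  stopifnot(all(vapply(cutoffs, inherits, logical(1L), "trusted_cutoff")))
  tab <- data.frame(
    hmm_name = vapply(cutoffs, `[[`, "", "model"),
    trusted_cutoff = vapply(cutoffs, `[[`, 0, "cutoff"),
    f = vapply(cutoffs, `[[`, 0, "f"),
    sensitivity = vapply(cutoffs, `[[`, 0, "sensitivity"),
    fpr = vapply(cutoffs, `[[`, 0, "fpr"),
    calibratable = vapply(cutoffs, `[[`, NA, "calibratable"),
    stringsAsFactors = FALSE
  )
  cal <- tab[tab$calibratable, , drop = FALSE]
  list(table = tab,
       aggregate = list(
         n_models = nrow(tab), n_calibratable = nrow(cal),
         sensitivity_min = sensitivity_min, f_min = f_min,
         frac_sensitivity_ge = mean(cal$sensitivity >= sensitivity_min),
         frac_f_ge = mean(cal$f >= f_min)))
}

#' Write a manifest-compatible cutoff table
#'
#' @param summary Output of [summarize_performance()].
#' @param path Output path (tab-separated: `hmm_name`,
#'   `trusted_cutoff`, `f`, `sensitivity`, `fpr`).
#' @export
write_cutoff_table <- function(summary, path) {
  tab <- summary$table
  tab$trusted_cutoff <- ifelse(is.na(tab$trusted_cutoff), ".",
                               format(tab$trusted_cutoff, trim = TRUE))
  utils::write.table(tab[, c("hmm_name", "trusted_cutoff", "f",
                             "sensitivity", "fpr")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- profile building (HMMER/hmmbuild) -------------------------------------

#' Build a profile HMM from a seed alignment
#'
#' Delegates alignment-to-profile training to HMMER/`hmmbuild`. The
#' input is an aligned FASTA (all sequences the same length, gaps as
#' `-`); the output profile is loadable by [scan_proteins()].
#'
#' @param msa Named character vector of aligned amino-acid sequences, or
#'   a path to an aligned FASTA file.
#' @param name Model name recorded in the profile.
#' @param out Output path for the HMMER3 ASCII profile; defaults to a
#'   temporary file.
#' @return Path to the profile file, with attribute `length` (number of
#'   match states reported by the engine).
#' @export
build_hmm_from_seed_alignment <- function(msa, name, out = tempfile(fileext = ".hmm")) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    aln <- Biostrings::readAAMultipleAlignment(msa, format = "fasta")
    msa <- as.character(aln)
  }
  msa <- toupper(as.character(msa))
  if (length(msa) < 2L) {
    stop("seed alignment needs at least 2 sequences", call. = FALSE)
  }
  if (length(unique(nchar(msa))) != 1L) {
    stop("ragged alignment: sequences differ in aligned length",
         call. = FALSE)
  }
  if (is.null(names(msa))) names(msa) <- sprintf("seq%d", seq_along(msa))
  require_tool("hmmbuild")
  tmp_aln <- tempfile(fileext = ".afa")
  on.exit(unlink(tmp_aln))
  writeLines(paste0(">", names(msa), "\n", msa), tmp_aln)
  log <- system2("hmmbuild",
                 c("--amino", "-n", name, out, tmp_aln),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(log, "status")) || !file.exists(out)) {
    stop("hmmbuild failed:\n", paste(log, collapse = "\n"), call. = FALSE)
  }
  leng <- NA_integer_
  hdr <- readLines(out, n = 20L)
  lline <- grep("^LENG", hdr, value = TRUE)
  if (length(lline) == 1L) {
    leng <- as.integer(sub("^LENG\\s+", "", lline))
  }
  attr(out, "length") <- leng
  out
}

#' Concatenate single-model profile files into one library
#'
#' @param profiles Character vector of profile file paths.
#' @param out Output library path.
#' @return `out`.
#' @export
concat_hmm_library <- function(profiles, out) {
  writeLines(unlist(lapply(profiles, readLines)), out)
  invisible(out)
}
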