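#' @title Trait matrices: genomes x traits at three granularities
#'
#' @description
#' The genome-level output of the pipeline is a trait matrix mixing
#' binary traits (presence/absence of a functional capacity, the bound
#' rule's assertion) and count traits (substrate-class-resolved complex
#' counts divided by genome length in base pairs -- per-base-pair
#' genomic investments). Traits live at the most granular level of a
#' three-level hierarchy; coarser matrices are obtained by rolling
#' children up into parents (binary: OR; count: sum).
#'
#' Normalised counts are stored per bp exactly; a per-Mbp display scale
#' is presentation only and never changes stored values.
#'
#' @name trait_matrices
NULL

new_trait_matrix <- function(values, value_type, strategy, granularity,
                             path = NULL) {
  stopifnot(is.matrix(values), length(value_type) == ncol(values),
            length(strategy) == ncol(values))
  structure(values, value_type = value_type, strategy = strategy,
            granularity = as.integer(granularity), path = path,
            class = c("trait_matrix", "matrix"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait matrix> %d genomes x %d traits (granularity %d; %d binary, %d count)\n",
              nrow(x), ncol(x), attr(x, "granularity"),
              sum(attr(x, "value_type") == "binary"),
              sum(attr(x, "value_type") == "count")))
  invisible(x)
}

#' Binary trait columns from rule assertions
#'
#' @param assertions A `"rule_assertion_matrix"`.
#' @param traits A `"trait_hierarchy"`; only rows with
#'   `value_type == "binary"` are used. Each binary trait's value is the
#'   assertion of its bound rule (0/1).
#' @return Numeric matrix (genomes x binary traits).
#' @export
binary_traits <- function(assertions, traits) {
  bt <- traits[traits$value_type == "binary", , drop = FALSE]
  cols <- vapply(seq_len(nrow(bt)), function(i) {
    b <- bt$binding[[i]]
    if (length(b) != 1L || !(b %in% colnames(assertions))) {
      stop("binary trait '", bt$name[[i]], "' has unresolved binding",
           call. = FALSE)
    }
    as.numeric(assertions[, b])
  }, numeric(nrow(assertions)))
  cols <- matrix(cols, nrow = nrow(assertions),
                 dimnames = list(rownames(assertions), bt$name))
  cols
}

#' Count trait columns normalised by genome size
#'
#' Each count trait is a substrate-class count (see
#' [count_substrate_class()]) divided by the genome length in base
#' pairs.
#'
#' @param table A `"gene_count_table"`.
#' @param manifest An `"hmm_manifest"`.
#' @param rules A `"ruleset"` providing complex definitions.
#' @param traits A `"trait_hierarchy"`; only `value_type == "count"`
#'   rows are used.
#' @param size_bp Named numeric vector of genome sizes in bp; defaults
#'   to the `size_bp` attribute of `table`.
#' @param unknown_size Policy when a genome size is missing: `"error"`
#'   (default) or `"raw"` (leave the raw count, with a warning).
#' @return Numeric matrix (genomes x count traits), values per bp.
#' @export
count_traits <- function(table, manifest, rules, traits, size_bp = NULL,
                         unknown_size = c("error", "raw")) {
  unknown_size <- match.arg(unknown_size)
  if (is.null(size_bp)) size_bp <- attr(table, "size_bp")
  genomes <- rownames(table)
  if (is.null(size_bp)) size_bp <- rep(NA_real_, length(genomes))
  size_bp <- as.numeric(size_bp)[match(genomes, names(size_bp))]
  if (anyNA(size_bp) || any(size_bp <= 0, na.rm = TRUE)) {
    if (unknown_size == "error") {
      stop("genome size unknown or non-positive for: ",
           paste(genomes[is.na(size_bp) | size_bp <= 0], collapse = ", "),
           call. = FALSE)
    }
    warning("genomes without a size keep raw (unnormalised) counts",
            call. = FALSE)
    size_bp[is.na(size_bp) | size_bp <= 0] <- 1
  }
  ct <- traits[traits$value_type == "count", , drop = FALSE]
  counts <- unclass(table)
  rule_names <- vapply(rules, `[[`, "", "name")
  lookup <- lapply(rules, `[[`, "expression")
  names(lookup) <- rule_names
  getcount <- function(var) {
    if (var %in% colnames(counts)) counts[, var] else
      rep(0L, nrow(counts))
  }
  cols <- vapply(seq_len(nrow(ct)), function(i) {
    # binding is authoritative: bound rules contribute as complexes
    # (max over alternative forms of min over subunits), bound gene
    # families as one-subunit complexes (their raw counts)
    raw <- rep(0, length(genomes))
    for (b in ct$binding[[i]]) {
      if (b %in% rule_names) {
        forms <- rule_expr_complex_forms(lookup[[b]], lookup)
        per_form <- vapply(forms, function(vars) {
          as.numeric(do.call(pmin, lapply(vars, getcount)))
        }, numeric(length(genomes)))
        per_form <- matrix(per_form, nrow = length(genomes))
        raw <- raw + apply(per_form, 1L, max)
      } else {
        raw <- raw + as.numeric(getcount(b))
      }
    }
    raw / size_bp
  }, numeric(length(genomes)))
  cols <- matrix(cols, nrow = length(genomes),
                 dimnames = list(genomes, ct$name))
  cols
}

#' Assemble the granularity-3 trait matrix
#'
#' @param assertions A `"rule_assertion_matrix"`.
#' @param table A `"gene_count_table"`.
#' @param schema A schema list as returned by [example_schema()]
#'   (elements `manifest`, `rules`, `hierarchy`, `compiled`).
#' @param size_bp,unknown_size Passed to [count_traits()].
#' @return A `"trait_matrix"` at granularity 3, columns ordered as in
#'   the hierarchy.
#' @export
build_trait_matrix <- function(assertions, table, schema, size_bp = NULL,
                               unknown_size = "error") {
  hier <- schema$hierarchy
  bin <- binary_traits(assertions, hier)
  cnt <- count_traits(table, schema$manifest, schema$rules, hier,
                      size_bp = size_bp, unknown_size = unknown_size)
  values <- cbind(bin, cnt)[, hier$name, drop = FALSE]
  new_trait_matrix(values, hier$value_type, hier$strategy, 3L,
                   path = hier[, c("level1", "level2", "level3")])
}

#' Roll a granularity-3 trait matrix up the hierarchy
#'
#' Parents aggregate their children: OR for binary traits, sum for
#' count traits (so a granularity-1 count trait equals the sum of its
#' granularity-3 descendants). Binary and count children under the same
#' parent are not mixed; each parent inherits its children's common
#' value type.
#'
#' @param matrix A granularity-3 `"trait_matrix"` with a `path`
#'   attribute.
#' @param granularity Target level, 1 or 2.
#' @return A `"trait_matrix"` at the requested granularity.
#' @export
rollup <- function(matrix, granularity) {
  stopifnot(inherits(matrix, "trait_matrix"),
            attr(matrix, "granularity") == 3L,
            granularity %in% c(1L, 2L))
  path <- attr(matrix, "path")
  if (is.null(path)) stop("trait matrix lacks hierarchy paths", call. = FALSE)
  key <- if (granularity == 1L) path$level1 else
    paste(path$level1, path$level2, sep = " > ")
  vt <- attr(matrix, "value_type")
  st <- attr(matrix, "strategy")
  groups <- split(seq_len(ncol(matrix)), factor(key, levels = unique(key)))

  cols <- lapply(groups, function(idx) {
    types <- unique(vt[idx])
    if (length(types) != 1L) {
      stop("mixed binary/count children under parent '",
           key[idx[[1L]]], "'", call. = FALSE)
    }
    block <- unclass(matrix)[, idx, drop = FALSE]
    if (types == "binary") as.numeric(rowSums(block) > 0) else
      rowSums(block)
  })
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(matrix)
  parent_vt <- vapply(groups, function(idx) vt[idx[[1L]]], "")
  parent_st <- vapply(groups, function(idx) st[idx[[1L]]], "")
  new_trait_matrix(values, parent_vt, parent_st, granularity)
}

#' Write a trait matrix with a two-row header
#'
#' The first header row carries trait names, the second the ecological
#' strategy of each trait.
#'
#' @param matrix A `"trait_matrix"`.
#' @param path Output path (tab-separated).
#' @export
write_trait_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("trait", colnames(matrix)), collapse = "\t"), con)
  writeLines(paste(c("strategy", attr(matrix, "strategy")),
                   collapse = "\t"), con)
  vals <- unclass(matrix)
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(c(rownames(vals)[i],
                       format(vals[i, ], trim = TRUE, digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
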