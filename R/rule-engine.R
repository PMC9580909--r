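#' @title Evaluating rules against gene content
#'
#' @description
#' A compiled ruleset is evaluated per genome against the Boolean
#' presence of its gene families (`count > 0`). Rules referencing other
#' rules are substituted by their computed values, which is well defined
#' because compilation ordered them topologically. Gene families in the
#' ruleset closure that are missing from the input presence vector
#' default to `FALSE` with a warning, so provisional genomes (MAGs,
#' SAGs) with sparse detections still evaluate.
#'
#' @name rule_engine
NULL

#' Evaluate a compiled ruleset for one genome
#'
#' @param ruleset A `"compiled_ruleset"`.
#' @param presence Named logical vector of gene-family presence.
#' @param warn_missing Warn when closure variables are absent from
#'   `presence` (they default to `FALSE`).
#' @return Named logical vector over rules, in evaluation order.
#' @export
evaluate_rules <- function(ruleset, presence, warn_missing = TRUE) {
  stopifnot(inherits(ruleset, "compiled_ruleset"))
  presence <- vapply(presence, isTRUE, logical(1L))
  missing <- setdiff(ruleset$closure, names(presence))
  if (length(missing) > 0L) {
    if (warn_missing) {
      warning("gene families absent from presence vector default to FALSE: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
    presence[missing] <- FALSE
  }
  values <- as.list(presence)
  out <- logical(length(ruleset$order))
  names(out) <- ruleset$order
  for (nm in ruleset$order) {
    v <- rule_expr_eval(ruleset$rules[[nm]]$expression, values)
    values[[nm]] <- v
    out[[nm]] <- v
  }
  out
}

#' Genomes-by-rules assertion matrix
#'
#' Row `g` is [evaluate_rules()] applied to the presence row of genome
#' `g` in the count table.
#'
#' @param ruleset A `"compiled_ruleset"`.
#' @param table A `"gene_count_table"` (or logical/integer matrix,
#'   genomes x gene families).
#' @return Logical matrix (genomes x rules) of class
#'   `"rule_assertion_matrix"`.
#' @export
assert_matrix <- function(ruleset, table) {
  pres <- if (inherits(table, "gene_count_table")) presence_matrix(table)
          else unclass(table) > 0
  missing <- setdiff(ruleset$closure, colnames(pres))
  if (length(missing) > 0L) {
    warning("gene families absent from count table default to FALSE: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(pres)), function(i) {
    evaluate_rules(ruleset, pres[i, ], warn_missing = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- rownames(pres)
  structure(out, class = c("rule_assertion_matrix", class(out)))
}

#' Write an assertion matrix as tab-separated text
#'
#' @param assertions A `"rule_assertion_matrix"`.
#' @param path Output path.
#' @export
write_assertion_matrix <- function(assertions, path) {
  df <- data.frame(genome_id = rownames(assertions),
                   as.data.frame(unclass(assertions) * 1L,
                                 check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- substrate-class complex counting --------------------------------------

# Decompose a negation-free expression into alternative complex forms:
# a list of character vectors of required subunit variables (OR
# distributes over AND). Rule references are expanded via `lookup`.
rule_expr_complex_forms <- function(e, lookup = list()) {
  switch(e$type,
    ref = {
      if (!is.null(lookup[[e$name]])) {
        rule_expr_complex_forms(lookup[[e$name]], lookup)
      } else {
        list(e$name)
      }
    },
    not = stop("NOT is not meaningful in complex counting", call. = FALSE),
    or = unlist(lapply(e$args, rule_expr_complex_forms, lookup),
                recursive = FALSE),
    and = {
      parts <- lapply(e$args, rule_expr_complex_forms, lookup)
      Reduce(function(acc, forms) {
        unlist(lapply(acc, function(a) {
          lapply(forms, function(f) unique(c(a, f)))
        }), recursive = FALSE)
      }, parts[-1L], init = parts[[1L]])
    }
  )
}

#' Count substrate-class-resolved complexes per genome
#'
#' A functional complex needs all of its subunits, so one complex
#' definition contributes `min` over its required subunit gene-family
#' counts; alternative complex forms of the same rule (OR branches,
#' e.g. two interchangeable nitrate reductases) contribute the `max`
#' across forms, since they realise the same function. Gene families
#' annotated to the class in the manifest but not referenced by any
#' counted complex definition count as one-subunit complexes (their raw
#' count).
#'
#' @param table A `"gene_count_table"`.
#' @param manifest An `"hmm_manifest"` carrying substrate annotations.
#' @param complex_defs A `"ruleset"` (or list of `"trait_rule"`) whose
#'   rules tagged with `substrate_class` define multi-subunit
#'   complexes.
#' @param class_name Substrate class to count.
#' @return Named integer vector (one count per genome).
#' @export
count_substrate_class <- function(table, manifest, complex_defs,
                                  class_name) {
  stopifnot(inherits(manifest, "hmm_manifest"))
  subs <- manifest_substrate_table(manifest)
  known_classes <- unique(c(subs$substrate_class,
                            vapply(complex_defs, `[[`, "",
                                   "substrate_class")))
  if (!class_name %in% known_classes) {
    stop("unknown substrate class: ", class_name, call. = FALSE)
  }
  counts <- unclass(table)
  getcount <- function(var) {
    if (var %in% colnames(counts)) counts[, var] else
      rep(0L, nrow(counts))
  }

  defs <- Filter(function(r) identical(r$substrate_class, class_name),
                 complex_defs)
  lookup <- lapply(complex_defs, `[[`, "expression")
  names(lookup) <- vapply(complex_defs, `[[`, "", "name")

  total <- rep(0, nrow(counts))
  used_vars <- character(0L)
  for (r in defs) {
    forms <- rule_expr_complex_forms(r$expression, lookup)
    per_form <- vapply(forms, function(vars) {
      do.call(pmin, lapply(vars, getcount))
    }, numeric(nrow(counts)))
    per_form <- matrix(per_form, nrow = nrow(counts))
    total <- total + apply(per_form, 1L, max)
    used_vars <- c(used_vars, unlist(forms))
  }

  standalone <- setdiff(subs$hmm_name[subs$substrate_class == class_name],
                        used_vars)
  for (var in standalone) total <- total + getcount(var)
  stats::setNames(as.integer(total), rownames(counts))
}

#' Substrate-class count matrix over several classes
#'
#' @param table A `"gene_count_table"`.
#' @param manifest An `"hmm_manifest"`.
#' @param complex_defs A `"ruleset"` of complex definitions.
#' @param classes Substrate classes; defaults to every class annotated
#'   in the manifest or the complex definitions.
#' @return Integer matrix (genomes x classes).
#' @export
substrate_class_counts <- function(table, manifest, complex_defs,
                                   classes = NULL) {
  if (is.null(classes)) {
    classes <- sort(unique(c(
      manifest_substrate_table(manifest)$substrate_class,
      stats::na.omit(vapply(complex_defs, `[[`, "", "substrate_class")))))
  }
  out <- vapply(classes, function(cl) {
    count_substrate_class(table, manifest, complex_defs, cl)
  }, integer(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), classes))
  out
}
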