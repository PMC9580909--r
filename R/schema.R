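#' @title Gene-family manifests, rulesets and the trait hierarchy
#'
#' @description
#' Three plain-text documents define a trait schema:
#'
#' * the **HMM manifest**: one row per profile-HMM gene family, with its
#'   trusted bit-score cutoff, optional database cross-references and
#'   optional `substrate:substrate_class` annotations;
#' * the **rules file**: named Boolean expressions over gene families
#'   and/or other rules (see [parse_rule_expression()]), optionally tagged
#'   with a substrate class when the rule describes a transporter/enzyme
#'   complex used for substrate-class counting;
#' * the **trait hierarchy**: one row per trait at the most granular
#'   level, with its three-level hierarchy path, ecological strategy,
#'   value type (`binary` or `count`) and the rule(s)/variable(s) it is
#'   bound to.
#'
#' All three are tab-separated files whose first line is a versioned
#' header of the form `#traitguilds-<kind> v1`.
#'
#' @name trait_schema
NULL

SCHEMA_FORMAT_VERSION <- "v1"

# ---- HMM manifest -----------------------------------------------------------

#' Construct an HMM manifest
#'
#' @param hmm_name Character vector of unique gene-family (profile HMM)
#'   names.
#' @param trusted_cutoff Numeric vector of per-model trusted bit-score
#'   cutoffs; `NA` marks an uncalibrated model. Finite and > 0 when set.
#' @param cross_refs Optional list (one element per model) of character
#'   vectors of external identifiers (orthology group, transporter class,
#'   EC number).
#' @param substrates Optional list (one element per model) of data frames
#'   with columns `substrate` and `substrate_class`.
#' @return A data frame of class `"hmm_manifest"`.
#' @export
hmm_manifest <- function(hmm_name, trusted_cutoff = NA_real_,
                         cross_refs = NULL, substrates = NULL) {
  hmm_name <- as.character(hmm_name)
  n <- length(hmm_name)
  if (n == 0L) stop("manifest needs at least one model", call. = FALSE)
  if (anyDuplicated(hmm_name)) {
    stop("duplicate hmm_name in manifest: ",
         paste(unique(hmm_name[duplicated(hmm_name)]), collapse = ", "),
         call. = FALSE)
  }
  trusted_cutoff <- rep_len(as.numeric(trusted_cutoff), n)
  bad <- !is.na(trusted_cutoff) & (!is.finite(trusted_cutoff) | trusted_cutoff <= 0)
  if (any(bad)) {
    stop("trusted_cutoff must be finite and > 0 when set: ",
         paste(hmm_name[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(cross_refs)) cross_refs <- rep(list(character(0L)), n)
  if (is.null(substrates)) {
    substrates <- rep(list(data.frame(substrate = character(0L),
                                      substrate_class = character(0L))), n)
  }
  stopifnot(length(cross_refs) == n, length(substrates) == n)
  out <- data.frame(hmm_name = hmm_name, trusted_cutoff = trusted_cutoff,
                    stringsAsFactors = FALSE)
  out$cross_refs <- cross_refs
  out$substrates <- substrates
  class(out) <- c("hmm_manifest", "data.frame")
  out
}

schema_read_lines <- function(path, kind) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  header <- sprintf("#traitguilds-%s", kind)
  if (!startsWith(lines[[1L]], header)) {
    stop(sprintf("'%s' does not look like a %s file (missing '%s' header)",
                 path, kind, header), call. = FALSE)
  }
  lines[-1L]
}

split_multi <- function(x) {
  if (is.na(x) || x == "." || !nzchar(x)) character(0L) else
    strsplit(x, ";", fixed = TRUE)[[1L]]
}

join_multi <- function(x) if (length(x) == 0L) "." else paste(x, collapse = ";")

#' Read / write an HMM manifest file
#'
#' @param path Path to a tab-separated manifest file with columns
#'   `hmm_name`, `trusted_cutoff` (`.` for unset), `cross_refs`
#'   (semicolon-separated, `.` for none) and `substrates`
#'   (semicolon-separated `substrate:substrate_class` pairs, `.` for
#'   none).
#' @return An `"hmm_manifest"` data frame.
#' @export
read_hmm_manifest <- function(path) {
  body <- schema_read_lines(path, "manifest")
  df <- utils::read.delim(text = body, colClasses = "character")
  cutoff <- suppressWarnings(as.numeric(ifelse(df$trusted_cutoff == ".",
                                               NA, df$trusted_cutoff)))
  xr <- lapply(df$cross_refs, split_multi)
  subs <- lapply(df$substrates, function(s) {
    pairs <- split_multi(s)
    if (length(pairs) == 0L) {
      return(data.frame(substrate = character(0L),
                        substrate_class = character(0L)))
    }
    parts <- strsplit(pairs, ":", fixed = TRUE)
    data.frame(substrate = vapply(parts, `[`, "", 1L),
               substrate_class = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
  hmm_manifest(df$hmm_name, cutoff, xr, subs)
}

#' @rdname read_hmm_manifest
#' @param manifest An `"hmm_manifest"` object.
#' @export
write_hmm_manifest <- function(manifest, path) {
  df <- data.frame(
    hmm_name = manifest$hmm_name,
    trusted_cutoff = ifelse(is.na(manifest$trusted_cutoff), ".",
                            format(manifest$trusted_cutoff, trim = TRUE)),
    cross_refs = vapply(manifest$cross_refs, join_multi, ""),
    substrates = vapply(manifest$substrates, function(s) {
      join_multi(paste(s$substrate, s$substrate_class, sep = ":"))
    }, ""),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#traitguilds-manifest %s", SCHEMA_FORMAT_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Substrate annotations of the manifest as one long data frame
manifest_substrate_table <- function(manifest) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- manifest$substrates[[i]]
    if (nrow(s) == 0L) return(NULL)
    cbind(hmm_name = manifest$hmm_name[[i]], s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(hmm_name = character(0L), substrate = character(0L),
                      substrate_class = character(0L))
  }
  out
}

# ---- rules ------------------------------------------------------------------

#' Construct a rule or a ruleset
#'
#' A rule is a named Boolean expression over gene-family variables and/or
#' other rules. `substrate_class` optionally tags the rule as a
#' transporter/enzyme complex definition used by
#' [count_substrate_class()].
#'
#' @param name Unique rule name.
#' @param expression A `rule_expr` or a string parsed with
#'   [parse_rule_expression()].
#' @param substrate_class Optional substrate class tag (`NA` for none).
#' @return `rule()` returns a `"trait_rule"` object; `ruleset()` a named
#'   list of them with class `"ruleset"`.
#' @export
rule <- function(name, expression, substrate_class = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(expression)) expression <- parse_rule_expression(expression)
  stopifnot(inherits(expression, "rule_expr"))
  structure(list(name = name, expression = expression,
                 substrate_class = as.character(substrate_class)),
            class = "trait_rule")
}

#' @rdname rule
#' @param ... `trait_rule` objects (or one list of them).
#' @export
ruleset <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && !inherits(rules[[1L]], "trait_rule")) {
    rules <- rules[[1L]]
  }
  stopifnot(all(vapply(rules, inherits, logical(1L), "trait_rule")))
  nm <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate rule names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(rules) <- nm
  structure(rules, class = "ruleset")
}

#' Read / write a rules file
#'
#' @param path Tab-separated rules file with columns `rule_name`,
#'   `expression` and `substrate_class` (`.` for none).
#' @return A `"ruleset"`.
#' @export
read_rules <- function(path) {
  body <- schema_read_lines(path, "rules")
  df <- utils::read.delim(text = body, colClasses = "character")
  ruleset(lapply(seq_len(nrow(df)), function(i) {
    sc <- df$substrate_class[[i]]
    rule(df$rule_name[[i]], df$expression[[i]],
         if (sc == "." || !nzchar(sc)) NA_character_ else sc)
  }))
}

#' @rdname read_rules
#' @param rules A `"ruleset"`.
#' @export
write_rules <- function(rules, path) {
  df <- data.frame(
    rule_name = vapply(rules, `[[`, "", "name"),
    expression = vapply(rules, function(r) format(r$expression), ""),
    substrate_class = vapply(rules, function(r) {
      if (is.na(r$substrate_class)) "." else r$substrate_class
    }, ""),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#traitguilds-rules %s", SCHEMA_FORMAT_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- compilation ------------------------------------------------------------

#' Compile a ruleset against an HMM manifest
#'
#' Resolves every leaf reference either to another rule or to a
#' gene-family variable of the manifest, orders the rules topologically
#' so that a rule is always evaluated after the rules it references, and
#' computes the closure of gene-family variables the ruleset depends on.
#' Compilation is deterministic given identical input order (stable
#' Kahn's algorithm).
#'
#' @param rules A `"ruleset"`.
#' @param manifest An `"hmm_manifest"`.
#' @return A `"compiled_ruleset"`: list with elements `rules` (in
#'   evaluation order), `order` (rule names), `index` (name -> position),
#'   `closure` (gene-family names used) and `manifest`.
#' @export
compile_ruleset <- function(rules, manifest) {
  stopifnot(inherits(rules, "ruleset"), inherits(manifest, "hmm_manifest"))
  rule_names <- names(rules)
  var_names <- manifest$hmm_name

  deps <- lapply(rules, function(r) {
    refs <- rule_expr_vars(r$expression)
    unknown <- setdiff(refs, c(rule_names, var_names))
    if (length(unknown) > 0L) {
      stop(sprintf("rule '%s' references unresolved name(s): %s",
                   r$name, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    intersect(refs, rule_names)
  })

  # stable Kahn topological sort over the rule->rule dependency graph
  indeg <- vapply(deps, length, integer(1L))
  dependents <- lapply(rule_names, function(nm) {
    rule_names[vapply(deps, function(d) nm %in% d, logical(1L))]
  })
  names(dependents) <- rule_names
  queue <- rule_names[indeg == 0L]
  order <- character(0L)
  indeg_left <- indeg
  while (length(queue) > 0L) {
    nm <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, nm)
    for (dep in dependents[[nm]]) {
      indeg_left[[dep]] <- indeg_left[[dep]] - 1L
      if (indeg_left[[dep]] == 0L) queue <- c(queue, dep)
    }
  }
  if (length(order) < length(rule_names)) {
    cyc <- setdiff(rule_names, order)
    stop("dependency cycle among rules: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  }

  closure <- sort(unique(unlist(lapply(rules, function(r) {
    setdiff(rule_expr_vars(r$expression), rule_names)
  }))))
  structure(list(rules = rules[order], order = order,
                 index = stats::setNames(seq_along(order), order),
                 closure = closure, manifest = manifest),
            class = "compiled_ruleset")
}

#' @export
print.compiled_ruleset <- function(x, ...) {
  cat(sprintf("<compiled ruleset> %d rules over %d gene-family variables\n",
              length(x$order), length(x$closure)))
  invisible(x)
}

# ---- trait hierarchy --------------------------------------------------------

TRAIT_STRATEGIES <- c("resource acquisition", "resource use",
                      "stress tolerance", "life history")

#' Define traits bound to rules at three hierarchy levels
#'
#' @param name Trait name (most granular level).
#' @param level1,level2,level3 Hierarchy address (coarsest to finest).
#' @param strategy One of `"resource acquisition"`, `"resource use"`,
#'   `"stress tolerance"`, `"life history"`.
#' @param value_type `"binary"` (trait = one rule's assertion) or
#'   `"count"` (trait = substrate-class-resolved complex count,
#'   normalised by genome size downstream).
#' @param binding For binary traits a single rule name; for count traits
#'   a character vector of rule and/or gene-family names.
#' @param substrate_class Optional substrate-class filter for count
#'   traits.
#' @return `trait_definition()` returns a one-row data frame;
#'   `trait_hierarchy()` binds definitions into a `"trait_hierarchy"`
#'   data frame.
#' @export
trait_definition <- function(name, level1, level2, level3, strategy,
                             value_type = c("binary", "count"),
                             binding, substrate_class = NA_character_) {
  value_type <- match.arg(value_type)
  strategy <- match.arg(strategy, TRAIT_STRATEGIES)
  out <- data.frame(name = name, level1 = level1, level2 = level2,
                    level3 = level3, strategy = strategy,
                    value_type = value_type,
                    substrate_class = as.character(substrate_class),
                    stringsAsFactors = FALSE)
  out$binding <- list(as.character(binding))
  class(out) <- c("trait_hierarchy", "data.frame")
  out
}

#' @rdname trait_definition
#' @param ... `trait_definition()` rows (or one list of them).
#' @export
trait_hierarchy <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1L]]) &&
      !inherits(defs[[1L]], "data.frame")) {
    defs <- defs[[1L]]
  }
  out <- do.call(rbind, defs)
  class(out) <- c("trait_hierarchy", "data.frame")
  out
}

#' Read / write a trait-hierarchy file
#'
#' @param path Tab-separated hierarchy file with columns `trait_name`,
#'   `level1`, `level2`, `level3`, `strategy`, `value_type`, `binding`
#'   (semicolon-separated) and `substrate_class` (`.` for none).
#' @return A `"trait_hierarchy"` data frame.
#' @export
read_trait_hierarchy <- function(path) {
  body <- schema_read_lines(path, "hierarchy")
  df <- utils::read.delim(text = body, colClasses = "character")
  trait_hierarchy(lapply(seq_len(nrow(df)), function(i) {
    sc <- df$substrate_class[[i]]
    trait_definition(df$trait_name[[i]], df$level1[[i]], df$level2[[i]],
                     df$level3[[i]], df$strategy[[i]], df$value_type[[i]],
                     split_multi(df$binding[[i]]),
                     if (sc == "." || !nzchar(sc)) NA_character_ else sc)
  }))
}

#' @rdname read_trait_hierarchy
#' @param hierarchy A `"trait_hierarchy"`.
#' @export
write_trait_hierarchy <- function(hierarchy, path) {
  df <- data.frame(
    trait_name = hierarchy$name, level1 = hierarchy$level1,
    level2 = hierarchy$level2, level3 = hierarchy$level3,
    strategy = hierarchy$strategy, value_type = hierarchy$value_type,
    binding = vapply(hierarchy$binding, join_multi, ""),
    substrate_class = ifelse(is.na(hierarchy$substrate_class), ".",
                             hierarchy$substrate_class),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#traitguilds-hierarchy %s", SCHEMA_FORMAT_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- validation -------------------------------------------------------------

#' Validate a trait hierarchy against a compiled ruleset
#'
#' Checks that every binding resolves (to a rule for binary traits; to
#' rules or gene-family variables for count traits), that hierarchy
#' paths are unique, and that the value type is consistent with the
#' binding kind. The schema is usable iff the report is empty.
#'
#' @param traits A `"trait_hierarchy"`.
#' @param compiled A `"compiled_ruleset"`.
#' @return Data frame with columns `severity`, `entity`, `message`
#'   (zero rows when the schema is valid).
#' @export
validate_schema <- function(traits, compiled) {
  report <- list()
  note <- function(severity, entity, message) {
    report[[length(report) + 1L]] <<- data.frame(
      severity = severity, entity = entity, message = message,
      stringsAsFactors = FALSE)
  }
  rule_names <- compiled$order
  var_names <- compiled$manifest$hmm_name

  paths <- paste(traits$level1, traits$level2, traits$level3, sep = " > ")
  dup <- duplicated(paths)
  for (p in unique(paths[dup])) {
    note("error", p, "duplicate hierarchy path")
  }
  for (i in seq_len(nrow(traits))) {
    nm <- traits$name[[i]]
    binding <- traits$binding[[i]]
    vt <- traits$value_type[[i]]
    if (length(binding) == 0L) {
      note("error", nm, "empty binding")
      next
    }
    unresolved <- setdiff(binding, c(rule_names, var_names))
    for (b in unresolved) {
      note("error", nm, sprintf("unresolved binding '%s'", b))
    }
    if (vt == "binary") {
      if (length(binding) != 1L) {
        note("error", nm,
             "binary trait must bind exactly one rule, got a set")
      } else if (length(unresolved) == 0L && !(binding %in% rule_names)) {
        note("error", nm, sprintf(
          "binary trait must bind a rule; '%s' is a gene-family variable",
          binding))
      }
    }
  }
  out <- do.call(rbind, report)
  if (is.null(out)) {
    out <- data.frame(severity = character(0L), entity = character(0L),
                      message = character(0L))
  }
  out
}

#' @rdname validate_schema
#' @param report A validation report data frame.
#' @param path Output path for the tab-separated report.
#' @export
write_validation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- packaged example schema ------------------------------------------------

#' Packaged example trait schema
#'
#' Loads the representative schema shipped with the package: the
#' four-step denitrification pathway (12 gene families: the NarGHI and
#' NapAB nitrate reductases, the NirS/NirK nitrite reductases, the
#' NorBC/NorVW nitric oxide reductases and NosZ), a small
#' substrate-uptake transporter set with substrate-class annotations,
#' and a small stress-tolerance set. The manifest's trusted cutoffs are
#' illustrative placeholders: calibrate real libraries with
#' [run_calibrate()] and substitute its cutoff table.
#'
#' @return List with elements `manifest` (`hmm_manifest`), `rules`
#'   (`ruleset`), `hierarchy` (`trait_hierarchy`) and `compiled`
#'   (`compiled_ruleset`).
#' @export
example_schema <- function() {
  dir <- system.file("extdata", "schema", package = "traitguilds",
                     mustWork = TRUE)
  manifest <- read_hmm_manifest(file.path(dir, "manifest.tsv"))
  rules <- read_rules(file.path(dir, "rules.tsv"))
  hierarchy <- read_trait_hierarchy(file.path(dir, "hierarchy.tsv"))
  compiled <- compile_ruleset(rules, manifest)
  list(manifest = manifest, rules = rules, hierarchy = hierarchy,
       compiled = compiled)
}
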