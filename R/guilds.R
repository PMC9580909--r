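#' @title Data-driven functional guilds from a mixed-type trait matrix
#'
#' @description
#' Guilds -- groups of phylogenetically diverse organisms with similar
#' trait profiles -- are discovered from the trait matrix in four
#' steps: a mixed-type genome-to-genome distance (Wishart's
#' variance-weighted metric), complete-linkage hierarchical clustering,
#' distance-based variance partitioning to express the fraction of
#' trait variance explained as a function of the number of guilds
#' (R-squared(k)), and a tree cut at either a fixed number of guilds or
#' a target explained-variance fraction.
#'
#' The Wishart distance between genomes i and j over p variables is
#' \deqn{d_{ij} = \sqrt{ \frac{1}{p} \left[ \sum_{numeric\ k}
#'   (x_{ik}-x_{jk})^2 / s_k^2 + \sum_{binary\ k}
#'   1[x_{ik} \ne x_{jk}] \right] }}
#' with \eqn{s_k^2} the sample variance of numeric column k; like the
#' Gower distance for mixed data it averages per-variable
#' contributions, but it weights numeric variables by their variance
#' rather than their range and uses a squared distance component.
#' Numeric columns are therefore invariant to affine rescaling.
#'
#' @name guilds
NULL

#' Wishart mixed-type distance between genomes
#'
#' @param matrix A `"trait_matrix"` (its `value_type` attribute
#'   separates binary from numeric columns) or a plain numeric matrix
#'   (columns with values only in \{0,1\} are treated as binary).
#' @return A `"dist"` object with attributes `variance_weights` (the
#'   \eqn{s_k^2} used per numeric column), `p` (number of variables
#'   used) and `dropped` (zero-variance numeric columns removed, with a
#'   warning).
#' @export
wishart_distance <- function(matrix) {
  x <- unclass(matrix)
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("trait matrix must be finite with no missing values",
         call. = FALSE)
  }
  vt <- attr(matrix, "value_type")
  if (is.null(vt)) {
    vt <- ifelse(apply(x, 2L, function(col) all(col %in% c(0, 1))),
                 "binary", "count")
  }
  is_bin <- vt == "binary"
  num <- x[, !is_bin, drop = FALSE]
  bin <- x[, is_bin, drop = FALSE]

  s2 <- apply(num, 2L, stats::var)
  dropped <- colnames(num)[s2 == 0]
  if (length(dropped) > 0L) {
    warning("zero-variance numeric columns dropped from distance: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    num <- num[, s2 > 0, drop = FALSE]
    s2 <- s2[s2 > 0]
  }
  p <- ncol(num) + ncol(bin)
  n <- nrow(x)
  if (p == 0L) {
    warning("all columns constant; distance matrix is identically zero",
            call. = FALSE)
    d2 <- matrix(0, n, n)
  } else {
    d2 <- matrix(0, n, n)
    if (ncol(num) > 0L) {
      scaled <- sweep(num, 2L, sqrt(s2), "/")
      sq <- rowSums(scaled^2)
      d2 <- d2 + outer(sq, sq, "+") - 2 * tcrossprod(scaled)
    }
    if (ncol(bin) > 0L) {
      # Hamming mismatch count = squared Euclidean on 0/1 columns
      sqb <- rowSums(bin^2)
      d2 <- d2 + outer(sqb, sqb, "+") - 2 * tcrossprod(bin)
    }
    d2 <- pmax(d2, 0) / p
    if (all(d2 == 0)) {
      warning("all columns constant; distance matrix is identically zero",
              call. = FALSE)
    }
  }
  dimnames(d2) <- list(rownames(x), rownames(x))
  d <- stats::as.dist(sqrt(d2))
  attr(d, "variance_weights") <- s2
  attr(d, "p") <- p
  attr(d, "dropped") <- dropped
  d
}

#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' Thin wrapper around [stats::hclust()] with complete linkage;
#' agglomeration (and its tie handling) is deterministic for a given
#' input order.
#'
#' @param d A `"dist"` object.
#' @return An `"hclust"` tree.
#' @export
hierarchical_cluster <- function(d) {
  if (attr(d, "Size") < 2L) stop("need at least 2 genomes", call. = FALSE)
  stats::hclust(d, method = "complete")
}

#' Explained variance as a function of the number of clusters
#'
#' For each k, the tree is cut into k clusters and the fraction of
#' squared-distance variance explained by cluster identity is computed
#' as in distance-based (PERMANOVA-style) variance partitioning:
#' `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `R^2(k) = 1 - SS_within / SS_total`. R^2 is 0 at k = 1, 1 at k = n,
#' and non-decreasing over the nested cuts of a hierarchical tree.
#'
#' @param d A `"dist"` over the same genomes as `tree`.
#' @param tree An `"hclust"` tree.
#' @param k_range Cluster numbers to evaluate (default `1:n`).
#' @return Data frame of class `"variance_curve"` with columns `k` and
#'   `r_squared`.
#' @export
variance_curve <- function(d, tree, k_range = NULL) {
  n <- attr(d, "Size")
  stopifnot(length(tree$order) == n)
  if (is.null(k_range)) k_range <- seq_len(n)
  D2 <- as.matrix(d)^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  if (ss_total == 0) {
    stop("total squared-distance variance is zero; R^2 undefined",
         call. = FALSE)
  }
  cuts <- stats::cutree(tree, k = k_range)
  cuts <- matrix(cuts, nrow = n)
  r2 <- vapply(seq_along(k_range), function(j) {
    cl <- cuts[, j]
    ssw <- 0
    for (g in unique(cl)) {
      idx <- which(cl == g)
      if (length(idx) > 1L) {
        sub <- D2[idx, idx]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    1 - ssw / ss_total
  }, numeric(1L))
  out <- data.frame(k = k_range, r_squared = r2)
  class(out) <- c("variance_curve", "data.frame")
  out
}

# ---- the fitted guild model -------------------------------------------------

#' Fit a guild model to a trait matrix
#'
#' Computes the Wishart distance, the complete-linkage tree and the
#' explained-variance curve in one step and returns them as a fitted
#' model object; guild assignments at any resolution are then read off
#' with [define_guilds()].
#'
#' @param matrix A `"trait_matrix"` (or numeric matrix) of genomes x
#'   traits.
#' @return An object of class `"guild_model"` with components
#'   `distance`, `tree`, `curve`, `n`, `traits` and `call`.
#' @seealso [define_guilds()], [guild_profiles()]
#' @export
guild_model <- function(matrix) {
  d <- wishart_distance(matrix)
  tree <- hierarchical_cluster(d)
  curve <- variance_curve(d, tree)
  structure(list(distance = d, tree = tree, curve = curve,
                 n = attr(d, "Size"), traits = colnames(matrix),
                 call = match.call()),
            class = "guild_model")
}

#' @export
print.guild_model <- function(x, ...) {
  cat(sprintf("Guild model: %d genomes, %d traits\n", x$n,
              length(x$traits)))
  cat("  distance: Wishart (variance-weighted, mixed-type)\n")
  cat("  linkage: complete\n")
  for (v in c(0.5, 0.7, 0.9)) {
    k <- smallest_k_for_variance(x$curve, v)
    cat(sprintf("  %d guilds explain >= %.0f%% of trait variance\n",
                k, 100 * v))
  }
  invisible(x)
}

#' @export
summary.guild_model <- function(object, targets = c(0.5, 0.7, 0.9), ...) {
  ks <- vapply(targets, function(v) smallest_k_for_variance(object$curve, v),
               integer(1L))
  out <- list(n = object$n, n_traits = length(object$traits),
              curve = object$curve,
              k_at_variance = data.frame(variance_target = targets, k = ks))
  class(out) <- "summary.guild_model"
  out
}

#' @export
print.summary.guild_model <- function(x, ...) {
  cat(sprintf("Guild model over %d genomes and %d traits\n", x$n,
              x$n_traits))
  print(x$k_at_variance, row.names = FALSE)
  invisible(x)
}

#' @export
plot.guild_model <- function(x, ...) {
  plot(x$curve$k, x$curve$r_squared, type = "s",
       xlab = "number of guilds (k)",
       ylab = expression(R^2 ~ "(variance explained)"),
       ylim = c(0, 1), ...)
  invisible(x)
}

smallest_k_for_variance <- function(curve, target) {
  ok <- curve$r_squared >= target - 1e-12
  if (!any(ok)) {
    stop(sprintf("variance target %.3f unachievable (max R^2 = %.3f)",
                 target, max(curve$r_squared)), call. = FALSE)
  }
  as.integer(min(curve$k[ok]))
}

#' Assign genomes to guilds
#'
#' Cuts the model's tree either into a fixed number of guilds `k` or at
#' the smallest k whose explained variance reaches `variance_target`.
#' Guilds smaller than `min_size` are retained but flagged.
#'
#' @param model A `"guild_model"` (or an `"hclust"` tree, in which case
#'   `curve` must be supplied for variance targets).
#' @param k Fixed number of guilds.
#' @param variance_target Explained-variance fraction in (0, 1].
#' @param min_size Minimum guild size below which a guild is flagged.
#' @param curve A `"variance_curve"` (only when `model` is a raw tree).
#' @return A `"guild_assignment"`: list with `assignment` (named
#'   integer vector, guild ids 1..k), `k`, `sizes`, `flagged` (guild
#'   ids with fewer than `min_size` genomes) and `r_squared` at the
#'   cut.
#' @export
define_guilds <- function(model, k = NULL, variance_target = NULL,
                          min_size = 1L, curve = NULL) {
  if (inherits(model, "guild_model")) {
    tree <- model$tree
    curve <- model$curve
  } else {
    tree <- model
  }
  if (is.null(k) == is.null(variance_target)) {
    stop("give exactly one of k or variance_target", call. = FALSE)
  }
  if (!is.null(variance_target)) {
    if (is.null(curve)) stop("variance target needs a variance curve",
                             call. = FALSE)
    k <- smallest_k_for_variance(curve, variance_target)
  }
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k out of range", call. = FALSE)
  cl <- stats::cutree(tree, k = k)
  sizes <- as.integer(table(cl))
  names(sizes) <- names(table(cl))
  flagged <- as.integer(names(sizes))[sizes < min_size]
  r2 <- if (!is.null(curve)) curve$r_squared[match(k, curve$k)] else NA_real_
  structure(list(assignment = cl, k = as.integer(k), sizes = sizes,
                 flagged = flagged, r_squared = r2),
            class = "guild_assignment")
}

#' @export
print.guild_assignment <- function(x, ...) {
  cat(sprintf("<guild assignment> %d guilds over %d genomes", x$k,
              length(x$assignment)))
  if (!is.na(x$r_squared)) cat(sprintf(" (R^2 = %.3f)", x$r_squared))
  cat("\n  sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (length(x$flagged) > 0L) {
    cat("  flagged (below min size):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-guild trait profiles with across-guild significance
#'
#' For every guild and trait the mean trait value is reported ("trait
#' positivity", the fraction of member genomes with the trait, for
#' binary traits; the mean per-bp investment for count traits). Each
#' trait is additionally tested for differences across guilds with a
#' Kruskal-Wallis rank test, Benjamini-Hochberg adjusted. Optional
#' life-history columns are summarised per guild as quantiles.
#'
#' @param assignment A `"guild_assignment"`.
#' @param matrix The trait matrix the guilds were defined on.
#' @param life_history Optional numeric matrix (genomes x life-history
#'   traits).
#' @return A `"guild_profile"`: list with `means` (guilds x traits),
#'   `tests` (per-trait statistic, p, adjusted p) and `life_history`
#'   (per guild quantile table or `NULL`).
#' @export
guild_profiles <- function(assignment, matrix, life_history = NULL) {
  cl <- assignment$assignment
  x <- unclass(matrix)
  stopifnot(length(cl) == nrow(x))
  guilds <- sort(unique(cl))
  means <- t(vapply(guilds, function(g) {
    colMeans(x[cl == g, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(means) <- paste0("guild", guilds)

  tests <- data.frame(trait = colnames(x), statistic = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
  if (length(guilds) > 1L) {
    for (j in seq_len(ncol(x))) {
      if (length(unique(x[, j])) < 2L) next  # constant trait: no test
      kt <- suppressWarnings(stats::kruskal.test(x[, j], factor(cl)))
      tests$statistic[j] <- unname(kt$statistic)
      tests$p[j] <- kt$p.value
    }
  }
  tests$p_adjusted <- stats::p.adjust(tests$p, method = "BH")

  lh <- NULL
  if (!is.null(life_history)) {
    lh <- do.call(rbind, lapply(guilds, function(g) {
      sub <- life_history[cl == g, , drop = FALSE]
      do.call(rbind, lapply(colnames(sub), function(trait) {
        q <- stats::quantile(sub[, trait], c(0.25, 0.5, 0.75),
                             na.rm = TRUE)
        data.frame(guild = g, trait = trait, q25 = q[[1L]],
                   median = q[[2L]], q75 = q[[3L]])
      }))
    }))
  }
  structure(list(means = means, tests = tests, life_history = lh),
            class = "guild_profile")
}

#' Spearman correlation structure of the trait matrix
#'
#' @param matrix A trait matrix with at least 3 genomes.
#' @return Trait-by-trait Spearman correlation matrix; entries
#'   involving constant traits are `NA` (flagged with a warning).
#' @export
trait_correlations <- function(matrix) {
  x <- unclass(matrix)
  stopifnot(nrow(x) >= 3L)
  constant <- apply(x, 2L, function(col) length(unique(col)) < 2L)
  if (any(constant)) {
    warning("constant traits have undefined correlations: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(stats::cor(x, method = "spearman"))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same
#' genomes; 1 for identical partitions (up to relabeling), about 0 for
#' independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Export a dendrogram in Newick format
#'
#' @param tree An `"hclust"` tree with genome ids as labels.
#' @param path Output path.
#' @export
export_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
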