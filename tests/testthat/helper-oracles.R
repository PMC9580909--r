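# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the cutoff oracle scans thresholds by brute
# force, the rule oracle routes through R's own parser/evaluator, and
# the variance oracle spells the partition sums out in loops.

# exhaustive threshold-scan oracle for trusted-cutoff selection
oracle_cutoff <- function(pos, neg, n_neg_total = length(neg)) {
  thresholds <- sort(unique(c(pos, neg)))
  best_f <- -Inf
  best_t <- NA_real_
  for (t in thresholds) {
    tp <- sum(pos >= t)
    fp <- sum(neg >= t)
    if (tp + fp == 0) next
    precision <- tp / (tp + fp)
    recall <- tp / length(pos)
    f <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    if (f > best_f + 1e-12) {
      best_f <- f
      best_t <- t
    }
  }
  if (best_f <= 0) return(list(cutoff = NA_real_, f = NA_real_))
  list(cutoff = best_t, f = best_f)
}

# truth-table oracle: inline rule references into a pure-variable
# expression and hand it to R's parser and evaluator
oracle_eval_rules <- function(rules, presence) {
  inline <- function(text) {
    repeat {
      replaced <- text
      for (nm in names(rules)) {
        pat <- paste0("\\b", nm, "\\b")
        if (grepl(pat, replaced)) {
          replaced <- gsub(pat, paste0("(", rules[[nm]], ")"), replaced)
        }
      }
      if (identical(replaced, text)) return(text)
      text <- replaced
    }
  }
  env <- as.list(presence)
  vapply(names(rules), function(nm) {
    isTRUE(eval(parse(text = inline(rules[[nm]])), envir = env))
  }, logical(1L))
}

# direct partition-sum implementation of distance-based R^2
oracle_r_squared <- function(d, cl) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  ss_total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) ss_total <- ss_total + D2[i, j]
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(cl)) {
    idx <- which(cl == g)
    ng <- length(idx)
    if (ng < 2L) next
    s <- 0
    for (a in seq_len(ng - 1L)) {
      for (b in (a + 1L):ng) s <- s + D2[idx[a], idx[b]]
    }
    ss_within <- ss_within + s / ng
  }
  1 - ss_within / ss_total
}

# random rule expression over the given variable names
random_expression <- function(vars, depth = 3L, allow_not = TRUE) {
  if (depth == 0L || stats::runif(1) < 0.35) {
    return(sample(vars, 1L))
  }
  op <- sample(if (allow_not) c("&", "|", "!") else c("&", "|"), 1L)
  if (op == "!") {
    paste0("!(", random_expression(vars, depth - 1L, allow_not), ")")
  } else {
    paste0("(", random_expression(vars, depth - 1L, allow_not), " ", op,
           " ", random_expression(vars, depth - 1L, allow_not), ")")
  }
}
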