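toy_mixed_matrix <- function() {
  # 3 genomes, 2 binary + 1 numeric column; distances below are fixed
  # from a hand computation of the variance-weighted formula:
  # s^2 = var(1,2,4) = 7/3, p = 3
  # d12^2 = (1/3)(1/(7/3) + 0 + 1) = 10/21
  # d13^2 = (1/3)(9/(7/3) + 1 + 0) = 34/21
  # d23^2 = (1/3)(4/(7/3) + 1 + 1) = 26/21
  values <- cbind(b1 = c(0, 0, 1), b2 = c(1, 0, 1), num = c(1, 2, 4))
  rownames(values) <- c("g1", "g2", "g3")
  traitguilds:::new_trait_matrix(values, c("binary", "binary", "count"),
                                 rep("resource use", 3), 3L)
}

test_that("Wishart distance matches the hand-computed 3x3 example", {
  d <- as.matrix(wishart_distance(toy_mixed_matrix()))
  expect_equal(d["g1", "g2"], sqrt(10 / 21), tolerance = 1e-12)
  expect_equal(d["g1", "g3"], sqrt(34 / 21), tolerance = 1e-12)
  expect_equal(d["g2", "g3"], sqrt(26 / 21), tolerance = 1e-12)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("Wishart distance is invariant to affine scaling of numeric columns", {
  set.seed(88)
  pg <- make_planted_guild_matrix(n_genomes = 25L, seed = 6)
  d0 <- as.matrix(wishart_distance(pg$matrix))
  scaled <- pg$matrix
  is_cnt <- attr(scaled, "value_type") == "count"
  unclassed <- unclass(scaled)
  unclassed[, is_cnt] <- unclassed[, is_cnt] * 1e6 + 3.5
  scaled2 <- traitguilds:::new_trait_matrix(
    unclassed, attr(scaled, "value_type"), attr(scaled, "strategy"), 3L)
  expect_equal(as.matrix(wishart_distance(scaled2)), d0,
               tolerance = 1e-9)

  # identical rows are at distance zero; permutation permutes d
  dup <- unclass(pg$matrix)
  dup[2, ] <- dup[1, ]
  ddup <- as.matrix(wishart_distance(traitguilds:::new_trait_matrix(
    dup, attr(pg$matrix, "value_type"), attr(pg$matrix, "strategy"), 3L)))
  expect_equal(ddup[1, 2], 0)
  perm <- sample(nrow(pg$matrix))
  dp <- as.matrix(wishart_distance(traitguilds:::new_trait_matrix(
    unclass(pg$matrix)[perm, ], attr(pg$matrix, "value_type"),
    attr(pg$matrix, "strategy"), 3L)))
  expect_equal(dp, d0[perm, perm], tolerance = 1e-12)
})

test_that("degenerate trait matrices are handled explicitly", {
  vals <- cbind(b = c(0, 0, 0), n = c(2, 2, 2))
  rownames(vals) <- paste0("g", 1:3)
  m <- traitguilds:::new_trait_matrix(vals, c("binary", "count"),
                                      rep("resource use", 2), 3L)
  w <- capture_warnings(d <- wishart_distance(m))
  expect_true(any(grepl("constant", w)))  # also warns about the drop
  expect_true(all(as.matrix(d) == 0))

  # a single zero-variance numeric column is dropped with a warning
  vals2 <- cbind(b = c(0, 1, 0), n = c(2, 2, 2))
  rownames(vals2) <- paste0("g", 1:3)
  m2 <- traitguilds:::new_trait_matrix(vals2, c("binary", "count"),
                                       rep("resource use", 2), 3L)
  expect_warning(d2 <- wishart_distance(m2), "dropped")
  expect_identical(attr(d2, "dropped"), "n")
  expect_identical(attr(d2, "p"), 1L)
})

test_that("complete-linkage clustering separates planted blobs", {
  pg <- make_planted_guild_matrix(n_genomes = 30L, n_guilds = 2L,
                                  seed = 17)
  d <- wishart_distance(pg$matrix)
  tree <- hierarchical_cluster(d)
  expect_s3_class(tree, "hclust")
  # merge heights are non-decreasing (complete-linkage property)
  expect_false(is.unsorted(tree$height))
  # the first cut recovers the two planted blobs
  expect_equal(adjusted_rand_index(cutree(tree, 2), pg$labels), 1)

  # n = 2 degenerates to a single merge at d_12
  two <- traitguilds:::new_trait_matrix(
    cbind(a = c(0, 1), b = c(0, 1)), rep("binary", 2),
    rep("resource use", 2), 3L)
  d2 <- wishart_distance(two)
  t2 <- hierarchical_cluster(d2)
  expect_equal(t2$height, as.numeric(d2))
  expect_error(hierarchical_cluster(stats::as.dist(matrix(0, 1, 1))),
               "at least 2")
})

test_that("variance curve matches the direct partition-sum oracle and vegan", {
  set.seed(55)
  pg <- make_planted_guild_matrix(n_genomes = 20L, seed = 8)
  d <- wishart_distance(pg$matrix)
  tree <- hierarchical_cluster(d)
  curve <- variance_curve(d, tree)
  expect_equal(curve$r_squared[curve$k == 1], 0)
  expect_equal(curve$r_squared[curve$k == 20], 1)
  expect_false(is.unsorted(curve$r_squared + 1e-12))
  for (k in 2:19) {
    cl <- cutree(tree, k)
    expect_equal(curve$r_squared[curve$k == k], oracle_r_squared(d, cl),
                 tolerance = 1e-12, info = k)
  }
  # independent route: PERMANOVA R^2 from vegan for a few cuts
  for (k in c(2, 5, 11)) {
    cl <- factor(cutree(tree, k))
    fit <- vegan::adonis2(d ~ cl, permutations = 0)
    expect_equal(curve$r_squared[curve$k == k], fit$R2[[1L]],
                 tolerance = 1e-10, info = k)
  }
  # all-identical rows make R^2 undefined
  same <- traitguilds:::new_trait_matrix(
    matrix(1, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b"))),
    c("binary", "binary"), rep("resource use", 2), 3L)
  dsame <- suppressWarnings(wishart_distance(same))
  expect_error(variance_curve(dsame, hierarchical_cluster(dsame)),
               "undefined")
})

test_that("guild definition honours k, variance targets and size flags", {
  pg <- make_planted_guild_matrix(seed = 11)  # 60 genomes, 3 guilds
  model <- guild_model(pg$matrix)

  # variance target 1.0 forces singletons
  all_k <- define_guilds(model, variance_target = 1.0)
  expect_identical(all_k$k, model$n)

  # planted three-guild structure is recovered exactly
  at3 <- define_guilds(model, k = 3L)
  expect_identical(sort(unique(at3$assignment)), 1:3)
  expect_identical(sum(at3$sizes), 60L)
  expect_gte(adjusted_rand_index(at3$assignment, pg$labels), 0.95)

  # a variance target picks the smallest k reaching it
  v <- model$curve$r_squared[model$curve$k == 3]
  atv <- define_guilds(model, variance_target = v)
  expect_lte(atv$k, 3L)
  expect_gte(model$curve$r_squared[model$curve$k == atv$k], v)

  # min-size flags small guilds but keeps them
  flagged <- define_guilds(model, k = 3L, min_size = 50L)
  expect_identical(sum(flagged$sizes), 60L)
  expect_true(length(flagged$flagged) >= 1L)

  expect_error(define_guilds(model, k = 3L, variance_target = 0.5),
               "exactly one")
  expect_error(define_guilds(model, variance_target = 2), "unachievable")
})

test_that("guild profiles report positivity and across-guild significance", {
  # two guilds, one perfectly separating trait, one pure-noise trait
  set.seed(23)
  vals <- cbind(sep = rep(c(1, 0), each = 10),
                part = c(rep(1, 5), rep(0, 5), rep(0, 8), rep(1, 2)),
                noise = rbinom(20, 1, 0.5))
  rownames(vals) <- sprintf("g%02d", 1:20)
  m <- traitguilds:::new_trait_matrix(vals, rep("binary", 3),
                                      rep("resource use", 3), 3L)
  assignment <- structure(list(
    assignment = setNames(rep(1:2, each = 10), rownames(vals)),
    k = 2L, sizes = c(`1` = 10L, `2` = 10L), flagged = integer(0L),
    r_squared = NA_real_), class = "guild_assignment")
  prof <- guild_profiles(assignment, m)
  expect_equal(prof$means["guild1", "sep"], 1)
  expect_equal(prof$means["guild2", "sep"], 0)
  expect_equal(prof$means["guild1", "part"], 0.5)
  # the separating trait has the smallest adjusted p
  expect_identical(
    prof$tests$trait[which.min(prof$tests$p_adjusted)], "sep")

  # identical guilds: no significant differences anywhere
  same <- rbind(vals[1:10, ], vals[1:10, ])
  rownames(same) <- sprintf("g%02d", 1:20)
  msame <- traitguilds:::new_trait_matrix(same, rep("binary", 3),
                                          rep("resource use", 3), 3L)
  prof0 <- guild_profiles(assignment, msame)
  expect_true(all(prof0$tests$p_adjusted > 0.05, na.rm = TRUE))

  # life-history quantiles are summarised per guild
  lh <- cbind(doubling_time_h = rexp(20) + 1,
              ogt_celsius = rnorm(20, 25))
  rownames(lh) <- rownames(vals)
  profl <- guild_profiles(assignment, m, life_history = lh)
  expect_identical(nrow(profl$life_history), 4L)
  med <- profl$life_history$median[
    profl$life_history$guild == 1 &
      profl$life_history$trait == "doubling_time_h"]
  expect_equal(med, median(lh[1:10, "doubling_time_h"]))
})

test_that("trait correlations are Spearman and flag constant traits", {
  set.seed(61)
  x <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, sprintf("t%d", 1:6)))
  got <- trait_correlations(x)
  # rank-then-Pearson oracle
  want <- stats::cor(apply(x, 2L, rank))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(unname(diag(got)), rep(1, 6))
  # a trait against its negation
  y <- cbind(t = x[, 1], neg = -x[, 1], o = x[, 2])
  expect_equal(trait_correlations(y)["t", "neg"], -1)
  # constant trait flagged
  z <- cbind(c = rep(1, 30), o = x[, 2])
  expect_warning(cz <- trait_correlations(z), "constant")
  expect_true(is.na(cz["c", "o"]))
})

test_that("adjusted Rand agreement matches mclust on random labelings", {
  set.seed(31)
  for (i in 1:50) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1:2, each = 5),
                                   rep(c(7, 9), each = 5)), 1)
})

test_that("dendrograms export to Newick with genome ids as leaves", {
  pg <- make_planted_guild_matrix(n_genomes = 12L, seed = 4)
  model <- guild_model(pg$matrix)
  tmp <- tempfile(fileext = ".nwk")
  export_dendrogram_newick(model$tree, tmp)
  phy <- ape::read.tree(tmp)
  expect_setequal(phy$tip.label, rownames(pg$matrix))
})
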