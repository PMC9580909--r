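make_small_schema <- function() {
  manifest <- hmm_manifest(c("a1", "a2", "b1", "c1", "c2"),
                           rep(50, 5),
                           substrates = list(
                             data.frame(substrate = "s1",
                                        substrate_class = "classA"),
                             data.frame(substrate = "s1",
                                        substrate_class = "classA"),
                             data.frame(substrate = "s2",
                                        substrate_class = "classB"),
                             data.frame(substrate = character(0L),
                                        substrate_class = character(0L)),
                             data.frame(substrate = character(0L),
                                        substrate_class = character(0L))))
  rules <- ruleset(
    rule("complexA", "a1 & a2", substrate_class = "classA"),
    rule("capC", "c1 | c2"))
  hierarchy <- trait_hierarchy(
    trait_definition("capacity_C", "L1x", "L2x", "cap", "resource use",
                     "binary", "capC"),
    trait_definition("uptake_A", "L1y", "L2y", "A", "resource acquisition",
                     "count", "complexA", "classA"),
    trait_definition("uptake_B", "L1y", "L2y", "B", "resource acquisition",
                     "count", "b1", "classB"))
  list(manifest = manifest, rules = rules, hierarchy = hierarchy,
       compiled = compile_ruleset(rules, manifest))
}

make_small_inputs <- function() {
  schema <- make_small_schema()
  counts <- matrix(c(2L, 2L, 4L, 1L, 0L,
                     0L, 3L, 0L, 0L, 2L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("gX", "gY"),
                                   c("a1", "a2", "b1", "c1", "c2")))
  tab <- structure(counts, size_bp = c(gX = 4e6, gY = 2e6),
                   class = c("gene_count_table", "matrix"))
  assertions <- assert_matrix(schema$compiled, tab)
  list(schema = schema, tab = tab, assertions = assertions)
}

test_that("binary traits are the bound rules' assertions", {
  inp <- make_small_inputs()
  bin <- binary_traits(inp$assertions, inp$schema$hierarchy)
  expect_identical(bin[, "capacity_C"], c(gX = 1, gY = 1))
  # all-FALSE assertions give all-zero binary traits
  zero_tab <- inp$tab
  zero_tab[] <- 0L
  a0 <- assert_matrix(inp$schema$compiled, zero_tab)
  expect_true(all(binary_traits(a0, inp$schema$hierarchy) == 0))
})

test_that("count traits are per-bp normalised complex counts", {
  inp <- make_small_inputs()
  cnt <- count_traits(inp$tab, inp$schema$manifest, inp$schema$rules,
                      inp$schema$hierarchy)
  # gX: min(a1, a2) = 2 complexes over 4 Mb
  expect_equal(cnt["gX", "uptake_A"], 2 / 4e6)
  expect_equal(cnt["gX", "uptake_B"], 4 / 4e6)
  expect_equal(cnt["gY", "uptake_A"], 0)
  # count 0 stays 0 at any genome size
  expect_equal(cnt["gY", "uptake_B"], 0)

  # unknown size: default errors, policy flag keeps raw counts
  bad <- inp$tab
  attr(bad, "size_bp") <- c(gX = 4e6, gY = NA_real_)
  expect_error(count_traits(bad, inp$schema$manifest, inp$schema$rules,
                            inp$schema$hierarchy), "size")
  expect_warning(raw <- count_traits(bad, inp$schema$manifest,
                                     inp$schema$rules,
                                     inp$schema$hierarchy,
                                     unknown_size = "raw"),
                 "raw")
  expect_equal(raw["gY", "uptake_B"], 0)
})

test_that("normalisation is invariant to doubling counts and genome size", {
  inp <- make_small_inputs()
  base <- count_traits(inp$tab, inp$schema$manifest, inp$schema$rules,
                       inp$schema$hierarchy)
  doubled <- inp$tab
  doubled[] <- unclass(inp$tab) * 2L
  attr(doubled, "size_bp") <- attr(inp$tab, "size_bp") * 2
  scaled <- count_traits(doubled, inp$schema$manifest, inp$schema$rules,
                         inp$schema$hierarchy)
  expect_equal(scaled, base)
})

test_that("rollup ORs binary children and sums count children", {
  inp <- make_small_inputs()
  tm3 <- build_trait_matrix(inp$assertions, inp$tab, inp$schema)
  expect_identical(ncol(tm3), nrow(inp$schema$hierarchy))
  tm2 <- rollup(tm3, 2L)
  tm1 <- rollup(tm3, 1L)

  # count parent is the sum of its children
  expect_equal(unclass(tm1)[, "L1y"],
               unclass(tm3)[, "uptake_A"] + unclass(tm3)[, "uptake_B"])
  # binary parent is the OR of its children
  expect_equal(unclass(tm1)[, "L1x"],
               (unclass(tm3)[, "capacity_C"] > 0) * 1)
  # conservation holds from granularity 1 down to 3
  expect_equal(rowSums(unclass(tm2)[, c("L1y > L2y"), drop = FALSE]),
               rowSums(unclass(tm3)[, c("uptake_A", "uptake_B")]))

  # brute-force aggregation over a toy two-parent hierarchy
  vals <- matrix(c(1, 0, 0, 1, 0, 0), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("t1", "t2", "t3")))
  toy <- traitguilds:::new_trait_matrix(
    vals, rep("binary", 3), rep("resource use", 3), 3L,
    path = data.frame(level1 = c("P", "P", "Q"),
                      level2 = c("P1", "P1", "Q1"),
                      level3 = c("t1", "t2", "t3")))
  up <- rollup(toy, 1L)
  expect_equal(unclass(up)[, "P"], c(g1 = 1, g2 = 1))
  expect_equal(unclass(up)[, "Q"], c(g1 = 0, g2 = 0))
})

test_that("trait matrices round-trip through their tab-separated format", {
  inp <- make_small_inputs()
  tm3 <- build_trait_matrix(inp$assertions, inp$tab, inp$schema)
  tmp <- tempfile(fileext = ".tsv")
  write_trait_matrix(tm3, tmp)
  back <- read_trait_matrix(tmp)
  expect_equal(unclass(back), unclass(tm3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(tm3))
  expect_identical(attr(back, "strategy"), attr(tm3, "strategy"))
})
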