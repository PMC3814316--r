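k4 <- function() {
  p <- combn(c("A", "B", "C", "D"), 2)
  interaction_network(p[1, ], p[2, ], sources = "x")
}

test_that("within-set edge counts match structure and a brute-force oracle", {
  net <- k4()
  expect_equal(within_set_edge_count(net, c("A", "B", "C", "D")), 6)
  expect_equal(within_set_edge_count(net, c("Z1", "Z2")), 0)

  g <- generate_interaction_network(200, 0.03, seed = 41)
  set.seed(42)
  for (i in 1:5) {
    genes <- sample(g$truth$genes, 30)
    expect_equal(within_set_edge_count(g$network, genes),
                 oracle_edge_count(g$network, genes))
  }
})

test_that("uniform permutation null is calibrated for random categories", {
  g <- generate_interaction_network(120, 0.05, seed = 51)
  universe <- g$truth$genes
  set.seed(52)
  z <- replicate(30, {
    cat_genes <- sample(universe, 12)
    e <- homotypic_enrichment(g$network, cat_genes, universe,
                              n_perm = 300, seed = sample.int(1e6, 1))
    (e$observed - e$null_mean) / e$null_sd
  })
  # observed counts of random categories should sit inside their own null
  expect_lt(mean(abs(z) > 3), 0.15)
  expect_lt(abs(mean(z)), 0.75)
})

test_that("a planted clique on sparse background reaches the p-value floor", {
  clique <- sprintf("G%04d", 1:8)
  g <- generate_interaction_network(
    150, 0.01, planted_modules = list(list(genes = 1:8, within_density = 1)),
    seed = 61)
  e <- homotypic_enrichment(g$network, clique, g$truth$genes,
                            n_perm = 999, seed = 62)
  expect_gt(e$fold, 10)
  expect_equal(e$p_empirical, 1 / 1000)
})

test_that("permutation null mean matches exhaustive enumeration on a toy graph", {
  set.seed(71)
  nodes <- sprintf("N%02d", 1:10)
  p <- combn(nodes, 2)
  keep <- runif(ncol(p)) < 0.3
  net <- interaction_network(p[1, keep], p[2, keep], sources = "x",
                             nodes = nodes)
  combos <- combn(nodes, 4)
  exact <- mean(vapply(seq_len(ncol(combos)), function(i) {
    oracle_edge_count(net, combos[, i])
  }, 0L))
  e <- homotypic_enrichment(net, nodes[1:4], nodes, n_perm = 4000, seed = 72)
  se <- e$null_sd / sqrt(4000)
  expect_lt(abs(e$null_mean - exact), 4 * se + 1e-9)
})

test_that("observed count is permutation-invariant and null means converge", {
  g <- generate_interaction_network(100, 0.05, seed = 81)
  genes <- g$truth$genes[1:10]
  e1 <- homotypic_enrichment(g$network, genes, g$truth$genes,
                             n_perm = 400, seed = 82)
  e2 <- homotypic_enrichment(g$network, genes, g$truth$genes,
                             n_perm = 800, seed = 83)
  expect_equal(e1$observed, e2$observed)
  se <- sqrt(e1$null_sd^2 / 400 + e2$null_sd^2 / 800)
  expect_lt(abs(e1$null_mean - e2$null_mean), 4 * se)
})

test_that("degree-matched sampling self-calibrates near PIE 1", {
  g <- generate_interaction_network(150, 0.06, seed = 91)
  deg <- table(factor(c(g$network$edges$from, g$network$edges$to),
                      levels = g$network$nodes))
  set.seed(92)
  pies <- replicate(25, {
    genes <- sample(g$truth$genes[deg > 0], 12)
    pie_score(g$network, genes, n_samples = 150,
              seed = sample.int(1e6, 1))$fold
  })
  expect_gt(mean(pies), 0.85)
  expect_lt(mean(pies), 1.15)
})

test_that("PIE degenerates correctly on structural zeros", {
  # star graph: leaves share no edges at all
  leaves <- sprintf("L%02d", 1:10)
  net <- interaction_network(rep("HUB", 10), leaves, sources = "x")
  p <- suppressWarnings(pie_score(net, leaves[1:5], n_samples = 100, seed = 7))
  expect_equal(p$observed, 0)
  expect_equal(p$fold, 0)
})

test_that("with one degree bin, PIE's null agrees with uniform sampling", {
  g <- generate_interaction_network(80, 0.08, seed = 93)
  genes <- g$truth$genes[1:10]
  pie <- pie_score(g$network, genes, n_samples = 600, seed = 94,
                   degree_bins = 1)
  uni <- homotypic_enrichment(g$network, genes, g$truth$genes,
                              n_perm = 600, seed = 95)
  se <- sqrt(pie$null_sd^2 / 600 + uni$null_sd^2 / 600)
  expect_lt(abs(pie$null_mean - uni$null_mean), 4 * se)
})

test_that("homotypic modules are per-category connected components", {
  net <- interaction_network(c("A", "B", "B"), c("B", "C", "X"),
                             sources = "x", nodes = c("A", "B", "C", "D", "X"))
  profiles <- list(A = "rough", B = "rough", C = "rough", D = "rough",
                   X = "fused")
  mods <- extract_homotypic_modules(net, profiles, "rough")
  expect_length(mods, 1)             # D is an isolated singleton
  expect_equal(mods[[1]]$genes, c("A", "B", "C"))

  # a neighbor without the category breaks the module
  profiles2 <- list(A = "rough", B = "rough", C = "fused")
  net2 <- interaction_network(c("A", "B"), c("B", "C"), sources = "x")
  mods2 <- extract_homotypic_modules(net2, profiles2, "rough")
  expect_length(mods2, 1)
  expect_equal(mods2[[1]]$genes, c("A", "B"))
})

test_that("module extraction agrees with a union-find oracle", {
  g <- generate_interaction_network(300, 0.01, seed = 96)
  set.seed(97)
  carriers <- sample(g$truth$genes, 80)
  profiles <- setNames(rep(list("rough"), 80), carriers)
  mods <- extract_homotypic_modules(g$network, profiles, "rough")
  keep <- g$network$edges$from %in% carriers & g$network$edges$to %in% carriers
  comps <- oracle_components(g$network$edges$from[keep],
                             g$network$edges$to[keep], carriers)
  comps <- Filter(function(x) length(x) >= 2, comps)
  got <- lapply(mods, function(m) sort(m$genes))
  want <- lapply(comps, sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  # modules partition the category's non-singleton connected genes
  allg <- unlist(got)
  expect_false(anyDuplicated(allg) > 0)
  expect_true(all(allg %in% carriers))
})

test_that("module summaries deduplicate genes and cross-category pairs", {
  m1 <- list(category = "rough", genes = c("A", "B"),
             edges = data.frame(from = "A", to = "B"))
  m2 <- list(category = "fused", genes = c("C", "D"),
             edges = data.frame(from = "C", to = "D"))
  s <- module_summary(list(m1, m2))
  expect_equal(s$n_modules, 2)
  expect_equal(s$n_genes_union, 4)
  expect_equal(s$n_connections_unique, 2)

  # the same pair homotypic in two categories counts once in the unique tally
  m3 <- list(category = "lethal", genes = c("A", "B"),
             edges = data.frame(from = "A", to = "B"))
  s2 <- module_summary(list(m1, m3))
  expect_equal(s2$n_genes_union, 2)
  expect_equal(s2$n_connections_unique, 1)
  expect_equal(s2$n_connections_per_category, 2)
  expect_equal(module_summary(list())$n_modules, 0)
})

test_that("input contracts are enforced", {
  net <- k4()
  expect_error(homotypic_enrichment(net, "A", c("A", "B"), 10, seed = 1),
               ">= 2")
  expect_error(homotypic_enrichment(net, c("A", "Z"), c("A", "B"), 10, seed = 1),
               "universe")
  expect_error(pie_score(net, c("A", "NOPE"), seed = 1), "NOPE")
})
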