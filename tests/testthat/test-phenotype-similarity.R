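test_that("ancestor closure reports minimal levels and reaches the root", {
  ont <- ontology(list(root = character(0), A = "root", B = "A"))
  expect_equal(ancestor_closure(ont, "B"),
               c(B = 0L, A = 1L, root = 2L))
  # diamond: X reaches M both directly (level 1) and via Y (level 2)
  dia <- ontology(list(root = character(0), M = "root", Y = "M",
                       X = c("M", "Y")))
  expect_equal(ancestor_closure(dia, "X")[["M"]], 1L)
  expect_error(ancestor_closure(ont, "nope"), "unknown term")
})

test_that("closure term sets match a matrix-power reachability oracle", {
  g <- generate_ontology(40, max_parents = 3, seed = 15)
  for (t in sample(g$ontology$terms, 8)) {
    expect_setequal(names(ancestor_closure(g$ontology, t)),
                    oracle_ancestors(g$ontology, t))
    expect_true(g$ontology$root %in% names(ancestor_closure(g$ontology, t)))
  }
})

test_that("subtree exclusion removes the marked terms everywhere", {
  g <- generate_ontology(30, excluded_subtree_size = 7, seed = 16)
  expect_length(g$excluded_terms, 7)
  ann <- generate_group_annotations(g$ontology, 20, terms_per_gene = 3,
                                    seed = 17, excluded_terms = character(0))
  pruned <- prune_excluded_subtree(ann$annotations, g$ontology,
                                   g$excluded_root)
  expect_false(any(unlist(pruned) %in% g$excluded_terms))
  # a gene annotated only inside the subtree empties and is flagged
  only_sub <- annotation_map(list(gx = g$excluded_terms[1:2],
                                  gy = setdiff(g$ontology$terms,
                                               c(g$ontology$root,
                                                 g$excluded_terms))[1]))
  p2 <- prune_excluded_subtree(only_sub, g$ontology, g$excluded_root)
  expect_length(p2$gx, 0)
  expect_equal(attr(p2, "emptied"), "gx")
  expect_equal(p2$gy, only_sub$gy)   # untouched gene unchanged
})

# Hand-computed weight table on the toy ontology (root -> P -> {D1,D2},
# root -> Q; genes g1={D1,D2}, g2={D1}, g3={D2}, g4={Q}; G = 4):
#   descendant-inclusive counts: D1=2, D2=2, P=3, Q=1
#   rarity: D1=D2=-ln(1/2), P=-ln(3/4), Q=-ln(1/4)
test_that("feature vectors match a hand-computed weight table", {
  vecs <- build_feature_vectors(toy_annotations(), toy_ontology())
  r_d <- -log(0.5); r_p <- -log(0.75)
  # g1: each direct term at level 0 (weight 1 each), P reached from both
  # at level 1 -> 0.5 + 0.5 = 1; all divided by 2 direct terms
  expect_equal(vecs$g1[["D1"]], 0.5 * r_d)
  expect_equal(vecs$g1[["D2"]], 0.5 * r_d)
  expect_equal(vecs$g1[["P"]], 0.5 * r_p)
  # g2: single direct term, parent at half weight
  expect_equal(vecs$g2[["D1"]], r_d)
  expect_equal(vecs$g2[["P"]], 0.5 * r_p)
  # root is dropped from every vector
  expect_false("root" %in% names(vecs$g1))
})

test_that("a small decay limits vectors to near the direct terms", {
  cfg <- similarity_config(decay = 1e-9)
  vecs <- build_feature_vectors(toy_annotations(), toy_ontology(), cfg)
  w <- vecs$g2
  expect_gt(w[["D1"]], 1e6 * w[["P"]])
})

test_that("excluded terms cannot re-enter vectors as ancestors", {
  g <- generate_ontology(30, excluded_subtree_size = 7, seed = 18)
  ann <- generate_group_annotations(g$ontology, 15, terms_per_gene = 3,
                                    seed = 19, excluded_terms = character(0))
  cfg <- similarity_config(excluded_root = g$excluded_root)
  vecs <- suppressWarnings(build_feature_vectors(ann$annotations,
                                                 g$ontology, cfg))
  expect_false(any(unlist(lapply(vecs, names)) %in% g$excluded_terms))
})

test_that("pairwise similarity is Pearson over the union, symmetric, bounded", {
  v1 <- c(A = 1, B = 2, C = 0.5, D = 1, E = 3)
  v2 <- c(C = 2, D = 1, E = 0.3, F = 1, G = 2)
  terms <- union(names(v1), names(v2))   # 7-term union
  x <- ifelse(terms %in% names(v1), v1[terms], 0)
  y <- ifelse(terms %in% names(v2), v2[terms], 0)
  expect_equal(pairwise_similarity(v1, v2), oracle_pearson(x, y))
  expect_equal(pairwise_similarity(v1, v2), pairwise_similarity(v2, v1))
  expect_equal(pairwise_similarity(v1, v1), 1.0)
  expect_lt(abs(pairwise_similarity(v1, v2)), 1 + 1e-12)
  # disjoint vectors anticorrelate over the union
  expect_lt(pairwise_similarity(c(A = 1, B = 1), c(C = 1, D = 1)), 0.5)
  # zero variance over the union -> undefined
  expect_true(is.na(pairwise_similarity(c(A = 1), c(A = 1))))
})

test_that("group mean similarity averages the defined pair scores", {
  v <- list(a = c(X = 1, Y = 2, Z = 0), b = c(X = 1, Y = 2, Z = 0),
            c = c(X = 2, Y = 0, W = 1))
  s_ab <- pairwise_similarity(v$a, v$b)
  s_ac <- pairwise_similarity(v$a, v$c)
  s_bc <- pairwise_similarity(v$b, v$c)
  g <- group_mean_similarity(c("a", "b", "c"), v)
  expect_equal(g$mean_score, mean(c(s_ab, s_ac, s_bc)))
  expect_equal(g$n_pairs, 3)
  expect_equal(group_mean_similarity(c("a", "b"), v)$mean_score, 1.0)
  expect_error(group_mean_similarity("a", v), ">= 2")
  expect_error(group_mean_similarity(c("a", "zz"), v), "zz")
})

test_that("similarity matrix agrees with direct pairwise computation", {
  g <- generate_ontology(40, seed = 23)
  ann <- generate_group_annotations(g, 12, terms_per_gene = 4, seed = 24)
  vecs <- build_feature_vectors(ann$annotations, g$ontology)
  m <- similarity_matrix(vecs)
  expect_equal(m["H0003", "H0007"],
               pairwise_similarity(vecs$H0003, vecs$H0007))
  expect_equal(m, t(m))
})

test_that("null test is directional and hits the floor for coherent groups", {
  g <- generate_ontology(60, seed = 25)
  ann <- generate_group_annotations(
    g, 60,
    groups = list(list(size = 8, coherence = 0.9, pool_size = 6)),
    terms_per_gene = 4, seed = 26)
  vecs <- build_feature_vectors(ann$annotations, g$ontology)
  m <- similarity_matrix(vecs)
  grp <- ann$truth$groups[[1]]$genes
  res <- similarity_null_test(grp, m, n_samples = 199, seed = 27)
  expect_equal(res$p_empirical, 1 / 200)
  expect_gt(res$mean_score, res$null_mean)
  expect_lte(res$null_q25, res$null_q75)
  # a group scoring below its null has p > 0.5
  low <- res$null_mean - 10   # impossible-to-beat observed
  expect_gt(empirical_pvalue(low, rnorm(100)), 0.5)
  expect_error(similarity_null_test(rownames(m)[1:3], m[1:2, 1:2],
                                    n_samples = 10, seed = 1),
               "universe|vector")
})

test_that("more shared annotation produces higher median similarity", {
  g <- generate_ontology(50, seed = 28)
  meds <- vapply(c(0, 0.5, 1), function(coh) {
    sims <- vapply(1:15, function(i) {
      ann <- generate_group_annotations(
        g, 10, groups = list(list(size = 2, coherence = coh, pool_size = 4)),
        terms_per_gene = 4, seed = 300 + 17 * i)
      vecs <- build_feature_vectors(ann$annotations, g$ontology)
      grp <- ann$truth$groups[[1]]$genes
      s <- pairwise_similarity(vecs[[grp[1]]], vecs[[grp[2]]])
      if (is.na(s)) 1.0 else s     # identical constant vectors
    }, 0.0)
    median(sims)
  }, 0.0)
  expect_true(all(diff(meds) >= 0))
})

test_that("top over-represented features match an exact enumeration oracle", {
  g <- generate_ontology(40, seed = 29)
  ann <- generate_group_annotations(
    g, 30, groups = list(list(size = 8, coherence = 0.8, pool_size = 5)),
    terms_per_gene = 3, seed = 30)
  grp <- ann$truth$groups[[1]]$genes
  tf <- suppressWarnings(
    top_overrepresented_features(grp, ann$annotations, g$ontology, K = 500))
  # recompute every term's p with the independent factorial oracle
  closure_of <- function(terms) {
    unique(unlist(lapply(terms, function(t)
      names(ancestor_closure(g$ontology, t)))))
  }
  member <- lapply(ann$annotations, closure_of)
  N <- length(member); n <- length(grp)
  for (i in sample(nrow(tf), 10)) {
    t <- tf$term[i]
    k <- sum(vapply(member[grp], function(x) t %in% x, TRUE))
    K <- sum(vapply(member, function(x) t %in% x, TRUE))
    expect_equal(tf$p[i], oracle_hyper_upper(k, K, n, N), tolerance = 1e-10)
  }
  expect_true(!is.unsorted(tf$p))
  # a term carried by every set gene but few others ranks first
  expect_equal(tf$k_set[1], max(tf$k_set[tf$p == tf$p[1]]))
})

test_that("category composition maps features to top-level ancestors", {
  parents <- list(root = character(0), C1 = "root", C2 = "root")
  for (i in 1:10) parents[[paste0("a", i)]] <- "C1"
  for (i in 1:10) parents[[paste0("b", i)]] <- "C2"
  parents[["orphanish"]] <- "root"   # no top-level ancestor except itself
  ont <- ontology(parents)
  topA <- c(paste0("a", 1:8), paste0("b", 1:2))
  topB <- c(paste0("a", 1:2), paste0("b", 1:8))
  cc <- compare_category_composition(topA, topB, ont,
                                     top_level_terms = c("C1", "C2"))
  c1 <- cc[cc$category == "C1", ]
  expect_equal(c1$countA, 8)
  expect_equal(c1$countB, 2)
  expect_equal(c1$fold, 4)
  # equal counts give fold 1 and chi-squared p of 1 without correction
  cc2 <- compare_category_composition(paste0("a", 1:5), paste0("a", 2:6),
                                      ont, top_level_terms = c("C1", "C2"))
  expect_equal(cc2$fold[cc2$category == "C1"], 1)
  expect_equal(cc2$chi2_p[cc2$category == "C1"], NA_real_) # all in C1
  cc3 <- compare_category_composition(c(paste0("a", 1:3), paste0("b", 1:2)),
                                      c(paste0("a", 4:6), paste0("b", 3:4)),
                                      ont, top_level_terms = c("C1", "C2"))
  expect_equal(cc3$chi2_p[cc3$category == "C1"], 1)
  expect_error(compare_category_composition(topA, topB, ont,
                                            top_level_terms = "a1"),
               "children of root")
})

test_that("excluding an unrelated subtree leaves untouched pairs unchanged", {
  g <- generate_ontology(40, excluded_subtree_size = 5, seed = 31)
  usable <- setdiff(g$ontology$terms, c(g$ontology$root, g$excluded_terms))
  ann <- annotation_map(list(p1 = usable[1:3], p2 = usable[2:4],
                             p3 = usable[5:7]))
  plain <- build_feature_vectors(ann, g$ontology)
  excl <- build_feature_vectors(
    ann, g$ontology, similarity_config(excluded_root = g$excluded_root))
  # none of these genes touch the excluded subtree directly; ancestors
  # inside it are impossible by construction, so scores are identical
  expect_equal(pairwise_similarity(plain$p1, plain$p2),
               pairwise_similarity(excl$p1, excl$p2))
})
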