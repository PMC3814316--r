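#' Configuration of the phenotype-similarity scoring
#'
#' Controls the weighted feature vectors used for gene–gene phenotype
#' similarity. Each gene's direct ontology annotations are augmented with
#' all ancestor terms at geometrically decaying weight, terms are
#' weighted by rarity, and an optional subtree (e.g. the feature the gene
#' set was selected on) is excluded so that it cannot inflate similarity.
#'
#' @param decay per-level ancestor weight multiplier, strictly in (0, 1).
#'   A term `l` levels above a direct annotation contributes with factor
#'   `decay^l`.
#' @param length_norm divide direct-term weights by the number of direct
#'   terms of the gene, so heavily annotated genes do not dominate.
#' @param excluded_root term id whose descendant subtree (inclusive) is
#'   removed from every vector, or NULL.
#' @return list of class `"similarity_config"`.
#' @export
similarity_config <- function(decay = 0.5, length_norm = TRUE,
                              excluded_root = NULL) {
  if (!(decay > 0 && decay < 1)) stop("decay must be strictly in (0, 1)")
  structure(list(decay = decay, length_norm = length_norm,
                 excluded_root = excluded_root),
            class = "similarity_config")
}

#' Ancestor closure of a term with minimal levels
#'
#' Breadth-first walk up the parent relation: level 0 is the term itself,
#' level 1 its parents, and so on; a term reachable along several paths
#' gets its minimum level. The closure always contains the root.
#'
#' @param ont an [ontology()].
#' @param term a term id.
#' @return named integer vector: term id -> minimal level.
#' @export
ancestor_closure <- function(ont, term) {
  if (!term %in% ont$terms) stop("unknown term: ", term)
  level <- stats::setNames(0L, term)
  frontier <- term
  l <- 0L
  while (length(frontier) > 0) {
    l <- l + 1L
    nxt <- setdiff(unique(unlist(ont$parents[frontier])), names(level))
    if (length(nxt) > 0) level[nxt] <- l
    frontier <- nxt
  }
  level
}

# Internal: descendant closure (inclusive) of a term.
descendant_closure <- function(ont, term) {
  children <- split(
    rep(names(ont$parents), lengths(ont$parents)),
    unlist(ont$parents)
  )
  out <- term
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(children[frontier])), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Remove an ontology subtree from all annotations
#'
#' Removes every term in the descendant closure of `excluded_root`
#' (inclusive) from each gene's direct annotation set. Used to exclude
#' the feature the analyzed gene set was ascertained on, so similarity
#' reflects phenotypic overlap beyond the selection criterion. Genes left
#' with no annotation are retained with an empty set and flagged.
#'
#' @param annos an annotation map (named list gene -> term ids).
#' @param ont an [ontology()].
#' @param excluded_root term id of the subtree root.
#' @return pruned annotation map with attribute `emptied` (genes whose
#'   annotations were entirely inside the subtree).
#' @export
prune_excluded_subtree <- function(annos, ont, excluded_root) {
  if (!excluded_root %in% ont$terms) {
    stop("excluded_root not in ontology: ", excluded_root)
  }
  banned <- descendant_closure(ont, excluded_root)
  pruned <- lapply(annos, function(x) setdiff(x, banned))
  emptied <- names(annos)[lengths(pruned) == 0 & lengths(annos) > 0]
  structure(annotation_map(pruned), emptied = emptied, banned = banned)
}

# Internal: rarity weight per term, -ln(g_t / G) with descendant-inclusive
# gene counts g_t (a gene annotated to a term is implicitly annotated to
# all its ancestors) and frequency clipped to >= 1/G.
term_rarity <- function(annos, ont) {
  G <- length(annos)
  counts <- stats::setNames(integer(length(ont$terms)), ont$terms)
  closures <- lapply(ont$terms, function(t) names(ancestor_closure(ont, t)))
  names(closures) <- ont$terms
  for (g in names(annos)) {
    terms <- unique(unlist(closures[annos[[g]]]))
    counts[terms] <- counts[terms] + 1L
  }
  freq <- pmax(counts / G, 1 / G)
  -log(freq)
}

#' Build weighted phenotype feature vectors for all genes
#'
#' Each gene's vector assigns to term `t` the weight
#' `rarity(t) * sum_d decay^level_d(t) [ / n_direct ]`,
#' where the sum runs over the gene's direct terms `d` from which `t` is
#' reachable, `level_d(t)` is the minimal number of parent steps, and
#' `rarity(t) = -ln(g_t/G)` with descendant-inclusive annotation counts
#' `g_t` out of `G` annotated genes (frequency clipped to `1/G`). The
#' root term and any excluded subtree are dropped from the vectors; the
#' exclusion is enforced both before and after ancestor augmentation so
#' banned terms cannot re-enter as ancestors.
#'
#' @param annos annotation map of direct annotations.
#' @param ont an [ontology()].
#' @param cfg a [similarity_config()].
#' @return named list gene -> named numeric vector (term -> weight >= 0).
#'   Genes with no usable annotation after pruning are omitted, with a
#'   warning naming them.
#' @export
build_feature_vectors <- function(annos, ont, cfg = similarity_config()) {
  if (!is.null(cfg$excluded_root)) {
    annos <- prune_excluded_subtree(annos, ont, cfg$excluded_root)
    banned <- attr(annos, "banned")
  } else {
    banned <- character(0)
  }
  rarity <- term_rarity(annos, ont)
  empty <- names(annos)[lengths(annos) == 0]
  if (length(empty) > 0) {
    warning("gene(s) without usable annotation dropped: ",
            paste(empty, collapse = ", "))
  }
  annos <- annos[lengths(annos) > 0]
  vecs <- lapply(annos, function(direct) {
    acc <- numeric(0)
    for (d in direct) {
      cl <- ancestor_closure(ont, d)
      w <- cfg$decay ^ cl
      acc_terms <- union(names(acc), names(cl))
      a <- stats::setNames(numeric(length(acc_terms)), acc_terms)
      a[names(acc)] <- acc
      a[names(cl)] <- a[names(cl)] + w
      acc <- a
    }
    if (cfg$length_norm) acc <- acc / length(direct)
    acc <- acc * rarity[names(acc)]
    drop <- c(ont$root, banned)
    acc <- acc[setdiff(names(acc), drop)]
    acc
  })
  vecs[lengths(vecs) > 0]
}

#' Build one gene's weighted feature vector
#'
#' Convenience wrapper around [build_feature_vectors()] for a single
#' gene; the rarity weights are still computed on the full annotation
#' map.
#'
#' @param gene gene symbol present in `annos`.
#' @inheritParams build_feature_vectors
#' @return named numeric vector term -> weight.
#' @export
build_feature_vector <- function(gene, annos, ont,
                                 cfg = similarity_config()) {
  if (!gene %in% names(annos)) stop("gene not annotated: ", gene)
  v <- build_feature_vectors(annos, ont, cfg)[[gene]]
  if (is.null(v)) stop("gene has no usable annotation after pruning: ", gene)
  v
}

#' Pairwise phenotype similarity of two feature vectors
#'
#' Pearson correlation of the two weight vectors over the union of their
#' terms, with absent terms taken as weight 0. Undefined (NA) when either
#' vector is constant over the union (zero variance).
#'
#' @param vA,vB named numeric vectors from [build_feature_vectors()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return similarity in \[-1, 1\], or NA when undefined.
#' @export
pairwise_similarity <- function(vA, vB, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(vA) == 0 || length(vB) == 0) stop("empty feature vector")
  terms <- union(names(vA), names(vB))
  if (length(terms) < 2) return(NA_real_)   # no variance over the union
  a <- b <- stats::setNames(numeric(length(terms)), terms)
  a[names(vA)] <- vA
  b[names(vB)] <- vB
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b, method = method)
}

#' Pairwise similarity matrix over a set of genes
#'
#' @param vectors named list of feature vectors.
#' @param method correlation method, see [pairwise_similarity()].
#' @return symmetric numeric matrix with NA diagonal-off undefined pairs.
#' @export
similarity_matrix <- function(vectors, method = "pearson") {
  n <- length(vectors)
  genes <- names(vectors)
  m <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    m[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      s <- pairwise_similarity(vectors[[i]], vectors[[j]], method = method)
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}

#' Mean pairwise phenotype similarity of a gene group
#'
#' Mean over all unordered gene pairs with a defined similarity;
#' undefined pairs are excluded and counted.
#'
#' @param genes character vector of >= 2 genes.
#' @param vectors named list of feature vectors covering `genes`, or a
#'   precomputed [similarity_matrix()].
#' @return list: `mean_score`, `n_pairs`, `n_undefined`.
#' @export
group_mean_similarity <- function(genes, vectors) {
  genes <- unique(genes)
  if (is.matrix(vectors)) {
    missing <- setdiff(genes, rownames(vectors))
  } else {
    missing <- setdiff(genes, names(vectors))
  }
  if (length(missing) > 0) {
    stop("gene(s) without feature vector: ", paste(missing, collapse = ", "))
  }
  if (length(genes) < 2) stop("need >= 2 genes with defined vectors")
  if (is.matrix(vectors)) {
    sub <- vectors[genes, genes, drop = FALSE]
    scores <- sub[upper.tri(sub)]
  } else {
    cmb <- utils::combn(genes, 2)
    scores <- vapply(seq_len(ncol(cmb)), function(i) {
      pairwise_similarity(vectors[[cmb[1, i]]], vectors[[cmb[2, i]]])
    }, numeric(1))
  }
  n_undef <- sum(is.na(scores))
  if (n_undef == length(scores)) stop("no defined pairwise scores in group")
  list(mean_score = mean(scores, na.rm = TRUE),
       n_pairs = length(scores) - n_undef, n_undefined = n_undef)
}

#' Empirical null test of group phenotype similarity
#'
#' Compares a gene group's mean pairwise similarity with the means of
#' `n_samples` equal-sized gene sets sampled uniformly from the annotated
#' universe (without replacement within a sample, independently across
#' samples). Reports the null mean, the 25%/75% quartiles of the null
#' distribution, and the add-one empirical p-value.
#'
#' @param genes the gene group (>= 2 genes).
#' @param vectors named list of feature vectors for the whole universe,
#'   or a precomputed [similarity_matrix()] over it.
#' @param n_samples number of random control sets (default 1000).
#' @param seed integer seed.
#' @param universe optional character vector restricting the sampling
#'   pool (default: all genes with vectors).
#' @return list of class `"group_similarity_result"`: `mean_score`,
#'   `null_mean`, `null_q25`, `null_q75`, `p_empirical`, `n_samples`,
#'   `seed`.
#' @export
similarity_null_test <- function(genes, vectors, n_samples = 1000, seed,
                                 universe = NULL) {
  if (is.null(universe)) {
    universe <- if (is.matrix(vectors)) rownames(vectors) else names(vectors)
  }
  genes <- unique(genes)
  if (length(genes) < 2) stop("need >= 2 genes")
  if (length(universe) < length(genes)) {
    stop("universe smaller than the gene group")
  }
  obs <- group_mean_similarity(genes, vectors)$mean_score
  null_means <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      group_mean_similarity(sample(universe, length(genes)),
                            vectors)$mean_score
    }, numeric(1))
  })
  q <- stats::quantile(null_means, c(0.25, 0.75), names = FALSE)
  structure(
    list(mean_score = obs, null_mean = mean(null_means),
         null_q25 = q[1], null_q75 = q[2],
         p_empirical = empirical_pvalue(obs, null_means),
         n_samples = n_samples, seed = seed),
    class = "group_similarity_result"
  )
}

#' @export
print.group_similarity_result <- function(x, ...) {
  cat(sprintf(
    "<group similarity> mean %.3f vs null %.3f [IQR %.3f, %.3f], p = %.4g (%d samples)\n",
    x$mean_score, x$null_mean, x$null_q25, x$null_q75, x$p_empirical,
    x$n_samples))
  invisible(x)
}

# Internal: descendant-inclusive term membership per gene — the set of
# terms a gene is annotated to directly or through the hierarchy.
gene_term_membership <- function(annos, ont) {
  lapply(annos, function(terms) {
    unique(unlist(lapply(terms, function(t) names(ancestor_closure(ont, t)))))
  })
}

#' Most over-represented ontology features of a gene set
#'
#' For every term (counting direct and inherited membership), tests
#' whether the term's gene count within `gene_set` is higher than
#' expected from the annotated universe (upper-tail hypergeometric).
#' Terms are ranked by ascending p, ties broken by higher fold enrichment
#' then term id; the first `K` are returned. Benjamini-Hochberg q-values
#' are included.
#'
#' @param gene_set character vector of genes (subset of the universe).
#' @param universe_annos annotation map of the whole universe.
#' @param ont an [ontology()].
#' @param K number of top features to return (default 200); if fewer
#'   terms are testable, all are returned with a warning.
#' @return data.frame: `term`, `name`, `k_set`, `k_universe`, `fold`,
#'   `p`, `q`, `rank`.
#' @export
top_overrepresented_features <- function(gene_set, universe_annos, ont,
                                         K = 200) {
  if (!all(gene_set %in% names(universe_annos))) {
    stop("gene set contains unannotated gene(s)")
  }
  membership <- gene_term_membership(universe_annos, ont)
  N <- length(universe_annos)
  n <- length(gene_set)
  in_set <- names(universe_annos) %in% gene_set
  tab_all <- table(unlist(membership))
  tab_set <- table(unlist(membership[in_set]))
  terms <- setdiff(names(tab_set), ont$root)   # root annotates every gene
  if (length(terms) == 0) stop("no testable terms for gene set")
  k <- as.integer(tab_set[terms])
  Kuniv <- as.integer(tab_all[terms])
  p <- vapply(seq_along(terms), function(i) {
    hypergeometric_pvalue(k[i], Kuniv[i], n, N)
  }, numeric(1))
  fold <- (k / n) / (Kuniv / N)
  ord <- order(p, -fold, terms)
  res <- data.frame(term = terms[ord],
                    name = unname(ont$names[terms[ord]]),
                    k_set = k[ord], k_universe = Kuniv[ord],
                    fold = fold[ord], p = p[ord],
                    q = stats::p.adjust(p, method = "BH")[ord],
                    stringsAsFactors = FALSE)
  res$rank <- seq_len(nrow(res))
  if (K > nrow(res)) {
    warning("K = ", K, " exceeds the ", nrow(res), " testable terms; ",
            "returning all")
    K <- nrow(res)
  }
  utils::head(res, K)
}

#' Compare top-level ontology category composition of two feature lists
#'
#' Maps each feature (term) of two top-feature lists to every top-level
#' category (child of the root) it descends from, then compares per
#' category the counts out of the list length `K`: fold of proportions
#' and a chi-squared p-value on the (count, K - count) 2x2 table. A
#' feature descending from no top-level term is assigned to an
#' `"unclassified"` bucket. A feature under several top-level categories
#' contributes to each.
#'
#' @param topA,topB character vectors of term ids (e.g. the `term` column
#'   of [top_overrepresented_features()] output), typically equal length.
#' @param ont an [ontology()].
#' @param top_level_terms the top-level category term ids (children of
#'   root); default: all children of the root.
#' @param yates apply continuity correction in the chi-squared test.
#' @return data.frame: `category`, `countA`, `countB`, `fold`, `chi2_p`.
#' @export
compare_category_composition <- function(topA, topB, ont,
                                         top_level_terms = NULL,
                                         yates = FALSE) {
  if (is.null(top_level_terms)) {
    top_level_terms <- ont$terms[
      vapply(ont$parents, function(p) ont$root %in% p, TRUE)]
  }
  bad <- top_level_terms[!vapply(ont$parents[top_level_terms],
                                 function(p) ont$root %in% p, TRUE)]
  if (length(bad) > 0) {
    stop("top-level term(s) not children of root: ",
         paste(bad, collapse = ", "))
  }
  assign_cats <- function(term) {
    anc <- names(ancestor_closure(ont, term))
    hits <- intersect(anc, top_level_terms)
    if (length(hits) == 0) "unclassified" else hits
  }
  catsA <- unlist(lapply(topA, assign_cats))
  catsB <- unlist(lapply(topB, assign_cats))
  levels <- c(top_level_terms, "unclassified")
  cA <- table(factor(catsA, levels = levels))
  cB <- table(factor(catsB, levels = levels))
  KA <- length(topA); KB <- length(topB)
  res <- data.frame(category = levels,
                    countA = as.integer(cA), countB = as.integer(cB),
                    stringsAsFactors = FALSE)
  res$fold <- mapply(function(a, b) fold_of_proportions(a, KA, b, KB),
                     res$countA, res$countB)
  res$chi2_p <- mapply(function(a, b) {
    tryCatch(chi2_2x2(a, KA - a, b, KB - b, yates = yates)$p,
             error = function(e) NA_real_)
  }, res$countA, res$countB)
  res
}
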