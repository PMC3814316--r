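# Internal: index a network's edges by integer node id for fast repeated
# within-set counting during permutation nulls.
network_index <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  nodes <- net$nodes
  ef <- match(net$edges$from, nodes)
  et <- match(net$edges$to, nodes)
  deg <- tabulate(c(ef, et), nbins = length(nodes))
  list(nodes = nodes, ef = ef, et = et, deg = deg)
}

count_within <- function(idx, members) {
  members <- members[!is.na(members)]   # genes absent from the network
  inset <- logical(length(idx$nodes))
  inset[members] <- TRUE
  sum(inset[idx$ef] & inset[idx$et])
}

#' Number of unique connections within a gene set
#'
#' Counts the unique unordered gene pairs of the network with both
#' endpoints inside `genes`. Genes absent from the network contribute no
#' edges.
#'
#' @param net an [interaction_network()].
#' @param genes character vector of gene ids.
#' @return integer edge count.
#' @export
within_set_edge_count <- function(net, genes) {
  idx <- network_index(net)
  count_within(idx, match(intersect(genes, idx$nodes), idx$nodes))
}

enrichment_result <- function(observed, null_counts, n_perm, seed) {
  null_mean <- mean(null_counts)
  degenerate <- FALSE
  if (null_mean == 0) {
    if (observed > 0) {
      fold <- Inf
    } else {
      fold <- 1
      degenerate <- TRUE
    }
  } else {
    fold <- observed / null_mean
  }
  structure(
    list(observed = observed, null_mean = null_mean,
         null_sd = stats::sd(null_counts), fold = fold,
         p_empirical = empirical_pvalue(observed, null_counts),
         n_perm = n_perm, seed = seed, degenerate = degenerate),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> observed %d, null %.2f +/- %.2f, fold %.2f, p = %.4g (%d perms)\n",
    x$observed, x$null_mean, x$null_sd, x$fold, x$p_empirical, x$n_perm))
  invisible(x)
}

#' Homotypic interaction enrichment of a phenotype category
#'
#' Tests whether genes sharing a phenotype category are more connected to
#' each other than expected: the observed number of unique connections
#' among `category_genes` is divided by the mean within-set connection
#' count of `n_perm` equal-sized gene sets drawn uniformly (without
#' replacement within a draw) from `universe`. The empirical p-value uses
#' the add-one estimator `(1 + #\{null >= obs\}) / (n_perm + 1)`, so its
#' floor is `1/(n_perm+1)`.
#'
#' @param net an [interaction_network()].
#' @param category_genes genes carrying the category (>= 2, subset of
#'   `universe`).
#' @param universe the gene pool the random sets are drawn from (e.g. all
#'   screened genes present in the network).
#' @param n_perm number of random sets (default 10000).
#' @param seed integer seed.
#' @param restrict_to_network if TRUE (default), random sets are drawn
#'   from the network-present members of `universe`; if FALSE, absent
#'   genes stay in the pool as degree-0 nodes.
#' @return an `enrichment_result`: `observed`, `null_mean`, `null_sd`,
#'   `fold`, `p_empirical`, `n_perm`, `seed`.
#' @export
homotypic_enrichment <- function(net, category_genes, universe,
                                 n_perm = 10000, seed,
                                 restrict_to_network = TRUE) {
  if (length(category_genes) < 2) stop("need >= 2 category genes")
  if (!all(category_genes %in% universe)) {
    stop("category genes must be contained in the universe")
  }
  if (restrict_to_network) {
    universe <- union(intersect(universe, net$nodes), category_genes)
  }
  idx <- network_index(net)
  obs <- count_within(idx, match(intersect(category_genes, idx$nodes),
                                 idx$nodes))
  uni <- match(universe, idx$nodes)   # NA for genes absent from network
  k <- length(category_genes)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      count_within(idx, uni[sample.int(length(uni), k)])
    }, integer(1))
  })
  enrichment_result(obs, null_counts, n_perm, seed)
}

# Internal: equal-frequency degree-quantile bin per node; bins with a
# single member are merged with the nearest lower bin so every gene has a
# substitute.
degree_bins_for <- function(deg, n_bins) {
  qs <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- findInterval(deg, qs, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- table(bin)
  lonely <- as.integer(names(counts)[counts < 2])
  while (length(lonely) > 0) {
    b <- lonely[1]
    target <- if (any(bin < b)) max(bin[bin < b]) else min(bin[bin > b])
    warning("degree bin with a single member widened (merged bin ", b,
            " into ", target, ")")
    bin[bin == b] <- target
    counts <- table(bin)
    lonely <- as.integer(names(counts)[counts < 2])
  }
  bin
}

#' Physical interaction enrichment (PIE) with a degree-matched null
#'
#' Like [homotypic_enrichment()], but the null corrects for the study
#' bias that well-studied (e.g. disease) genes have more reported
#' interactions: in each null draw every member of `gene_set` is replaced
#' by a gene sampled from the same degree-quantile bin of the whole
#' network (equal-frequency bins over node degree; a gene never
#' substitutes for itself within a draw). The PIE score is the observed
#' within-set connection count divided by the degree-matched null mean.
#'
#' @param net an [interaction_network()].
#' @param gene_set genes to score (>= 2, all present in the network).
#' @param n_samples number of null draws (default 1000).
#' @param seed integer seed.
#' @param degree_bins number of equal-frequency degree bins (default 10);
#'   bins left with a single member are widened with a warning.
#' @return an `enrichment_result` whose `fold` is the PIE score.
#' @export
pie_score <- function(net, gene_set, n_samples = 1000, seed,
                      degree_bins = 10) {
  idx <- network_index(net)
  members <- match(gene_set, idx$nodes)
  if (anyNA(members)) {
    stop("gene(s) not in network: ",
         paste(gene_set[is.na(members)], collapse = ", "))
  }
  if (length(members) < 2) stop("need >= 2 genes")
  obs <- count_within(idx, members)
  bin <- degree_bins_for(idx$deg, degree_bins)
  by_bin <- split(seq_along(idx$nodes), bin)
  member_bins <- bin[members]
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      repl <- integer(length(members))
      for (b in unique(member_bins)) {
        slots <- which(member_bins == b)
        cand <- by_bin[[as.character(b)]]
        pick <- cand[sample.int(length(cand), length(slots))]
        # no gene may stand in for itself within a draw
        tries <- 0L
        while (any(pick == members[slots]) && tries < 50L) {
          clash <- pick == members[slots]
          free <- setdiff(cand, pick)
          if (length(free) < sum(clash)) break
          pick[clash] <- free[sample.int(length(free), sum(clash))]
          tries <- tries + 1L
        }
        repl[slots] <- pick
      }
      count_within(idx, unique(repl))
    }, integer(1))
  })
  enrichment_result(obs, null_counts, n_samples, seed)
}

#' Extract homotypic phenotype modules
#'
#' A homotypic module is a maximal set of genes that share one screen
#' phenotype category and are connected through the interaction network:
#' the connected components (of size >= 2) of the subgraph induced on the
#' genes carrying the category. Genes with a non-overlapping phenotype
#' cannot be part of the same phenotype-based module because the subgraph
#' is induced per category. Modules are ordered by size (descending),
#' then by their lexicographically smallest gene.
#'
#' @param net an [interaction_network()].
#' @param profiles per-gene phenotype profiles (data.frame with `fly_id`
#'   or `gene_id` column and list-column `categories`), or a named list
#'   gene -> category vector.
#' @param category the phenotype category to extract modules for.
#' @return list of modules; each is a list with `category`, `genes`
#'   (sorted character vector) and `edges` (data.frame `from`/`to`).
#' @export
extract_homotypic_modules <- function(net, profiles, category) {
  check_categories(category)
  if (is.data.frame(profiles)) {
    idcol <- if ("gene_id" %in% names(profiles)) "gene_id" else "fly_id"
    carriers <- profiles[[idcol]][
      vapply(profiles$categories, function(x) category %in% x, TRUE)]
  } else {
    carriers <- names(profiles)[
      vapply(profiles, function(x) category %in% x, TRUE)]
  }
  carriers <- intersect(carriers, net$nodes)
  if (length(carriers) == 0) return(list())
  keep <- net$edges$from %in% carriers & net$edges$to %in% carriers
  sub <- net$edges[keep, c("from", "to"), drop = FALSE]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                     vertices = carriers)
  comp <- igraph::components(g)
  mods <- lapply(which(comp$csize >= 2), function(ci) {
    genes <- sort(names(comp$membership)[comp$membership == ci])
    e <- sub[sub$from %in% genes & sub$to %in% genes, , drop = FALSE]
    rownames(e) <- NULL
    list(category = category, genes = genes, edges = e)
  })
  ord <- order(-vapply(mods, function(m) length(m$genes), 1L),
               vapply(mods, function(m) m$genes[1], ""))
  mods[ord]
}

#' Summarize homotypic modules across all categories
#'
#' Counts modules, the union of genes across modules (a gene in modules
#' of two categories is counted once), and homotypic connections. The
#' connection count is reported both ways the notion can be read:
#' `n_connections_unique` deduplicates gene pairs across categories,
#' `n_connections_per_category` counts a pair once per category in which
#' it is homotypic.
#'
#' @param modules list of modules from [extract_homotypic_modules()],
#'   concatenated over categories.
#' @return list: `n_modules`, `n_genes_union`, `n_connections_unique`,
#'   `n_connections_per_category`.
#' @export
module_summary <- function(modules) {
  if (length(modules) == 0) {
    return(list(n_modules = 0L, n_genes_union = 0L,
                n_connections_unique = 0L, n_connections_per_category = 0L))
  }
  genes <- unique(unlist(lapply(modules, `[[`, "genes")))
  pair_keys <- unlist(lapply(modules, function(m) {
    if (nrow(m$edges) == 0) return(character(0))
    paste0(pmin(m$edges$from, m$edges$to), "\r",
           pmax(m$edges$from, m$edges$to))
  }))
  list(
    n_modules = length(modules),
    n_genes_union = length(genes),
    n_connections_unique = length(unique(pair_keys)),
    n_connections_per_category = length(pair_keys)
  )
}
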