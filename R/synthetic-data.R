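# Seeded generators that emulate the statistical structure of the real
# inputs (screen tables, interaction networks, ontologies, annotation
# maps, EST-style expression matrices). Every generator returns the data
# together with a `truth` record of what was planted, so recovery can be
# scored exactly in tests.

#' Generate a rooted DAG ontology with a designated excludable subtree
#'
#' Produces a single-root directed acyclic ontology of `n_terms` terms.
#' One marked subtree of exactly `excluded_subtree_size` terms (rooted at
#' a child of the root, with all parents internal to the subtree) models
#' an ascertainment feature that downstream similarity scoring must be
#' able to exclude cleanly. Remaining terms attach to 1..`max_parents`
#' earlier non-subtree terms, giving a DAG with multiple inheritance.
#'
#' @param n_terms total number of terms, >= `excluded_subtree_size + 2`.
#' @param max_parents maximal number of parents per term (default 2).
#' @param excluded_subtree_size size of the marked subtree (default 7).
#' @param seed integer seed.
#' @return list: `ontology` (an [ontology()]), `excluded_root` (the
#'   subtree's root term id), `excluded_terms` (all subtree term ids).
#' @export
generate_ontology <- function(n_terms, max_parents = 2,
                              excluded_subtree_size = 7, seed) {
  if (n_terms < excluded_subtree_size + 2) {
    stop("need n_terms >= excluded_subtree_size + 2")
  }
  with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    root <- ids[1]
    parents <- stats::setNames(vector("list", n_terms), ids)
    parents[[root]] <- character(0)
    sub <- ids[2:(1 + excluded_subtree_size)]
    parents[[sub[1]]] <- root
    for (i in seq_along(sub)[-1]) {
      parents[[sub[i]]] <- sample(sub[seq_len(i - 1)], 1)
    }
    rest <- setdiff(ids, c(root, sub))
    pool <- root
    for (t in rest) {
      np <- sample.int(min(max_parents, length(pool)), 1)
      parents[[t]] <- sample(pool, np)
      pool <- c(pool, t)
    }
    ont <- ontology(parents,
                    stats::setNames(paste("term", ids), ids))
    list(ontology = ont, excluded_root = sub[1], excluded_terms = sub)
  })
}

#' Generate a synthetic RNAi screen table with planted phenotype groups
#'
#' Emulates a screen with `lines_per_gene` independent RNAi lines per
#' gene. Genes in a planted group receive the group's category in each
#' line with probability `line_efficacy` (modelling variable knockdown
#' strength); background categories are drawn independently per gene from
#' `category_probs`. PI replicates are drawn Normal(true PI, `pi_noise`)
#' truncated to \[1, 6\]; planted phototaxis-defective genes get a true PI
#' below 4, all others a control-like true PI of 5.2.
#'
#' @param n_genes number of fly genes (ids `F0001`...).
#' @param category_probs named numeric vector: background probability per
#'   phenotype category (default: none).
#' @param planted_groups named list: category -> character vector of gene
#'   ids (or integer indices) planted with that category.
#' @param lines_per_gene RNAi lines per gene (default 2).
#' @param line_efficacy probability a planted line shows its category.
#' @param pi_noise replicate noise SD (default 0.4, small enough that
#'   control-like genes rarely cross the PI < 4 hit threshold).
#' @param seed integer seed.
#' @return list: `screen` (a screen table as from [read_screen_table()]),
#'   `truth` (planted group memberships, true PI per gene, seed).
#' @export
generate_screen_annotations <- function(n_genes, category_probs = NULL,
                                        planted_groups = list(),
                                        lines_per_gene = 2,
                                        line_efficacy = 0.8,
                                        pi_noise = 0.4, seed) {
  if (length(planted_groups) > 0) {
    check_categories(names(planted_groups), "planted group")
  }
  if (!is.null(category_probs)) {
    check_categories(names(category_probs), "background category")
    stopifnot(all(category_probs >= 0 & category_probs <= 1))
  }
  with_seed(seed, {
    genes <- sprintf("F%04d", seq_len(n_genes))
    planted_groups <- lapply(planted_groups, function(g) {
      if (is.numeric(g)) genes[g] else g
    })
    # one planted category per gene: overlapping groups with different
    # categories are rejected to keep truth unambiguous
    carrier <- unlist(planted_groups, use.names = FALSE)
    if (anyDuplicated(carrier)) {
      stop("planted groups overlap with inconsistent categories: ",
           carrier[duplicated(carrier)][1])
    }
    true_pi <- stats::setNames(rep(5.2, n_genes), genes)
    pdg <- planted_groups[["phototaxis_defective"]]
    if (length(pdg) > 0) true_pi[pdg] <- stats::runif(length(pdg), 2, 3.5)

    rows <- list()
    for (g in genes) {
      planted_cat <- names(planted_groups)[
        vapply(planted_groups, function(x) g %in% x, TRUE)]
      bg <- if (!is.null(category_probs)) {
        names(category_probs)[stats::runif(length(category_probs)) <
                              category_probs]
      } else character(0)
      for (l in seq_len(lines_per_gene)) {
        cats <- bg
        for (pc in planted_cat) {
          if (stats::runif(1) < line_efficacy) cats <- c(cats, pc)
        }
        reps <- pmin(6, pmax(1, stats::rnorm(3, true_pi[g], pi_noise)))
        rows[[length(rows) + 1L]] <- list(
          line_id = sprintf("%s_L%d", g, l), fly_id = g,
          s19 = round(stats::runif(1, 0.95, 1), 3),
          pi_replicates = reps,
          categories = sort(unique(setdiff(cats, "phototaxis_defective")))
        )
      }
    }
    screen <- data.frame(
      line_id = vapply(rows, `[[`, "", "line_id"),
      fly_id = vapply(rows, `[[`, "", "fly_id"),
      s19 = vapply(rows, `[[`, 0.0, "s19"),
      stringsAsFactors = FALSE
    )
    screen$pi_replicates <- lapply(rows, `[[`, "pi_replicates")
    screen$categories <- lapply(rows, `[[`, "categories")
    list(screen = screen,
         truth = list(genes = genes, planted_groups = planted_groups,
                      true_pi = true_pi, line_efficacy = line_efficacy,
                      seed = seed))
  })
}

#' Write a screen table to TSV
#'
#' @param screen screen table (as produced by
#'   [generate_screen_annotations()] or [read_screen_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  nrep <- max(lengths(screen$pi_replicates), 1)
  reps <- t(vapply(screen$pi_replicates, function(r) {
    c(r, rep(NA_real_, nrep - length(r)))
  }, numeric(nrep)))
  df <- data.frame(line_id = screen$line_id, fly_id = screen$fly_id,
                   s19 = screen$s19, stringsAsFactors = FALSE)
  for (i in seq_len(nrep)) df[[paste0("pi_rep", i)]] <- round(reps[, i], 4)
  df$categories <- vapply(screen$categories, paste, "", collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Generate a sparse interaction network with planted modules
#'
#' Erdos-Renyi background at `background_density` over `n_genes` nodes
#' (ids `G0001`...), with extra edges planted inside each module at
#' `within_density`, emulating the within-category connection excess of a
#' combined multi-source interaction network.
#'
#' @param n_genes number of genes.
#' @param background_density background edge probability.
#' @param planted_modules list of `list(genes = ..., within_density = ...)`
#'   where `genes` is a character vector of gene ids or integer indices.
#' @param seed integer seed.
#' @param gene_ids optional character vector of node ids (length
#'   `n_genes`); default `G0001`, `G0002`, ...
#' @return list: `network` (an [interaction_network()]), `truth` (module
#'   memberships and densities, seed).
#' @export
generate_interaction_network <- function(n_genes, background_density,
                                         planted_modules = list(), seed,
                                         gene_ids = NULL) {
  stopifnot(background_density >= 0, background_density <= 1)
  with_seed(seed, {
    genes <- if (is.null(gene_ids)) {
      sprintf("G%04d", seq_len(n_genes))
    } else {
      stopifnot(length(gene_ids) == n_genes)
      gene_ids
    }
    planted_modules <- lapply(planted_modules, function(m) {
      g <- if (is.numeric(m$genes)) genes[m$genes] else m$genes
      if (!all(g %in% genes)) stop("module gene outside gene range")
      list(genes = g, within_density = m$within_density)
    })
    pairs <- utils::combn(genes, 2)
    keep <- stats::runif(ncol(pairs)) < background_density
    from <- pairs[1, keep]; to <- pairs[2, keep]
    for (m in planted_modules) {
      mp <- utils::combn(sort(m$genes), 2)
      mk <- stats::runif(ncol(mp)) < m$within_density
      from <- c(from, mp[1, mk]); to <- c(to, mp[2, mk])
    }
    net <- interaction_network(from, to, sources = "synthetic",
                               nodes = genes)
    list(network = net,
         truth = list(genes = genes, modules = planted_modules,
                      background_density = background_density, seed = seed))
  })
}

#' Write a network's edge list to TSV
#'
#' Two tab-separated columns, no header — the edge-list dialect read by
#' [load_interaction_edges()].
#'
#' @param net an [interaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_edges <- function(net, path) {
  utils::write.table(net$edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate group-coherent gene-to-term annotations
#'
#' Emulates a gene-to-phenotype annotation map in which some gene groups
#' share phenotypic structure: each group has a hidden pool of terms, and
#' members draw a fraction `coherence` of their `terms_per_gene` terms
#' from the pool, the remainder uniformly from all non-excluded,
#' non-root terms. Background genes draw fully uniformly. With coherence
#' 1 and a pool of exactly `terms_per_gene` terms, group members are
#' annotated identically; with coherence 0 a group is indistinguishable
#' from background.
#'
#' @param ont ontology from [generate_ontology()] (the result list, or an
#'   [ontology()] plus `excluded_terms` argument).
#' @param n_genes number of genes (ids `H0001`...).
#' @param groups list of `list(size = ..., coherence = ..., pool_size = ...)`
#'   (pool_size defaults to `terms_per_gene`).
#' @param terms_per_gene direct terms per gene (default 4).
#' @param seed integer seed.
#' @param excluded_terms terms never used for annotation (defaults to the
#'   generated ontology's marked subtree).
#' @return list: `annotations` (an annotation map), `truth` (group
#'   memberships and pools, seed).
#' @export
generate_group_annotations <- function(ont, n_genes, groups = list(),
                                       terms_per_gene = 4, seed,
                                       excluded_terms = NULL) {
  if (is.list(ont) && !inherits(ont, "ontology")) {
    if (is.null(excluded_terms)) excluded_terms <- ont$excluded_terms
    ont <- ont$ontology
  }
  usable <- setdiff(ont$terms, c(ont$root, excluded_terms))
  with_seed(seed, {
    genes <- sprintf("H%04d", seq_len(n_genes))
    truth_groups <- list()
    membership <- rep(0L, n_genes)
    next_gene <- 1L
    pools <- list()
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      pool_size <- if (is.null(g$pool_size)) terms_per_gene else g$pool_size
      if (pool_size > length(usable)) stop("term pool larger than ontology")
      members <- genes[next_gene:(next_gene + g$size - 1L)]
      next_gene <- next_gene + g$size
      pool <- sample(usable, pool_size)
      pools[[gi]] <- pool
      membership[match(members, genes)] <- gi
      truth_groups[[gi]] <- list(genes = members, coherence = g$coherence,
                                 pool = pool)
    }
    annos <- lapply(seq_len(n_genes), function(i) {
      gi <- membership[i]
      if (gi > 0) {
        coh <- groups[[gi]]$coherence
        n_pool <- round(coh * terms_per_gene)
        n_pool <- min(n_pool, length(pools[[gi]]))
        from_pool <- if (n_pool > 0) sample(pools[[gi]], n_pool) else character(0)
        rest <- sample(setdiff(usable, from_pool),
                       terms_per_gene - n_pool)
        sort(unique(c(from_pool, rest)))
      } else {
        sort(sample(usable, terms_per_gene))
      }
    })
    names(annos) <- genes
    list(annotations = annotation_map(annos),
         truth = list(groups = truth_groups, seed = seed))
  })
}

#' Generate an EST-style expression matrix with spiked genes
#'
#' Baseline abundances are log-normal (meanlog 0, sdlog 1 — a heavy
#' right tail typical of EST counts), multiplied by per-tissue scale
#' factors spanning roughly an order of magnitude (so average expression
#' differs strongly between tissues, which is why downstream assignment
#' works on within-tissue ranks). Spiked (gene, tissue) entries are
#' multiplied by `foldboost`.
#'
#' @param n_genes number of genes (ids `E0001`...).
#' @param tissues number of tissues or a character vector of tissue names
#'   (default 45).
#' @param spiked data.frame with columns `gene`, `tissue`, `foldboost`
#'   (gene may be an integer index; tissue an index or name), or NULL.
#' @param seed integer seed.
#' @return list: `expression` (genes x tissues matrix), `truth` (spiked
#'   pairs, tissue scale factors, seed).
#' @export
generate_expression_matrix <- function(n_genes, tissues = 45,
                                       spiked = NULL, seed) {
  if (length(tissues) == 1 && is.numeric(tissues)) {
    tissues <- sprintf("tissue_%02d", seq_len(tissues))
  }
  with_seed(seed, {
    genes <- sprintf("E%04d", seq_len(n_genes))
    scale <- stats::setNames(10 ^ stats::runif(length(tissues), -0.5, 0.5),
                             tissues)
    m <- matrix(stats::rlnorm(n_genes * length(tissues)),
                nrow = n_genes, dimnames = list(genes, tissues))
    m <- sweep(m, 2, scale, `*`)
    if (!is.null(spiked) && nrow(spiked) > 0) {
      sg <- if (is.numeric(spiked$gene)) genes[spiked$gene] else spiked$gene
      st <- if (is.numeric(spiked$tissue)) tissues[spiked$tissue] else spiked$tissue
      if (anyDuplicated(sg)) {
        stop("duplicate spike for gene ", sg[duplicated(sg)][1])
      }
      if (any(spiked$foldboost <= 1)) stop("foldboost must exceed 1")
      for (i in seq_along(sg)) {
        m[sg[i], st[i]] <- m[sg[i], st[i]] * spiked$foldboost[i]
      }
      spiked <- data.frame(gene = sg, tissue = st,
                           foldboost = spiked$foldboost,
                           stringsAsFactors = FALSE)
    }
    list(expression = m,
         truth = list(spiked = spiked, tissue_scale = scale, seed = seed))
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Generates and writes every input the pipeline consumes — ontology
#' (OBO), gene/orthology table, screen table, interaction edge list,
#' gene-to-phenotype annotations and expression matrix (all TSV) — plus
#' a `truth.json` recording what was planted. All generation is driven
#' by `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_genes number of screened fly genes.
#' @param n_terms ontology size.
#' @param n_tissues number of tissues.
#' @return invisibly, a list with the in-memory objects and `truth`.
#' @export
simulate_bundle <- function(dir, seed, n_genes = 120, n_terms = 80,
                            n_tissues = 45) {
  if (n_genes < 40) stop("the default bundle plants groups over 32 genes; ",
                         "use n_genes >= 40")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sprintf("F%04d", seq_len(n_genes))

  planted <- list(
    rough = genes[1:10],
    long_bristles = genes[11:18],
    lethal = genes[19:26],
    phototaxis_defective = genes[27:32]
  )
  scr <- generate_screen_annotations(
    n_genes, category_probs = c(necrosis = 0.05, small_eye = 0.05),
    planted_groups = planted, seed = derive_seed(seed, "screen"))

  human <- sprintf("HS%04d", seq_len(n_genes))
  n_paralog <- min(8, n_genes)
  hs <- as.list(human)
  hs[seq_len(n_paralog)] <- lapply(seq_len(n_paralog), function(i) {
    c(human[i], paste0(human[i], "B"))
  })
  gene_tab <- data.frame(fly_id = genes, is_screened = TRUE,
                         stringsAsFactors = FALSE)
  gene_tab$human_symbols <- hs

  netmods <- lapply(names(planted), function(cat) {
    list(genes = planted[[cat]], within_density = 0.7)
  })
  net <- generate_interaction_network(
    n_genes, background_density = 0.02, planted_modules = netmods,
    seed = derive_seed(seed, "network"), gene_ids = genes)
  ontg <- generate_ontology(n_terms, seed = derive_seed(seed, "ontology"))
  ann <- generate_group_annotations(
    ontg, n_genes,
    groups = list(list(size = 12, coherence = 0.8)),
    terms_per_gene = 4, seed = derive_seed(seed, "annotations"))
  names(ann$annotations) <- human[seq_len(n_genes)]
  expr <- generate_expression_matrix(
    n_genes, tissues = n_tissues,
    spiked = data.frame(gene = 1:12, tissue = 1, foldboost = 50),
    seed = derive_seed(seed, "expression"))
  rownames(expr$expression) <- human[seq_len(n_genes)]

  write_obo(ontg$ontology, file.path(dir, "ontology.obo"))
  gt <- gene_tab
  gt$human_symbols <- vapply(gt$human_symbols, paste, "", collapse = ",")
  utils::write.table(gt[, c("fly_id", "human_symbols", "is_screened")],
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_screen_table(scr$screen, file.path(dir, "screen.tsv"))
  write_interaction_edges(net$network, file.path(dir, "edges.tsv"))
  anns <- ann$annotations
  write_gene_phenotype_map(anns, file.path(dir, "gene_phenotypes.tsv"))
  write_expression_matrix(expr$expression, file.path(dir, "expression.tsv"))
  truth <- list(seed = seed, screen = scr$truth,
                network = list(modules = net$truth$modules,
                               background_density = 0.02),
                annotations = ann$truth, expression = expr$truth$spiked,
                excluded_root = ontg$excluded_root)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, gene_table = gene_tab, screen = scr$screen,
                 network = net$network, ontology = ontg,
                 annotations = ann$annotations,
                 expression = expr$expression, truth = truth))
}
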