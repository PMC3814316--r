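#' Build a pipeline configuration
#'
#' Collects the input paths and tuning parameters of a full analysis
#' run. One global `seed` deterministically derives per-stage seeds (by
#' stage-name hashing), so individual stages can be rerun in isolation
#' and still reproduce the full run.
#'
#' @param genes_path gene/orthology table TSV.
#' @param screen_path per-line screen results TSV.
#' @param edges_paths named character vector of edge-list TSVs; names are
#'   used as source tags.
#' @param ontology_path OBO ontology file.
#' @param annotations_path gene-to-phenotype TSV.
#' @param expression_path expression matrix TSV.
#' @param out_dir output directory.
#' @param seed global integer seed (mandatory).
#' @param pi_threshold phototaxis hit threshold (default 4).
#' @param s19_min optional RNAi specificity filter (default NULL = off).
#' @param n_perm permutations for network enrichment (default 10000).
#' @param n_similarity_samples random control sets for similarity nulls
#'   (default 1000).
#' @param top_k_features top over-represented features compared between
#'   classes (default 200).
#' @param similarity [similarity_config()] block; its `excluded_root`
#'   names the ascertainment subtree to exclude.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(genes_path, screen_path, edges_paths,
                            ontology_path, annotations_path,
                            expression_path, out_dir, seed,
                            pi_threshold = 4.0, s19_min = NULL,
                            n_perm = 10000, n_similarity_samples = 1000,
                            top_k_features = 200,
                            similarity = similarity_config()) {
  if (missing(seed) || is.null(seed)) stop("a global seed is mandatory")
  counts <- c(n_perm = n_perm,
              n_similarity_samples = n_similarity_samples,
              top_k_features = top_k_features)
  bad <- names(counts)[counts <= 0]
  if (length(bad) > 0) {
    stop("configuration counts must be positive: ", paste(bad, collapse = ", "))
  }
  structure(
    list(genes_path = genes_path, screen_path = screen_path,
         edges_paths = edges_paths, ontology_path = ontology_path,
         annotations_path = annotations_path,
         expression_path = expression_path, out_dir = out_dir,
         seed = as.integer(seed), pi_threshold = pi_threshold,
         s19_min = s19_min, n_perm = n_perm,
         n_similarity_samples = n_similarity_samples,
         top_k_features = top_k_features, similarity = similarity),
    class = "pipeline_config"
  )
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full integrative phenomics pipeline
#'
#' Executes every stage in order — screen quantification and per-gene
#' phenotype aggregation, major-class assignment, orthology expansion,
#' within-tissue expression ranking and top-tissue assignment,
#' interaction-network enrichment per phenotype category plus homotypic
#' module extraction, and phenotype-similarity scoring with empirical
#' nulls — and writes per-stage TSVs, a machine-readable JSON summary
#' and a run log into the configured output directory. Reruns with the
#' same configuration and seed produce a byte-identical JSON summary.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logcon))
  pipeline_log(logcon, "pipeline start; package idphenomics ",
               as.character(utils::packageVersion("idphenomics")),
               "; R ", R.version.string, "; seed ", config$seed)

  stage <- function(name, expr) {
    pipeline_log(logcon, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  genes <- stage("read gene table", read_gene_table(config$genes_path))
  screen <- stage("read screen table", read_screen_table(config$screen_path))
  profiles <- stage("aggregate phenotypes", aggregate_gene_phenotypes(
    screen, s19_min = config$s19_min, pi_threshold = config$pi_threshold))
  report <- classify_report(profiles)
  human_profiles <- stage("orthology expansion",
                          expand_orthology(profiles, genes))

  nets <- stage("load interaction networks", {
    lapply(seq_along(config$edges_paths), function(i) {
      load_interaction_edges(config$edges_paths[[i]],
                             source_tag = names(config$edges_paths)[i])
    })
  })
  net <- do.call(merge_networks, nets)

  expr <- stage("read expression matrix",
                read_expression_matrix(config$expression_path))
  ranks <- rank_within_tissue(expr)
  top_tissue <- top_tissue_per_gene(ranks, expr)

  universe <- intersect(profiles$fly_id, net$nodes)
  present_cats <- sort(unique(unlist(profiles$categories)))
  enrich <- list()
  modules <- list()
  for (cat in present_cats) {
    cg <- profiles$fly_id[vapply(profiles$categories,
                                 function(x) cat %in% x, TRUE)]
    cg <- intersect(cg, universe)
    if (length(cg) >= 2) {
      enrich[[cat]] <- homotypic_enrichment(
        net, cg, universe, n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste0("enrich_", cat)))
    }
    modules <- c(modules, extract_homotypic_modules(net, profiles, cat))
  }
  modsum <- module_summary(modules)
  pipeline_log(logcon, "modules: ", modsum$n_modules, " covering ",
               modsum$n_genes_union, " genes")

  ont <- stage("parse ontology", parse_obo(config$ontology_path))
  annos <- stage("load annotations",
                 load_gene_phenotype_map(config$annotations_path, ont))
  vectors <- stage("build feature vectors", suppressWarnings(
    build_feature_vectors(annos, ont, config$similarity)))
  simmat <- similarity_matrix(vectors)

  sim_results <- list()
  for (cat in present_cats) {
    hum <- unique(human_profiles$human_symbol[
      vapply(human_profiles$categories, function(x) cat %in% x, TRUE)])
    hum <- intersect(hum, rownames(simmat))
    if (length(hum) >= 2) {
      sim_results[[cat]] <- similarity_null_test(
        hum, simmat, n_samples = config$n_similarity_samples,
        seed = derive_seed(config$seed, paste0("sim_", cat)))
    }
  }

  # per-stage TSV outputs
  prof_out <- data.frame(
    fly_id = profiles$fly_id,
    categories = vapply(profiles$categories, paste, "", collapse = ";"),
    major_classes = vapply(profiles$major_classes, paste, "", collapse = ";"),
    mean_pi = round(profiles$mean_pi, 4), pi_sd = round(profiles$pi_sd, 4),
    n_lines = profiles$n_lines, stringsAsFactors = FALSE)
  utils::write.table(prof_out, file.path(config$out_dir, "gene_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(top_tissue, file.path(config$out_dir, "top_tissue.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mod_out <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(category = m$category, module_index = i,
               size = length(m$genes),
               genes = paste(m$genes, collapse = ","),
               edges = paste(paste0(m$edges$from, "-", m$edges$to),
                             collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(mod_out)) {
    utils::write.table(mod_out, file.path(config$out_dir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sim_out <- do.call(rbind, lapply(names(sim_results), function(cat) {
    r <- sim_results[[cat]]
    data.frame(group = cat, mean_score = r$mean_score,
               null_mean = r$null_mean, q25 = r$null_q25, q75 = r$null_q75,
               p = r$p_empirical, n = r$n_samples, stringsAsFactors = FALSE)
  }))
  if (!is.null(sim_out)) {
    utils::write.table(sim_out, file.path(config$out_dir, "similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_genes = report$n_genes,
    n_any_phenotype = report$n_any_phenotype,
    class_counts = stats::setNames(as.list(report$classes$count),
                                   report$classes$class),
    category_counts = stats::setNames(as.list(report$categories$count),
                                      report$categories$category),
    network = list(n_nodes = length(net$nodes),
                   n_unique_connections = nrow(net$edges)),
    enrichment = lapply(enrich, function(e) {
      list(observed = e$observed, null_mean = e$null_mean, fold = e$fold,
           p_empirical = e$p_empirical, n_perm = e$n_perm)
    }),
    module_summary = modsum,
    similarity = lapply(sim_results, function(r) {
      list(mean_score = r$mean_score, null_mean = r$null_mean,
           null_q25 = r$null_q25, null_q75 = r$null_q75,
           p_empirical = r$p_empirical, n_samples = r$n_samples)
    })
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  # effective configuration next to outputs, for reproducibility
  cfg_echo <- config
  cfg_echo$similarity <- unclass(cfg_echo$similarity)
  jsonlite::write_json(unclass(cfg_echo),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  pipeline_log(logcon, "pipeline complete")
  invisible(summary)
}
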