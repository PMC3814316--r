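#' Controlled vocabulary of screen phenotype categories
#'
#' The thirteen eye-morphology categories scored in the screen, plus the
#' lethality, phototaxis and electroretinogram (ERG) labels. Category
#' strings found anywhere in input files are validated against this
#' closed vocabulary; unknown labels are rejected at parse time.
#'
#' @format `phenotype_categories` is a character vector of 16 labels;
#'   `morphology_categories` is the 13-label eye-morphology subset.
#' @export
morphology_categories <- c(
  "mildly_rough", "rough", "partially_fused", "fused",
  "fewer_bristles", "no_bristles", "stubble_bristles", "long_bristles",
  "necrosis", "loss_of_pigmentation", "small_eye",
  "wrinkled_surface", "dented_surface"
)

#' @rdname morphology_categories
#' @export
phenotype_categories <- c(
  morphology_categories, "lethal", "phototaxis_defective", "erg_defective"
)

check_categories <- function(x, context = "category") {
  bad <- setdiff(x, phenotype_categories)
  if (length(bad) > 0) {
    stop("unknown ", context, " label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(phenotype_categories, collapse = ", "), ")")
  }
  invisible(x)
}

# ---- Ontology ---------------------------------------------------------------

#' Construct an ontology object
#'
#' A rooted directed acyclic graph of terms. `parents` is a named list
#' mapping each term id to the character vector of its parent ids (empty
#' for the root). Validation enforces acyclicity, a unique root, and that
#' every term reaches the root.
#'
#' @param parents named list: term id -> character vector of parent ids.
#' @param names named character vector of human-readable term names
#'   (optional, defaults to the ids).
#' @return an object of class `"ontology"` with elements `terms`
#'   (character vector of ids), `parents`, `names`, `root`.
#' @export
ontology <- function(parents, names = NULL) {
  ids <- base::names(parents)
  if (is.null(ids) || anyDuplicated(ids)) stop("term ids must be unique and named")
  unknown <- setdiff(unique(unlist(parents)), ids)
  if (length(unknown) > 0) {
    stop("parent id(s) not defined as terms: ", paste(unknown, collapse = ", "))
  }
  roots <- ids[vapply(parents, length, 1L) == 0]
  if (length(roots) == 0) stop("no root term (every term has a parent): cycle?")
  if (length(roots) > 1) {
    stop("multiple root terms: ", paste(roots, collapse = ", "))
  }
  check_ontology_acyclic(parents)
  if (is.null(names)) names <- stats::setNames(ids, ids)
  missing_names <- setdiff(ids, base::names(names))
  if (length(missing_names) > 0) {
    names[missing_names] <- missing_names
  }
  structure(
    list(terms = ids, parents = parents, names = names[ids], root = roots),
    class = "ontology"
  )
}

# Kahn topological sort over the child->parent relation; reports one cycle
# edge when the sort stalls.
check_ontology_acyclic <- function(parents) {
  indeg <- vapply(parents, length, 1L)
  remaining <- parents
  queue <- names(indeg)[indeg == 0]
  # child lists for decrementing
  children <- split(
    rep(names(parents), vapply(parents, length, 1L)),
    unlist(parents)
  )
  seen <- character(0)
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]
    seen <- c(seen, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(seen) < length(parents)) {
    bad <- setdiff(names(parents), seen)[1]
    stop("cycle detected in ontology involving edge ", bad, " -> ",
         parents[[bad]][1])
  }
  invisible(TRUE)
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", length(x$terms), " terms, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Parse a minimal OBO 1.2 file into an ontology
#'
#' Reads `[Term]` stanzas with `id`, `name` and `is_a` tags. Obsolete
#' terms (`is_obsolete: true`) are skipped; `is_a` references to skipped
#' or undefined terms are an error. Exactly one root (a term with no
#' `is_a`) must remain.
#'
#' @param path path to an OBO file.
#' @return an [ontology()] object.
#' @seealso [write_obo()]
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[Term\\]\\s*$", lines)
  if (length(stanza_starts) == 0) stop("no [Term] stanzas in ", path)
  other_stanzas <- grep("^\\[", lines)
  bounds <- c(other_stanzas, length(lines) + 1L)

  parents <- list()
  term_names <- character(0)
  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[s:end]
    idl <- grep("^id:", block, value = TRUE)
    if (length(idl) == 0) {
      stop("OBO parse error: [Term] stanza at line ", s, " has no id")
    }
    id <- trimws(sub("^id:", "", idl[1]))
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    nml <- grep("^name:", block, value = TRUE)
    nm <- if (length(nml) > 0) trimws(sub("^name:", "", nml[1])) else id
    isa <- trimws(sub("!.*$", "", sub("^is_a:", "", grep("^is_a:", block, value = TRUE))))
    isa <- isa[nzchar(isa)]
    parents[[id]] <- unique(isa)
    term_names[id] <- nm
  }
  ontology(parents, term_names)
}

#' Write an ontology to a minimal OBO 1.2 file
#'
#' @param ont an [ontology()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  out <- c("format-version: 1.2", "")
  for (id in ont$terms) {
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ont$names[[id]]),
             if (length(ont$parents[[id]]) > 0)
               paste0("is_a: ", ont$parents[[id]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- Interaction network ----------------------------------------------------

#' Construct an interaction network
#'
#' An undirected multi-source gene graph. Edges are stored once in
#' canonical (lexicographically sorted) orientation; each edge carries the
#' set of data sources that reported it, but a pair is one "unique
#' connection" regardless of how many sources report it. Self-loops are
#' dropped.
#'
#' @param from,to character vectors of gene ids (equal length).
#' @param sources list of character vectors (one per edge) or a single
#'   character tag recycled to all edges.
#' @param nodes optional character vector of node ids; nodes not incident
#'   to any edge (degree 0) are retained.
#' @return object of class `"interaction_network"` with elements `nodes`
#'   and `edges` (data.frame: `from`, `to`, list-column `sources`).
#' @export
interaction_network <- function(from = character(0), to = character(0),
                                sources = "unspecified", nodes = NULL) {
  stopifnot(length(from) == length(to))
  if (!is.list(sources)) sources <- rep(list(sources), length(from))
  keep <- from != to
  n_loops <- sum(!keep)
  if (n_loops > 0) {
    message(n_loops, " self-loop(s) dropped")
  }
  from <- from[keep]; to <- to[keep]; sources <- sources[keep]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- if (length(a) == 0) character(0) else paste0(a, "\r", b)
  first <- !duplicated(key)
  merged_sources <- lapply(split(sources, key), function(s) sort(unique(unlist(s))))
  edges <- data.frame(from = a[first], to = b[first], stringsAsFactors = FALSE)
  edges$sources <- merged_sources[key[first]]
  all_nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = all_nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " unique connections\n", sep = "")
  invisible(x)
}

#' Load an interaction edge list from a TSV file
#'
#' Expects two tab-separated gene-id columns (no header required;
#' '#'-prefixed comment lines are skipped). Self-loops are dropped with a
#' message; duplicate pairs in either orientation are merged.
#'
#' @param path path to the edge-list TSV.
#' @param source_tag label recorded on every edge, e.g. `"ppi_hprd"`,
#'   `"interolog"`, `"coap_complex"`, `"genetic"`.
#' @return an [interaction_network()].
#' @export
load_interaction_edges <- function(path, source_tag) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty edge file: ", path)
    return(interaction_network(sources = source_tag))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2)) {
    stop("malformed edge row ", which(nc != 2)[1], " in ", path,
         ": expected 2 tab-separated columns, got ", nc[nc != 2][1])
  }
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, `[[`, "", 2)
  interaction_network(from, to, sources = source_tag)
}

#' Merge interaction networks from multiple sources
#'
#' Unions nodes and edges; an edge present in several input networks
#' carries the union of their source tags but still counts as a single
#' unique connection.
#'
#' @param ... [interaction_network()] objects.
#' @return the combined [interaction_network()].
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  stopifnot(all(vapply(nets, inherits, TRUE, "interaction_network")))
  from <- unlist(lapply(nets, function(n) n$edges$from))
  to <- unlist(lapply(nets, function(n) n$edges$to))
  sources <- do.call(c, lapply(nets, function(n) n$edges$sources))
  nodes <- unique(unlist(lapply(nets, `[[`, "nodes")))
  interaction_network(from, to, sources = sources, nodes = nodes)
}

# ---- Gene-to-phenotype annotations -----------------------------------------

#' Load gene-to-ontology-term annotations
#'
#' Reads a tab-separated file in the HPO `genes_to_phenotype` dialect: a
#' header row, one gene-symbol column and one term-id column (matched by
#' name, case-insensitively; defaults cover `gene_symbol`/`term_id` and
#' the HPO column names). Rows whose term id is absent from the companion
#' ontology are dropped and counted; per-gene term sets are deduplicated.
#'
#' @param path path to the annotation TSV.
#' @param ont companion [ontology()]; terms are validated against it.
#' @param gene_col,term_col column names (defaults recognise common
#'   dialects).
#' @return a named list (class `"annotation_map"`): gene symbol ->
#'   character vector of direct term ids, with attribute `n_dropped`.
#' @export
load_gene_phenotype_map <- function(path, ont,
                                    gene_col = c("gene_symbol", "gene-symbol", "entrez-gene-symbol"),
                                    term_col = c("term_id", "hpo_id", "hpo-term-id")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(df))
  gi <- which(lc %in% tolower(gene_col))[1]
  ti <- which(lc %in% tolower(term_col))[1]
  if (is.na(gi) || is.na(ti)) {
    stop("annotation file ", path, " lacks gene/term columns; found: ",
         paste(names(df), collapse = ", "))
  }
  genes <- as.character(df[[gi]])
  terms <- as.character(df[[ti]])
  ok <- terms %in% ont$terms & nzchar(genes)
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no valid annotation rows in ", path)
  annos <- lapply(split(terms[ok], genes[ok]), function(x) sort(unique(x)))
  annotation_map(annos, n_dropped = n_dropped)
}

#' Construct an annotation map
#'
#' @param annos named list: gene symbol -> character vector of term ids.
#' @param n_dropped count of rows dropped during parsing (bookkeeping).
#' @return the list with class `"annotation_map"`.
#' @export
annotation_map <- function(annos, n_dropped = 0L) {
  if (is.null(names(annos)) || !all(nzchar(names(annos)))) {
    stop("annotation map requires nonempty gene symbols as names")
  }
  structure(annos, class = "annotation_map", n_dropped = n_dropped)
}

#' Write an annotation map to TSV (genes_to_phenotype dialect)
#'
#' @param annos an annotation map (named list gene -> term ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_phenotype_map <- function(annos, path) {
  df <- data.frame(
    gene_symbol = rep(names(annos), lengths(annos)),
    term_id = unlist(annos, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Gene table and orthology ----------------------------------------------

#' Read the fly-to-human gene/orthology table
#'
#' Tab-separated with header: `fly_id`, `human_symbols` (comma-separated,
#' at least one), `is_screened` (TRUE/FALSE). One fly gene may map to
#' several human symbols (one-to-many orthology).
#'
#' @param path path to the gene table TSV.
#' @return data.frame with columns `fly_id`, `human_symbols`
#'   (list-column), `is_screened`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("fly_id", "human_symbols", "is_screened")
  if (!all(req %in% names(df))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$fly_id)) {
    stop("duplicate fly_id in gene table: ",
         df$fly_id[duplicated(df$fly_id)][1])
  }
  hs <- strsplit(df$human_symbols, ",", fixed = TRUE)
  hs <- lapply(hs, function(x) trimws(x[nzchar(trimws(x))]))
  if (any(lengths(hs) == 0)) {
    stop("gene(s) with empty human_symbols: ",
         df$fly_id[lengths(hs) == 0][1])
  }
  out <- data.frame(fly_id = df$fly_id,
                    is_screened = as.logical(df$is_screened),
                    stringsAsFactors = FALSE)
  out$human_symbols <- hs
  out[, c("fly_id", "human_symbols", "is_screened")]
}

#' Expand per-fly-gene results to human orthologs
#'
#' Each fly gene's data row is duplicated to every human symbol listed for
#' it in the gene table, so phenotypes observed in the fly are assigned to
#' all of its human orthologs (one-to-many orthology expansion).
#'
#' @param profiles data.frame with a `fly_id` column (e.g. per-gene
#'   phenotype profiles).
#' @param genes gene table from [read_gene_table()].
#' @return `profiles` with rows duplicated per human symbol and a new
#'   first column `human_symbol`.
#' @export
expand_orthology <- function(profiles, genes) {
  missing <- setdiff(profiles$fly_id, genes$fly_id)
  if (length(missing) > 0) {
    stop("fly gene(s) absent from gene table: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(profiles$fly_id, genes$fly_id)
  reps <- lengths(genes$human_symbols[idx])
  out <- profiles[rep(seq_len(nrow(profiles)), reps), , drop = FALSE]
  out <- cbind(
    human_symbol = unlist(genes$human_symbols[idx], use.names = FALSE),
    out
  )
  rownames(out) <- NULL
  out
}
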