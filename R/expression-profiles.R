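#' Read a genes x tissues expression matrix from TSV
#'
#' First column: gene id; remaining columns: one per tissue, header row of
#' tissue names (EST-count profile layout). Entries must be non-negative.
#'
#' @param path path to the expression TSV.
#' @return numeric matrix, genes as rownames, tissues as colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression table needs gene id + >=1 tissue column")
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(colnames(m))) stop("duplicate tissue names")
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression value")
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr genes x tissues numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank genes within each tissue
#'
#' Average EST abundance differs strongly between tissue libraries, so
#' expression is compared through within-tissue ranks rather than raw
#' values: within each tissue column, genes are ranked ascending with
#' expression (1 = lowest), ties receiving the average rank. The result
#' is invariant under any strictly monotone transform of a tissue's
#' expression values.
#'
#' @param expr genes x tissues numeric matrix (>= 2 genes).
#' @return matrix of the same shape containing per-tissue ranks.
#' @export
rank_within_tissue <- function(expr) {
  if (is.null(dim(expr)) || nrow(expr) < 2 || ncol(expr) < 1) {
    stop("expression matrix must have >= 2 genes and >= 1 tissue")
  }
  apply(expr, 2, rank, ties.method = "average")
}

#' Tissue of highest normalized expression per gene
#'
#' Assigns each gene the tissue in which it reaches its highest
#' within-tissue rank. Rank ties across tissues are broken by the
#' declared tissue (column) order and flagged. Genes with all-zero
#' expression have no defined top tissue and are excluded (reported with
#' `NA` tissue).
#'
#' @param ranks rank matrix from [rank_within_tissue()].
#' @param expr optional original expression matrix, used to detect
#'   all-zero genes; defaults to treating every gene as expressed.
#' @return data.frame: `gene_id`, `top_tissue` (NA for all-zero genes),
#'   `tie` (TRUE when the top rank is shared by several tissues).
#' @export
top_tissue_per_gene <- function(ranks, expr = NULL) {
  tissues <- colnames(ranks)
  idx <- apply(ranks, 1, which.max)        # first maximum in tissue order
  tie <- apply(ranks, 1, function(r) sum(r == max(r)) > 1)
  top <- tissues[idx]
  if (!is.null(expr)) {
    allzero <- rowSums(expr) == 0
    top[allzero] <- NA_character_
    tie[allzero] <- FALSE
  }
  data.frame(gene_id = rownames(ranks), top_tissue = top, tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tissue enrichment of one gene class over another
#'
#' Compares the fraction of genes assigned a given top tissue between two
#' disjoint gene groups: `fold = (k_A/n_A) / (k_B/n_B)` with a two-sided
#' Fisher exact p-value on the underlying 2x2 table (assigned vs not, by
#' group). The fold is `Inf` when no group-B gene is assigned the tissue.
#'
#' @param groupA,groupB disjoint character vectors of gene ids.
#' @param assignments data.frame from [top_tissue_per_gene()].
#' @param tissue tissue name to test.
#' @param test `"fisher"` (default) or `"chisq"`.
#' @return list: `k_A`, `n_A`, `k_B`, `n_B`, `fold`, `p`.
#' @export
tissue_class_enrichment <- function(groupA, groupB, assignments, tissue,
                                    test = c("fisher", "chisq")) {
  test <- match.arg(test)
  if (length(groupA) == 0 || length(groupB) == 0) stop("empty gene group")
  if (length(intersect(groupA, groupB)) > 0) stop("groups must be disjoint")
  tt <- stats::setNames(assignments$top_tissue, assignments$gene_id)
  k_A <- sum(tt[groupA] == tissue, na.rm = TRUE)
  k_B <- sum(tt[groupB] == tissue, na.rm = TRUE)
  n_A <- length(groupA); n_B <- length(groupB)
  tab <- matrix(c(k_A, n_A - k_A, k_B, n_B - k_B), nrow = 2, byrow = TRUE)
  p <- if (test == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    chi2_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p
  }
  list(k_A = k_A, n_A = n_A, k_B = k_B, n_B = n_B,
       fold = fold_of_proportions(k_A, n_A, k_B, n_B), p = p)
}
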