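#' Phototaxis index from per-tube fly counts
#'
#' In the countercurrent phototaxis assay flies distribute over six tubes
#' according to their movement toward light. The phototaxis index is the
#' count-weighted mean tube number, `PI = sum(i * N_i) / N`, where `N_i`
#' is the number of flies in tube `i` (1..6) and `N = sum(N_i)`. It is
#' bounded in \[1, 6\]; higher values mean stronger phototaxis.
#'
#' @param counts integer vector of length 6: flies per tube, tube 1 first.
#' @return the phototaxis index, a single numeric value in \[1, 6\].
#' @examples
#' phototaxis_index(c(2, 1, 4, 9, 14, 30)) # 5.0
#' @export
phototaxis_index <- function(counts) {
  if (length(counts) != 6) stop("expected 6 tube counts, got ", length(counts))
  if (any(counts < 0)) stop("negative fly count")
  n <- sum(counts)
  if (n == 0) stop("phototaxis index undefined: no flies counted")
  sum(seq_len(6) * counts) / n
}

#' Summarize phototaxis-index replicates
#'
#' Computes the mean and sample standard deviation (n-1 denominator) of
#' replicate PI measurements for one RNAi line, typically three
#' independent experiments. A quality-control flag is raised when the
#' replicate spread exceeds `sd_max` (default 1.2, the maximal accepted
#' per-line standard deviation).
#'
#' @param replicates numeric vector of PI values, each in \[1, 6\].
#' @param sd_max QC ceiling on the replicate standard deviation.
#' @return list with `mean`, `sd` (NA when only one replicate) and
#'   `qc_flag` (TRUE when `sd > sd_max`).
#' @export
summarize_pi <- function(replicates, sd_max = 1.2) {
  if (length(replicates) == 0) stop("no PI replicates")
  m <- mean(replicates)
  s <- if (length(replicates) > 1) stats::sd(replicates) else NA_real_
  list(mean = m, sd = s, qc_flag = isTRUE(s > sd_max))
}

#' Phototaxis hit call
#'
#' A line is a phototaxis hit when its mean PI falls strictly below the
#' threshold (default 4.0, a stringent cut-off well separated from
#' control behaviour around PI 5.2).
#'
#' @param mean_pi mean phototaxis index of a line, in \[1, 6\].
#' @param threshold hit threshold; strict inequality is applied.
#' @return TRUE if `mean_pi < threshold`.
#' @export
classify_phototaxis_hit <- function(mean_pi, threshold = 4.0) {
  if (any(mean_pi < 1 | mean_pi > 6, na.rm = TRUE)) {
    stop("mean PI outside [1, 6]")
  }
  !is.na(mean_pi) & mean_pi < threshold
}

#' Read per-RNAi-line screen results
#'
#' Tab-separated with header: `line_id`, `fly_id`, `s19` (blank allowed),
#' `pi_rep1..pi_rep3` (blank allowed) and `categories`, a
#' semicolon-separated list of phenotype category labels validated
#' against [phenotype_categories].
#'
#' @param path path to the screen TSV.
#' @return data.frame with one row per line: `line_id`, `fly_id`, `s19`,
#'   list-column `pi_replicates`, list-column `categories`.
#' @export
read_screen_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("line_id", "fly_id", "s19", "categories")
  if (!all(req %in% names(df))) {
    stop("screen table must have columns: ", paste(req, collapse = ", "))
  }
  rep_cols <- grep("^pi_rep", names(df), value = TRUE)
  reps <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(df[i, rep_cols]))
    v <- v[!is.na(v)]
    if (any(v < 1 | v > 6)) {
      stop("PI replicate outside [1, 6] in line ", df$line_id[i])
    }
    v
  })
  cats <- lapply(strsplit(ifelse(is.na(df$categories), "", df$categories),
                          ";", fixed = TRUE),
                 function(x) sort(unique(trimws(x[nzchar(trimws(x))]))))
  check_categories(unlist(cats), context = "screen category")
  out <- data.frame(line_id = df$line_id, fly_id = df$fly_id,
                    s19 = suppressWarnings(as.numeric(df$s19)),
                    stringsAsFactors = FALSE)
  out$pi_replicates <- reps
  out$categories <- cats
  out
}

#' Aggregate per-line screen results into per-gene phenotype profiles
#'
#' RNAi knockdown is variable, so a gene is assigned every category
#' called in at least one of its passing lines (the "single hit" rule: a
#' single positive line suffices; requiring agreement across lines would
#' let one inefficient construct mask an efficient one). Lines failing
#' the optional `s19_min` specificity filter are excluded before the
#' union; lines with a missing s19 are treated as unfiltered. The
#' `phototaxis_defective` category is added when any passing line's mean
#' PI is a hit under `pi_threshold`.
#'
#' @param lines screen table from [read_screen_table()].
#' @param s19_min optional minimum s19 specificity score; NULL disables
#'   filtering (the default: screen lines are typically pre-filtered).
#' @param pi_threshold phototaxis hit threshold (strict `<`).
#' @return data.frame with one row per fly gene: `fly_id`, list-column
#'   `categories`, `mean_pi`, `pi_sd`, `n_lines`.
#' @export
aggregate_gene_phenotypes <- function(lines, s19_min = NULL,
                                      pi_threshold = 4.0) {
  if (nrow(lines) == 0) stop("no screen lines to aggregate")
  if (!is.null(s19_min)) {
    keep <- is.na(lines$s19) | lines$s19 >= s19_min
    lines <- lines[keep, , drop = FALSE]
  }
  genes <- unique(lines$fly_id)
  rows <- lapply(genes, function(g) {
    gl <- lines[lines$fly_id == g, , drop = FALSE]
    cats <- sort(unique(unlist(gl$categories)))
    line_means <- vapply(gl$pi_replicates, function(r) {
      if (length(r) == 0) NA_real_ else mean(r)
    }, numeric(1))
    assayed <- !is.na(line_means)
    if (any(assayed) && any(classify_phototaxis_hit(line_means[assayed],
                                                    pi_threshold))) {
      cats <- sort(unique(c(cats, "phototaxis_defective")))
    }
    all_reps <- unlist(gl$pi_replicates)
    list(fly_id = g, categories = cats,
         mean_pi = if (length(all_reps) > 0) mean(all_reps) else NA_real_,
         pi_sd = if (length(all_reps) > 1) stats::sd(all_reps) else NA_real_,
         n_lines = nrow(gl))
  })
  out <- data.frame(
    fly_id = vapply(rows, `[[`, "", "fly_id"),
    mean_pi = vapply(rows, `[[`, 0.0, "mean_pi"),
    pi_sd = vapply(rows, `[[`, 0.0, "pi_sd"),
    n_lines = vapply(rows, `[[`, 0L, "n_lines"),
    stringsAsFactors = FALSE
  )
  out$categories <- lapply(rows, `[[`, "categories")
  assign_major_classes(out)
}

#' Assign major phenotype classes to gene profiles
#'
#' Classes: `EMD` (eye morphology defective; any of the 13 morphology
#' categories), `ERG_defective`, `lethal`, and `NED` (no eye defect: no
#' category at all). Classes other than NED are not mutually exclusive —
#' a gene can be both EMD and ERG defective — but NED holds exactly when
#' the category set is empty.
#'
#' @param profiles data.frame with a list-column `categories`.
#' @return `profiles` with an added list-column `major_classes`.
#' @export
assign_major_classes <- function(profiles) {
  profiles$major_classes <- lapply(profiles$categories, function(cats) {
    cls <- character(0)
    if (length(cats) == 0) cls <- "NED"
    if (any(cats %in% morphology_categories)) cls <- c(cls, "EMD")
    if ("erg_defective" %in% cats) cls <- c(cls, "ERG_defective")
    if ("lethal" %in% cats) cls <- c(cls, "lethal")
    cls
  })
  profiles
}

#' Tabulate class and category membership across gene profiles
#'
#' @param profiles output of [aggregate_gene_phenotypes()].
#' @return list with `n_genes`, data.frames `classes` and `categories`
#'   (count and percentage of all genes), and `n_any_phenotype`.
#' @export
classify_report <- function(profiles) {
  n <- nrow(profiles)
  cls <- unlist(profiles$major_classes)
  cls_tab <- table(factor(cls, levels = c("EMD", "ERG_defective",
                                          "lethal", "NED")))
  cat_tab <- table(factor(unlist(profiles$categories),
                          levels = phenotype_categories))
  list(
    n_genes = n,
    n_any_phenotype = sum(lengths(profiles$categories) > 0),
    classes = data.frame(class = names(cls_tab),
                         count = as.integer(cls_tab),
                         percent = 100 * as.integer(cls_tab) / n,
                         stringsAsFactors = FALSE),
    categories = data.frame(category = names(cat_tab),
                            count = as.integer(cat_tab),
                            percent = 100 * as.integer(cat_tab) / n,
                            stringsAsFactors = FALSE)
  )
}
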