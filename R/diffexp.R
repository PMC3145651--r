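#' Per-gene two-sample Student t test
#'
#' Pooled-variance two-sided t test of case versus control for every gene,
#' with Benjamini-Hochberg adjusted q-values. Genes with zero pooled variance
#' get t = 0, p = 1. Welch's unequal-variance form is available behind
#' `var_equal = FALSE`.
#'
#' @param ds a complete (no missing values) `ExpressionDataset` with both
#'   classes present.
#' @param var_equal use the pooled-variance Student statistic (default); set
#'   `FALSE` for Welch.
#' @return a `DEGeneTable`: data frame with one row per gene and columns
#'   `gene`, `t_statistic`, `p_value`, `q_value`, `mean_case`,
#'   `mean_control`, `direction` (`up` iff `mean_case > mean_control`).
#' @export
per_gene_ttest <- function(ds, var_equal = TRUE) {
  .assert_binary_labels(ds$labels)
  if (n_missing(ds) > 0L) {
    stop("dataset contains missing values; run impute_and_filter() first")
  }
  case <- ds$values[, ds$labels == 1L, drop = FALSE]
  ctrl <- ds$values[, ds$labels == 0L, drop = FALSE]
  n1 <- ncol(case); n0 <- ncol(ctrl)
  if (n1 < 2L || n0 < 2L) stop("need >=2 samples per class")
  m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v0 <- rowSums((ctrl - m0)^2) / (n0 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  }
  tstat <- ifelse(se > 0, (m1 - m0) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
  out <- data.frame(gene = ds$gene_ids, t_statistic = tstat, p_value = p,
                    q_value = bh_qvalues(p), mean_case = m1, mean_control = m0,
                    direction = ifelse(m1 > m0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DEGeneTable", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment; monotone non-decreasing in p and
#' capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted q-values, same order as input.
#' @export
bh_qvalues <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Cross-dataset candidate marker selection
#'
#' A gene is an up-candidate iff it reaches `q <= q_threshold` with
#' direction `up` in every supplied table (or in at least one when
#' `require_all = FALSE`), and, when a concept gene set is given, belongs to
#' it; down-candidates are symmetric. Genes qualifying in both directions
#' (possible only with `require_all = FALSE`) are discarded, so the two sets
#' are always disjoint.
#'
#' @param tables a `DEGeneTable` or list of them (one per dataset).
#' @param q_threshold FDR cut-off in `(0, 1]` (default 0.05).
#' @param concept optional `GeneSet` restricting candidates (e.g. a cancer
#'   gene census list).
#' @param require_all require the criterion in every table (default) or any.
#' @return list with `GeneSet`s `up` and `down`.
#' @export
select_candidates <- function(tables, q_threshold = 0.05, concept = NULL,
                              require_all = TRUE) {
  if (inherits(tables, "DEGeneTable")) tables <- list(tables)
  if (length(tables) == 0L) stop("need at least one DE table")
  if (q_threshold <= 0 || q_threshold > 1) {
    stop("q_threshold must be in (0, 1]")
  }
  hits <- function(dir) {
    per_table <- lapply(tables, function(tb) {
      sort(tb$gene[tb$q_value <= q_threshold & tb$direction == dir])
    })
    if (require_all) Reduce(intersect, per_table)
    else sort(unique(unlist(per_table)))
  }
  up <- hits("up"); down <- hits("down")
  both <- intersect(up, down)
  up <- setdiff(up, both); down <- setdiff(down, both)
  if (!is.null(concept)) {
    cg <- as_gene_vector(concept)
    if (length(cg) == 0L) stop("concept gene set is empty")
    up <- intersect(up, cg); down <- intersect(down, cg)
  }
  list(up = gene_set(sort(up), "candidates_up"),
       down = gene_set(sort(down), "candidates_down"))
}
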