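#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' relative tolerance 1e-7, guarding floating-point ties). A table with a
#' zero margin carries no information and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative counts, or a vector
#'   `c(a, b, c, d)` filled by row.
#' @return two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, byrow = TRUE)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Immunohistochemistry composite score
#'
#' Semiquantitative staining score: each specimen component is a staining
#' intensity grade (0 negative, 1 weak, 2 moderate, 3 strong) with the
#' percentage of tumor cells at that grade; the composite score is the sum
#' of grade x percentage (range 0-300) and a specimen scoring at least 100
#' is called positive.
#'
#' @param components two-column data frame or matrix (`grade`, `percentage`),
#'   or a list of `c(grade, percentage)` pairs. Percentages must be
#'   non-negative and sum to at most 100.
#' @return list of class `IHCSample` with `components`, `score`, `positive`.
#' @export
ihc_composite_score <- function(components) {
  if (is.list(components) && !is.data.frame(components)) {
    components <- do.call(rbind, lapply(components, function(x) x[1:2]))
  }
  components <- as.matrix(components)
  if (ncol(components) != 2L) stop("components need (grade, percentage)")
  grade <- as.numeric(components[, 1L])
  pct <- as.numeric(components[, 2L])
  if (!all(grade %in% 0:3)) stop("grades must be integers 0-3")
  if (any(pct < 0)) stop("percentages must be non-negative")
  if (sum(pct) > 100 + 1e-9) stop("percentages sum to more than 100")
  score <- sum(grade * pct)
  structure(list(components = data.frame(grade = grade, percentage = pct),
                 score = score, positive = score >= 100),
            class = "IHCSample")
}

#' @export
print.IHCSample <- function(x, ...) {
  cat("IHC composite score:", x$score,
      if (x$positive) "(positive)" else "(negative)", "\n")
  invisible(x)
}

#' Association of a binary marker with a binary clinical variable
#'
#' Cross-tabulates marker status against the clinical category and tests
#' association with the two-sided Fisher exact test.
#'
#' @param status per-subject 0/1 marker status.
#' @param category per-subject 0/1 clinical variable.
#' @return list with the 2x2 `table` (status x category) and the Fisher `p`.
#' @export
group_association <- function(status, category) {
  if (length(status) != length(category)) stop("length mismatch")
  status <- as.integer(status); category <- as.integer(category)
  if (!all(status %in% c(0L, 1L)) || !all(category %in% c(0L, 1L))) {
    stop("both variables must be binary 0/1")
  }
  tab <- matrix(c(sum(status == 0L & category == 0L),
                  sum(status == 0L & category == 1L),
                  sum(status == 1L & category == 0L),
                  sum(status == 1L & category == 1L)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(status = c("0", "1"),
                                category = c("0", "1")))
  list(table = tab, p = fisher_exact_2x2(tab))
}
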