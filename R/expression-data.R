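#' Two-class expression dataset
#'
#' Container for a genes x samples expression matrix with binary phenotype
#' labels (1 = case/tumor, 0 = control/non-tumor). Missing values are allowed
#' at ingest and must be removed by [impute_and_filter()] before any model is
#' fitted.
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   give gene and sample identifiers.
#' @param labels per-sample labels, either 0/1 or a two-level factor/character
#'   vector (mapped via `case_label`).
#' @param case_label which input label codes the case (tumor) class when
#'   `labels` is not already 0/1.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `gene_ids`, `sample_ids`, `values`, `labels`.
#' @export
expression_dataset <- function(values, labels, case_label = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("values must carry gene (row) and sample (column) names")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (length(labels) != ncol(values)) {
    stop("need one label per sample: got ", length(labels), " labels for ",
         ncol(values), " samples")
  }
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    lev <- unique(as.character(labels))
    if (length(lev) > 2L) stop("labels must be binary; found levels: ",
                               paste(lev, collapse = ", "))
    if (is.null(case_label)) {
      stop("non 0/1 labels require case_label to identify the case class")
    }
    if (!case_label %in% lev) stop("case_label '", case_label,
                                   "' not among labels")
    labels <- as.integer(as.character(labels) == case_label)
  }
  structure(
    list(gene_ids = rownames(values), sample_ids = colnames(values),
         values = values, labels = as.integer(labels)),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("  cases:", sum(x$labels == 1L), " controls:", sum(x$labels == 0L), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0L) cat("  missing values:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Count missing entries of a dataset
#' @param ds an `ExpressionDataset`.
#' @return integer count of NA cells.
#' @export
n_missing <- function(ds) sum(is.na(ds$values))

#' Restrict a dataset to a gene subset
#' @param ds an `ExpressionDataset`.
#' @param genes character vector or [gene_set()] of gene identifiers, all of
#'   which must be present.
#' @return an `ExpressionDataset` with rows restricted (and ordered) to `genes`.
#' @export
restrict_genes <- function(ds, genes) {
  genes <- as_gene_vector(genes)
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing) > 0L) {
    stop("genes absent from dataset: ", paste(missing, collapse = ", "))
  }
  expression_dataset(ds$values[genes, , drop = FALSE], ds$labels)
}

#' Read a tab-delimited expression table
#'
#' Expects a TSV with gene/probe identifiers in the first column and sample
#' identifiers in the header. Class labels come either from a designated row
#' of the table (default name `CLASS`, holding 0/1 or two named levels) or
#' from a sidecar two-column file `sample_id TAB label`. Empty cells and the
#' token `NA` are read as missing.
#'
#' @param path expression TSV path.
#' @param label_row name of the in-table label row, or `NULL` if labels come
#'   from `labels_file`.
#' @param labels_file optional sidecar label file.
#' @param case_label label value coding the case class when labels are not 0/1.
#' @return an `ExpressionDataset`.
#' @export
read_expression_table <- function(path, label_row = "CLASS",
                                  labels_file = NULL, case_label = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression table needs a header and >=1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  # trailing empty cells are dropped by strsplit; pad to header width
  header <- fields[[1L]]
  ncol_expect <- length(header)
  bad <- which(widths > ncol_expect)
  if (length(bad) > 0L) {
    stop("ragged row at line ", bad[1L], ": ", widths[bad[1L]],
         " fields, expected ", ncol_expect)
  }
  short <- which(widths[-1L] < ncol_expect - 1L) + 1L
  if (length(short) > 0L) {
    stop("ragged row at line ", short[1L], ": ", widths[short[1L]],
         " fields, expected ", ncol_expect)
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- fields[-1L]
  body <- lapply(body, function(f) c(f, rep("", ncol_expect - length(f))))
  ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- t(vapply(body, function(f) f[-1L], character(ncol_expect - 1L)))

  labels <- NULL
  if (!is.null(label_row) && label_row %in% ids) {
    lab_raw <- cells[match(label_row, ids), ]
    keep <- ids != label_row
    ids <- ids[keep]; cells <- cells[keep, , drop = FALSE]
    labels <- lab_raw
  }
  if (!is.null(labels_file)) {
    lab_tab <- utils::read.delim(labels_file, header = FALSE,
                                 colClasses = "character")
    if (ncol(lab_tab) < 2L) stop("labels file needs two columns")
    m <- match(sample_ids, lab_tab[[1L]])
    if (anyNA(m)) stop("labels file missing samples: ",
                       paste(sample_ids[is.na(m)], collapse = ", "))
    labels <- lab_tab[[2L]][m]
  }
  if (is.null(labels)) {
    stop("no labels found: supply a '", label_row,
         "' row or a labels_file sidecar")
  }
  if (anyDuplicated(ids)) stop("duplicate gene identifiers: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))

  is_missing <- cells == "" | cells == "NA"
  num <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    stop("non-numeric cell at gene '", ids[bad_cell[1L, 1L]], "', sample '",
         sample_ids[bad_cell[1L, 2L]], "': '",
         cells[bad_cell[1L, 1L], bad_cell[1L, 2L]], "'")
  }
  num[is_missing] <- NA_real_
  values <- matrix(num, nrow = length(ids),
                   dimnames = list(ids, sample_ids))
  suppressWarnings(lab_num <- as.numeric(labels))
  if (!anyNA(lab_num)) labels <- lab_num
  expression_dataset(values, labels, case_label = case_label)
}

#' Write an expression table (with a CLASS label row) to TSV
#' @param ds an `ExpressionDataset`.
#' @param path output path.
#' @param label_row name under which the 0/1 labels are written.
#' @export
write_expression_table <- function(ds, path, label_row = "CLASS") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", ds$sample_ids), collapse = "\t"), con)
  writeLines(paste(c(label_row, ds$labels), collapse = "\t"), con)
  vals <- format(ds$values, trim = TRUE, digits = 15)
  vals[is.na(ds$values)] <- "NA"
  writeLines(paste(ds$gene_ids, apply(vals, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Filter high-missingness genes and median-impute the remainder
#'
#' Genes whose fraction of missing samples exceeds `max_missing_fraction` are
#' dropped; remaining missing cells are replaced by the gene's median over
#' observed samples. Idempotent: a complete dataset is returned unchanged.
#'
#' @param ds an `ExpressionDataset`.
#' @param max_missing_fraction maximum tolerated per-gene missing fraction,
#'   in `[0, 1]`.
#' @return a complete `ExpressionDataset`.
#' @export
impute_and_filter <- function(ds, max_missing_fraction = 0.3) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be in [0, 1]")
  }
  miss_frac <- rowMeans(is.na(ds$values))
  if (any(miss_frac == 1)) {
    stop("gene(s) with all values missing: ",
         paste(utils::head(ds$gene_ids[miss_frac == 1], 5L), collapse = ", "))
  }
  keep <- miss_frac <= max_missing_fraction
  values <- ds$values[keep, , drop = FALSE]
  na_rows <- which(rowSums(is.na(values)) > 0L)
  for (i in na_rows) {
    v <- values[i, ]
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    values[i, ] <- v
  }
  expression_dataset(values, ds$labels)
}

#' Collapse probes to genes by maximal mean expression
#'
#' When several probes map to one gene symbol, the probe with the highest mean
#' expression across all samples is kept and renamed to the symbol; ties keep
#' the probe that comes first in the input row order. Unmapped probes are
#' dropped.
#'
#' @param ds an `ExpressionDataset` keyed by probe identifiers.
#' @param probe_to_gene named character vector: names are probe IDs, values
#'   gene symbols (or a two-column data frame probe, gene).
#' @return an `ExpressionDataset` keyed by unique gene symbols.
#' @export
collapse_probes <- function(ds, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2L]]),
                                     as.character(probe_to_gene[[1L]]))
  }
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  mapped <- ds$gene_ids[ds$gene_ids %in% names(probe_to_gene)]
  if (length(mapped) == 0L) stop("mapping covers none of the dataset probes")
  sym <- probe_to_gene[mapped]
  means <- rowMeans(ds$values[mapped, , drop = FALSE], na.rm = TRUE)
  # stable within-gene order: probes appear in input row order, so
  # which.max on that order realises the documented tie-break
  pick <- vapply(split(seq_along(mapped), sym)[unique(sym)],
                 function(idx) idx[which.max(means[idx])], integer(1L))
  values <- ds$values[mapped[pick], , drop = FALSE]
  rownames(values) <- unique(sym)
  expression_dataset(values, ds$labels)
}
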