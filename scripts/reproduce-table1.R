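#!/usr/bin/env Rscript
# Side-by-side benchmark on externally obtained microarray tables.
#
# Given an expression TSV (genes x samples, CLASS label row or sidecar
# labels), an optional probe-to-gene mapping, and a hub gene list, this
# reports the repeated random-split mean +/- SD accuracy and AUC of the
# single-score PLS hub classifier, in the format of the published
# independent-validation benchmark. The benchmark microarray tables are
# distributed as journal supplementary files and are not shipped here.
#
# Usage:
#   Rscript scripts/reproduce-table1.R --expr chen.tsv --genes hubs_down7.txt
#       [--labels labels.tsv --case-label HCC] [--probe-map map.tsv]
#       [--repeats 100] [--train-fraction 0.5] [--seed 1]

suppressPackageStartupMessages(library(hubclass))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(expr = NULL, genes = NULL, labels = NULL, case_label = NULL,
            probe_map = NULL, repeats = 100L, train_fraction = 0.5, seed = 1L)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  key <- gsub("-", "_", key)
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
if (is.null(opt$expr) || is.null(opt$genes)) {
  stop("--expr and --genes are required")
}

ds <- read_expression_table(opt$expr,
                            label_row = if (is.null(opt$labels)) "CLASS"
                                        else NULL,
                            labels_file = opt$labels,
                            case_label = opt$case_label)
ds <- impute_and_filter(ds)
if (!is.null(opt$probe_map)) {
  map <- utils::read.delim(opt$probe_map, header = FALSE,
                           colClasses = "character")
  ds <- collapse_probes(ds, stats::setNames(map[[2L]], map[[1L]]))
}
hubs <- read_gene_list(opt$genes)
present <- intersect(hubs$genes, ds$gene_ids)
if (length(present) < length(hubs$genes)) {
  message("missing from dataset: ",
          paste(setdiff(hubs$genes, present), collapse = ", "))
}
ev <- repeated_split_eval(ds, present,
                          n_repeats = as.integer(opt$repeats),
                          train_fraction = as.numeric(opt$train_fraction),
                          seed = as.integer(opt$seed))
cat(sprintf("genes used: %d of %d\n", length(present), length(hubs$genes)))
cat(sprintf("accuracy: %.2f +/- %.2f %%\n", ev$accuracy_mean, ev$accuracy_sd))
cat(sprintf("AUC:      %.2f +/- %.2f\n", ev$auc_mean, ev$auc_sd))
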