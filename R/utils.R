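# internal helpers shared across modules

# Derive an independent sub-stream seed from a master seed and a stream label,
# so e.g. changing the number of samples never perturbs the simulated network.
# Kept below 2^31 - 1 (R integers are 32-bit).
.sub_seed <- function(seed, stream) {
  offsets <- c(network = 1L, baseline = 2L, effects = 3L, noise = 4L,
               mask = 5L, split = 6L, draw = 7L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 48271 + offsets[[stream]] * 1000003) %% 2147483647)
}

.assert_binary_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be coded 0 (control) / 1 (case)")
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present")
  }
  invisible(labels)
}

# samples x genes predictor matrix plus 0/1 response for a gene subset
.xy_from_dataset <- function(ds, genes) {
  genes <- as_gene_vector(genes)
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing) > 0L) {
    stop("genes absent from dataset: ", paste(missing, collapse = ", "))
  }
  list(X = t(ds$values[genes, , drop = FALSE]), y = as.integer(ds$labels))
}
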