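# Hub/non-hub perturbation experiments: do the network-topological features
# (hub membership) drive classifier performance, or would any genes do?

.perturb_core <- function(ds, hubs, nonhub_pool, configs, n_repeats,
                          train_fraction, n_components, seed) {
  hubs <- as_gene_vector(hubs)
  pool <- as_gene_vector(nonhub_pool)
  if (length(intersect(hubs, pool)) > 0L) {
    stop("nonhub_pool must be disjoint from the hub set")
  }
  xy <- .xy_from_dataset(ds, c(hubs, pool))
  # canonical configuration order (hubs descending, then non-hubs ascending)
  # so results do not depend on how the caller ordered the configurations
  ord <- order(-vapply(configs, `[[`, integer(1L), "n_hub"),
               vapply(configs, `[[`, integer(1L), "n_nonhub"))
  configs <- configs[ord]
  n_cfg <- length(configs)
  acc <- auc <- matrix(NA_real_, n_repeats, n_cfg)
  correct <- incorrect <- matrix(0L, n_repeats, n_cfg)
  withr::with_seed(.sub_seed(seed, "draw"), {
    for (r in seq_len(n_repeats)) {
      # one split per repeat, shared by every configuration (paired design)
      idx <- .stratified_train_idx(xy$y, train_fraction)
      for (ci in seq_len(n_cfg)) {
        cfg <- configs[[ci]]
        sig <- c(if (cfg$n_hub > 0L) sample(hubs, cfg$n_hub),
                 if (cfg$n_nonhub > 0L) sample(pool, cfg$n_nonhub))
        res <- .split_fit_eval(xy$X[, sig, drop = FALSE], xy$y, idx,
                               n_components)
        acc[r, ci] <- 100 * res$accuracy
        auc[r, ci] <- res$auc
        correct[r, ci] <- res$correct
        incorrect[r, ci] <- res$incorrect
      }
    }
  })
  summary <- data.frame(
    hub_count = vapply(configs, `[[`, integer(1L), "n_hub"),
    nonhub_count = vapply(configs, `[[`, integer(1L), "n_nonhub"),
    accuracy_mean = colMeans(acc), accuracy_sd = apply(acc, 2L, stats::sd),
    auc_mean = colMeans(auc), auc_sd = apply(auc, 2L, stats::sd),
    row.names = NULL)
  baseline <- which(vapply(configs, `[[`, logical(1L), "baseline"))[1L]
  summary$p_vs_baseline <- vapply(seq_len(n_cfg), function(ci) {
    if (ci == baseline) return(1)
    compare_performance(
      list(correct = sum(correct[, ci]), incorrect = sum(incorrect[, ci])),
      list(correct = sum(correct[, baseline]),
           incorrect = sum(incorrect[, baseline])))
  }, numeric(1L))
  structure(list(summary = summary, accuracy = acc, auc = auc,
                 correct = correct, incorrect = incorrect,
                 baseline = baseline, n_repeats = n_repeats, seed = seed),
            class = "PerturbationResult")
}

#' @export
print.PerturbationResult <- function(x, ...) {
  cat("PerturbationResult over", x$n_repeats, "repeats:\n")
  print(x$summary, digits = 4L)
  invisible(x)
}

#' Non-hub addition experiment
#'
#' Keeps the full hub signature and adds increasing numbers of randomly
#' drawn non-hub genes (fresh draw and fresh stratified split each repeat;
#' splits are shared across configurations so comparisons are paired). The
#' zero-addition configuration is the baseline. Each configuration's pooled
#' test predictions are compared against the baseline with a two-sided
#' Fisher exact test.
#'
#' @param ds a complete `ExpressionDataset`.
#' @param hubs hub `GeneSet` or character vector.
#' @param nonhub_pool pool of non-hub genes to draw from (disjoint from
#'   `hubs`).
#' @param added_counts numbers of non-hubs to add (0 = baseline is always
#'   included).
#' @param n_repeats repeats (default 100).
#' @param train_fraction training fraction per class (default 0.5).
#' @param n_components PLS components (default 1).
#' @param seed RNG seed.
#' @return a `PerturbationResult`: per-configuration summary (mean +/- SD of
#'   accuracy and AUC, Fisher p versus baseline) and per-repeat matrices.
#' @export
addition_experiment <- function(ds, hubs, nonhub_pool,
                                added_counts = c(1, 2, 4, 6, 8),
                                n_repeats = 100, train_fraction = 0.5,
                                n_components = 1L, seed = 1) {
  added_counts <- sort(unique(c(0L, as.integer(added_counts))))
  pool <- as_gene_vector(nonhub_pool)
  if (max(added_counts) > length(pool)) {
    stop("nonhub_pool smaller than the largest added count")
  }
  nh <- length(as_gene_vector(hubs))
  configs <- lapply(added_counts, function(a)
    list(n_hub = nh, n_nonhub = a, baseline = a == 0L))
  .perturb_core(ds, hubs, nonhub_pool, configs, n_repeats, train_fraction,
                n_components, seed)
}

#' Hub substitution experiment at fixed signature size
#'
#' Holds the signature size fixed and varies the number of hub genes in it,
#' replacing the remainder with randomly drawn non-hubs (both drawn fresh
#' each repeat; splits shared across configurations). The all-hub
#' configuration is the baseline; every other configuration is compared to
#' it with a two-sided Fisher exact test on pooled test predictions.
#'
#' @inheritParams addition_experiment
#' @param hub_counts numbers of hubs in the signature, highest first by
#'   convention (default `signature_size:0`).
#' @param signature_size total genes in every signature (default 7).
#' @return a `PerturbationResult`.
#' @export
substitution_experiment <- function(ds, hubs, nonhub_pool,
                                    hub_counts = NULL, signature_size = 7,
                                    n_repeats = 100, train_fraction = 0.5,
                                    n_components = 1L, seed = 1) {
  signature_size <- as.integer(signature_size)
  if (is.null(hub_counts)) hub_counts <- seq(signature_size, 0L)
  hub_counts <- as.integer(hub_counts)
  if (any(hub_counts < 0L | hub_counts > signature_size)) {
    stop("hub_counts must lie in [0, signature_size]")
  }
  if (!signature_size %in% hub_counts) {
    hub_counts <- c(signature_size, hub_counts)
  }
  if (signature_size > length(as_gene_vector(hubs))) {
    stop("signature_size exceeds the number of hub genes")
  }
  if (signature_size > length(as_gene_vector(nonhub_pool))) {
    stop("nonhub_pool smaller than signature_size")
  }
  configs <- lapply(hub_counts, function(h)
    list(n_hub = h, n_nonhub = signature_size - h,
         baseline = h == signature_size))
  .perturb_core(ds, hubs, nonhub_pool, configs, n_repeats, train_fraction,
                n_components, seed)
}

#' Compare pooled classifier performance of two configurations
#'
#' Pools correct/incorrect test predictions over all repeats into a 2x2
#' table (configuration x outcome) and returns the two-sided Fisher exact
#' p-value.
#'
#' @param a,b either lists with elements `correct` and `incorrect`, or 0/1
#'   vectors of per-prediction correctness.
#' @return two-sided p-value.
#' @export
compare_performance <- function(a, b) {
  pool <- function(x) {
    if (is.list(x)) c(x$correct, x$incorrect)
    else c(sum(x == 1L), sum(x == 0L))
  }
  ca <- pool(a); cb <- pool(b)
  if (sum(ca) == 0L || sum(cb) == 0L) stop("empty prediction set")
  fisher_exact_2x2(matrix(c(ca, cb), nrow = 2L, byrow = TRUE))
}
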