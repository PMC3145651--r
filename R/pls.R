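# Single-score PLS discriminant classifier.
#
# The classifier projects each sample onto one weight vector w (unit Euclidean
# norm) chosen to maximize covariance between the standardized predictors and
# the centered 0/1 class indicator; the per-sample score S = sum_i w_i * x_i
# (standardized x) is compared against a threshold chosen on the training ROC.

# core fit on a plain samples x genes matrix; y in {0,1}
.pls_weights <- function(X, y, n_components = 1L) {
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1L || n_components > min(p, n - 1L)) {
    stop("n_components must be in [1, min(#genes, #samples-1)]")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  keep <- scale_ > 0
  if (!any(keep)) stop("all predictors have zero training variance")
  if (!all(keep)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, center[keep]), 2L,
              scale_[keep], "/")
  yc <- y - mean(y)
  pk <- ncol(Xs)
  if (n_components == 1L) {
    w <- as.numeric(crossprod(Xs, yc))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("predictors carry no covariance with the response")
    beta <- w / nw
  } else {
    # NIPALS PLS1 with deflation of X on its score vectors
    W <- P <- matrix(0, pk, n_components)
    q <- numeric(n_components)
    Xt <- Xs
    for (k in seq_len(n_components)) {
      w <- as.numeric(crossprod(Xt, yc))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) { W <- W[, seq_len(k - 1L), drop = FALSE]
                        P <- P[, seq_len(k - 1L), drop = FALSE]
                        q <- q[seq_len(k - 1L)]; break }
      w <- w / nw
      t_sc <- as.numeric(Xt %*% w)
      tt <- sum(t_sc^2)
      P[, k] <- as.numeric(crossprod(Xt, t_sc)) / tt
      q[k] <- sum(yc * t_sc) / tt
      W[, k] <- w
      Xt <- Xt - tcrossprod(t_sc, P[, k])
    }
    beta <- as.numeric(W %*% solve(crossprod(P, W), q))
    beta <- beta / sqrt(sum(beta^2))
  }
  list(weights = stats::setNames(beta, colnames(Xs)),
       center = center[keep], scale = scale_[keep])
}

#' Fit PLS weight coefficients
#'
#' Standardizes each predictor gene by its training mean and standard
#' deviation, centers the 0/1 response, and extracts the PLS weight vector.
#' With one component (the default) the weights are the closed form
#' `w = X'y_c / ||X'y_c||`; with more components the NIPALS deflation
#' algorithm is used and the equivalent single coefficient vector is
#' returned, rescaled to unit norm so the score remains `S = sum w_i x_i`.
#' Zero-variance predictors are dropped with a warning.
#'
#' @param ds an `ExpressionDataset` restricted to the predictor genes.
#' @param n_components number of latent components (default 1).
#' @return list with named `weights` (unit Euclidean norm), training `center`
#'   and `scale`.
#' @export
fit_weights <- function(ds, n_components = 1L) {
  .assert_binary_labels(ds$labels)
  if (sum(ds$labels == 1L) < 2L || sum(ds$labels == 0L) < 2L) {
    stop("need >=2 samples per class")
  }
  xy <- .xy_from_dataset(ds, ds$gene_ids)
  .pls_weights(xy$X, xy$y, as.integer(n_components))
}

#' Fit a complete PLS classifier
#'
#' Restricts the training data to the given genes, fits the PLS weights,
#' scores the training samples, and picks the decision threshold theta that
#' maximizes Youden's J (sensitivity + specificity - 1) on the training ROC.
#' Samples with score >= theta are called case.
#'
#' @param train training `ExpressionDataset`.
#' @param genes predictor `GeneSet` or character vector (e.g. selected hubs).
#' @param n_components number of latent components (default 1).
#' @return an object of class `PLSModel` with elements `genes`, `weights`,
#'   `center`, `scale`, `threshold`, `n_components`.
#' @export
fit_pls_classifier <- function(train, genes, n_components = 1L) {
  sub <- restrict_genes(train, genes)
  fw <- fit_weights(sub, n_components)
  model <- structure(
    list(genes = names(fw$weights), weights = fw$weights,
         center = fw$center, scale = fw$scale, threshold = NA_real_,
         n_components = as.integer(n_components)),
    class = "PLSModel")
  model$threshold <- select_threshold(compute_scores(model, train),
                                      train$labels)
  model
}

#' @export
print.PLSModel <- function(x, ...) {
  cat("PLSModel:", length(x$genes), "genes,", x$n_components,
      "component(s), threshold", signif(x$threshold, 4L), "\n")
  invisible(x)
}

#' Score samples with a fitted PLS model
#'
#' `S_s = sum_i w_i (x_is - center_i) / scale_i`; genes are matched by
#' identifier, so row order of `X` is irrelevant.
#'
#' @param model a `PLSModel`.
#' @param X an `ExpressionDataset` containing all model genes.
#' @return named numeric vector of per-sample scores.
#' @export
compute_scores <- function(model, X) {
  missing <- setdiff(model$genes, X$gene_ids)
  if (length(missing) > 0L) {
    stop("model gene(s) absent from data: ", paste(missing, collapse = ", "))
  }
  vals <- X$values[model$genes, , drop = FALSE]
  std <- (vals - model$center) / model$scale
  stats::setNames(as.numeric(crossprod(std, model$weights)), X$sample_ids)
}

#' ROC-derived decision threshold (Youden's J)
#'
#' Evaluates every candidate cutoff -- the midpoints between adjacent
#' distinct sorted scores plus sentinels below the minimum and above the
#' maximum -- under the rule `score >= theta -> case`, and returns the theta
#' maximizing J = sensitivity + specificity - 1. Ties in J are broken by the
#' smallest theta.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels, both classes present.
#' @return the selected threshold theta.
#' @export
select_threshold <- function(scores, labels) {
  .assert_binary_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  s <- sort(unique(scores))
  cand <- c(s[1L] - 1, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & labels == 1L) / n1 + sum(!pred & labels == 0L) / n0 - 1
  }, numeric(1L))
  cand[which.max(j)]   # which.max returns the first (smallest) maximizer
}

#' Classify samples with a fitted PLS model
#'
#' @param model a `PLSModel` with a threshold.
#' @param X an `ExpressionDataset` containing all model genes.
#' @return named integer vector: 1 (case) iff score >= threshold.
#' @export
classify <- function(model, X) {
  sc <- compute_scores(model, X)
  stats::setNames(as.integer(sc >= model$threshold), names(sc))
}

#' Serialize a PLS model to JSON
#' @param model a `PLSModel`.
#' @param path output path.
#' @export
write_pls_model <- function(model, path) {
  jsonlite::write_json(
    list(genes = model$genes, weights = unname(model$weights),
         center = unname(model$center), scale = unname(model$scale),
         threshold = model$threshold, n_components = model$n_components),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PLS model from JSON
#' @param path path written by [write_pls_model()].
#' @return a `PLSModel`.
#' @export
read_pls_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes = m$genes,
                 weights = stats::setNames(m$weights, m$genes),
                 center = stats::setNames(m$center, m$genes),
                 scale = stats::setNames(m$scale, m$genes),
                 threshold = m$threshold,
                 n_components = as.integer(m$n_components)),
            class = "PLSModel")
}
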