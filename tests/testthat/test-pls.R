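test_that("one-component weights equal the closed form X'y on random data", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(c(10, 20, 40), 1)
    p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    y <- sample(rep(c(1, 0), length.out = n))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    ds <- make_ds(X, y)
    fw <- fit_weights(ds)
    Xs <- scale(X)
    w_oracle <- as.numeric(crossprod(Xs, y - mean(y)))
    # scale() uses the n-1 sd, as does the implementation
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    expect_equal(unname(fw$weights), w_oracle, tolerance = 1e-10)
    expect_equal(sum(fw$weights^2), 1, tolerance = 1e-12)
  }
})

test_that("weights behave as theory dictates on constructed inputs", {
  # gene1 tracks the label pattern, gene2 is noise orthogonal to y
  n <- 400
  y <- rep(c(1, 0), each = n / 2)
  set.seed(7)
  noise <- rnorm(n)
  noise <- residuals(lm(noise ~ y))           # exactly orthogonal to y
  X <- cbind(g1 = y + rnorm(n, sd = 1e-3), g2 = noise)
  fw <- fit_weights(make_ds(X, y))
  expect_equal(abs(unname(fw$weights["g1"])), 1, tolerance = 1e-4)
  expect_lt(abs(fw$weights["g2"]), 1e-3)
  # duplicated predictor: symmetric weights 1/sqrt(2)
  X2 <- cbind(g1 = rnorm(40) + rep(c(1, 0), 20), g2 = 0)
  X2[, 2] <- X2[, 1]
  colnames(X2) <- c("g1", "g2")
  fw2 <- fit_weights(make_ds(X2, rep(c(1, 0), 20)))
  expect_equal(unname(fw2$weights), rep(1 / sqrt(2), 2), tolerance = 1e-10)
})

test_that("multi-component NIPALS reduces to the closed form at one component
           and matches least squares at full rank", {
  set.seed(12)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c(1, 0), each = 30)
  ds <- make_ds(X, y)
  w1 <- fit_weights(ds, n_components = 1)$weights
  # with p components, PLS spans the full predictor space: coefficient
  # direction equals the OLS direction on standardized predictors
  wp <- fit_weights(ds, n_components = 4)$weights
  b_ols <- coef(lm(I(y - mean(y)) ~ scale(X) - 1))
  b_ols <- b_ols / sqrt(sum(b_ols^2))
  expect_equal(unname(wp), unname(b_ols) * sign(sum(wp * b_ols)),
               tolerance = 1e-8)
  expect_equal(sum(wp^2), 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unname(w1), unname(wp))))
  expect_error(fit_weights(ds, n_components = 10), "n_components")
})

test_that("PLS weight direction agrees with an independent PLS-DA fit", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
  X[, 1] <- X[, 1] + rep(c(1.5, 0), c(25, 25))
  X[, 2] <- X[, 2] - rep(c(1, 0), c(25, 25))
  y <- rep(c(1, 0), c(25, 25))
  w <- fit_weights(make_ds(X, y))$weights
  ref <- mixOmics::plsda(X, factor(y), ncomp = 1)
  load <- ref$loadings$X[, 1]
  expect_gt(abs(cor(w, load[names(w)])), 0.999)
})

test_that("zero-variance predictors are dropped, all-constant input errors", {
  X <- cbind(g1 = rep(c(1, 0), 10) + rnorm(20, sd = 0.1), g2 = rep(5, 20))
  y <- rep(c(1, 0), 10)
  expect_warning(fw <- fit_weights(make_ds(X, y)), "zero-variance")
  expect_equal(names(fw$weights), "g1")
  X0 <- cbind(g1 = rep(1, 20), g2 = rep(2, 20))
  expect_error(suppressWarnings(fit_weights(make_ds(X0, y))), "variance")
})

test_that("scores are centered, ID-matched, and scale-equivariant", {
  fx <- make_fixture("separable7")
  model <- fit_pls_classifier(fx$dataset, fx$truth$hub_genes)
  # data equal to the training means score exactly zero
  mu <- matrix(model$center, nrow = length(model$genes), ncol = 3,
               dimnames = list(model$genes, paste0("m", 1:3)))
  ds_mu <- expression_dataset(mu, c(1, 0, 0))
  expect_equal(unname(compute_scores(model, ds_mu)), rep(0, 3))
  # permuting gene rows leaves scores unchanged
  perm <- fx$dataset
  idx <- rev(seq_along(perm$gene_ids))
  perm <- expression_dataset(perm$values[idx, ], perm$labels)
  expect_equal(compute_scores(model, perm), compute_scores(model, fx$dataset))
  # multiplying one gene's raw values by 10 leaves test scores unchanged
  scaled_vals <- fx$dataset$values
  scaled_vals[model$genes[1], ] <- scaled_vals[model$genes[1], ] * 10
  ds_scaled <- expression_dataset(scaled_vals, fx$dataset$labels)
  m2 <- fit_pls_classifier(ds_scaled, fx$truth$hub_genes)
  expect_equal(compute_scores(m2, ds_scaled),
               compute_scores(model, fx$dataset), tolerance = 1e-10)
  # missing model gene is a named error
  small <- restrict_genes(fx$dataset, setdiff(fx$dataset$gene_ids,
                                              model$genes[1]))
  expect_error(compute_scores(model, small), model$genes[1])
})

test_that("threshold selection maximizes Youden's J over all cutoffs", {
  # separable: midpoint between the classes
  expect_equal(select_threshold(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1.5)
  # degenerate all-equal scores: sentinel below the minimum, everything case
  th <- select_threshold(rep(2, 4), c(1, 1, 0, 0))
  expect_lt(th, 2)
  expect_true(all(rep(2, 4) >= th))
  # interleaved: equals the brute-force maximizer of J
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    sc <- round(rnorm(n), 1)
    y <- sample(rep_len(c(1, 0), n))
    th <- select_threshold(sc, y)
    s <- sort(unique(sc))
    cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
              s[length(s)] + 1)
    jfun <- function(t) {
      mean(sc[y == 1] >= t) + mean(sc[y == 0] < t) - 1
    }
    js <- vapply(cand, jfun, numeric(1))
    expect_equal(jfun(th), max(js), tolerance = 1e-12)
    # tie-break: no candidate with equal J is smaller than the pick
    expect_equal(th, min(cand[js >= max(js) - 1e-12]))
  }
  expect_error(select_threshold(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("classification uses the score >= threshold convention", {
  fx <- make_fixture("separable7")
  model <- fit_pls_classifier(fx$dataset, fx$truth$hub_genes)
  expect_equal(unname(classify(model, fx$dataset)), fx$dataset$labels)
  # boundary: scores theta - eps, theta, theta + eps -> 0, 1, 1, checked on
  # a hand-built single-gene model where scores are float-exact
  hand <- structure(list(genes = "g1", weights = c(g1 = 1),
                         center = c(g1 = 0), scale = c(g1 = 1),
                         threshold = 0.5, n_components = 1L),
                    class = "PLSModel")
  vals <- matrix(c(0.25, 0.5, 0.75), nrow = 1,
                 dimnames = list("g1", c("a", "b", "c")))
  ds3 <- expression_dataset(vals, c(0, 1, 1))
  expect_equal(unname(compute_scores(hand, ds3)), c(0.25, 0.5, 0.75))
  expect_equal(unname(classify(hand, ds3)), c(0L, 1L, 1L))
  # empty sample set classifies to an empty vector
  m0 <- matrix(numeric(0), nrow = 1, ncol = 0,
               dimnames = list("g1", character(0)))
  ds0 <- expression_dataset(m0, integer(0))
  expect_length(classify(hand, ds0), 0L)
})

test_that("fitting is deterministic and survives a JSON round-trip", {
  fx <- make_fixture("paperlike")
  m1 <- fit_pls_classifier(fx$dataset, fx$truth$hub_genes)
  m2 <- fit_pls_classifier(fx$dataset, fx$truth$hub_genes)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$threshold, m2$threshold)
  path <- tempfile(fileext = ".json")
  write_pls_model(m1, path)
  m3 <- read_pls_model(path)
  expect_equal(m3$weights, m1$weights, tolerance = 1e-12)
  expect_equal(m3$threshold, m1$threshold, tolerance = 1e-12)
  expect_equal(classify(m3, fx$dataset), classify(m1, fx$dataset))
})
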