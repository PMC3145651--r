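# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Benjamini-Hochberg by the literal double loop over the sorted p-values:
# q for the i-th smallest p is min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of the margin-fixed
# support, summing hypergeometric masses <= the observed mass (relative
# tolerance 1e-7).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Mann-Whitney concordance: fraction of case/control pairs in which the case
# scores higher, ties counting one half.
auc_pair_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  total <- 0
  for (x in s1) for (y in s0) total <- total + (x > y) + 0.5 * (x == y)
  total / (length(s1) * length(s0))
}

# Degree by direct neighbor-set enumeration on the raw edge rows.
degree_oracle <- function(edges, nodes) {
  vapply(nodes, function(v) {
    nb <- unique(c(edges$target[edges$source == v],
                   edges$source[edges$target == v]))
    length(setdiff(nb, v))
  }, integer(1L))
}

# small ExpressionDataset from a samples x genes matrix
make_ds <- function(X, y) {
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  expression_dataset(t(X), y)
}

# write a small expression TSV with a CLASS row; returns the path
write_expr_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
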