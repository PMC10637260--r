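# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# All-pairs shortest paths by Floyd-Warshall on a distance matrix
# (0 off-diagonal entries denote absent edges).
fw_apsp <- function(d) {
  n <- nrow(d)
  D <- d
  D[D == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

closeness_fw <- function(d) {
  D <- fw_apsp(d)
  (nrow(d) - 1) / rowSums(D)
}

# Textbook Welch statistic with Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  dof <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

# Simple-regression normal equations, solved explicitly.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - 2)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  t <- beta[2] / se[2]
  list(intercept = beta[1], slope = beta[2], se = se[2],
       t = t, p = 2 * pt(-abs(t), length(y) - 2))
}

# Random symmetric distance matrix for a complete weighted graph.
rand_dist_matrix <- function(n, lo = 0.05, hi = 1) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, lo, hi)
  d <- d + t(d)
  d
}

# Dense toy expression matrix (genes x cells) with names.
toy_expr <- function(values, n_genes, n_cells) {
  matrix(values, n_genes, n_cells,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("c%02d", seq_len(n_cells))))
}

# Tiny sc_counts from a dense matrix.
toy_counts <- function(m, mito = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  sc_counts(Matrix::Matrix(m, sparse = TRUE), mito_mask = mito)
}
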