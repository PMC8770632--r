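# Shared fixtures and independent oracles used across the suite.

# Build an interaction_network directly from a gene-level edge table.
make_net <- function(gene_a, gene_b, focal, score = 1) {
  edges <- data.frame(gene_a = gene_a, gene_b = gene_b,
                      score = rep_len(score, length(gene_a)),
                      stringsAsFactors = FALSE)
  attr(edges, "score_scale") <- "0-1"
  suppressWarnings(shell_restrict(edges, focal))
}

# Random negative Laplacian of an Erdos-Renyi-ish graph (for kernel oracles).
rand_neg_laplacian <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  H <- A
  diag(H) <- -rowSums(A)
  dimnames(H) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  H
}

# Truncated power-series matrix exponential: the series definition of the
# diffusion kernel, independent of the eigendecomposition implementation.
series_kernel <- function(H, beta, terms = 60) {
  n <- nrow(H)
  K <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% (beta * H) / k
    K <- K + term
  }
  K
}

# Coordinate-descent oracle for the penalized least-squares objectives:
# RSS + lambda*sum|beta| (lasso) and RSS + lambda*sum(beta^2) +
# lambda*sum|beta| (elastic net), with an unpenalized intercept handled by
# centering. Independent of glmnet.
cd_penalized <- function(X, y, lambda, l2 = FALSE, iters = 2000) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  p <- ncol(X)
  beta <- numeric(p)
  xx <- colSums(Xc^2)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(iters)) {
    for (j in seq_len(p)) {
      r_j <- yc - Xc[, -j, drop = FALSE] %*% beta[-j]
      rho <- sum(Xc[, j] * r_j)
      denom <- xx[j] + if (l2) lambda else 0
      beta[j] <- soft(rho, lambda / 2) / denom
    }
  }
  b0 <- ym - sum(xm * beta)
  list(intercept = b0, beta = beta)
}

penalized_objective <- function(X, y, intercept, beta, lambda,
                                l2 = FALSE) {
  rss <- sum((y - intercept - X %*% beta)^2)
  rss + lambda * sum(abs(beta)) + if (l2) lambda * sum(beta^2) else 0
}

# Small standard bundle configuration used by fast cross-module tests.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 60, n_cells = 60, n_shell1 = 10, n_planted = 3,
         n_markers = 4, n_extra_genes = 15, n_decoy_genes = 12,
         n_amplified = 5, seed = seed),
    list(...))
  do.call(sim_config, args)
}
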