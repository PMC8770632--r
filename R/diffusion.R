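#' Negative graph Laplacian of an interaction network
#'
#' Returns H = -(D - A), where A is the adjacency matrix (binary, or edge
#' weights when `mode = "weighted"`) and D the corresponding degree
#' diagonal. H is symmetric with zero row sums and non-negative
#' off-diagonal entries; it is the generator of the heat/continuous-time
#' random-walk diffusion on the graph.
#'
#' @param network An `interaction_network`.
#' @param mode `"binary"` (every retained edge has weight 1; default) or
#'   `"weighted"` (use edge weights).
#' @return A dense symmetric matrix with dimnames set to the gene order.
#' @export
negative_laplacian <- function(network, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  genes <- network$genes
  n <- length(genes)
  if (n == 0L) stop("network has no genes", call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(network$edges) > 0L) {
    ia <- match(network$edges$gene_a, genes)
    ib <- match(network$edges$gene_b, genes)
    w <- if (mode == "binary") rep(1, length(ia)) else network$edges$weight
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  H <- A
  diag(H) <- -rowSums(A)
  H
}

#' Diffusion kernel K = exp(beta * H)
#'
#' Computes the diffusion (heat) kernel of a graph, the matrix exponential
#' of beta times the negative Laplacian, equivalently the limit of the
#' power series I + beta H + beta^2 H^2 / 2! + ... . The kernel is computed
#' exactly through the symmetric eigendecomposition of H. Because H has
#' zero row sums, K is a doubly stochastic matrix: entries are
#' non-negative and every row sums to 1. `K[i, j]` measures the
#' information/heat flow from node i to node j after "time" beta.
#'
#' @param H Symmetric matrix from [negative_laplacian()].
#' @param beta Diffusion parameter, a single positive number. Small values
#'   keep information near its source; large values spread it towards the
#'   uniform distribution over each connected component.
#' @return An object of class `kernel_matrix`: list with elements `K`
#'   (dense matrix with the node dimnames), `beta` and `node_order`.
#' @export
diffusion_kernel <- function(H, beta) {
  if (!is.matrix(H) || nrow(H) != ncol(H)) {
    stop("H must be a square matrix", call. = FALSE)
  }
  if (max(abs(H - t(H))) > 1e-8) {
    stop("H must be symmetric", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  eig <- eigen(H, symmetric = TRUE)
  K <- eig$vectors %*% (exp(beta * eig$values) * t(eig$vectors))
  # eigendecomposition round-off can leave tiny negatives; clamp well below
  # the documented -1e-10 tolerance without touching real entries
  K[K < 0 & K > -1e-12] <- 0
  dimnames(K) <- dimnames(H)
  structure(list(K = K, beta = beta, node_order = rownames(H)),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("Diffusion kernel over", length(x$node_order), "genes, beta =",
      format(x$beta), "\n")
  invisible(x)
}

#' Geometric schedule of diffusion parameters
#'
#' The beta sweep used for hyperparameter tuning: `base^n` for each
#' exponent n. The defaults give the five values 0.75^1, 0.75^5, 0.75^10,
#' 0.75^20, 0.75^30, spanning near-local to very local diffusion.
#'
#' @param base Base in (0, 1); default 0.75.
#' @param exponents Positive integer exponents; default `c(1, 5, 10, 20, 30)`.
#' @return Numeric vector `base^exponents`, in input order.
#' @export
beta_schedule <- function(base = 0.75, exponents = c(1L, 5L, 10L, 20L, 30L)) {
  if (!is.numeric(base) || length(base) != 1L || base <= 0 || base >= 1) {
    stop("`base` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(exponents) == 0L) return(numeric(0))
  if (any(exponents <= 0)) {
    stop("all exponents must be positive", call. = FALSE)
  }
  base^exponents
}

#' Diffusion-kernel centrality (closeness) of network genes
#'
#' Ranks genes by how much diffusion reaches them, used to pick predictor
#' candidates. Two methods are provided:
#' \describe{
#'   \item{`focal_row`}{closeness of gene i is `K[focal, i]` - the amount
#'     of information flowing from the focal gene to i (default; the
#'     network is focal-centered, and plain row sums of K are degenerate
#'     since every row sums to 1). The focal gene itself receives no
#'     score.}
#'   \item{`kernel_distance_closeness`}{classical closeness
#'     `1 / sum_j d(i, j)` under the kernel-induced metric
#'     `d(i, j) = sqrt(K_ii + K_jj - 2 K_ij)`.}
#' }
#'
#' @param kernel A `kernel_matrix`.
#' @param focal Focal gene symbol (must be a kernel node).
#' @param method Centrality method; see Details.
#' @return An object of class `centrality_scores`: list with `scores`
#'   (named numeric, gene order deterministic), `method` and `beta`.
#' @export
kernel_centrality <- function(kernel, focal,
                              method = c("focal_row",
                                         "kernel_distance_closeness")) {
  method <- match.arg(method)
  focal <- normalize_symbol(focal)
  K <- kernel$K
  nodes <- kernel$node_order
  if (!focal %in% nodes) {
    stop("focal gene ", focal, " is not a kernel node", call. = FALSE)
  }
  if (method == "focal_row") {
    scores <- K[focal, ]
    scores <- scores[names(scores) != focal]
  } else {
    d2 <- outer(diag(K), diag(K), "+") - 2 * K
    d2[d2 < 0] <- 0
    dist_sum <- rowSums(sqrt(d2))
    scores <- ifelse(dist_sum > 0, 1 / dist_sum, Inf)
    names(scores) <- nodes
  }
  scores <- scores[order(names(scores))]
  structure(list(scores = scores, method = method, beta = kernel$beta),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat("Kernel centrality (", x$method, "), beta = ", format(x$beta),
      ", ", length(x$scores), " genes\n", sep = "")
  invisible(x)
}

#' Centrality scores for a schedule of beta values
#'
#' Computes the negative Laplacian once and returns one
#' `centrality_scores` object per beta.
#'
#' @inheritParams negative_laplacian
#' @inheritParams kernel_centrality
#' @param betas Numeric vector of diffusion parameters, e.g.
#'   [beta_schedule()].
#' @return Named list of `centrality_scores`, names `format(beta)`.
#' @export
centrality_sweep <- function(network, betas = beta_schedule(),
                             mode = "binary", method = "focal_row") {
  H <- negative_laplacian(network, mode)
  out <- lapply(betas, function(b) {
    kernel_centrality(diffusion_kernel(H, b), network$focal_gene, method)
  })
  names(out) <- format(betas)
  out
}
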