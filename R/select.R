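#' Drop genes with missing expression values
#'
#' Returns the genes that are present as columns of the expression matrix
#' and have no missing entries across the cohort. Gene expressions with
#' missing values are discarded before the final selection step.
#'
#' @param expr Cell line x gene expression matrix (log2(TPM+1) scale).
#' @param genes Candidate gene symbols.
#' @return Character vector, the complete-data subset of `genes` in input
#'   order.
#' @export
drop_missing <- function(expr, genes) {
  present <- genes[genes %in% colnames(expr)]
  if (length(present) == 0L) return(character(0))
  ok <- colSums(is.na(expr[, present, drop = FALSE])) == 0L
  present[ok]
}

#' Filter genes by minimum expression percentile
#'
#' Summarizes each gene as its mean expression over the cohort, computes
#' the stated percentile of those summaries (linear interpolation) over
#' the candidate genes, and keeps genes whose summary strictly exceeds
#' the threshold.
#'
#' @inheritParams drop_missing
#' @param percentile Expression percentile in (0, 100), e.g. 25/50/75/95.
#' @return Character vector of retained genes with attribute
#'   `expression_threshold`.
#' @export
expression_filter <- function(expr, genes, percentile) {
  if (length(genes) == 0L) {
    stop("gene list is empty", call. = FALSE)
  }
  absent <- setdiff(genes, colnames(expr))
  if (length(absent) > 0L) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  summaries <- colMeans(expr[, genes, drop = FALSE])
  thr <- percentile_threshold(summaries, percentile)
  keep <- genes[summaries > thr]
  if (length(keep) == 0L) {
    warning("no gene exceeds the expression threshold (all summaries ",
            "tied at ", format(thr), ")", call. = FALSE)
  }
  attr(keep, "expression_threshold") <- thr
  keep
}

#' Select the top-k genes by kernel centrality
#'
#' Ranks the eligible genes by closeness (descending), breaking ties by
#' lexicographic gene symbol, and keeps the top k. If fewer than k genes
#' are eligible, all are returned with a warning.
#'
#' @param centrality A `centrality_scores` object.
#' @param eligible Eligible gene symbols (subset of the centrality domain).
#' @param k Number of genes to select.
#' @param config Optional list describing the hyperparameter combination
#'   (stored as provenance).
#' @return An object of class `predictor_set`: list with `genes`, `source`
#'   (`"kernel"`), `config` and `provenance`.
#' @export
select_predictors <- function(centrality, eligible, k, config = NULL) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  eligible <- unique(eligible)
  missing <- setdiff(eligible, names(centrality$scores))
  if (length(missing) > 0L) {
    stop("eligible gene(s) missing centrality scores: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(eligible) == 0L) {
    stop("eligible gene set is empty", call. = FALSE)
  }
  s <- centrality$scores[eligible]
  ord <- order(-s, names(s))
  if (length(eligible) < k) {
    warning("only ", length(eligible), " eligible genes for k = ", k,
            "; returning all", call. = FALSE)
    k <- length(eligible)
  }
  genes <- names(s)[ord][seq_len(k)]
  new_predictor_set(genes, source = "kernel", config = config,
                    provenance = list(beta = centrality$beta,
                                      method = centrality$method,
                                      n_eligible = length(eligible)))
}

new_predictor_set <- function(genes, source, config = NULL,
                              provenance = list()) {
  structure(list(genes = genes, source = source, config = config,
                 provenance = provenance),
            class = "predictor_set")
}

#' Construct a named (non-kernel) predictor set
#'
#' Wraps a plain gene list as a `predictor_set` so the same modeling
#' engine serves the comparison arms: all available RNA genes, all network
#' genes, published signatures, RAE markers or mutation indicators.
#'
#' @param genes Gene symbols.
#' @param source Label, e.g. `"all_rna"`, `"network_all"`,
#'   `"signature:loboda"`, `"rae"`, `"mutation"`.
#' @return A `predictor_set`.
#' @export
named_predictor_set <- function(genes, source) {
  new_predictor_set(unique(genes), source = source)
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("Predictor set [", x$source, "]: ", length(x$genes), " genes\n",
      sep = "")
  if (!is.null(x$config)) {
    cat("  config: percentile =", x$config$expression_percentile,
        ", beta =", format(x$config$beta), ", k =", x$config$n_genes, "\n")
  }
  invisible(x)
}

#' Enumerate the hyperparameter grid of selection configurations
#'
#' Cartesian product of expression percentile, diffusion beta and gene
#' count, in deterministic percentile-major order (then beta, then k).
#' The defaults (4 percentiles x 5 betas x 3 gene counts) give the 60
#' configurations of the standard grid.
#'
#' @param percentiles Expression percentiles; default `c(25, 50, 75, 95)`.
#' @param betas Diffusion parameters; default [beta_schedule()].
#' @param ks Gene counts; default `c(100, 500, 1000)`.
#' @return Data frame with columns `expression_percentile`, `beta`,
#'   `n_genes`; one row per configuration.
#' @export
enumerate_grid <- function(percentiles = c(25, 50, 75, 95),
                           betas = beta_schedule(),
                           ks = c(100, 500, 1000)) {
  if (length(percentiles) == 0L || length(betas) == 0L || length(ks) == 0L) {
    stop("all grid dimensions must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(n_genes = ks, beta = betas,
                      expression_percentile = percentiles,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, c("expression_percentile", "beta", "n_genes")]
}

#' Run the full kernel selection workflow for one configuration
#'
#' Restrict candidates to network genes, drop genes with missing
#' expression, apply the expression-percentile filter, then keep the top-k
#' genes by diffusion-kernel centrality.
#'
#' @param network An `interaction_network`.
#' @param centrality A `centrality_scores` for this network (the beta must
#'   match `config$beta`).
#' @param expr Expression matrix (cell line x gene).
#' @param config One row of [enumerate_grid()] (or an equivalent list with
#'   `expression_percentile`, `beta`, `n_genes`).
#' @return A `predictor_set`.
#' @export
select_for_config <- function(network, centrality, expr, config) {
  candidates <- setdiff(network$genes, network$focal_gene)
  complete <- drop_missing(expr, candidates)
  if (length(complete) == 0L) {
    stop("no network gene has complete expression data", call. = FALSE)
  }
  expressed <- expression_filter(expr, complete,
                                 config$expression_percentile)
  select_predictors(centrality, expressed, config$n_genes,
                    config = as.list(config))
}
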