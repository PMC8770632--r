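#' Specify a dependency model
#'
#' Captures the algorithm and its tuning rules for one model family.
#' Lasso minimizes `RSS + lambda * sum(|beta_j|)`; the elastic net adds an
#' L2 term with the same weight, `RSS + lambda * sum(beta_j^2) +
#' lambda * sum(|beta_j|)`. Both are fit with glmnet (whose internal
#' penalty parameterization is rescaled accordingly). When `lambda` is
#' `NULL` (default) the penalty is chosen per training split by k-fold
#' cross-validation at the minimum mean CV error; a fixed `lambda` is
#' interpreted on the objective scale above.
#'
#' @param algorithm `"lasso"` (default), `"elastic_net"` or
#'   `"random_forest"`.
#' @param lambda `NULL` for inner-CV selection, or a fixed non-negative
#'   penalty.
#' @param nfolds Folds for inner cross-validation; default 10.
#' @param standardize Standardize predictors on training statistics before
#'   penalized fitting (coefficients are always reported on the original
#'   scale); default `TRUE`.
#' @param ntree Random-forest tree count; default 500.
#' @param mtry Random-forest features per split; default `floor(p / 3)`
#'   (the regression default).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("lasso", "elastic_net",
                                     "random_forest"),
                       lambda = NULL, nfolds = 10, standardize = TRUE,
                       ntree = 500, mtry = NULL) {
  algorithm <- match.arg(algorithm)
  if (!is.null(lambda) && (length(lambda) != 1L || lambda < 0)) {
    stop("`lambda` must be NULL or a single non-negative number",
         call. = FALSE)
  }
  if (ntree < 1) stop("`ntree` must be at least 1", call. = FALSE)
  structure(list(algorithm = algorithm, lambda = lambda, nfolds = nfolds,
                 standardize = standardize, ntree = ntree, mtry = mtry),
            class = "model_spec")
}

# glmnet mixing parameter and lambda that reproduce the stated objectives.
# glmnet minimizes RSS/(2n) + lambda_g * ((1-a)/2 ||b||_2^2 + a ||b||_1),
# but for gaussian fits it internally rescales y to unit variance, which
# leaves the L1 term invariant and shrinks the effective ridge weight by
# sd(y) (1/n formula). Solving for equal L1 and L2 weights lambda on the
# original scale:
#   lasso:       a = 1,          lambda_g = lambda / (2n)
#   elastic net: a = 1/(1+2*s),  lambda_g = lambda / (2n*a),  s = sd_n(y)
glmnet_alpha <- function(algorithm, ytr) {
  if (algorithm == "lasso") return(1)
  n <- length(ytr)
  s <- stats::sd(ytr) * sqrt((n - 1) / n)
  1 / (1 + 2 * s)
}
glmnet_lambda <- function(lambda, n, alpha) {
  lambda / (2 * n * alpha)
}

#' Fit one model on a train/test split
#'
#' Fits the specified model on the training rows only and predicts the
#' held-out test rows. Penalized fits standardize predictors on training
#' statistics (unless disabled) and report coefficients on the original
#' predictor scale.
#'
#' @param X Cell line x predictor numeric matrix with dimnames.
#' @param y Numeric response (gene-effect values), aligned with `X` rows.
#' @param spec A [model_spec()].
#' @param split List with integer elements `train` and `test` (disjoint
#'   row indices).
#' @return An object of class `fitted_model`: list with `algorithm`,
#'   `intercept`, `coefficients` (named, zero entries kept; `NULL` for
#'   random forest), `lambda` (penalty used, objective scale; `NA` for
#'   random forest), `train`, `test`, `test_predictions` (named by cell
#'   line).
#' @export
fit_one <- function(X, y, spec, split) {
  if (nrow(X) != length(y)) {
    stop("`X` rows and `y` must align", call. = FALSE)
  }
  tr <- split$train
  te <- split$test
  if (length(intersect(tr, te)) > 0L) {
    stop("train and test indices overlap", call. = FALSE)
  }
  if (length(tr) < 10L) {
    stop("fewer than 10 training rows", call. = FALSE)
  }
  ytr <- y[tr]
  if (stats::var(ytr) == 0) {
    stop("response is constant on the training split", call. = FALSE)
  }
  Xtr <- X[tr, , drop = FALSE]
  Xte <- X[te, , drop = FALSE]
  n <- length(tr)

  if (spec$algorithm == "random_forest") {
    mtry <- spec$mtry %||% max(1L, floor(ncol(X) / 3))
    fit <- randomForest::randomForest(x = Xtr, y = ytr, ntree = spec$ntree,
                                      mtry = mtry)
    pred <- as.numeric(stats::predict(fit, Xte))
    coefs <- NULL
    intercept <- NA_real_
    lambda <- NA_real_
  } else {
    alpha <- glmnet_alpha(spec$algorithm, ytr)
    if (is.null(spec$lambda)) {
      cv <- glmnet::cv.glmnet(Xtr, ytr, alpha = alpha,
                              nfolds = spec$nfolds,
                              standardize = spec$standardize)
      lam_g <- cv$lambda.min
      fit <- cv$glmnet.fit
      lambda <- lam_g * 2 * n * alpha
    } else {
      lam_g <- glmnet_lambda(spec$lambda, n, alpha)
      # fit along a short decreasing path ending at the target penalty:
      # glmnet's coordinate descent is substantially more accurate with
      # warm starts than with a single cold lambda
      lam_path <- if (lam_g > 0) lam_g * c(16, 8, 4, 2, 1) else {
        c(max(abs(crossprod(Xtr, ytr - mean(ytr)))) / n * c(1, 0.1, 0.01), 0)
      }
      fit <- glmnet::glmnet(Xtr, ytr, alpha = alpha, lambda = lam_path,
                            standardize = spec$standardize,
                            thresh = 1e-12)
      lambda <- spec$lambda
    }
    cf <- as.matrix(stats::coef(fit, s = lam_g))[, 1L]
    intercept <- unname(cf[1L])
    coefs <- cf[-1L]
    pred <- as.numeric(intercept + Xte %*% coefs)
  }
  names(pred) <- rownames(Xte)
  structure(list(algorithm = spec$algorithm, intercept = intercept,
                 coefficients = coefs, lambda = lambda,
                 train = tr, test = te, test_predictions = pred),
            class = "fitted_model")
}

#' Fit an ensemble over repeated random 80/20 holdout splits
#'
#' Draws `n_models` independent uniform train/test splits from a seeded
#' generator (train fraction `train_frac`, sampled without
#' stratification), fits one model per split, and averages each cell
#' line's test-set predictions over the models in which it was held out.
#' Performance is the Pearson correlation between these averaged
#' predictions and the observed dependency, over the covered cell lines.
#' All per-model randomness (split, inner CV folds, forest bootstraps)
#' is driven by a per-model seed derived from the master seed, so results
#' are reproducible and independent of execution order.
#'
#' @inheritParams fit_one
#' @param n_models Number of resampled models; default 100.
#' @param train_frac Training fraction; default 0.8.
#' @param seed Master seed (integer).
#' @param keep_models Keep the per-model coefficient records (needed for
#'   [predictor_frequency()] / [extract_nonzero_predictors()]); default
#'   `TRUE`.
#' @return An object of class `ensemble_result`: list with `predictions`
#'   (data frame `cell_line`, `observed`, `predicted_mean`,
#'   `n_test_appearances`, `abs_error`), `r` (Pearson), `n` (covered
#'   lines), `n_models`, `seed`, `spec`, `uncovered` (cell lines never
#'   held out) and `models`.
#' @export
run_ensemble <- function(X, y, spec = model_spec(), n_models = 100,
                         train_frac = 0.8, seed = 1,
                         keep_models = TRUE) {
  n <- nrow(X)
  if (n < 25L) {
    stop("cohort must contain at least 25 cell lines", call. = FALSE)
  }
  if (is.null(rownames(X))) {
    rownames(X) <- paste0("sample_", seq_len(n))
  }
  cells <- rownames(X)
  pred_sum <- stats::setNames(numeric(n), cells)
  pred_count <- stats::setNames(integer(n), cells)
  models <- if (keep_models) vector("list", n_models) else NULL
  n_train <- round(train_frac * n)
  for (i in seq_len(n_models)) {
    set.seed(derive_seed(seed, i))
    tr <- sample.int(n, n_train)
    te <- setdiff(seq_len(n), tr)
    fm <- fit_one(X, y, spec, list(train = tr, test = te))
    pred_sum[te] <- pred_sum[te] + fm$test_predictions
    pred_count[te] <- pred_count[te] + 1L
    if (keep_models) {
      cf <- fm$coefficients
      models[[i]] <- list(intercept = fm$intercept,
                          coefficients = if (is.null(cf)) NULL else
                            cf[cf != 0],
                          lambda = fm$lambda, train = tr, test = te)
    }
  }
  covered <- pred_count > 0L
  if (!any(covered)) {
    stop("no cell line was ever held out; increase n_models", call. = FALSE)
  }
  if (any(!covered)) {
    warning(sum(!covered), " cell line(s) never appeared in a test set ",
            "and are excluded from evaluation", call. = FALSE)
  }
  avg <- pred_sum[covered] / pred_count[covered]
  obs <- y[covered]
  r <- stats::cor(avg, obs)
  predictions <- data.frame(cell_line = cells[covered], observed = obs,
                            predicted_mean = avg,
                            n_test_appearances = pred_count[covered],
                            abs_error = abs(avg - obs),
                            row.names = NULL, stringsAsFactors = FALSE)
  structure(list(predictions = predictions, r = r, n = sum(covered),
                 n_models = n_models, seed = seed, spec = spec,
                 uncovered = cells[!covered], models = models,
                 provenance = list(train_frac = train_frac,
                                   n_predictors = ncol(X))),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("Ensemble of", x$n_models, x$spec$algorithm, "models on",
      x$provenance$n_predictors, "predictors\n")
  cat("  Pearson r =", format(round(x$r, 4)), "over", x$n, "cell lines\n")
  invisible(x)
}

#' Per-cell-line absolute prediction error, ordered by observed dependency
#'
#' @param ensemble An `ensemble_result`.
#' @return Data frame (`cell_line`, `observed`, `abs_error`) sorted by
#'   ascending observed dependency.
#' @export
evaluate_absolute_error <- function(ensemble) {
  p <- ensemble$predictions
  if (nrow(p) == 0L) stop("ensemble covers no cell line", call. = FALSE)
  p <- p[order(p$observed), c("cell_line", "observed", "abs_error")]
  rownames(p) <- NULL
  p
}

coefficient_records <- function(x) {
  if (inherits(x, "ensemble_result")) {
    if (is.null(x$models)) {
      stop("ensemble was run with keep_models = FALSE", call. = FALSE)
    }
    return(x$models)
  }
  if (inherits(x, "fitted_model")) return(list(x))
  if (is.list(x)) {
    return(do.call(c, lapply(x, coefficient_records)))
  }
  stop("expected fitted models or ensemble results", call. = FALSE)
}

#' Frequency of non-zero coefficients per predictor gene
#'
#' Counts, over all models of one or more ensembles, how often each
#' predictor carried a negative and a positive coefficient. In
#' gene-effect models a negative coefficient links higher expression to
#' stronger dependency (more negative gene effect). Genes never used
#' (zero in every model) are omitted; the union of predictor universes is
#' taken when ensembles differ.
#'
#' @param models A `fitted_model`, an `ensemble_result`, or a list of
#'   either.
#' @return Data frame (`gene`, `neg_count`, `pos_count`, `total`) sorted
#'   by descending total, ties by gene symbol.
#' @export
predictor_frequency <- function(models) {
  recs <- coefficient_records(models)
  if (length(recs) == 0L) stop("no models supplied", call. = FALSE)
  neg <- new.env(parent = emptyenv())
  pos <- new.env(parent = emptyenv())
  bump <- function(env, genes) {
    for (g in genes) assign(g, (get0(g, env) %||% 0L) + 1L, envir = env)
  }
  for (m in recs) {
    cf <- m$coefficients
    if (is.null(cf)) {
      stop("predictor frequency requires coefficient-based models ",
           "(lasso or elastic net)", call. = FALSE)
    }
    bump(neg, names(cf)[cf < 0])
    bump(pos, names(cf)[cf > 0])
  }
  genes <- sort(union(ls(neg), ls(pos)))
  out <- data.frame(
    gene = genes,
    neg_count = vapply(genes, function(g) get0(g, neg) %||% 0L,
                       integer(1)),
    pos_count = vapply(genes, function(g) get0(g, pos) %||% 0L,
                       integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$total <- out$neg_count + out$pos_count
  out <- out[order(-out$total, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Union of predictors used at least once in an ensemble
#'
#' Extracts every gene whose coefficient was non-zero in any model, in
#' lexicographic order. Used to build the exclusion lists for the
#' non-substitutability experiment.
#'
#' @inheritParams predictor_frequency
#' @return Character vector (possibly empty, with a warning).
#' @export
extract_nonzero_predictors <- function(models) {
  recs <- coefficient_records(models)
  if (length(recs) == 0L) stop("no models supplied", call. = FALSE)
  genes <- sort(unique(unlist(lapply(recs, function(m) {
    cf <- m$coefficients
    names(cf)[cf != 0]
  }))))
  if (length(genes) == 0L) {
    warning("no predictor was ever non-zero", call. = FALSE)
    genes <- character(0)
  }
  genes
}

#' Re-run an ensemble with a gene list excluded from the network superset
#'
#' Implements the non-substitutability experiment: remove a gene list
#' from the set of all network genes, rebuild the design matrix from the
#' remaining genes (after dropping genes with missing expression), and
#' refit the ensemble with the same seed, so any performance change is
#' attributable to the exclusion.
#'
#' @param network_genes All genes of the interaction network.
#' @param exclude Genes to remove (non-members are ignored with a
#'   warning).
#' @param expr Expression matrix (cell line x gene).
#' @param y Observed dependency values aligned with `expr` rows.
#' @inheritParams run_ensemble
#' @return An `ensemble_result` with the exclusion recorded in
#'   `provenance`.
#' @export
exclusion_run <- function(network_genes, exclude, expr, y,
                          spec = model_spec(), n_models = 100, seed = 1) {
  stray <- setdiff(exclude, network_genes)
  if (length(stray) > 0L) {
    warning(length(stray), " excluded gene(s) not in the network; ignored",
            call. = FALSE)
  }
  remaining <- setdiff(network_genes, exclude)
  remaining <- drop_missing(expr, remaining)
  if (length(remaining) == 0L) {
    stop("no predictors remain after exclusion", call. = FALSE)
  }
  X <- as.matrix(expr[, remaining, drop = FALSE])
  res <- run_ensemble(X, y, spec, n_models = n_models, seed = seed)
  res$provenance$excluded <- sort(intersect(exclude, network_genes))
  res$provenance$n_excluded <- length(res$provenance$excluded)
  res
}

#' Enumerate the modeling plan over predictor sets and datasets
#'
#' Bookkeeping for ensemble campaigns: one job per (predictor set,
#' dataset, resample) triple. With the default 60-configuration selection
#' grid, 100 resamples and the two dependency datasets (CRISPR and RNAi)
#' the plan comprises 12,000 models; a mutation-status-versus-RNA
#' comparison (2 predictor sets x 2 datasets x 100 resamples) comprises
#' 400.
#'
#' @param predictor_sets Character labels (or a data frame of grid
#'   configurations, one row per set).
#' @param datasets Dependency dataset labels; default
#'   `c("crispr", "rnai")`.
#' @param n_models Resamples per (set, dataset); default 100.
#' @return Data frame (`predictor_set`, `dataset`, `model_id`), one row
#'   per scheduled model.
#' @export
model_plan <- function(predictor_sets, datasets = c("crispr", "rnai"),
                       n_models = 100) {
  if (is.data.frame(predictor_sets)) {
    predictor_sets <- paste0("config_", seq_len(nrow(predictor_sets)))
  }
  if (length(predictor_sets) == 0L || length(datasets) == 0L ||
      n_models < 1) {
    stop("plan dimensions must be nonempty", call. = FALSE)
  }
  out <- expand.grid(model_id = seq_len(n_models),
                     dataset = datasets,
                     predictor_set = predictor_sets,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("predictor_set", "dataset", "model_id")]
}
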