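#' Standardize a feature matrix
#'
#' Column-wise z-scoring with the sample (n - 1) SD. The column means and
#' SDs are stored as attributes `center` and `scale` so fitted models can be
#' applied to new raw data and predictions mapped back.
#'
#' @param X Numeric matrix or data frame of features (rows = photos).
#' @return Numeric matrix with unit-variance, zero-mean columns and
#'   attributes `center` and `scale`.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing cells")
  sds <- apply(X, 2, stats::sd)
  zero <- colnames(X)[sds == 0]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2, mus), 2, sds, `/`)
  attr(Z, "center") <- mus
  attr(Z, "scale") <- sds
  Z
}

## Apply stored standardization parameters to raw features.
apply_standardization <- function(X, center, scale) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, center[colnames(X)]), 2, scale[colnames(X)], `/`)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the ordinary
#' least-squares regression of column `j` on all other columns plus an
#' intercept. Perfect collinearity yields `Inf`, not an error.
#'
#' @param X Numeric matrix or data frame, more rows than columns, no
#'   constant columns.
#' @return Named numeric vector of VIFs (each >= 1).
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("VIF requires at least 2 columns")
  if (nrow(X) <= p + 1) stop("VIF requires rows > columns + 1")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in VIF input")
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' Iterative VIF pruning with protected predictors
#'
#' Repeatedly computes VIFs and removes the non-protected feature with the
#' largest VIF at or above the threshold, until every retained feature's VIF
#' is below the threshold. Protected features are never removed (even when
#' their own VIF exceeds the threshold) but still count as regressors when
#' VIFs are computed. Ties on the maximum are broken by column order (first
#' column wins), so runs are deterministic.
#'
#' @param X Numeric matrix or data frame.
#' @param threshold VIF threshold (default 5).
#' @param protected Character vector of column names never to remove.
#' @return List with `retained` (column names), `vif` (final VIFs),
#'   and `removal_trace` (tibble: step, feature, vif at removal).
#' @export
vif_prune <- function(X, threshold = 5, protected = character()) {
  X <- as.matrix(X)
  if (!all(protected %in% colnames(X)))
    stop("protected features not in X: ",
         paste(setdiff(protected, colnames(X)), collapse = ", "))
  trace <- list()
  repeat {
    vif <- compute_vif(X)
    candidates <- setdiff(colnames(X), protected)
    vc <- vif[candidates]
    if (length(vc) == 0 || max(vc) < threshold) break
    worst <- candidates[which.max(vc)]     # ties: first column order wins
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(trace) + 1L, feature = worst, vif = unname(vif[worst]))
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
    if (ncol(X) < 2) break
  }
  list(retained = colnames(X),
       vif = if (ncol(X) >= 2) compute_vif(X) else stats::setNames(1, colnames(X)),
       removal_trace = if (length(trace)) dplyr::bind_rows(trace)
                       else tibble::tibble(step = integer(), feature = character(),
                                           vif = numeric()))
}

#' Seeded train/test split
#'
#' Draws `n_test` test ids uniformly without replacement; deterministic for
#' a given seed. The study geometry is 60 photos split 50/10.
#'
#' @param ids Vector of photo ids.
#' @param n_test Number of test ids (default 10).
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `seed`.
#' @export
split_train_test <- function(ids, n_test = 10, seed) {
  if (n_test >= length(ids)) stop("n_test must be smaller than the number of ids")
  test <- if (n_test == 0) ids[0] else
    withr::with_seed(seed, sample(ids, n_test))
  list(train_ids = setdiff(ids, test), test_ids = test, seed = seed)
}

## Default lambda grid: 100 log-spaced values from lambda_max (the smallest
## penalty that zeroes every coefficient under the 1/(2n) objective) down to
## 1e-4 * lambda_max.
lambda_grid <- function(X, y, n_lambda = 100, ratio = 1e-4) {
  n <- nrow(X)
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  lmax <- max(abs(crossprod(Xc, y - mean(y)))) / n
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Fit a lasso model at a fixed penalty
#'
#' Minimizes `(1/2n) * sum((y - yhat)^2) + lambda * sum(|beta|)` with an
#' unpenalized intercept (coordinate descent via glmnet, exact solution at
#' the requested `lambda`). `X` is expected to be standardized already; no
#' internal re-standardization takes place.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Numeric outcome.
#' @param lambda Penalty (>= 0).
#' @param outcome Outcome label stored in the model.
#' @param standardization Optional list with `center` and `scale` (taken
#'   from [standardize()] attributes) so the model can consume raw features.
#' @return An object of class `lasso_model`: `outcome`, `intercept`,
#'   `coefficients` (full named vector, zeros included), `lambda`,
#'   `standardization`, `provenance = "fitted"`.
#' @export
fit_lasso <- function(X, y, lambda, outcome = "outcome",
                      standardization = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (lambda < 0) stop("lambda must be >= 0")
  single <- ncol(X) == 1L
  if (single) X <- cbind(X, .dummy = 0)   # glmnet needs >= 2 columns
  grid <- sort(unique(c(lambda_grid(X, y), lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = grid, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12)
  ## glmnet truncates flat paths early; interpolating over the truncated
  ## grid emits a benign duplicate-knot warning from stats::approx
  cf <- suppressWarnings(as.matrix(glmnet::coef.glmnet(
    fit, s = lambda, exact = TRUE, x = X, y = y))[, 1])
  if (single) cf <- cf[names(cf) != ".dummy"]
  if (is.null(standardization) && !is.null(attr(X, "center")))
    standardization <- list(center = attr(X, "center"),
                            scale = attr(X, "scale"))
  structure(list(outcome = outcome,
                 intercept = unname(cf[1]),
                 coefficients = cf[-1],
                 lambda = lambda,
                 standardization = standardization,
                 provenance = "fitted"),
            class = "lasso_model")
}

#' @export
print.lasso_model <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  cat(sprintf("<lasso_model '%s' (%s): intercept %.3f, lambda %.4g, %d nonzero>\n",
              x$outcome, x$provenance, x$intercept, x$lambda, length(nz)))
  if (length(nz)) print(round(nz, 4))
  invisible(x)
}

#' 10-fold cross-validated lasso with the one-standard-error rule
#'
#' Assigns folds by a seeded shuffle followed by contiguous blocks. For
#' every penalty on the grid, the lasso is fitted on k - 1 folds and the
#' RMSE measured on the held-out fold; the per-penalty mean RMSE and its
#' standard error across folds (SD / sqrt(k)) are recorded.
#' `lambda_min` minimizes the mean RMSE; `lambda_1se` is the largest
#' penalty whose mean RMSE is within one standard error of the minimum --
#' the sparsest near-optimal model.
#'
#' @param X Standardized feature matrix (training photos).
#' @param y Outcome vector.
#' @param lambda Optional decreasing penalty grid; computed from the data
#'   by default.
#' @param nfolds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param outcome Outcome label for the returned models.
#' @return An object of class `cv_lasso`: `cv_table` (tibble: lambda,
#'   mean_rmse, se_rmse, nonzero), `lambda_min`, `lambda_1se`, `seed`, and
#'   `model_1se` / `model_min` refitted on all training rows.
#' @export
cv_lasso <- function(X, y, lambda = NULL, nfolds = 10, seed = 1,
                     outcome = "outcome") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < nfolds) stop("fewer rows than folds")
  if (is.null(lambda)) lambda <- lambda_grid(X, y)
  lambda <- sort(lambda, decreasing = TRUE)
  ## seeded shuffle, then contiguous blocks over the shuffled order
  fold <- withr::with_seed(seed, {
    perm <- sample.int(n)
    sizes <- diff(floor(seq(0, n, length.out = nfolds + 1)))
    f <- integer(n)
    f[perm] <- rep(seq_len(nfolds), times = sizes)
    f
  })
  rmse <- matrix(NA_real_, nfolds, length(lambda))
  for (k in seq_len(nfolds)) {
    tr <- fold != k
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "gaussian",
                          alpha = 1, lambda = lambda, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-10)
    pred <- suppressWarnings(
      stats::predict(fit, newx = X[!tr, , drop = FALSE], s = lambda))
    rmse[k, ] <- sqrt(colMeans((pred - y[!tr])^2))
  }
  mean_rmse <- colMeans(rmse)
  se_rmse <- apply(rmse, 2, stats::sd) / sqrt(nfolds)
  i_min <- which.min(mean_rmse)
  within <- mean_rmse <= mean_rmse[i_min] + se_rmse[i_min]
  i_1se <- which(within)[1]               # grid is decreasing: first = largest
  cv_table <- tibble::tibble(lambda = lambda, mean_rmse = mean_rmse,
                             se_rmse = se_rmse)
  std <- if (!is.null(attr(X, "center")))
    list(center = attr(X, "center"), scale = attr(X, "scale")) else NULL
  structure(list(cv_table = cv_table,
                 lambda_min = lambda[i_min],
                 lambda_1se = lambda[i_1se],
                 seed = seed,
                 model_min = fit_lasso(X, y, lambda[i_min], outcome,
                                       standardization = std),
                 model_1se = fit_lasso(X, y, lambda[i_1se], outcome,
                                       standardization = std)),
            class = "cv_lasso")
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat(sprintf("<cv_lasso: %d lambdas, lambda_min %.4g, lambda_1se %.4g>\n",
              nrow(x$cv_table), x$lambda_min, x$lambda_1se))
  print(x$model_1se)
  invisible(x)
}

#' Predict from a lasso model
#'
#' `intercept + sum(coefficient * z)` over the model's features. If the
#' model carries standardization parameters and `standardized = FALSE`,
#' raw features are z-scored with the stored training means/SDs first.
#'
#' @param model A `lasso_model` (fitted or published).
#' @param newdata Named numeric vector, matrix, or data frame holding at
#'   least the model's feature columns.
#' @param standardized Is `newdata` already on the standardized scale?
#' @return Numeric vector of predicted scores.
#' @export
apply_model <- function(model, newdata, standardized = TRUE) {
  stopifnot(inherits(model, "lasso_model"))
  feats <- names(model$coefficients)
  if (is.vector(newdata) && !is.list(newdata))
    newdata <- matrix(newdata, 1, dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  Z <- newdata[, feats, drop = FALSE]
  if (!standardized) {
    if (is.null(model$standardization))
      stop("model carries no standardization parameters for raw features")
    Z <- apply_standardization(Z, model$standardization$center,
                               model$standardization$scale)
  }
  as.vector(model$intercept + Z %*% model$coefficients)
}

#' Root-mean-square prediction error of a model
#'
#' @param model A `lasso_model`.
#' @param X Feature matrix or data frame.
#' @param y Observed outcomes.
#' @param standardized Is `X` already standardized?
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
evaluate_rmse <- function(model, X, y, standardized = TRUE) {
  pred <- apply_model(model, X, standardized = standardized)
  sqrt(mean((y - pred)^2))
}

#' Published lasso models linking visual properties to restorativeness
#'
#' Returns the four published standardized-scale models (Overall
#' restorativeness, Being Away, Fascination, Extent) as `lasso_model`
#' objects with `provenance = "published"`. The Overall model has
#' four nonzero coefficients, Being Away and Fascination three each, and
#' Extent none (intercept only). Coefficients are read from the JSON data
#' asset shipped in `inst/extdata/published_models.json`.
#'
#' @return Named list of four `lasso_model` objects.
#' @export
published_models <- function() {
  path <- system.file("extdata", "published_models.json", package = "restorevis")
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(spec$models, function(m) {
    cf <- stats::setNames(
      vapply(m$coefficients, function(cc) as.numeric(cc$value), numeric(1)),
      vapply(m$coefficients, function(cc) cc$feature, character(1)))
    structure(list(outcome = m$outcome,
                   intercept = m$intercept,
                   coefficients = cf,
                   lambda = NA_real_,
                   standardization = NULL,
                   provenance = "published",
                   rmse_train = m$rmse_train,
                   rmse_test = m$rmse_test),
              class = "lasso_model")
  })
  stats::setNames(out, vapply(spec$models, `[[`, character(1), "outcome"))
}

#' Write / read a lasso model as JSON
#'
#' @param model A `lasso_model`.
#' @param path Output JSON path.
#' @return [write_model()]: `path`; [read_model()]: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lasso_model"))
  std <- model$standardization
  if (!is.null(std)) std <- list(center = as.list(std$center),
                                 scale = as.list(std$scale))
  payload <- list(outcome = model$outcome, intercept = model$intercept,
                  coefficients = as.list(model$coefficients),
                  lambda = model$lambda,
                  standardization = std,
                  provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- x$standardization
  if (!is.null(std)) std <- list(center = unlist(std$center),
                                 scale = unlist(std$scale))
  structure(list(outcome = x$outcome, intercept = x$intercept,
                 coefficients = unlist(x$coefficients),
                 lambda = x$lambda, standardization = std,
                 provenance = x$provenance),
            class = "lasso_model")
}

#' Correlations of photo scores with greenery
#'
#' Pearson correlations between each photo-level mean score and both the
#' square root of greenery and the raw greenery percentage, so the
#' improvement from the square-root transform is inspectable.
#'
#' @param features Data frame with `photo_id`, `sqrt_greenery`, and
#'   `greenery_pct`.
#' @param photo_scores Data frame with `photo_id` and `*_mean` score
#'   columns (the output of [aggregate_by_photo()]).
#' @return Tibble with `score`, `r_sqrt` and `r_raw` per score.
#' @export
sqrt_greenery_correlations <- function(features, photo_scores) {
  merged <- dplyr::inner_join(features, photo_scores, by = "photo_id")
  if (nrow(merged) < 3) stop("need at least 3 matched photos")
  score_cols <- grep("_mean$", names(photo_scores), value = TRUE)
  tibble::tibble(
    score = sub("_mean$", "", score_cols),
    r_sqrt = vapply(score_cols, function(s)
      correlate(merged$sqrt_greenery, merged[[s]]), numeric(1),
      USE.NAMES = FALSE),
    r_raw = vapply(score_cols, function(s)
      correlate(merged$greenery_pct, merged[[s]]), numeric(1),
      USE.NAMES = FALSE))
}
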