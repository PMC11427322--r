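test_that("standardization gives exact z-scores and is idempotent", {
  Z <- standardize(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(Z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(Z, 2, stats::sd), c(a = 1, b = 1), tolerance = 1e-12)
  Z2 <- standardize(Z)
  expect_equal(unclass(Z2), unclass(Z), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(standardize(cbind(a = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("VIFs match the inverse-correlation-matrix oracle", {
  ## orthogonal columns
  X <- cbind(x1 = c(1, 1, -1, -1, 0, 0), x2 = c(1, -1, 1, -1, 0, 0),
             x3 = c(0, 0, 0, 0, 1, -1))
  expect_equal(unname(compute_vif(X)), rep(1, 3), tolerance = 1e-10)

  ## perfect collinearity reports +Inf
  Xc <- withr::with_seed(2, cbind(x1 = rnorm(20), x2 = rnorm(20)))
  Xc <- cbind(Xc, x3 = Xc[, 1] + Xc[, 2])
  expect_equal(unname(compute_vif(Xc)["x3"]), Inf)

  ## known pairwise correlation ~0.9: match diag(solve(cor(X))) to 1e-6
  Xr <- withr::with_seed(4, {
    z <- rnorm(200)
    cbind(x1 = z + rnorm(200, 0, 0.33), x2 = z + rnorm(200, 0, 0.33),
          x3 = z + rnorm(200, 0, 0.33))
  })
  expect_equal(unname(compute_vif(Xr)), unname(diag(solve(stats::cor(Xr)))),
               tolerance = 1e-6)
})

test_that("VIF pruning respects the threshold, protection, and terminates", {
  Xo <- cbind(x1 = c(1, 1, -1, -1, 0, 0, 1, -1),
              x2 = c(1, -1, 1, -1, 0, 0, -1, 1),
              x3 = c(0, 0, 0, 0, 1, -1, 1, -1))
  res <- vif_prune(Xo)
  expect_equal(nrow(res$removal_trace), 0)
  expect_equal(res$retained, c("x1", "x2", "x3"))

  Xc <- withr::with_seed(6, cbind(x1 = rnorm(40), x2 = rnorm(40),
                                  x4 = rnorm(40)))
  Xc <- cbind(Xc, x3 = Xc[, "x1"] + Xc[, "x2"] + rnorm(40, 0, 0.01))
  res <- vif_prune(Xc, threshold = 5)
  expect_equal(nrow(res$removal_trace), 1)
  expect_true(res$removal_trace$feature %in% c("x1", "x2", "x3"))
  expect_true(all(res$vif < 5))
  expect_lte(nrow(res$removal_trace), ncol(Xc))

  prot <- vif_prune(Xc, threshold = 5, protected = "x3")
  expect_true("x3" %in% prot$retained)
  expect_false("x3" %in% prot$removal_trace$feature)
  expect_true(prot$removal_trace$feature[1] %in% c("x1", "x2"))
})

test_that("train/test split is seeded, disjoint, and exhaustive", {
  ids <- sprintf("photo_%02d", 1:60)
  s1 <- split_train_test(ids, 10, seed = 42)
  s2 <- split_train_test(ids, 10, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1$train_ids, 50)
  expect_length(s1$test_ids, 10)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_setequal(c(s1$train_ids, s1$test_ids), ids)
  s0 <- split_train_test(ids, 0, seed = 1)
  expect_length(s0$test_ids, 0)
  expect_error(split_train_test(ids, 60, seed = 1), "smaller")
})

test_that("lasso limits: full shrinkage and the OLS end of the path", {
  set.seed(31)
  n <- 50
  X <- standardize(matrix(rnorm(n * 4), n, 4,
                          dimnames = list(NULL, paste0("x", 1:4))))
  y <- 1.5 + 2 * X[, 1] - X[, 3] + rnorm(n, 0, 0.3)

  big <- fit_lasso(X, y, lambda = 100)
  expect_equal(unname(big$coefficients), rep(0, 4))
  expect_equal(big$intercept, mean(y))

  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  zero <- fit_lasso(X, y, lambda = 0)
  expect_equal(unname(c(zero$intercept, zero$coefficients)), unname(ols),
               tolerance = 1e-5)
})

test_that("univariate lasso equals the closed-form soft threshold", {
  set.seed(7)
  n <- 40
  x <- as.numeric(scale(rnorm(n)))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  y <- 3 + 0.8 * x + rnorm(n, 0, 0.2)
  for (lam in c(0.01, 0.1, 0.3)) {
    fit <- fit_lasso(X, y, lambda = lam)
    rho <- sum(x * (y - mean(y))) / n
    beta <- sign(rho) * max(abs(rho) - lam, 0) / (sum(x^2) / n)
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-6)
  }
})

test_that("lasso solutions satisfy the KKT conditions", {
  set.seed(19)
  for (rep in 1:3) {
    n <- 60; p <- 8
    X <- standardize(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, paste0("x", 1:p))))
    y <- X %*% rnorm(p) + rnorm(n)
    lam <- 0.2
    fit <- fit_lasso(X, y, lambda = lam)
    resid <- y - fit$intercept - X %*% fit$coefficients
    grad <- as.vector(crossprod(X, resid)) / n
    active <- fit$coefficients != 0
    expect_true(all(abs(grad[!active]) <= lam + 1e-6))
    if (any(active))
      expect_equal(grad[active], lam * sign(fit$coefficients[active]),
                   tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("one-standard-error rule matches an exhaustive grid scan", {
  set.seed(55)
  n <- 50
  X <- standardize(matrix(rnorm(n * 6), n, 6,
                          dimnames = list(NULL, paste0("x", 1:6))))
  y <- 2.8 + 1.2 * X[, 1] + rnorm(n, 0, 0.5)
  cv <- cv_lasso(X, y, seed = 9)
  tab <- cv$cv_table
  i_min <- which.min(tab$mean_rmse)
  expect_equal(cv$lambda_min, tab$lambda[i_min])
  eligible <- tab$lambda[tab$mean_rmse <= tab$mean_rmse[i_min] + tab$se_rmse[i_min]]
  expect_equal(cv$lambda_1se, max(eligible))
  expect_gte(cv$lambda_1se, cv$lambda_min)
  expect_lte(tab$mean_rmse[tab$lambda == cv$lambda_1se],
             tab$mean_rmse[i_min] + tab$se_rmse[i_min])
})

test_that("pure-noise outcomes collapse to the intercept at lambda_1se", {
  set.seed(77)
  X <- standardize(matrix(rnorm(50 * 6), 50, 6,
                          dimnames = list(NULL, paste0("x", 1:6))))
  y <- rnorm(50)
  cv <- cv_lasso(X, y, seed = 3)
  expect_equal(unname(cv$model_1se$coefficients), rep(0, 6))
})

test_that("a planted signal is recovered at lambda_1se in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    X <- standardize(matrix(rnorm(50 * 6), 50, 6,
                            dimnames = list(NULL, paste0("x", 1:6))))
    y <- 2 * X[, 1] + rnorm(50, 0, 0.4)
    cv <- cv_lasso(X, y, seed = s)
    if (cv$model_1se$coefficients["x1"] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 16)   # >= 80% of 20 seeds
})

test_that("RMSE evaluation matches hand computation and handles raw features", {
  model <- structure(list(outcome = "toy", intercept = 1,
                          coefficients = c(z = 1), lambda = 0,
                          standardization = NULL, provenance = "fitted"),
                     class = "lasso_model")
  X <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "z"))
  expect_equal(evaluate_rmse(model, X, c(2, 4)), sqrt(2.5))
  expect_equal(evaluate_rmse(model, X, c(1, 2)), 0)

  ## stored standardization lets the model consume raw features
  raw <- matrix(c(10, 20, 30), 3, 1, dimnames = list(NULL, "z"))
  model$standardization <- list(center = c(z = 20), scale = c(z = 10))
  expect_equal(apply_model(model, raw, standardized = FALSE), c(0, 1, 2))
  expect_error(apply_model(model, matrix(1, 1, 1, dimnames = list(NULL, "w"))),
               "missing feature")
})

test_that("model JSON round trip preserves coefficients exactly", {
  set.seed(88)
  X <- standardize(matrix(rnorm(40 * 3), 40, 3,
                          dimnames = list(NULL, c("a", "b", "c"))))
  y <- 1 + X[, 2] + rnorm(40, 0, 0.1)
  fit <- fit_lasso(X, y, lambda = 0.05, outcome = "demo",
                   standardization = list(center = attr(X, "center"),
                                          scale = attr(X, "scale")))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$standardization$center, fit$standardization$center)
})

test_that("greenery correlations recover planted structure", {
  set.seed(101)
  g <- seq(0, 60, length.out = 60)
  feats <- tibble::tibble(photo_id = sprintf("p%02d", 1:60),
                          sqrt_greenery = sqrt(g), greenery_pct = g)
  exact <- tibble::tibble(photo_id = feats$photo_id,
                          overall_mean = 2 + 0.1 * sqrt(g))
  r <- sqrt_greenery_correlations(feats, exact)
  expect_equal(r$r_sqrt[r$score == "overall"], 1, tolerance = 1e-12)
  expect_lt(r$r_raw[r$score == "overall"], 1)

  ## independent scores: |r| small at n = 60 (checked over 100 seeds)
  rs <- vapply(1:100, function(s) {
    noise <- tibble::tibble(photo_id = feats$photo_id,
                            overall_mean = withr::with_seed(s, rnorm(60)))
    sqrt_greenery_correlations(feats, noise)$r_sqrt[1]
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.2)
  expect_error(sqrt_greenery_correlations(feats[1:2, ], exact[1:2, ]),
               "at least 3")
})
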