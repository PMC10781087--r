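test_that("a planted single-signal model predicts near-perfectly", {
  beta <- c(1, rep(0, 5))
  train <- sim_linear(1000, 6, beta, noise_sd = 0.01, seed = 2)
  test <- sim_linear(1000, 6, beta, noise_sd = 0.01, seed = 3, id = "B")
  fit <- fit_elastic_net(train, item_names(6), seed = 1)
  res <- evaluate_net(fit, test)
  expect_gte(res$r, 0.99)
  expect_true(res$valid)
  expect_true(res$ci95[1] <= res$r && res$r <= res$ci95[2])
  expect_equal(names(which.max(abs(fit$weights))), "item_001")
  expect_true(fit$lambda_chosen %in% fit$lambda_grid)
})

test_that("pure-noise outcomes give test r centered at zero", {
  rs <- vapply(1:6, function(s) {
    train <- sim_linear(400, 20, rep(0, 20), seed = 10 + s)
    test <- sim_linear(400, 20, rep(0, 20), seed = 50 + s, id = "B")
    res <- evaluate_net(fit_elastic_net(train, item_names(20), seed = s), test)
    if (res$valid) res$r else 0
  }, 0)
  expect_lte(abs(mean(rs)), 2 / sqrt(400))
})

test_that("tiny-instance solutions satisfy elastic-net stationarity (KKT)", {
  set.seed(6)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- item_names(3)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.3)
  tab <- make_residual_table(as.data.frame(X), y)
  fit <- fit_elastic_net(tab, item_names(3), seed = 1, folds = 3)
  Xs <- scale(X, center = fit$standardization$mean,
              scale = fit$standardization$sd)
  yt <- (y - fit$outcome_center) / fit$outcome_scale
  lam <- fit$lambda_chosen
  viol <- enet_kkt_violation(fit$intercept, fit$weights, Xs, yt, lam, 0.5)
  expect_lt(viol, 1e-4)
  # the fit attains an objective no worse than a grid-search oracle
  best <- Inf
  b1 <- seq(-2, 2, length.out = 41)
  for (i in b1) for (j in b1) for (k in seq(-1, 1, length.out = 21)) {
    b <- c(i, j, k)
    o <- enet_objective(mean(yt), b, Xs, yt, lam, 0.5)
    best <- min(best, o)
  }
  got <- enet_objective(fit$intercept, fit$weights, Xs, yt, lam, 0.5)
  expect_lte(got, best + 1e-4)
})

test_that("training accuracy dominates test accuracy in expectation", {
  d <- vapply(1:5, function(s) {
    beta <- c(0.5, 0.3, rep(0, 8))
    train <- sim_linear(300, 10, beta, noise_sd = 2, seed = 100 + s)
    test <- sim_linear(300, 10, beta, noise_sd = 2, seed = 200 + s, id = "B")
    fit <- fit_elastic_net(train, item_names(10), seed = s)
    evaluate_net(fit, train)$r - evaluate_net(fit, test)$r
  }, 0)
  expect_gt(mean(d), 0)
})

test_that("degenerate inputs are handled as specified", {
  tab <- sim_linear(50, 3, c(1, 0, 0), seed = 4)
  fit <- fit_elastic_net(tab, item_names(3), seed = 1, folds = 5)
  expect_error(evaluate_net(fit, tab[0, ]), "empty test")
  # constant predictions -> invalid, not an error
  fit0 <- fit
  fit0$weights[] <- 0
  res <- evaluate_net(fit0, tab)
  expect_false(res$valid)
  expect_true(is.na(res$r))
  # all-missing predictor dropped with warning
  tab$item_002 <- NA_real_
  expect_warning(fit2 <- fit_elastic_net(tab, item_names(3), seed = 1,
                                         folds = 5),
                 "no information")
  expect_equal(fit2$predictor_ids, c("item_001", "item_003"))
  # degenerate outcome
  tab$bmi <- 1
  expect_error(fit_elastic_net(tab, item_names(3), seed = 1), "zero variance")
})

test_that("missing predictors are zero-imputed with training standardization", {
  train <- sim_linear(500, 4, c(1, 0.5, 0, 0), noise_sd = 0.5, seed = 8)
  train$item_001[sample(500, 200)] <- NA
  fit <- fit_elastic_net(train, item_names(4), seed = 2)
  test <- sim_linear(200, 4, c(1, 0.5, 0, 0), noise_sd = 0.5, seed = 9, "B")
  test$item_002[1:100] <- NA
  pred <- predict(fit, test)
  X <- as.matrix(test[item_names(4)]); X[is.na(X)] <- 0
  Xs <- scale(X, fit$standardization$mean, fit$standardization$sd)
  expect_equal(pred,
               as.numeric(fit$outcome_center + fit$outcome_scale *
                            (fit$intercept + Xs %*% fit$weights)),
               tolerance = 1e-12)
})

test_that("variable-set comparison equalizes training rows across sets", {
  set.seed(12)
  n <- 1500
  f <- rnorm(n)
  X <- sapply(1:8, function(j) 0.7 * f + rnorm(n, 0, 0.7))
  colnames(X) <- item_names(8)
  X[sample(length(X), length(X) * 0.3)] <- NA
  y <- 1.5 * f + rnorm(n, 0, 2)
  train <- make_residual_table(as.data.frame(X), y, "A")
  test <- make_residual_table(
    as.data.frame(sapply(1:8, function(j) 0.7 * rnorm(n) + rnorm(n, 0, 0.7),
                         simplify = TRUE) |>
                    (\(M) {colnames(M) <- item_names(8); M})()),
    rnorm(n), "B")
  def1 <- structure(list(name = "Fac1", item_ids = item_names(8)[1:4],
                         keys = setNames(rep(1, 4), item_names(8)[1:4]),
                         lead_item = "item_001"),
                    class = "factor_definition")
  def2 <- structure(list(name = "Fac2", item_ids = item_names(8)[5:8],
                         keys = setNames(rep(1, 4), item_names(8)[5:8]),
                         lead_item = "item_005"),
                    class = "factor_definition")
  sets <- list(all_items = item_names(8),
               half_items = item_names(8)[1:4],
               factors = list(def1, def2))
  cmp <- compare_variable_sets(train, test, sets, seed = 3)
  expect_named(cmp$results, names(sets))
  expect_equal(unique(vapply(cmp$models, function(m) m$n_train, 0)),
               cmp$n_train_shared)
  expect_equal(cmp$summaries$n_predictors, c(8, 4, 2))
  expect_true(all(cmp$summaries$max_abs_r <= 1))
  # identical sets under different names give identical results
  cmp2 <- compare_variable_sets(train, test,
                                list(a = item_names(8), b = item_names(8)),
                                seed = 3)
  expect_equal(cmp2$results$a$r, cmp2$results$b$r)
})

test_that("model YAML serialization preserves weights and metadata", {
  tab <- sim_linear(100, 3, c(1, 0, 0), seed = 5)
  fit <- fit_elastic_net(tab, item_names(3), seed = 1, folds = 5)
  path <- tempfile(fileext = ".yaml")
  write_net_model(fit, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$weights, unname(as.numeric(fit$weights)), tolerance = 1e-12)
  expect_equal(back$alpha, 0.5)
  expect_equal(back$cv_folds, 5)
  unlink(path)
})
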