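#' Fit an elastic net on residualized predictors
#'
#' Minimizes `(1/2n) sum((y - b0 - X b)^2) + lambda (alpha |b|_1 +
#' ((1 - alpha)/2) |b|_2^2)` over a 100-point log-spaced lambda grid from
#' `lambda_max = max|X'y| / (n alpha)` down to `lambda_max * 1e-4`, choosing
#' lambda at the minimum mean cross-validated squared error (10-fold by
#' default, folds assigned by seeded shuffle). Fitting is delegated to
#' glmnet with this grid and `standardize = FALSE`; predictors are
#' standardized here on the training data, after missing values are imputed
#' as 0 -- the mean of a residualized variable -- so the stored
#' standardization can be replayed exactly on test data.
#'
#' @param train A `residual_table` (training rows only).
#' @param predictors Predictor column names (residualized items or scored
#'   factor columns).
#' @param outcome Outcome column, default `"bmi"` (residualized).
#' @param alpha Elastic-net mixing parameter, default .50.
#' @param folds Cross-validation folds, default 10.
#' @param seed Integer seed for fold assignment (required; no hidden
#'   randomness).
#' @param nlambda Grid size, default 100.
#' @param lambda_min_ratio Grid floor relative to `lambda_max`, default 1e-4.
#' @return An object of class `"net_model"`: list with `predictor_ids`,
#'   `weights` (on the standardized predictor/outcome scale used in fitting),
#'   `intercept`, `outcome_center`, `outcome_scale`, `alpha`, `lambda_grid`,
#'   `lambda_chosen`, `cv_folds`, `fold_seed`, `standardization`
#'   (data.frame: predictor, mean, sd), `n_train`.
#' @export
fit_elastic_net <- function(train, predictors, outcome = "bmi",
                            alpha = 0.5, folds = 10, seed,
                            nlambda = 100, lambda_min_ratio = 1e-4) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  y <- as.numeric(train[[outcome]])
  rows <- !is.na(y)
  y <- y[rows]
  n <- length(y)
  if (n < folds) stop("fewer outcome rows than folds", call. = FALSE)
  if (stats::var(y) == 0) stop("outcome has zero variance", call. = FALSE)
  X <- as.matrix(train[rows, predictors, drop = FALSE])
  all_na <- colSums(!is.na(X)) == 0
  X[is.na(X)] <- 0
  sds <- apply(X, 2, stats::sd)
  drop <- all_na | sds == 0
  if (any(drop)) {
    warning("dropping predictor(s) with no information: ",
            paste(predictors[drop], collapse = ", "), call. = FALSE)
    X <- X[, !drop, drop = FALSE]
    predictors <- predictors[!drop]
    sds <- sds[!drop]
  }
  if (ncol(X) < 2) stop("need >= 2 usable predictors", call. = FALSE)
  mus <- colMeans(X)
  Xs <- scale(X, center = mus, scale = sds)
  # the outcome is standardized to zero mean / unit (1/n) variance so the
  # penalized objective is exactly the stated one on a scale-free problem;
  # predictions are transformed back to the outcome's original scale
  y_center <- mean(y)
  y_scale <- sqrt(mean((y - y_center)^2))
  yt <- (y - y_center) / y_scale
  lambda_max <- max(abs(crossprod(Xs, yt))) / (n * alpha)
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  set.seed(seed)
  foldid <- rep_len(seq_len(folds), n)[sample.int(n)]
  cv <- glmnet::cv.glmnet(Xs, yt, alpha = alpha, lambda = grid,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "mse", thresh = 1e-12)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  structure(list(
    predictor_ids = predictors,
    weights = stats::setNames(co[-1], predictors),
    intercept = co[1],
    outcome_center = y_center,
    outcome_scale = y_scale,
    alpha = alpha,
    lambda_grid = grid,
    lambda_chosen = cv$lambda.min,
    cv_folds = folds,
    fold_seed = as.integer(seed),
    standardization = data.frame(predictor = predictors, mean = mus, sd = sds,
                                 row.names = NULL, stringsAsFactors = FALSE),
    n_train = n
  ), class = "net_model")
}

#' Predict from a fitted elastic net
#'
#' Applies zero-imputation and the training standardization, then the linear
#' model.
#'
#' @param object A `net_model`.
#' @param newdata Table containing the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.net_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictor_ids])
  X[is.na(X)] <- 0
  Xs <- scale(X, center = object$standardization$mean,
              scale = object$standardization$sd)
  as.numeric(object$outcome_center + object$outcome_scale *
               (object$intercept + Xs %*% object$weights))
}

#' Out-of-sample accuracy of an elastic-net model
#'
#' Pearson correlation between predictions and the observed outcome on test
#' persons with an observed outcome, with a Fisher-z 95\% confidence
#' interval. Constant predictions make r undefined; the result is flagged
#' invalid rather than erroring.
#'
#' @param model A `net_model`.
#' @param test A `residual_table` of test rows (must be disjoint from
#'   training rows; enforce by using distinct `dataset_id`s).
#' @param outcome Outcome column, default `"bmi"`.
#' @return An object of class `"prediction_result"`: list with `r`, `ci95`,
#'   `n_test`, `n_train`, `valid`.
#' @export
evaluate_net <- function(model, test, outcome = "bmi") {
  if (nrow(test) == 0) stop("empty test table", call. = FALSE)
  pred <- predict(model, test)
  y <- as.numeric(test[[outcome]])
  ok <- !is.na(y)
  pred <- pred[ok]
  y <- y[ok]
  n <- length(y)
  if (n < 4 || stats::sd(pred) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, ci95 = c(NA_real_, NA_real_),
                          n_test = n, n_train = model$n_train, valid = FALSE),
                     class = "prediction_result"))
  }
  r <- stats::cor(pred, y)
  ci <- if (abs(r) >= 1) c(r, r) else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    pmin(pmax(tanh(c(z - 1.96 * se, z + 1.96 * se)), -1), 1)
  }
  structure(list(r = r, ci95 = ci, n_test = n, n_train = model$n_train,
                 valid = TRUE),
            class = "prediction_result")
}

#' Compare predictor variable sets on a shared training subsample
#'
#' For each named set, builds a predictor matrix (item columns directly, or
#' factor/domain/facet scores from scoring-key definitions), restricts
#' training to the single shared subsample in which every set has at least
#' one observed predictor per person (so no set benefits from a larger
#' training sample), fits one elastic net per set on those identical rows,
#' and evaluates each on the test table. Per-set summaries of the absolute
#' item/score--outcome correlations (mean, median, range) are also returned.
#'
#' @param train,test `residual_table`s (disjoint samples).
#' @param sets Named list; each element is either a character vector of
#'   predictor columns or a list of `factor_definition`s (scored with
#'   [score_factor()], producing one predictor column per definition).
#' @param outcome Outcome column, default `"bmi"`.
#' @inheritParams fit_elastic_net
#' @param min_score_items Floor for scoring key-based predictors.
#' @return List with `results` (per-set `prediction_result`s), `models`,
#'   `summaries` (data.frame: set, n_predictors, mean_abs_r, median_abs_r,
#'   min_abs_r, max_abs_r), `n_train_shared`.
#' @export
compare_variable_sets <- function(train, test, sets, outcome = "bmi",
                                  alpha = 0.5, folds = 10, seed,
                                  min_score_items = 3) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  build <- function(tab, set) {
    if (is.character(set)) {
      as.matrix(tab[set])
    } else {
      cols <- lapply(set, function(d) score_factor(tab, d, min_score_items))
      mat <- do.call(cbind, cols)
      colnames(mat) <- vapply(set, `[[`, "", "name")
      mat
    }
  }
  Xtr <- lapply(sets, build, tab = train)
  Xte <- lapply(sets, build, tab = test)
  usable <- vapply(Xtr, function(M) any(colSums(!is.na(M)) > 0), logical(1))
  if (any(!usable)) {
    warning("skipping set(s) with no available predictors: ",
            paste(names(sets)[!usable], collapse = ", "), call. = FALSE)
    Xtr <- Xtr[usable]; Xte <- Xte[usable]; sets <- sets[usable]
  }
  avail <- Reduce(`&`, lapply(Xtr, function(M) rowSums(!is.na(M)) >= 1))
  avail <- avail & !is.na(train[[outcome]])
  results <- models <- vector("list", length(sets))
  names(results) <- names(models) <- names(sets)
  summaries <- NULL
  y_tr <- as.numeric(train[[outcome]])[avail]
  for (s in names(sets)) {
    df_tr <- data.frame(Xtr[[s]][avail, , drop = FALSE], check.names = FALSE)
    df_tr[[outcome]] <- y_tr
    fit <- fit_elastic_net(df_tr, colnames(Xtr[[s]]), outcome = outcome,
                           alpha = alpha, folds = folds, seed = seed)
    df_te <- data.frame(Xte[[s]], check.names = FALSE)
    df_te[[outcome]] <- as.numeric(test[[outcome]])
    models[[s]] <- fit
    results[[s]] <- evaluate_net(fit, df_te, outcome = outcome)
    rr <- abs(suppressWarnings(
      as.numeric(stats::cor(Xtr[[s]][avail, , drop = FALSE], y_tr,
                            use = "pairwise.complete.obs"))))
    rr <- rr[is.finite(rr)]
    summaries <- rbind(summaries, data.frame(
      set = s, n_predictors = ncol(Xtr[[s]]),
      mean_abs_r = mean(rr), median_abs_r = stats::median(rr),
      min_abs_r = min(rr), max_abs_r = max(rr),
      stringsAsFactors = FALSE))
  }
  list(results = results, models = models, summaries = summaries,
       n_train_shared = sum(avail))
}

#' Serialize a fitted elastic net as YAML
#'
#' @param model A `net_model`.
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_net_model <- function(model, path) {
  yaml::write_yaml(list(
    predictor_ids = model$predictor_ids,
    weights = as.numeric(model$weights),
    intercept = model$intercept,
    outcome_center = model$outcome_center,
    outcome_scale = model$outcome_scale,
    alpha = model$alpha,
    lambda_chosen = model$lambda_chosen,
    cv_folds = model$cv_folds,
    fold_seed = model$fold_seed,
    standardization_mean = as.numeric(model$standardization$mean),
    standardization_sd = as.numeric(model$standardization$sd),
    n_train = model$n_train
  ), path, precision = 15L)
  invisible(path)
}
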