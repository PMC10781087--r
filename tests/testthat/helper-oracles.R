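# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# OLS residuals via the normal equations on complete rows.
ols_residual_oracle <- function(y, X) {
  obs <- !is.na(y)
  b <- solve(crossprod(X[obs, , drop = FALSE]),
             crossprod(X[obs, , drop = FALSE], y[obs]))
  r <- y
  r[obs] <- y[obs] - X[obs, , drop = FALSE] %*% b
  r
}

# Complete-case Pearson r and two-sided p from first principles.
cor_oracle <- function(x, y) {
  obs <- !is.na(x) & !is.na(y)
  x <- x[obs]; y <- y[obs]
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE))
}

# Closed-form item--BMI correlation for a one-factor generator with loading
# lambda, outcome weight w, BMI noise sd s, and equal-mass discretization of
# a standard-normal propensity to categories 1..6:
#   cov(item, BMI) = w * lambda * E[g(u) u],  E[g(u)u] = sum_c c (phi(t_{c-1}) - phi(t_c))
#   var(item)      = sum c^2/6 - (sum c/6)^2,  var(BMI) = w^2 + s^2
discretized_item_bmi_r <- function(lambda, w, noise_sd) {
  cuts <- qnorm((1:5) / 6)
  phi <- c(0, dnorm(cuts), 0)
  cats <- 1:6
  egu <- sum(cats * (phi[1:6] - phi[2:7]))
  v_item <- mean(cats^2) - mean(cats)^2
  w * lambda * egu / sqrt(v_item * (w^2 + noise_sd^2))
}

# Naive O(m^3) winnow: full re-scan of the remaining submatrix every step,
# with the same documented tie-breaks.
winnow_oracle <- function(R, outcome_r, criterion) {
  ids <- sort(colnames(R))
  R <- abs(R[ids, ids, drop = FALSE])
  orel <- abs(outcome_r[ids])
  alive <- ids
  repeat {
    sub <- R[alive, alive, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- -Inf
    mx <- max(sub)
    if (!is.finite(mx) || mx <= criterion) break
    cand <- which(sub == mx, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    a <- alive[cand[1, 1]]; b <- alive[cand[1, 2]]
    drop <- if (orel[a] < orel[b]) a
            else if (orel[b] < orel[a]) b
            else max(a, b)
    alive <- setdiff(alive, drop)
  }
  alive
}

# Elastic-net objective as stated: (1/2n) RSS + lambda (a |b|_1 + (1-a)/2 |b|_2^2)
enet_objective <- function(b0, b, X, y, lambda, alpha) {
  n <- length(y)
  sum((y - b0 - X %*% b)^2) / (2 * n) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

# Max KKT/stationarity violation of a candidate solution (standardized X).
enet_kkt_violation <- function(b0, b, X, y, lambda, alpha) {
  n <- length(y)
  r <- y - b0 - X %*% b
  g <- as.numeric(crossprod(X, r)) / n          # gradient of the smooth part
  viol_int <- abs(mean(r))
  viol <- vapply(seq_along(b), function(j) {
    gj <- g[j] - lambda * (1 - alpha) * b[j]
    if (b[j] == 0) max(0, abs(gj) - lambda * alpha)
    else abs(gj - lambda * alpha * sign(b[j]))
  }, 0)
  max(viol_int, viol)
}

# Small random participant-table-like data.frame of residual-style columns.
make_residual_table <- function(X, bmi, dataset_id = "A") {
  df <- data.frame(dataset_id = dataset_id, bmi = bmi, X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("residual_table", "data.frame")
  df
}

# Gaussian linear-signal table: y = X beta + noise, residual-table layout.
sim_linear <- function(n, p, beta, noise_sd = 1, seed = 1, id = "A") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- item_names(p)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, noise_sd)
  make_residual_table(as.data.frame(X), y, id)
}

published_factor_summary <- function() {
  read.csv(system.file("extdata", "factor_summary_published.csv",
                       package = "traitmap"),
           stringsAsFactors = FALSE)
}
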