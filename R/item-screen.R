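#' Pairwise-complete Pearson correlation with significance
#'
#' Computes r on the rows where both vectors are observed; the two-sided
#' p-value comes from the t statistic `r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Records with fewer than `min_n` complete pairs,
#' or with zero variance on the complete pairs, are flagged invalid rather
#' than raising an error -- under 87\% planned missingness some pairs are tiny
#' and unstable.
#'
#' @param x,y Equal-length numeric vectors, possibly with missing values.
#' @param min_n Minimum complete-pair count for a valid record (default 30).
#' @param item_id Optional label carried into the record.
#' @return A one-row `data.frame` with columns `item_id`, `r`, `n`, `p`,
#'   `valid`.
#' @export
pairwise_correlation <- function(x, y, min_n = 30, item_id = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  obs <- !is.na(x) & !is.na(y)
  n <- sum(obs)
  r <- NA_real_
  p <- NA_real_
  valid <- FALSE
  if (n >= 3 && stats::sd(x[obs]) > 0 && stats::sd(y[obs]) > 0) {
    r <- stats::cor(x[obs], y[obs])
    p <- r_to_p(r, n)
    valid <- n >= min_n
  }
  data.frame(item_id = item_id, r = r, n = n, p = p, valid = valid,
             stringsAsFactors = FALSE)
}

r_to_p <- function(r, n) {
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[is.infinite(tt)] <- 0
  p
}

#' Item--outcome correlation records for a whole table
#'
#' Vectorized [pairwise_correlation()] of every item column against the
#' residualized outcome.
#'
#' @param residuals A `residual_table` (or data.frame of residualized items).
#' @param outcome Outcome column name, default `"bmi"`.
#' @param items Item columns; default all.
#' @param min_n Minimum complete pairs per item.
#' @return `data.frame` with one row per item: `item_id`, `r`, `n`, `p`,
#'   `valid`.
#' @export
item_outcome_correlations <- function(residuals, outcome = "bmi",
                                      items = item_names(residuals),
                                      min_n = 30) {
  X <- as.matrix(residuals[items])
  y <- as.numeric(residuals[[outcome]])
  ok_y <- !is.na(y)
  n <- as.integer(colSums(!is.na(X) & ok_y))
  r <- suppressWarnings(as.numeric(stats::cor(X, y, use = "pairwise.complete.obs")))
  p <- ifelse(n >= 3 & !is.na(r), r_to_p(r, n), NA_real_)
  data.frame(item_id = items, r = r, n = n, p = p,
             valid = n >= pmax(min_n, 3) & !is.na(r),
             stringsAsFactors = FALSE)
}

#' Power of the Pearson correlation test (Fisher z approximation)
#'
#' Two-sided power at significance level `alpha` for detecting a true
#' correlation `r` with `n` pairs:
#' `power = P(Z > z_{1-alpha/2} - atanh(|r|) sqrt(n-3)) +
#'          P(Z < -z_{1-alpha/2} - atanh(|r|) sqrt(n-3))`.
#' At `r = 0` this returns `alpha` exactly. Used to flag factor--outcome
#' correlations whose available sample gives power below a reporting
#' threshold (conventionally .80).
#'
#' @param r Assumed true correlation(s), `|r| < 1`.
#' @param n Sample size(s), `n >= 4`.
#' @param alpha Significance level, default .05.
#' @return Power value(s) in `[0, 1]`.
#' @export
correlation_power <- function(r, n, alpha = 0.05) {
  if (any(n < 4)) stop("n must be >= 4", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  delta <- atanh(abs(r)) * sqrt(n - 3)
  stats::pnorm(delta - za) + stats::pnorm(-delta - za)
}

#' Dual-dataset consistency selection
#'
#' Selects the items that correlate with the outcome at `p < alpha` *and* in
#' the same direction in both datasets -- the screening rule that guards
#' against capitalizing on chance when a lenient alpha is used on hundreds of
#' items. Items invalid in either dataset, or present in only one, are never
#' selected (the latter with a warning).
#'
#' @param records_a,records_b Records from [item_outcome_correlations()].
#' @param alpha Significance threshold, default .05.
#' @return An object of class `"selection_result"`: list with
#'   `selected_items`, `records` (merged per-dataset records with a
#'   `selected` flag), and `alpha`.
#' @export
select_consistent_items <- function(records_a, records_b, alpha = 0.05) {
  only <- union(setdiff(records_a$item_id, records_b$item_id),
                setdiff(records_b$item_id, records_a$item_id))
  if (length(only)) {
    warning(length(only), " item(s) present in only one dataset; excluded",
            call. = FALSE)
  }
  m <- merge(records_a, records_b, by = "item_id",
             suffixes = c("_a", "_b"), sort = TRUE)
  sel <- m$valid_a & m$valid_b &
    !is.na(m$p_a) & !is.na(m$p_b) & m$p_a < alpha & m$p_b < alpha &
    m$r_a != 0 & m$r_b != 0 & sign(m$r_a) == sign(m$r_b)
  m$selected <- sel
  structure(list(
    selected_items = m$item_id[sel],
    records = m,
    alpha = alpha
  ), class = "selection_result")
}

#' Write a correlation/selection report as CSV
#'
#' @param selection A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  utils::write.csv(selection$records, path, row.names = FALSE)
  invisible(path)
}
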