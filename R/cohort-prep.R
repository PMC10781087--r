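#' Apply participant exclusion filters
#'
#' Removes persons with missing BMI, age, sex, or continent, and persons with
#' implausible BMI: the exclusion rule is `bmi < bmi_min` OR `bmi >= bmi_max`
#' (so the kept interval is closed at the minimum and open at the maximum).
#' Counts removed per reason are attached as the `"exclusion_counts"`
#' attribute.
#'
#' @param table A `participant_table` (or any data.frame with `bmi`, `age`,
#'   `sex`, `continent` columns).
#' @param bmi_min,bmi_max Plausibility bounds in kg/m^2; defaults 14 and 75.
#' @return The filtered table, same class as the input.
#' @export
apply_exclusions <- function(table, bmi_min = 14, bmi_max = 75) {
  req <- c("bmi", "age", "sex", "continent")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("table lacks required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n0 <- nrow(table)
  covar_missing <- !stats::complete.cases(table[req])
  bmi_out <- !covar_missing & (table$bmi < bmi_min | table$bmi >= bmi_max)
  keep <- !covar_missing & !bmi_out
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- NULL
  attr(out, "exclusion_counts") <- c(
    input = n0,
    missing_covariates = sum(covar_missing),
    bmi_out_of_range = sum(bmi_out),
    retained = sum(keep)
  )
  out
}

#' Residualize items and BMI on demographic covariates
#'
#' Each variable (every item column plus BMI) is independently regressed by
#' ordinary least squares on an intercept, age, age^2, a sex indicator, and
#' continent indicators (reference = most frequent level), using that
#' variable's non-missing rows; the variable is replaced by its residuals.
#' The missingness pattern is untouched. This removes demographic confounding
#' before any correlation or prediction step.
#'
#' Variables with fewer non-missing rows than design columns are set to
#' all-missing with a warning.
#'
#' @param table A `participant_table` after [apply_exclusions()] (covariates
#'   must be complete).
#' @param items Item columns to residualize; default all `item_*` columns.
#' @param include_bmi Also residualize BMI (default `TRUE`).
#' @return A `residual_table`: same shape, item and `bmi` columns now hold
#'   residuals; covariates retained for audit. Fitted coefficients are in the
#'   `"coefficients"` attribute.
#' @export
residualize <- function(table, items = item_names(table), include_bmi = TRUE) {
  req <- c("age", "sex", "continent")
  if (!all(req %in% names(table))) {
    stop("table lacks covariate columns", call. = FALSE)
  }
  if (anyNA(table[req])) {
    stop("covariates must be complete; run apply_exclusions() first",
         call. = FALSE)
  }
  X <- covariate_design(table)
  vars <- c(items, if (include_bmi) "bmi")
  out <- table
  coefs <- vector("list", length(vars))
  names(coefs) <- vars
  for (v in vars) {
    y <- as.numeric(table[[v]])
    obs <- !is.na(y)
    if (sum(obs) < ncol(X)) {
      out[[v]] <- NA_real_
      coefs[[v]] <- NULL
      warning("variable '", v, "' has fewer observed rows than design columns; ",
              "set to all-missing", call. = FALSE)
      next
    }
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    r <- y
    r[obs] <- fit$residuals
    out[[v]] <- r
    coefs[[v]] <- fit$coefficients
  }
  class(out) <- c("residual_table", "data.frame")
  attr(out, "coefficients") <- coefs
  attr(out, "truth") <- attr(table, "truth")
  out
}

# Covariate design matrix: intercept, age, age^2, sex indicator, continent
# one-hot with the most frequent level as reference. Residuals are invariant
# to the coding, so the reference choice is cosmetic.
covariate_design <- function(table) {
  sex_levels <- sort(unique(as.character(table$sex)))
  cont <- as.character(table$continent)
  cont_ref <- names(sort(table(cont), decreasing = TRUE))[1]
  cont_levels <- setdiff(sort(unique(cont)), cont_ref)
  X <- cbind(
    `(Intercept)` = 1,
    age = table$age,
    age2 = table$age^2,
    if (length(sex_levels) > 1) {
      s <- outer(as.character(table$sex), sex_levels[-1], `==`) * 1
      colnames(s) <- paste0("sex_", sex_levels[-1])
      s
    },
    if (length(cont_levels)) {
      cc <- outer(cont, cont_levels, `==`) * 1
      colnames(cc) <- paste0("continent_", cont_levels)
      cc
    }
  )
  X
}

#' Pool datasets by row-binding
#'
#' Stacks participant (or residual) tables so residualization and
#' correlations can be computed on the combined sample. Item columns must
#' agree.
#'
#' @param tables List of tables.
#' @return One table of the same class as the first input.
#' @export
combine_tables <- function(tables) {
  cols <- lapply(tables, names)
  if (length(unique(vapply(cols, paste, "", collapse = "\r"))) != 1L) {
    stop("tables must share identical columns", call. = FALSE)
  }
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  class(out) <- class(tables[[1]])
  attr(out, "truth") <- NULL
  out
}
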