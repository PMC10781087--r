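#' Stratify a test sample into deciles of predicted outcome
#'
#' Ranks persons by predicted value (ties broken by stable input order),
#' partitions them into ten groups whose sizes differ by at most one, and
#' summarizes observed BMI (and weight, when available) per decile. The
#' top-minus-bottom gap quantifies how well the prediction separates the
#' highest- and lowest-risk tails.
#'
#' @param predicted Per-person predicted outcome.
#' @param observed_bmi Observed BMI, kg/m^2, aligned with `predicted`.
#' @param observed_weight Optional observed weight, kg.
#' @return A `data.frame` of class `"decile_summary"` with columns `decile`,
#'   `n`, `mean_predicted`, `mean_observed_bmi` (and `mean_observed_weight`),
#'   plus attributes `top_bottom_gap_bmi` and `top_bottom_gap_weight`.
#' @export
stratify_deciles <- function(predicted, observed_bmi, observed_weight = NULL) {
  n <- length(predicted)
  if (length(observed_bmi) != n ||
      (!is.null(observed_weight) && length(observed_weight) != n)) {
    stop("inputs must be aligned vectors", call. = FALSE)
  }
  if (n < 10) stop("need at least 10 persons", call. = FALSE)
  rk <- order(order(predicted, seq_len(n)))   # stable rank, ties by input order
  decile <- ceiling(10 * rk / n)
  agg <- function(x) tapply(x, decile, mean)
  out <- data.frame(
    decile = 1:10,
    n = as.integer(tabulate(decile, 10)),
    mean_predicted = as.numeric(agg(predicted)),
    mean_observed_bmi = as.numeric(agg(observed_bmi))
  )
  gap_bmi <- out$mean_observed_bmi[10] - out$mean_observed_bmi[1]
  gap_w <- NA_real_
  if (!is.null(observed_weight)) {
    out$mean_observed_weight <- as.numeric(agg(observed_weight))
    gap_w <- out$mean_observed_weight[10] - out$mean_observed_weight[1]
  }
  class(out) <- c("decile_summary", "data.frame")
  attr(out, "top_bottom_gap_bmi") <- gap_bmi
  attr(out, "top_bottom_gap_weight") <- gap_w
  out
}

#' Monotone-trend test across deciles
#'
#' Spearman correlation (with test) of decile index against the decile's mean
#' observed outcome -- a simple check that observed risk rises across
#' predicted deciles.
#'
#' @param summary A `decile_summary`.
#' @return List with `rho` and `p`.
#' @export
decile_trend_test <- function(summary) {
  ct <- suppressWarnings(
    stats::cor.test(summary$decile, summary$mean_observed_bmi,
                    method = "spearman", alternative = "greater"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Factor summary table (name, members, lead item, correlations, power)
#'
#' The reporting format for vetted factors: per factor its member count, lead
#' item, scoreable sample size, the scored factor's correlation with the
#' outcome, the lead item's correlation in the same subsample, and flags
#' marking entries whose statistical power at the available n falls below
#' `power_threshold` (conventionally .80).
#'
#' @param definitions List of `factor_definition`s (from [vet_factors()]).
#' @param residuals Combined-sample `residual_table` for scoring.
#' @param outcome Outcome column, default `"bmi"`.
#' @param alpha Significance level for the power calculation, default .05.
#' @param power_threshold Flag threshold, default .80.
#' @param min_score_items Scoring floor, default 3.
#' @return `data.frame`: `factor`, `n_items`, `lead_item`, `n`, `r_factor`,
#'   `r_lead`, `power_factor`, `power_lead`, `low_power_factor`,
#'   `low_power_lead`.
#' @export
factor_summary_table <- function(definitions, residuals, outcome = "bmi",
                                 alpha = 0.05, power_threshold = 0.80,
                                 min_score_items = 3) {
  rows <- lapply(definitions, function(d) {
    sc <- score_factor(residuals, d, min_score_items)
    y <- as.numeric(residuals[[outcome]])
    ok <- !is.na(sc) & !is.na(y)
    n <- sum(ok)
    r_f <- if (n >= 4) stats::cor(sc[ok], y[ok]) else NA_real_
    lead <- as.numeric(residuals[[d$lead_item]])
    ok_l <- ok & !is.na(lead)
    r_l <- if (sum(ok_l) >= 4) stats::cor(lead[ok_l], y[ok_l]) else NA_real_
    pw_f <- if (!is.na(r_f)) correlation_power(r_f, n, alpha) else NA_real_
    pw_l <- if (!is.na(r_l)) correlation_power(r_l, sum(ok_l), alpha) else NA_real_
    data.frame(factor = d$name, n_items = length(d$item_ids),
               lead_item = d$lead_item, n = n,
               r_factor = r_f, r_lead = r_l,
               power_factor = pw_f, power_lead = pw_l,
               low_power_factor = !is.na(pw_f) & pw_f < power_threshold,
               low_power_lead = !is.na(pw_l) & pw_l < power_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

md_table <- function(df, digits = 3) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col) && all(col == round(col), na.rm = TRUE)) {
      as.character(col)
    } else if (is.numeric(col)) {
      fmt_num(col, digits)
    } else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Assemble a human-readable pipeline report (Markdown + JSON twin)
#'
#' Collects whatever stage outputs are supplied -- exclusion counts, the
#' screening selection, the factor summary table, the replication report, the
#' winnow trace, per-set prediction accuracies, the decile table, and the
#' seeds used -- into one Markdown document with a machine-readable JSON
#' twin. Stages not supplied are marked absent rather than failing, so a
#' partial run still reports.
#'
#' @param stages Named list; recognized elements: `exclusions` (named counts),
#'   `selection` (`selection_result`), `factors` (data.frame from
#'   [factor_summary_table()]), `replication` (`replication_report`),
#'   `winnow` (`winnow_result` or list of them), `predictions` (named list of
#'   `prediction_result`s), `deciles` (`decile_summary`), `seeds` (named
#'   integers), `decisions` (character notes).
#' @param path Optional output stem; writes `<path>.md` and `<path>.json`.
#' @return List with `markdown` (character scalar) and `json` (list), invisibly
#'   when `path` is given.
#' @export
pipeline_report <- function(stages, path = NULL) {
  md <- c("# Pipeline report", "")
  js <- list()

  if (!is.null(stages$seeds)) {
    md <- c(md, "## Seeds", "",
            paste0("- ", names(stages$seeds), ": ", unlist(stages$seeds)), "")
    js$seeds <- as.list(stages$seeds)
  }

  md <- c(md, "## Exclusions", "")
  if (!is.null(stages$exclusions)) {
    ex <- stages$exclusions
    md <- c(md, paste0("- ", names(ex), ": ", unlist(ex)), "")
    js$exclusions <- as.list(ex)
  } else md <- c(md, "(not run)", "")

  md <- c(md, "## Item screening", "")
  if (!is.null(stages$selection)) {
    sel <- stages$selection
    md <- c(md, paste0("Selected ", length(sel$selected_items), " of ",
                       nrow(sel$records), " items at alpha = ", sel$alpha,
                       " (p < alpha and same sign in both datasets)."), "")
    js$selection <- list(alpha = sel$alpha,
                         n_candidates = nrow(sel$records),
                         selected_items = sel$selected_items)
  } else md <- c(md, "(not run)", "")

  md <- c(md, "## Factors", "")
  if (!is.null(stages$factors)) {
    ft <- stages$factors
    md <- c(md, md_table(ft), "",
            "Low-power flags mark correlations whose power at the available n is below .80.", "")
    js$factors <- ft
  } else md <- c(md, "(not run)", "")

  md <- c(md, "## Replication", "")
  if (!is.null(stages$replication)) {
    rp <- stages$replication
    md <- c(md,
            paste0("Matched factor pairs: ", nrow(rp$matched_pairs),
                   "; surviving items: ", nrow(rp$items),
                   "; dropped (different factors): ", length(rp$dropped_items),
                   "; volatile items (d^2 >= ", rp$volatile_d2, "): ",
                   sum(rp$items$volatile), "."),
            paste0("Cross-solution loading correlation: r = ",
                   fmt_num(rp$cross_solution_loading_r), "."), "")
    js$replication <- list(
      matched_pairs = rp$matched_pairs,
      n_items = nrow(rp$items),
      dropped_items = rp$dropped_items,
      volatile_items = rp$items$item_id[rp$items$volatile],
      cross_solution_loading_r = rp$cross_solution_loading_r)
  } else md <- c(md, "(not run)", "")

  md <- c(md, "## Winnowing", "")
  if (!is.null(stages$winnow)) {
    wl <- stages$winnow
    if (inherits(wl, "winnow_result")) wl <- list(wl)
    for (w in wl) {
      md <- c(md, paste0("- criterion ", format(w$criterion), ": ",
                         length(w$surviving_items), " surviving items, ",
                         nrow(w$removal_trace), " removals"))
    }
    md <- c(md, "")
    js$winnow <- lapply(wl, function(w) list(
      criterion = w$criterion, surviving_items = w$surviving_items,
      removal_trace = w$removal_trace))
  } else md <- c(md, "(not run)", "")

  md <- c(md, "## Prediction", "")
  if (!is.null(stages$predictions)) {
    pr <- stages$predictions
    df <- data.frame(
      set = names(pr),
      r = vapply(pr, function(p) p$r, 0),
      ci_lo = vapply(pr, function(p) p$ci95[1], 0),
      ci_hi = vapply(pr, function(p) p$ci95[2], 0),
      n_train = vapply(pr, function(p) p$n_train, 0),
      n_test = vapply(pr, function(p) p$n_test, 0),
      stringsAsFactors = FALSE)
    md <- c(md, md_table(df), "")
    js$predictions <- df
  } else md <- c(md, "(not run)", "")

  md <- c(md, "## Decile stratification", "")
  if (!is.null(stages$deciles)) {
    dc <- stages$deciles
    md <- c(md, md_table(as.data.frame(dc)), "",
            paste0("Top-minus-bottom decile gap: ",
                   fmt_num(attr(dc, "top_bottom_gap_bmi"), 2), " kg/m^2",
                   if (!is.na(attr(dc, "top_bottom_gap_weight")))
                     paste0(" / ", fmt_num(attr(dc, "top_bottom_gap_weight"), 2),
                            " kg") else "", "."), "")
    js$deciles <- list(table = as.data.frame(dc),
                       top_bottom_gap_bmi = attr(dc, "top_bottom_gap_bmi"),
                       top_bottom_gap_weight = attr(dc, "top_bottom_gap_weight"))
  } else md <- c(md, "(not run)", "")

  if (!is.null(stages$decisions)) {
    md <- c(md, "## Decisions", "", paste0("- ", stages$decisions), "")
    js$decisions <- stages$decisions
  }

  out <- list(markdown = paste(md, collapse = "\n"), json = js)
  if (!is.null(path)) {
    writeLines(out$markdown, paste0(path, ".md"))
    jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    return(invisible(out))
  }
  out
}
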