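#' Greedy item winnowing by inter-item correlation
#'
#' Iteratively finds the remaining item pair with the largest absolute
#' inter-item correlation; while that exceeds `criterion`, the pair member
#' with the smaller absolute outcome correlation is removed. Correlations
#' among remaining items are never recomputed -- removing an item does not
#' alter the others' pairwise correlations. Ties on pair magnitude are broken
#' by lexicographic item-id pair order; ties on outcome relevance by removing
#' the lexicographically later item. The full removal trace is recorded so
#' the surviving set can be replayed and audited.
#'
#' @param item_corr A `corr_matrix` (or plain symmetric correlation matrix
#'   with dimnames) over the candidate items.
#' @param outcome_r Named numeric vector of item--outcome correlations
#'   covering every item in the matrix.
#' @param criterion Upper bound on surviving absolute inter-item
#'   correlations.
#' @return An object of class `"winnow_result"`: list with `criterion`,
#'   `surviving_items`, `removal_trace` (data.frame: removed_item,
#'   paired_with, abs_r).
#' @export
winnow <- function(item_corr, outcome_r, criterion) {
  R <- if (inherits(item_corr, "corr_matrix")) item_corr$r_matrix else item_corr
  ids <- colnames(R)
  if (is.null(ids)) stop("correlation matrix needs item names", call. = FALSE)
  if (!all(ids %in% names(outcome_r))) {
    stop("outcome_r missing for item(s): ",
         paste(setdiff(ids, names(outcome_r)), collapse = ", "), call. = FALSE)
  }
  ord <- order(ids)                      # lexicographic layout fixes tie order
  R <- abs(R[ord, ord, drop = FALSE])
  ids <- ids[ord]
  orel <- abs(outcome_r[ids])
  m <- length(ids)
  A <- R
  A[lower.tri(A, diag = TRUE)] <- -Inf
  alive <- rep(TRUE, m)
  trace <- list()
  repeat {
    mx <- max(A)
    if (!is.finite(mx) || mx <= criterion) break
    cand <- which(A == mx, arr.ind = TRUE)
    # first pair in (row, col) = lexicographic (first id, second id) order
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    drop_idx <- if (orel[i] < orel[j]) i
                else if (orel[j] < orel[i]) j
                else max(i, j)           # |outcome r| tie: later id goes
    keep_idx <- if (drop_idx == i) j else i
    trace[[length(trace) + 1L]] <- data.frame(
      removed_item = ids[drop_idx], paired_with = ids[keep_idx],
      abs_r = mx, stringsAsFactors = FALSE)
    alive[drop_idx] <- FALSE
    A[drop_idx, ] <- -Inf
    A[, drop_idx] <- -Inf
  }
  structure(list(
    criterion = criterion,
    surviving_items = ids[alive],
    removal_trace = if (length(trace)) do.call(rbind, trace)
                    else data.frame(removed_item = character(0),
                                    paired_with = character(0),
                                    abs_r = numeric(0))
  ), class = "winnow_result")
}

#' Winnow over a grid of criteria
#'
#' One [winnow()] per criterion. Because a stricter criterion simply
#' continues the same removal sequence further, surviving set sizes are
#' non-decreasing in the criterion.
#'
#' @inheritParams winnow
#' @param criteria Numeric vector of criteria.
#' @return List of `winnow_result`s, named by criterion.
#' @export
winnow_grid <- function(item_corr, outcome_r, criteria) {
  out <- lapply(criteria, function(cr) winnow(item_corr, outcome_r, cr))
  names(out) <- format(criteria, trim = TRUE)
  out
}

#' Write a winnow result as a scoring key + trace CSV
#'
#' @param result A `winnow_result`.
#' @param key_path YAML path for the surviving set (scoring-key format,
#'   unit keys).
#' @param trace_path Optional CSV path for the removal trace.
#' @return `key_path`, invisibly.
#' @export
write_winnow_result <- function(result, key_path, trace_path = NULL) {
  def <- structure(list(
    name = paste0("winnow_", format(result$criterion)),
    item_ids = result$surviving_items,
    keys = stats::setNames(rep(1, length(result$surviving_items)),
                           result$surviving_items),
    lead_item = NA_character_,
    factor_outcome_r = NA_real_, n_scoreable = NA_integer_
  ), class = "factor_definition")
  write_scoring_key(list(def), key_path)
  if (!is.null(trace_path)) {
    utils::write.csv(result$removal_trace, trace_path, row.names = FALSE)
  }
  invisible(key_path)
}
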