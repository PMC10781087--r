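#' Pairwise-complete correlation matrix with PSD repair
#'
#' Builds the item correlation matrix under pairwise deletion, which under
#' heavy planned missingness is frequently indefinite. If the smallest
#' eigenvalue is below `-1e-8`, the matrix is repaired by clipping negative
#' eigenvalues at zero, reconstructing, and rescaling to unit diagonal; the
#' `psd_repaired` field records that the repair ran.
#'
#' @param residuals A `residual_table` (or data.frame of residualized items).
#' @param items Item columns to include.
#' @param min_pair_n Minimum complete pairs per item pair; any pair below it
#'   raises an error listing the offending pairs.
#' @return An object of class `"corr_matrix"`: list with `item_ids`,
#'   `r_matrix`, `n_matrix`, `psd_repaired`.
#' @export
build_corr_matrix <- function(residuals, items = item_names(residuals),
                              min_pair_n = 10) {
  X <- as.matrix(residuals[items])
  obs <- !is.na(X)
  n_matrix <- crossprod(obs)
  off <- n_matrix[upper.tri(n_matrix)]
  if (any(off < min_pair_n)) {
    idx <- which(upper.tri(n_matrix) & n_matrix < min_pair_n, arr.ind = TRUE)
    bad <- paste0(items[idx[, 1]], "--", items[idx[, 2]],
                  " (n=", n_matrix[idx], ")")
    stop("item pairs below min_pair_n: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  if (anyNA(R)) {
    stop("correlation undefined for some pairs (zero variance)", call. = FALSE)
  }
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    # floor slightly above zero so the repaired matrix stays invertible for
    # downstream ML factoring
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    repaired <- TRUE
  }
  dimnames(R) <- list(items, items)
  structure(list(item_ids = items, r_matrix = R, n_matrix = n_matrix,
                 psd_repaired = repaired),
            class = "corr_matrix")
}

#' Parallel analysis on a pairwise-complete correlation matrix
#'
#' Chooses the number of factors by comparing the observed eigenvalues with
#' eigenvalues from null datasets formed by independently permuting each
#' item's observed values within the dataset (each item's missingness pattern
#' is preserved), each null dataset reduced to a pairwise correlation matrix
#' and repaired identically to the observed one. The retained count `k` is
#' the length of the initial run of observed eigenvalues exceeding the null
#' reference at the same rank.
#'
#' @param corr A `corr_matrix` built from `observed_table`'s item columns.
#' @param observed_table The `residual_table` the matrix was built from.
#' @param n_replicates Number of permutation replicates (>= 20).
#' @param seed Integer seed for the permutations.
#' @param quantile `"mean"` (Horn's original: null reference is the mean
#'   eigenvalue per rank) or `"p95"` (95th percentile per rank, stricter
#'   under pure noise).
#' @return Integer `k`, with attributes `eigenvalues` (observed) and
#'   `null_reference`.
#' @export
parallel_analysis <- function(corr, observed_table, n_replicates = 50,
                              seed = 1L, quantile = c("mean", "p95")) {
  quantile <- match.arg(quantile)
  if (n_replicates < 20) stop("n_replicates must be >= 20", call. = FALSE)
  X <- as.matrix(observed_table[corr$item_ids])
  obs_eig <- eigen(corr$r_matrix, symmetric = TRUE, only.values = TRUE)$values
  m <- ncol(X)
  set.seed(seed)
  null_eig <- matrix(NA_real_, n_replicates, m)
  for (b in seq_len(n_replicates)) {
    Xb <- X
    for (j in seq_len(m)) {
      oj <- which(!is.na(X[, j]))
      Xb[oj, j] <- X[oj[sample.int(length(oj))], j]
    }
    Rb <- suppressWarnings(stats::cor(Xb, use = "pairwise.complete.obs"))
    evb <- eigen(Rb, symmetric = TRUE)
    if (min(evb$values) < -1e-8) {
      vals <- pmax(evb$values, 0)
      Rb <- evb$vectors %*% (vals * t(evb$vectors))
      d <- sqrt(diag(Rb))
      Rb <- Rb / tcrossprod(d)
      null_eig[b, ] <- eigen(Rb, symmetric = TRUE, only.values = TRUE)$values
    } else {
      null_eig[b, ] <- evb$values
    }
  }
  ref <- if (quantile == "mean") {
    colMeans(null_eig)
  } else {
    apply(null_eig, 2, stats::quantile, probs = 0.95, names = FALSE)
  }
  exceed <- obs_eig > ref
  k <- if (exceed[1]) {
    rle(exceed)$lengths[1]
  } else 0L
  structure(as.integer(k), eigenvalues = obs_eig, null_reference = ref)
}

#' Maximum-likelihood factor extraction
#'
#' Unrotated ML factoring of a (repaired) correlation matrix via
#' [stats::factanal()], with uniquenesses bounded below at 0.005 as a guard
#' against Heywood cases. The effective sample size for the fit statistic is
#' the harmonic mean of the off-diagonal pairwise counts -- a conservative
#' summary when every pair has its own n.
#'
#' @param corr A `corr_matrix`.
#' @param k Number of factors, `1 <= k < n_items`.
#' @return List with `loadings` (items x k matrix), `uniquenesses`,
#'   `n_effective`, `converged`.
#' @export
extract_ml_factors <- function(corr, k) {
  m <- length(corr$item_ids)
  if (k < 1 || k >= m) stop("k must satisfy 1 <= k < n_items", call. = FALSE)
  off <- corr$n_matrix[upper.tri(corr$n_matrix)]
  n_eff <- max(4, round(1 / mean(1 / pmax(off, 1))))
  fit <- tryCatch(
    stats::factanal(covmat = corr$r_matrix, factors = k, rotation = "none",
                    n.obs = n_eff,
                    control = list(nstart = 1, lower = 0.005,
                                   opt = list(maxit = 1000))),
    error = function(e) stop("ML factor extraction failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  L <- unclass(fit$loadings)
  attr(L, "dimnames") <- list(corr$item_ids, paste0("F", seq_len(k)))
  list(loadings = L, uniquenesses = fit$uniquenesses, n_effective = n_eff,
       converged = fit$converged %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quartimin criterion (direct oblimin with gamma = 0): value and gradient
vgq_oblimin <- function(L, gam = 0) {
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L^2 %*% N
  if (gam != 0) {
    p <- nrow(L)
    X <- (diag(p) - matrix(gam / p, p, p)) %*% X
  }
  list(f = sum(L^2 * X) / 4, Gq = L * X)
}

#' Direct oblimin rotation by gradient projection
#'
#' Rotates an unrotated loading matrix to a direct-oblimin (`gamma = 0`,
#' quartimin) criterion using the Bernaards--Jennrich gradient-projection
#' algorithm for oblique rotation. Columns are sign-aligned afterwards so
#' each factor's largest-magnitude item loads positively. With a single
#' factor the rotation is the identity.
#'
#' @param loadings Unrotated items x k loading matrix (or the list returned
#'   by [extract_ml_factors()]).
#' @param gamma Oblimin family parameter, default 0.
#' @param eps Convergence tolerance on the projected gradient norm.
#' @param maxit Maximum iterations.
#' @param dataset_id Optional label stored on the solution.
#' @return An object of class `"factor_solution"`: list with `loadings`,
#'   `Phi` (factor correlations), `uniquenesses` (when supplied),
#'   `n_factors`, `dataset_id`, `converged`.
#' @export
rotate_oblimin <- function(loadings, gamma = 0, eps = 1e-6, maxit = 1000,
                           dataset_id = NA_character_) {
  uniq <- NULL
  if (is.list(loadings) && !is.null(loadings$loadings)) {
    uniq <- loadings$uniquenesses
    loadings <- loadings$loadings
  }
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k == 1) {
    sol <- list(loadings = A, Phi = matrix(1, 1, 1), converged = TRUE)
  } else {
    sol <- gpf_oblique(A, function(L) vgq_oblimin(L, gamma), eps, maxit)
    if (!sol$converged) stop("oblimin rotation did not converge", call. = FALSE)
  }
  L <- sol$loadings
  Phi <- sol$Phi
  # sign-align: the largest-|loading| item of each factor loads positively
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
    }
  }
  dimnames(L) <- dimnames(A)
  dimnames(Phi) <- list(colnames(A), colnames(A))
  structure(list(loadings = L, Phi = Phi, uniquenesses = uniq,
                 n_factors = k, dataset_id = dataset_id,
                 converged = sol$converged),
            class = "factor_solution")
}

# Gradient-projection algorithm for oblique rotation (Bernaards & Jennrich).
# A: unrotated loadings; vgq: criterion returning list(f, Gq).
gpf_oblique <- function(A, vgq, eps = 1e-6, maxit = 1000) {
  k <- ncol(A)
  Tmat <- diag(k)
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- vgq(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:10) {
      X <- Tmat - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v, k)
      L <- A %*% t(solve(Tt))
      vgt <- vgq(L)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  list(loadings = L, Phi = crossprod(Tmat), converged = s < eps)
}

#' Run one EFA: ML extraction + oblimin rotation
#'
#' @param corr A `corr_matrix`.
#' @param k Number of factors.
#' @param dataset_id Label stored on the solution.
#' @inheritParams rotate_oblimin
#' @return A `factor_solution`.
#' @export
efa <- function(corr, k, dataset_id = NA_character_, gamma = 0) {
  ext <- extract_ml_factors(corr, k)
  sol <- rotate_oblimin(ext, gamma = gamma, dataset_id = dataset_id)
  sol$n_effective <- ext$n_effective
  sol$eigenvalues <- eigen(corr$r_matrix, symmetric = TRUE,
                           only.values = TRUE)$values
  sol
}

#' Assign items to factors by primary loading
#'
#' Each item goes to the factor carrying its largest-magnitude loading; items
#' whose largest magnitude falls below `threshold` stay unassigned. Exact
#' magnitude ties go to the lower-index factor and are logged in the
#' `"ties"` attribute.
#'
#' @param solution A `factor_solution`.
#' @param threshold Minimum absolute primary loading, default .30.
#' @return Named integer vector (item -> factor index, `NA` = unassigned)
#'   with attribute `ties`.
#' @export
assign_items <- function(solution, threshold = 0.30) {
  L <- abs(solution$loadings)
  prim <- apply(L, 1, which.max)          # first max = lower-index tie-break
  mx <- L[cbind(seq_len(nrow(L)), prim)]
  ties <- rownames(L)[apply(L, 1, function(z) sum(z == max(z)) > 1)]
  out <- ifelse(mx >= threshold, prim, NA_integer_)
  names(out) <- rownames(solution$loadings)
  attr(out, "ties") <- ties
  out
}

#' Tucker congruence coefficient
#'
#' Cosine similarity `sum(a*b) / sqrt(sum(a^2) sum(b^2))` between two loading
#' vectors; the standard measure for matching factors across samples.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Congruence in `[-1, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match factors across two solutions and audit replication
#'
#' Pairs factors across solutions by maximal absolute Tucker congruence with
#' one-to-one greedy assignment (largest congruence first); pairs below
#' `min_congruence` stay unmatched. Items must be assigned (primary loading
#' `>= threshold`) to the *same* matched pair in both solutions to survive;
#' all other assigned items are dropped. For survivors the per-item squared
#' loading difference `d2 = (loading_A - loading_B)^2` on the matched factor
#' is computed (with B's column sign-flipped when the matching congruence is
#' negative); items with `d2 >= .04` are flagged volatile. The Pearson
#' correlation of survivors' matched loadings summarizes cross-sample
#' loading similarity.
#'
#' @param sol_a,sol_b `factor_solution`s over the same item universe.
#' @param threshold Assignment threshold passed to [assign_items()].
#' @param min_congruence Minimum |congruence| to accept a pair (default .70).
#' @param volatile_d2 Volatility flag threshold on d2 (default .04,
#'   inclusive).
#' @return An object of class `"replication_report"`: list with
#'   `matched_pairs` (data.frame: factor_a, factor_b, congruence),
#'   `items` (data.frame: item_id, factor_a, factor_b, loading_a, loading_b,
#'   d2, volatile), `dropped_items`, `unmatched_a`, `unmatched_b`,
#'   `cross_solution_loading_r`.
#' @export
match_factors <- function(sol_a, sol_b, threshold = 0.30,
                          min_congruence = 0.70, volatile_d2 = 0.04) {
  if (!identical(rownames(sol_a$loadings), rownames(sol_b$loadings))) {
    stop("solutions must cover the same items in the same order", call. = FALSE)
  }
  La <- sol_a$loadings
  Lb <- sol_b$loadings
  ka <- ncol(La)
  kb <- ncol(Lb)
  C <- matrix(NA_real_, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    C[i, j] <- tucker_congruence(La[, i], Lb[, j])
  }
  # greedy one-to-one: repeatedly take the largest remaining |congruence|
  pairs <- data.frame(factor_a = integer(0), factor_b = integer(0),
                      congruence = numeric(0))
  Cw <- abs(C)
  while (any(is.finite(Cw)) && max(Cw, na.rm = TRUE) >= min_congruence) {
    ij <- which(Cw == max(Cw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(factor_a = ij[1], factor_b = ij[2],
                                     congruence = C[ij[1], ij[2]]))
    Cw[ij[1], ] <- -Inf
    Cw[, ij[2]] <- -Inf
  }
  rownames(pairs) <- NULL
  asg_a <- assign_items(sol_a, threshold)
  asg_b <- assign_items(sol_b, threshold)
  map_ab <- rep(NA_integer_, ka)
  if (nrow(pairs)) map_ab[pairs$factor_a] <- pairs$factor_b
  ids <- rownames(La)
  keep <- !is.na(asg_a) & !is.na(asg_b) &
    !is.na(map_ab[asg_a]) & map_ab[pmax(asg_a, 1)] == asg_b
  keep[is.na(keep)] <- FALSE
  dropped <- ids[(!is.na(asg_a) | !is.na(asg_b)) & !keep]
  items <- data.frame(item_id = ids[keep],
                      factor_a = asg_a[keep],
                      factor_b = asg_b[keep],
                      stringsAsFactors = FALSE)
  if (nrow(items)) {
    sgn <- sign(pairs$congruence)[match(items$factor_a, pairs$factor_a)]
    items$loading_a <- La[cbind(match(items$item_id, ids), items$factor_a)]
    items$loading_b <- sgn * Lb[cbind(match(items$item_id, ids), items$factor_b)]
    items$d2 <- (items$loading_a - items$loading_b)^2
    items$volatile <- items$d2 >= volatile_d2
  } else {
    items$loading_a <- items$loading_b <- items$d2 <- numeric(0)
    items$volatile <- logical(0)
  }
  rownames(items) <- NULL
  r_load <- if (nrow(items) >= 3) stats::cor(items$loading_a, items$loading_b)
            else NA_real_
  structure(list(
    matched_pairs = pairs,
    items = items,
    dropped_items = dropped,
    unmatched_a = setdiff(seq_len(ka), pairs$factor_a),
    unmatched_b = setdiff(seq_len(kb), pairs$factor_b),
    cross_solution_loading_r = r_load,
    volatile_d2 = volatile_d2
  ), class = "replication_report")
}

#' Vet matched factors into final scoreable definitions
#'
#' Applies, in order: (1) unmatched factors are already gone (only matched
#' pairs enter); (2) factors with fewer than `min_items` members are dropped;
#' (3) a factor whose members' item--outcome correlations have mixed signs is
#' split into two sign-homogeneous factors, each re-checked against the
#' member floor; (4) factors whose scored-factor correlation with the outcome
#' falls below `negligible_r` in magnitude are dropped; (5) factors named in
#' `exclude` are dropped -- interpretability is a human judgement, so this
#' hook is configuration, never automatic.
#'
#' @param report A `replication_report` from [match_factors()].
#' @param solution The `factor_solution` whose loadings define member keys
#'   (sign of the loading on the matched factor; typically solution A).
#' @param residuals `residual_table` used to score factors (combined sample).
#' @param outcome Outcome column, default `"bmi"`.
#' @param min_items Member floor, default 3.
#' @param negligible_r Drop threshold on the scored factor's |r| with the
#'   outcome, default .02.
#' @param exclude Character vector of factor names to drop by hand.
#' @param min_score_items Minimum observed member items for a person to get a
#'   score, default 3.
#' @return List of `factor_definition` objects: each has `name`, `item_ids`,
#'   `keys` (+1/-1 per member), `lead_item`, `factor_outcome_r`,
#'   `n_scoreable`.
#' @export
vet_factors <- function(report, solution, residuals, outcome = "bmi",
                        min_items = 3, negligible_r = 0.02,
                        exclude = character(0), min_score_items = 3) {
  items <- report$items
  if (!nrow(items)) return(list())
  rec <- item_outcome_correlations(residuals, outcome = outcome,
                                   items = items$item_id, min_n = 3)
  item_r <- stats::setNames(rec$r, rec$item_id)
  defs <- list()
  for (fa in sort(unique(items$factor_a))) {
    member <- items$item_id[items$factor_a == fa]
    if (length(member) < min_items) next
    rs <- item_r[member]
    groups <- if (all(rs >= 0, na.rm = TRUE) || all(rs <= 0, na.rm = TRUE)) {
      list(member)
    } else {
      # mixed outcome signs: split into sign-homogeneous halves
      list(member[rs > 0], member[rs < 0])
    }
    suffixes <- if (length(groups) == 1) "" else c("_pos", "_neg")
    for (g in seq_along(groups)) {
      mem <- groups[[g]]
      if (length(mem) < min_items) next
      name <- paste0("F", fa, suffixes[g])
      keys <- sign(solution$loadings[mem, fa])
      keys[keys == 0] <- 1
      def <- structure(list(name = name, item_ids = mem,
                            keys = stats::setNames(keys, mem),
                            lead_item = mem[which.max(abs(item_r[mem]))],
                            factor_outcome_r = NA_real_,
                            n_scoreable = NA_integer_),
                       class = "factor_definition")
      sc <- score_factor(residuals, def, min_score_items)
      ok <- !is.na(sc) & !is.na(residuals[[outcome]])
      def$n_scoreable <- sum(!is.na(sc))
      def$factor_outcome_r <- if (sum(ok) >= 3) {
        stats::cor(sc[ok], residuals[[outcome]][ok])
      } else NA_real_
      if (!is.na(def$factor_outcome_r) &&
          abs(def$factor_outcome_r) < negligible_r) next
      if (name %in% exclude) next
      defs[[name]] <- def
    }
  }
  defs
}

#' Score a factor for every person
#'
#' Mean of the person's available member items after reversing
#' negatively-keyed members; persons with fewer than `min_score_items`
#' observed members get a missing score.
#'
#' @param residuals `residual_table`.
#' @param definition A `factor_definition` (needs `item_ids` and `keys`).
#' @param min_score_items Minimum observed members, default 3.
#' @return Numeric vector of per-person scores (NA where unscoreable).
#' @export
score_factor <- function(residuals, definition, min_score_items = 3) {
  X <- as.matrix(residuals[definition$item_ids])
  keys <- definition$keys[definition$item_ids]
  X <- sweep(X, 2, keys, `*`)
  n_obs <- rowSums(!is.na(X))
  sc <- rowMeans(X, na.rm = TRUE)
  sc[n_obs < min_score_items] <- NA_real_
  sc
}

#' Write / read factor definitions as a YAML scoring key
#'
#' The same key format ingests external inventory definitions (domains,
#' facets) for prediction comparisons: a list of entries with `name`,
#' `items`, `keys`, `lead_item`.
#'
#' @param definitions List of `factor_definition`s.
#' @param path YAML path.
#' @return `path` invisibly; `read_scoring_key()` returns the definitions.
#' @export
write_scoring_key <- function(definitions, path) {
  yaml::write_yaml(lapply(definitions, function(d) list(
    name = d$name,
    items = as.character(d$item_ids),
    keys = as.integer(d$keys),
    lead_item = d$lead_item
  )), path)
  invisible(path)
}

#' @rdname write_scoring_key
#' @export
read_scoring_key <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(d) {
    structure(list(name = d$name, item_ids = d$items,
                   keys = stats::setNames(as.numeric(d$keys), d$items),
                   lead_item = d$lead_item %||% NA_character_,
                   factor_outcome_r = NA_real_, n_scoreable = NA_integer_),
              class = "factor_definition")
  })
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}
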