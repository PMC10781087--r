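# small planted-structure dataset reused across tests
planted_data <- function(n = 6000, k = 3, per = 8, loading = 0.6,
                         missing = 0.4, seed = 77, weights = rep(1.2, k)) {
  m <- per * k
  lam <- matrix(0, m, k)
  for (j in seq_len(k)) lam[(j - 1) * per + seq_len(per), j] <- loading
  sp <- synthetic_spec(n, m, k, lam, outcome_weights = weights,
                       missing_rate = missing, seed = seed)
  generate_dataset(sp)
}

test_that("complete-data pairwise matrix equals the full-case matrix", {
  tab <- residualize(planted_data(n = 800, missing = 0, seed = 5))
  cm <- build_corr_matrix(tab)
  X <- as.matrix(tab[item_names(tab)])
  expect_equal(cm$r_matrix, cor(X), tolerance = 1e-12)
  expect_false(cm$psd_repaired)
  expect_true(all(cm$n_matrix == nrow(tab)))
  # permuting item order permutes rows/columns identically
  ids <- rev(cm$item_ids)
  cm2 <- build_corr_matrix(tab, items = ids)
  expect_equal(cm2$r_matrix, cm$r_matrix[ids, ids], tolerance = 1e-12)
})

test_that("indefinite pairwise matrices are repaired to PSD with unit diagonal", {
  # plant a non-PSD pattern: each pair is observed on its own row segment,
  # giving r12 ~ r13 ~ +.9 but r23 ~ -.9, which no PSD matrix allows
  set.seed(11)
  seg <- function() {
    u <- rnorm(80)
    cbind(u, 0.9 * u + rnorm(80, 0, sqrt(1 - 0.81)))
  }
  s1 <- seg(); s2 <- seg(); s3 <- seg()
  X <- matrix(NA_real_, 240, 3)
  X[1:80, c(1, 2)] <- s1
  X[81:160, c(1, 3)] <- s2
  X[161:240, c(2, 3)] <- s3 %*% diag(c(1, -1))
  colnames(X) <- item_names(3)
  tab <- make_residual_table(as.data.frame(X), bmi = rnorm(240))
  cm <- build_corr_matrix(tab, min_pair_n = 5)
  ev <- eigen(cm$r_matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(unname(diag(cm$r_matrix)), rep(1, 3), tolerance = 1e-12)
  expect_true(cm$psd_repaired)
})

test_that("pairs with too few complete observations raise a listing error", {
  tab <- make_residual_table(
    data.frame(item_001 = c(rnorm(5), rep(NA, 20)),
               item_002 = c(rep(NA, 20), rnorm(5)),
               item_003 = rnorm(25)),
    bmi = rnorm(25))
  expect_error(build_corr_matrix(tab, min_pair_n = 3), "item_001--item_002")
})

test_that("parallel analysis recovers the planted factor count", {
  hits <- 0L
  for (s in 1:5) {
    tab <- residualize(planted_data(n = 4000, k = 3, per = 10,
                                    missing = 0.5, seed = 300 + s))
    cm <- build_corr_matrix(tab)
    k <- parallel_analysis(cm, tab, n_replicates = 20, seed = s)
    hits <- hits + (k == 3L)
  }
  expect_gte(hits, 4L)
})

test_that("parallel analysis stays at zero on pure noise (p95 reference)", {
  hits <- 0L
  for (s in 1:5) {
    m <- 30
    sp <- synthetic_spec(2000, m, 1, loading_matrix = matrix(0, m, 1),
                         outcome_weights = 0, missing_rate = 0.4,
                         seed = 400 + s)
    tab <- residualize(generate_dataset(sp))
    cm <- build_corr_matrix(tab)
    k <- parallel_analysis(cm, tab, n_replicates = 20, seed = s,
                           quantile = "p95")
    hits <- hits + (k == 0L)
  }
  expect_gte(hits, 4L)
})

test_that("ML extraction recovers an exact one-factor structure", {
  lam <- rep(0.7, 8)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(R) <- list(item_names(8), item_names(8))
  cm <- structure(list(item_ids = item_names(8), r_matrix = R,
                       n_matrix = matrix(1000, 8, 8), psd_repaired = FALSE),
                  class = "corr_matrix")
  ext <- extract_ml_factors(cm, 1)
  L <- ext$loadings * sign(ext$loadings[1])
  expect_equal(as.numeric(L), lam, tolerance = 1e-4)
  expect_equal(unname(ext$uniquenesses), rep(1 - 0.49, 8), tolerance = 1e-3)
  expect_error(extract_ml_factors(cm, 0), "k must")
  expect_error(extract_ml_factors(cm, 8), "k must")
})

test_that("oblimin rotation recovers planted simple structure obliquely", {
  tab <- residualize(planted_data(n = 8000, k = 3, per = 8, loading = 0.65,
                                  missing = 0.3, seed = 55))
  cm <- build_corr_matrix(tab)
  sol <- efa(cm, 3)
  lam_true <- dataset_truth(planted_data(n = 8000, k = 3, per = 8,
                                         loading = 0.65, missing = 0.3,
                                         seed = 55))$loading_matrix
  # match each planted factor to its closest rotated column
  cong <- sapply(1:3, function(jt)
    max(abs(sapply(1:3, function(jr)
      tucker_congruence(lam_true[, jt], sol$loadings[, jr])))))
  expect_gte(mean(cong), 0.98)
  # Phi symmetric with unit diagonal
  expect_equal(unname(diag(sol$Phi)), rep(1, 3), tolerance = 1e-8)
  expect_equal(sol$Phi, t(sol$Phi), tolerance = 1e-10)
})

test_that("rotation preserves communalities and is identity for k = 1", {
  tab <- residualize(planted_data(n = 3000, k = 2, per = 6, seed = 66,
                                  weights = c(1, 1)))
  cm <- build_corr_matrix(tab)
  ext <- extract_ml_factors(cm, 2)
  sol <- rotate_oblimin(ext)
  h_unrot <- rowSums(ext$loadings^2)
  h_rot <- diag(sol$loadings %*% sol$Phi %*% t(sol$loadings))
  expect_equal(unname(h_rot), unname(h_unrot), tolerance = 1e-6)

  ext1 <- extract_ml_factors(cm, 1)
  sol1 <- rotate_oblimin(ext1)
  expect_equal(sol1$Phi, matrix(1, 1, 1, dimnames = list("F1", "F1")))
  expect_equal(abs(sol1$loadings), abs(ext1$loadings), tolerance = 1e-12)
  # sign alignment: the largest-|loading| item loads positively
  expect_true(all(apply(sol$loadings, 2,
                        function(z) z[which.max(abs(z))] > 0)))
})

test_that("items go to their primary loading's factor; ties break low", {
  L <- rbind(item_a = c(0.5, 0.2), item_b = c(0.25, -0.28),
             item_c = c(0.40, -0.40), item_d = c(-0.6, 0.1))
  sol <- structure(list(loadings = L, Phi = diag(2), n_factors = 2),
                   class = "factor_solution")
  asg <- assign_items(sol, threshold = 0.30)
  expect_equal(unname(asg[c("item_a", "item_d")]), c(1L, 1L))
  expect_true(is.na(asg["item_b"]))
  expect_equal(unname(asg["item_c"]), 1L)        # exact |.40| tie -> factor 1
  expect_equal(attr(asg, "ties"), "item_c")
})

test_that("self-match is perfect and d2 = .04 is flagged inclusively", {
  tab <- residualize(planted_data(n = 3000, k = 2, per = 6, seed = 44,
                                  weights = c(1, 1)))
  sol <- efa(build_corr_matrix(tab), 2, dataset_id = "A")
  rep0 <- match_factors(sol, sol)
  expect_equal(nrow(rep0$matched_pairs), 2)
  expect_true(all(rep0$items$d2 == 0))
  expect_false(any(rep0$items$volatile))
  expect_equal(rep0$cross_solution_loading_r, 1, tolerance = 1e-12)

  # boundary is inclusive: exact-arithmetic check at a representable
  # threshold (loadings .5 vs .25 -> d2 = 0.0625 exactly)
  solA <- sol; solB <- sol
  i <- which(abs(sol$loadings[, 1]) >= 0.3)[1]
  solA$loadings[i, 1] <- 0.5
  solB$loadings[i, 1] <- 0.25
  repb <- match_factors(solA, solB, threshold = 0.2, volatile_d2 = 0.0625)
  row <- repb$items[repb$items$item_id == rownames(sol$loadings)[i], ]
  expect_identical(row$d2, 0.0625)
  expect_true(row$volatile)
  # just below the boundary is not flagged
  repc <- match_factors(solA, solB, threshold = 0.2, volatile_d2 = 0.0625000001)
  rowc <- repc$items[repc$items$item_id == rownames(sol$loadings)[i], ]
  expect_false(rowc$volatile)
})

test_that("replicated planted factors match across independent samples", {
  lam <- simple_loadings(24, 3, c(0.55, 0.75), seed = 10)
  spA <- synthetic_spec(8000, 24, 3, lam, outcome_weights = c(1.5, -1, 1),
                        missing_rate = 0.4, seed = 501)
  spB <- spA; spB$seed <- 502L
  tr <- generate_triple(spA, spB)
  ra <- residualize(apply_exclusions(tr$A))
  rb <- residualize(apply_exclusions(tr$B))
  solA <- efa(build_corr_matrix(ra), 3, "A")
  solB <- efa(build_corr_matrix(rb), 3, "B")
  rp <- match_factors(solA, solB)
  expect_equal(nrow(rp$matched_pairs), 3)
  expect_true(all(abs(rp$matched_pairs$congruence) >= 0.9))
  expect_gte(rp$cross_solution_loading_r, 0.8)
})

test_that("vetting drops small factors, splits mixed signs, drops negligible r", {
  # construct a replication report directly: one 6-item mixed-sign factor,
  # one 2-item factor (below the floor)
  set.seed(33)
  n <- 2000
  f <- rnorm(n)
  mk <- function(sgn) pmin(pmax(round(3.5 + sgn * 0.8 * f + rnorm(n)), 1), 6)
  X <- data.frame(item_001 = mk(1), item_002 = mk(1), item_003 = mk(-1),
                  item_004 = mk(-1), item_005 = mk(1), item_006 = mk(-1),
                  item_007 = mk(1), item_008 = mk(1))
  bmi <- 2 * f + rnorm(n, 0, 4)
  # items 1,2,5 aligned +f; 3,4,6 aligned -f; outcome r mixed in factor 1
  tab <- make_residual_table(X, bmi)
  items <- data.frame(
    item_id = item_names(8)[1:8],
    factor_a = c(1, 1, 1, 1, 1, 1, 2, 2),
    factor_b = c(1, 1, 1, 1, 1, 1, 2, 2),
    loading_a = 0.6, loading_b = 0.6, d2 = 0, volatile = FALSE,
    stringsAsFactors = FALSE)
  report <- structure(list(
    matched_pairs = data.frame(factor_a = 1:2, factor_b = 1:2,
                               congruence = 0.95),
    items = items, dropped_items = character(0),
    unmatched_a = integer(0), unmatched_b = integer(0),
    cross_solution_loading_r = 1, volatile_d2 = 0.04),
    class = "replication_report")
  L <- matrix(0, 8, 2, dimnames = list(item_names(8)[1:8], c("F1", "F2")))
  L[1:6, 1] <- c(0.6, 0.6, -0.6, -0.6, 0.6, -0.6)
  L[7:8, 2] <- 0.6
  sol <- structure(list(loadings = L, Phi = diag(2), n_factors = 2),
                   class = "factor_solution")
  defs <- vet_factors(report, sol, tab, min_score_items = 1)
  expect_equal(sort(names(defs)), c("F1_neg", "F1_pos"))   # F2 under the floor
  expect_equal(sort(defs$F1_pos$item_ids),
               c("item_001", "item_002", "item_005"))
  expect_equal(sort(defs$F1_neg$item_ids),
               c("item_003", "item_004", "item_006"))
  # lead item has the largest |r| within members; keys follow loadings
  expect_equal(unname(defs$F1_neg$keys), c(-1, -1, -1))
  # negligible-r drop: shuffle the outcome so factor r ~ 0
  set.seed(4); tab$bmi <- sample(tab$bmi)
  defs2 <- vet_factors(report, sol, tab, negligible_r = 0.05,
                       min_score_items = 1)
  expect_length(defs2, 0)
  # manual interpretability exclusion
  defs3 <- vet_factors(report, sol, tab, negligible_r = 0,
                       exclude = "F1_pos", min_score_items = 1)
  expect_false("F1_pos" %in% names(defs3))
})

test_that("factor scores honor the 3-item floor and key reversal", {
  def <- structure(list(name = "F1",
                        item_ids = c("item_001", "item_002", "item_003",
                                     "item_004", "item_005"),
                        keys = setNames(c(1, 1, -1, 1, 1), item_names(5)),
                        lead_item = "item_001"),
                   class = "factor_definition")
  X <- data.frame(item_001 = c(2, 2), item_002 = c(2, NA),
                  item_003 = c(-2, NA), item_004 = c(2, NA),
                  item_005 = c(2, 2))
  tab <- make_residual_table(X, bmi = c(0, 0))
  sc <- score_factor(tab, def)
  expect_equal(sc[1], 2)            # reversal makes all members equal 2
  expect_true(is.na(sc[2]))         # only 2 of 5 observed
})

test_that("scores track planted trait scores under 50% missingness", {
  tab <- planted_data(n = 5000, k = 1, per = 8, loading = 0.7,
                      missing = 0.5, seed = 88, weights = 1.5)
  truth <- dataset_truth(tab)
  res <- residualize(tab)
  def <- structure(list(name = "F1", item_ids = item_names(8),
                        keys = setNames(rep(1, 8), item_names(8)),
                        lead_item = "item_001"),
                   class = "factor_definition")
  sc <- score_factor(res, def)
  ok <- !is.na(sc)
  expect_gte(cor(sc[ok], truth$factor_scores[ok, 1]), 0.8)
})

test_that("scoring keys survive a YAML round-trip", {
  defs <- list(F1 = structure(list(name = "F1",
                                   item_ids = c("item_001", "item_002",
                                                "item_003"),
                                   keys = setNames(c(1, -1, 1),
                                                   item_names(3)),
                                   lead_item = "item_002",
                                   factor_outcome_r = 0.1,
                                   n_scoreable = 100L),
                              class = "factor_definition"))
  path <- tempfile(fileext = ".yaml")
  write_scoring_key(defs, path)
  back <- read_scoring_key(path)
  expect_equal(back$F1$item_ids, defs$F1$item_ids)
  expect_equal(back$F1$keys, defs$F1$keys)
  expect_equal(back$F1$lead_item, "item_002")
  unlink(path)
})
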