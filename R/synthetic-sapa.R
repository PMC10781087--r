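#' Specification for a synthetic SAPA-style dataset
#'
#' Defines the generative model used by [generate_dataset()]: standard-normal
#' latent trait scores, items loading on those traits and discretized to a
#' 1--6 Likert scale, BMI linked to the traits plus covariate confounding
#' (age, age squared, sex, continent), and responses deleted completely at
#' random at a fixed rate -- the planned-missingness structure of SAPA
#' designs, where each respondent answers a random subset of the item pool.
#'
#' @param n_participants Number of persons to generate.
#' @param n_items Number of questionnaire items.
#' @param n_factors Number of latent traits.
#' @param loading_matrix Optional `n_items x n_factors` matrix of loadings.
#'   Row communalities (row sums of squared loadings) must not exceed 1;
#'   unique item noise is scaled so continuous item propensities have unit
#'   variance. Defaults to [simple_loadings()] with loadings drawn in
#'   `[0.4, 0.7]`.
#' @param outcome_weights Numeric vector, one per factor: the effect of a
#'   one-SD change in the trait on BMI, in kg/m^2.
#' @param covariate_effects List with elements `items` (an
#'   `n_items x 6` matrix of coefficients on age, age^2, sex, and three
#'   continent indicators, or `NULL` for none) and `bmi` (length-6 vector,
#'   same order). Covariate contributions are centered at generation time so
#'   `bmi_baseline` remains the population mean.
#' @param bmi_baseline Target mean BMI, kg/m^2 (default 25, a typical
#'   population mean).
#' @param noise_sd SD of the Gaussian noise added to BMI, kg/m^2.
#' @param missing_rate Probability that any single response is deleted
#'   (missing completely at random). Must be in `[0, 1)`. Default 0.875,
#'   the 87--88\% missingness typical of large SAPA collections.
#' @param response_scale Integer response categories, default `1:6`.
#' @param seed Integer seed; together with the spec it fully determines the
#'   generated dataset.
#' @return An object of class `"synthetic_spec"`.
#' @seealso [generate_dataset()], [generate_triple()]
#' @export
synthetic_spec <- function(n_participants, n_items,
                           n_factors = 1,
                           loading_matrix = NULL,
                           outcome_weights = rep(0, n_factors),
                           covariate_effects = default_covariate_effects(n_items),
                           bmi_baseline = 25,
                           noise_sd = 4,
                           missing_rate = 0.875,
                           response_scale = 1:6,
                           seed = 1L) {
  if (is.null(loading_matrix)) {
    loading_matrix <- simple_loadings(n_items, n_factors, seed = seed)
  }
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != n_items || ncol(loading_matrix) != n_factors) {
    stop("loading_matrix must be n_items x n_factors", call. = FALSE)
  }
  if (length(outcome_weights) != n_factors) {
    stop("outcome_weights must have one entry per factor", call. = FALSE)
  }
  if (any(rowSums(loading_matrix^2) > 1 + 1e-12)) {
    stop("loading_matrix rows must have communality <= 1", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_items = as.integer(n_items),
    n_factors = as.integer(n_factors),
    loading_matrix = loading_matrix,
    outcome_weights = as.numeric(outcome_weights),
    covariate_effects = covariate_effects,
    bmi_baseline = bmi_baseline,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    response_scale = as.integer(response_scale),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Default covariate effects (confounding on BMI only)
#'
#' Age raises BMI with a mild quadratic taper, female sex lowers it, and
#' continents carry small shifts; items carry no covariate effects unless
#' supplied. Coefficient order: age, age^2, sex (female = 1), and indicators
#' for Europe, Asia, Other (North America is the reference).
#'
#' @param n_items Number of items (used only to size the `items` element).
#' @return List with elements `items` (`NULL`) and `bmi` (length-6 vector).
#' @export
default_covariate_effects <- function(n_items) {
  list(
    items = NULL,
    bmi = c(age = 0.30, age2 = -0.0025, sex = -1.2,
            cont_eu = -0.4, cont_as = -1.0, cont_other = -0.3)
  )
}

#' Simple-structure loading matrix
#'
#' Each item loads on exactly one factor, items split as evenly as possible
#' across factors, loadings drawn uniformly from `range`.
#'
#' @param n_items,n_factors Dimensions.
#' @param range Loading magnitude range.
#' @param seed Integer seed.
#' @return `n_items x n_factors` matrix.
#' @export
simple_loadings <- function(n_items, n_factors, range = c(0.4, 0.7), seed = 1L) {
  set.seed(seed)
  lam <- matrix(0, n_items, n_factors)
  fac <- rep_len(seq_len(n_factors), n_items)
  lam[cbind(seq_len(n_items), fac)] <- stats::runif(n_items, range[1], range[2])
  lam
}

# Right-skewed age on [14, 89], mean ~26.5: shifted gamma, resampled into range.
draw_age <- function(n) {
  a <- 14 + stats::rgamma(n, shape = 2, scale = 6.25)
  while (any(bad <- a > 89)) {
    a[bad] <- 14 + stats::rgamma(sum(bad), shape = 2, scale = 6.25)
  }
  a
}

covariate_design_raw <- function(age, sex, continent) {
  cbind(age = age, age2 = age^2, sex = as.numeric(sex == "female"),
        cont_eu = as.numeric(continent == "Europe"),
        cont_as = as.numeric(continent == "Asia"),
        cont_other = as.numeric(continent == "Other"))
}

#' Generate one synthetic SAPA-style dataset
#'
#' Draws latent trait scores, forms continuous item propensities
#' `loadings %*% traits + covariate effects + unique noise`, discretizes them
#' to the response scale by fixed standard-normal quantile cut-points (equal
#' population mass per category), builds BMI as
#' `baseline + outcome_weights %*% traits + covariate effects + noise`, and
#' finally deletes each response independently with probability
#' `missing_rate`. Self-consistent height and weight are generated so that
#' `bmi == weight_kg / (height_cm / 100)^2` exactly.
#'
#' Ground truth (latent scores, loadings, weights) is attached as the
#' `"truth"` attribute, never as columns of the analysis-facing table; use
#' [dataset_truth()] to retrieve it and [write_participant_table()] to write
#' it as a sidecar file.
#'
#' @param spec A [synthetic_spec()].
#' @param dataset_id Label for the dataset ("A", "B", "C", ...).
#' @return A `data.frame` of class `"participant_table"` with columns
#'   `dataset_id`, `bmi`, `age`, `sex`, `continent`, `height_cm`,
#'   `weight_kg`, and one column per item (`item_001`, ...).
#' @export
generate_dataset <- function(spec, dataset_id = "A") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  m <- spec$n_items
  k <- spec$n_factors

  age <- draw_age(n)
  sex <- ifelse(stats::runif(n) < 0.62, "female", "male")
  continent <- sample(c("North America", "Europe", "Asia", "Other"),
                      n, replace = TRUE, prob = c(0.75, 0.12, 0.08, 0.05))
  D <- covariate_design_raw(age, sex, continent)

  f <- matrix(stats::rnorm(n * k), n, k)
  uniq_sd <- sqrt(pmax(0, 1 - rowSums(spec$loading_matrix^2)))
  prop <- f %*% t(spec$loading_matrix) +
    matrix(stats::rnorm(n * m), n, m) * rep(uniq_sd, each = n)
  if (!is.null(spec$covariate_effects$items)) {
    ci <- as.matrix(spec$covariate_effects$items)
    contrib <- D %*% t(ci)
    prop <- prop + scale(contrib, center = TRUE, scale = FALSE)
  }

  # equal-mass discretization on the propensity's standard-normal scale
  sc <- spec$response_scale
  cuts <- stats::qnorm(seq_len(length(sc) - 1) / length(sc))
  resp <- matrix(sc[findInterval(prop, cuts) + 1L], n, m)
  colnames(resp) <- item_names(m)

  bmi_cov <- as.numeric(D %*% spec$covariate_effects$bmi)
  bmi <- spec$bmi_baseline + (bmi_cov - mean(bmi_cov)) +
    as.numeric(f %*% spec$outcome_weights) +
    stats::rnorm(n, 0, spec$noise_sd)

  height_cm <- ifelse(sex == "female", 164, 178) + stats::rnorm(n, 0, 7)
  weight_kg <- bmi * (height_cm / 100)^2

  if (spec$missing_rate > 0) {
    resp[stats::runif(n * m) < spec$missing_rate] <- NA_integer_
  }

  tab <- data.frame(dataset_id = dataset_id, bmi = bmi, age = age, sex = sex,
                    continent = continent, height_cm = height_cm,
                    weight_kg = weight_kg, resp,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(tab) <- c("participant_table", "data.frame")
  attr(tab, "truth") <- list(
    factor_scores = f,
    loading_matrix = spec$loading_matrix,
    outcome_weights = spec$outcome_weights,
    spec = spec
  )
  tab
}

#' @rdname generate_dataset
#' @param table A `participant_table`.
#' @export
dataset_truth <- function(table) attr(table, "truth")

#' Item column names of a participant or residual table
#'
#' @param x A table with item columns, or an integer item count.
#' @return Character vector of item column names.
#' @export
item_names <- function(x) {
  if (is.numeric(x) && length(x) == 1L) {
    return(sprintf("item_%03d", seq_len(x)))
  }
  grep("^item_", names(x), value = TRUE)
}

#' Generate three datasets (A, B, C) from one design
#'
#' Mirrors the three-sample design used for replication and independent
#' train/test evaluation: datasets A and B support dual-dataset screening and
#' factor replication, and A + C vs B supports out-of-sample prediction.
#'
#' @param specA,specB,specC [synthetic_spec()]s. Item counts must agree.
#' @param shared_truth If `TRUE` (default) all three datasets use dataset A's
#'   loading matrix and outcome weights (same generative truth, independent
#'   sampling); if `FALSE` each spec keeps its own.
#' @return Named list of three `participant_table`s (`A`, `B`, `C`).
#' @export
generate_triple <- function(specA, specB, specC = NULL, shared_truth = TRUE) {
  specs <- list(A = specA, B = specB, C = specC)
  specs <- specs[!vapply(specs, is.null, logical(1))]
  m <- vapply(specs, function(s) s$n_items, integer(1))
  if (length(unique(m)) != 1L) {
    stop("all specs must share n_items", call. = FALSE)
  }
  if (shared_truth) {
    for (id in names(specs)[-1]) {
      if (specs[[id]]$n_factors != specA$n_factors) {
        stop("shared_truth requires equal n_factors", call. = FALSE)
      }
      specs[[id]]$loading_matrix <- specA$loading_matrix
      specs[[id]]$outcome_weights <- specA$outcome_weights
    }
  }
  out <- lapply(names(specs), function(id) generate_dataset(specs[[id]], id))
  names(out) <- names(specs)
  out
}

#' Write / read a participant table as CSV (+ ground-truth sidecar)
#'
#' The analysis-facing table is written as a plain CSV with a header row;
#' when ground truth is attached it goes to a separate YAML sidecar
#' (`<path>.truth.yaml`), never into the table itself.
#'
#' @param table A `participant_table`.
#' @param path Output CSV path.
#' @param truth_sidecar Write the ground-truth sidecar if truth is attached.
#' @return `path`, invisibly.
#' @export
write_participant_table <- function(table, path, truth_sidecar = TRUE) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  tr <- attr(table, "truth")
  if (truth_sidecar && !is.null(tr)) {
    yaml::write_yaml(list(
      loading_matrix = apply(tr$loading_matrix, 1, as.numeric, simplify = FALSE),
      outcome_weights = as.numeric(tr$outcome_weights),
      seed = tr$spec$seed
    ), paste0(path, ".truth.yaml"))
  }
  invisible(path)
}

#' @rdname write_participant_table
#' @export
read_participant_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(tab) <- c("participant_table", "data.frame")
  tab
}
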