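# Synthetic cohort generator.  Compositions follow a logistic-normal law on
# the simplex: ILR coordinates are drawn from a Gaussian centred at the ILR
# of a target geometric-mean day, inverted to minutes, and rounded to the
# 10-minute diary grid by largest-remainder apportionment (so zeros arise
# mechanically, as they do in real diaries).  The outcome is linear in the
# ILR coordinates of the zero-replaced composition plus covariate dummy
# effects plus Gaussian noise, so the generating model matches the analysis
# model and noiseless recovery is exact.

#' Default covariate category frequencies
#'
#' Category probabilities broadly matching a UK adolescent cohort: 54%
#' female, 80% White British, 7% eligible for free school meals, and a
#' maternal-education distribution with degree-level (NVQ4/5) as the modal
#' category.
#'
#' @return Named list of named probability vectors, one per covariate.
#' @export
default_covariate_freqs <- function() {
  list(
    sex = c(female = 0.54, male = 0.46),
    ethnicity = c(white_british = 0.80, mixed = 0.04, indian = 0.03,
                  pakistani_bangladeshi = 0.06, black = 0.04, other = 0.03),
    fsm = c(no = 0.93, yes = 0.07),
    maternal_education = c(none = 0.04, overseas = 0.03, nvq1 = 0.08,
                           nvq2 = 0.25, nvq3 = 0.216, nvq4_5 = 0.384)
  )
}

default_target_gm <- function(day_type) {
  if (day_type == "weekday") {
    c(sleep = 897, physical_activity = 23, media = 143, school = 50,
      hobbies = 61, domestic = 266)
  } else {
    c(sleep = 852, media = 202, hobbies = 114, domestic = 272)
  }
}

default_beta_ilr <- function(D) {
  if (D == 6) c(-3, 2, 1, -1, 1.5) else c(-3, 1.5, 1)
}

default_beta_cov <- function() {
  c(sex_male = -2,
    ethnicity_mixed = -1, ethnicity_indian = 3,
    ethnicity_pakistani_bangladeshi = -1, ethnicity_black = -2,
    ethnicity_other = 0.5,
    fsm_yes = -8,
    maternal_education_none = -12, maternal_education_overseas = -6,
    maternal_education_nvq1 = -9, maternal_education_nvq2 = -6,
    maternal_education_nvq3 = -3)
}

#' Ground truth for a synthetic cohort
#'
#' Collects every parameter of the generating process, with defaults that
#' emulate a realistic adolescent time-use cohort: geometric-mean day
#' profiles per day type, a logistic-normal spread in ILR space, Table-1
#' style covariate frequencies, and an attainment outcome (roughly 0-90
#' scale) linear in ILR coordinates and covariate dummies.
#'
#' @param day_type `"weekday"` (six behaviour sets) or `"weekend"` (four).
#' @param target_geometric_mean Named minutes per set, strictly positive,
#'   summing to 1440.
#' @param ilr_scale (D-1)x(D-1) symmetric PSD covariance of the ILR draws;
#'   default `0.5 * I`, giving minute-scale dispersion broadly like observed
#'   diary data and a small rate of structural zeros in the shortest sets.
#' @param beta_ilr True outcome coefficients on the D-1 ILR coordinates.
#' @param beta_cov Named true coefficients for covariate dummies (names are
#'   `covariate_level`, relative to each covariate's modal category).
#' @param intercept Outcome intercept, attainment points.
#' @param noise_sd Residual SD of the outcome, attainment points.
#' @param covariate_freqs Named list of category probability vectors; each
#'   must sum to 1.
#' @param zero_resolution Diary grid in minutes (default 10).
#' @param missing_slot_rate Probability each diary slot is blanked.
#' @param zero_sleep_rate Probability a diary's sleep slots are relabelled
#'   (to media), producing an invalid no-sleep day.
#' @param clip_outcome Clip outcomes into `[0, 90]`? Off by default because
#'   clipping breaks the linearity that recovery tests rely on.
#' @param seed Integer seed giving byte-identical regeneration.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(day_type = c("weekday", "weekend"),
                            target_geometric_mean = NULL,
                            ilr_scale = NULL,
                            beta_ilr = NULL,
                            beta_cov = default_beta_cov(),
                            intercept = 56,
                            noise_sd = 15,
                            covariate_freqs = default_covariate_freqs(),
                            zero_resolution = 10,
                            missing_slot_rate = 0,
                            zero_sleep_rate = 0,
                            clip_outcome = FALSE,
                            seed = 20260101) {
  day_type <- match.arg(day_type)
  if (is.null(target_geometric_mean)) {
    target_geometric_mean <- default_target_gm(day_type)
  }
  D <- length(target_geometric_mean)
  if (is.null(names(target_geometric_mean))) {
    stop("target_geometric_mean must be named")
  }
  if (any(target_geometric_mean <= 0)) {
    stop("target_geometric_mean must be strictly positive")
  }
  if (abs(sum(target_geometric_mean) - DAY_MINUTES) > 1e-6) {
    stop("target_geometric_mean must sum to ", DAY_MINUTES)
  }
  if (is.null(ilr_scale)) ilr_scale <- 0.5 * diag(D - 1)
  ilr_scale <- as.matrix(ilr_scale)
  if (!all(dim(ilr_scale) == D - 1) ||
      max(abs(ilr_scale - t(ilr_scale))) > 1e-8) {
    stop("ilr_scale must be a symmetric (D-1)x(D-1) matrix")
  }
  if (min(eigen(ilr_scale, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("ilr_scale must be positive semi-definite")
  }
  if (is.null(beta_ilr)) beta_ilr <- default_beta_ilr(D)
  if (length(beta_ilr) != D - 1) {
    stop("beta_ilr must have length D-1 = ", D - 1)
  }
  known_cov <- c("sex", "ethnicity", "fsm", "maternal_education")
  if (is.null(names(covariate_freqs)) ||
      !all(names(covariate_freqs) %in% known_cov)) {
    stop("covariate_freqs names must be among: ",
         paste(known_cov, collapse = ", "))
  }
  for (nm in names(covariate_freqs)) {
    p <- covariate_freqs[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("covariate_freqs$", nm, " must be named, non-negative, summing to 1")
    }
  }
  stopifnot(noise_sd >= 0,
            missing_slot_rate >= 0, missing_slot_rate <= 1,
            zero_sleep_rate >= 0, zero_sleep_rate <= 1,
            zero_resolution > 0, DAY_MINUTES %% zero_resolution == 0)
  structure(list(day_type = day_type,
                 target_geometric_mean = target_geometric_mean,
                 ilr_scale = ilr_scale, beta_ilr = beta_ilr,
                 beta_cov = beta_cov, intercept = intercept,
                 noise_sd = noise_sd, covariate_freqs = covariate_freqs,
                 zero_resolution = zero_resolution,
                 missing_slot_rate = missing_slot_rate,
                 zero_sleep_rate = zero_sleep_rate,
                 clip_outcome = clip_outcome,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic cohort truth (", x$day_type, "), ",
      length(x$target_geometric_mean), " behaviour sets, seed ", x$seed,
      "\n", sep = "")
  print(x$target_geometric_mean)
  invisible(x)
}

next_seed <- function(seed, k) as.integer((seed + k) %% .Machine$integer.max)

#' Reference (modal) category per covariate implied by the truth
#' @param truth A `synthetic_truth`.
#' @return Named character vector of reference levels.
#' @export
truth_reference_levels <- function(truth) {
  vapply(truth$covariate_freqs, function(p) {
    names(p)[which.max(p)]
  }, character(1))
}

#' Generate categorical covariates
#'
#' Each covariate is drawn independently from its categorical distribution
#' in `truth$covariate_freqs`.
#'
#' @param truth A `synthetic_truth`.
#' @param n Number of participants.
#' @param seed Seed; defaults to `truth$seed`.
#' @return Data frame with `participant_id` and one column per covariate.
#' @export
generate_covariates <- function(truth, n, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1)
  set.seed(seed)
  out <- data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (nm in names(truth$covariate_freqs)) {
    p <- truth$covariate_freqs[[nm]]
    out[[nm]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  out
}

# Largest-remainder apportionment of each row of `x` (minutes, closed to
# `total`) onto a grid of `resolution` minutes; the rounded rows still sum
# to `total` exactly.  Ties in the fractional remainders are broken by part
# order (earlier parts win).
round_to_grid <- function(x, resolution = 10, total = DAY_MINUTES) {
  m <- as_comp_matrix(x)
  units_total <- total / resolution
  q <- m / resolution
  base <- floor(q)
  rem <- q - base
  extra <- as.integer(round(units_total - rowSums(base)))
  for (i in seq_len(nrow(base))) {
    if (extra[i] > 0) {
      take <- order(-rem[i, ], seq_len(ncol(base)))[seq_len(extra[i])]
      base[i, take] <- base[i, take] + 1
    }
  }
  out <- base * resolution
  if (is.matrix(x)) out else stats::setNames(drop(out), names(x))
}

#' Generate behaviour compositions
#'
#' Draws ILR vectors from a Gaussian centred at the ILR of the target
#' geometric-mean day, inverts them to the simplex, closes to 1440 minutes,
#' and rounds to the diary grid with largest-remainder apportionment, so the
#' integer rows still sum to 1440 and short behaviours can round to exact
#' zeros.
#'
#' @param truth A `synthetic_truth`.
#' @param n Number of person-days.
#' @param seed Seed; defaults to `truth$seed`.
#' @param basis ILR basis; default pivot basis in the truth's part order.
#' @return Integer-valued matrix (n x D) of minutes, rows summing to 1440.
#' @export
generate_compositions <- function(truth, n, seed = truth$seed,
                                  basis = pivot_basis(names(truth$target_geometric_mean))) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1)
  D <- length(truth$target_geometric_mean)
  set.seed(seed)
  ev <- eigen(truth$ilr_scale, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("ilr_scale must be positive semi-definite")
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), D - 1) %*% t(ev$vectors)
  mu <- ilr(truth$target_geometric_mean, basis)
  Z <- matrix(stats::rnorm(n * (D - 1)), nrow = n) %*% A
  Z <- sweep(Z, 2, mu, `+`)
  comp <- ilr_inverse(Z, basis)
  round_to_grid(comp, resolution = truth$zero_resolution)
}

#' Generate the attainment outcome
#'
#' `y = intercept + ilr(x) . beta_ilr + dummies . beta_cov + Normal(0,
#' noise_sd^2)`.  Compositions must be strictly positive (apply
#' [replace_zeros()] first), so the analysis pipeline fitting the same
#' zero-replaced compositions recovers `beta_ilr` exactly when `noise_sd`
#' is 0.
#'
#' @param compositions Strictly positive matrix of minutes (n x D).
#' @param covariates Data frame from [generate_covariates()].
#' @param truth A `synthetic_truth`.
#' @param basis ILR basis; default pivot basis in the truth's part order.
#' @param seed Seed; defaults to `truth$seed`.
#' @return Numeric outcome vector of length n.
#' @export
generate_outcome <- function(compositions, covariates, truth,
                             basis = pivot_basis(names(truth$target_geometric_mean)),
                             seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- as_comp_matrix(compositions)
  if (nrow(m) != nrow(covariates)) {
    stop("compositions and covariates must have equal row counts")
  }
  if (any(m <= 0)) {
    stop("compositions contain zeros; apply replace_zeros() before ",
         "generating outcomes")
  }
  set.seed(seed)
  z <- ilr(m, basis)
  y <- truth$intercept + drop(z %*% truth$beta_ilr)
  X <- encode_covariates(covariates,
                         covariate_names = names(truth$covariate_freqs),
                         reference = truth_reference_levels(truth))
  use <- intersect(names(truth$beta_cov), colnames(X))
  if (length(use)) {
    y <- y + drop(X[, use, drop = FALSE] %*% truth$beta_cov[use])
  }
  y <- y + stats::rnorm(nrow(m), 0, truth$noise_sd)
  if (isTRUE(truth$clip_outcome)) {
    message("outcome clipped to [0, 90]; linear recovery no longer exact")
    y <- pmin(90, pmax(0, y))
  }
  y
}

#' Expand a composition into a 144-slot diary
#'
#' Sleep is anchored at the start and end of the 04:00-04:00 window (split
#' roughly in half); the other behaviour sets occupy contiguous blocks in
#' randomised order between.  Optional corruption exercises the validity
#' filters: with probability `missing_slot_rate` each slot is blanked, and
#' with probability `zero_sleep_rate` all sleep slots are relabelled to
#' media.
#'
#' @param composition Named minutes on the 10-minute grid, summing to 1440.
#' @param truth A `synthetic_truth` (for the corruption rates).
#' @param mapping Activity mapping supplying one canonical code per set.
#' @param participant_id Identifier stored in the diary.
#' @param day_type Day type stored in the diary; default the truth's.
#' @param seed Seed; defaults to `truth$seed`.
#' @return A `time_use_diary`.
#' @export
expand_to_diary <- function(composition, truth,
                            mapping = default_activity_mapping(),
                            participant_id = "P00001",
                            day_type = truth$day_type,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(composition %% 10 != 0)) {
    stop("composition parts must be divisible by 10 minutes")
  }
  if (abs(sum(composition) - DAY_MINUTES) > 1e-9) {
    stop("composition must sum to ", DAY_MINUTES)
  }
  set.seed(seed)
  canon <- vapply(behaviour_sets("weekday"), function(s) {
    mapping$entries$activity_code[mapping$entries$behaviour_set == s][1]
  }, character(1))
  nslots <- composition / 10
  parts <- names(composition)
  ns <- if ("sleep" %in% parts) nslots[["sleep"]] else 0
  n_end <- floor(ns / 2)
  n_start <- ns - n_end
  others <- setdiff(parts, "sleep")
  others <- others[nslots[others] > 0]
  order_mid <- if (length(others) > 1) sample(others) else others
  mid <- unlist(lapply(order_mid, function(p) {
    rep(canon[[p]], nslots[[p]])
  }), use.names = FALSE)
  slots <- c(rep(canon[["sleep"]], n_start), mid, rep(canon[["sleep"]], n_end))
  stopifnot(length(slots) == N_SLOTS)
  if (truth$zero_sleep_rate > 0 &&
      stats::runif(1) < truth$zero_sleep_rate && ns > 0) {
    slots[slots == canon[["sleep"]]] <- canon[["media"]]
  }
  if (truth$missing_slot_rate > 0) {
    slots[stats::runif(N_SLOTS) < truth$missing_slot_rate] <- NA_character_
  }
  time_use_diary(participant_id, day_type, slots)
}

#' Simulate a full synthetic cohort
#'
#' Draws covariates, compositions (with structural zeros from grid
#' rounding), the outcome (from the zero-replaced compositions), and
#' expanded diaries (with any configured corruption), all reproducibly from
#' `truth$seed`.
#'
#' @param truth A `synthetic_truth`.
#' @param n Number of participants.
#' @param mapping Activity mapping used for diary expansion.
#' @param impute Minutes used for multiplicative zero replacement before
#'   outcome generation; default 5.
#' @param expand_diaries Expand each composition into a 144-slot diary?
#'   Set `FALSE` for simulation studies that work on compositions directly.
#' @return A `synthetic_cohort`: list with `covariates`, `compositions`
#'   (raw, grid-rounded), `compositions_replaced`, `outcomes`, `diaries`,
#'   `truth`, `mapping`.
#' @export
simulate_cohort <- function(truth, n, mapping = default_activity_mapping(),
                            impute = 5, expand_diaries = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1)
  s <- truth$seed
  covs <- generate_covariates(truth, n, seed = s)
  comps <- generate_compositions(truth, n, seed = next_seed(s, 1))
  comps_pos <- replace_zeros(comps, impute = impute)
  y <- generate_outcome(comps_pos, covs, truth, seed = next_seed(s, 2))
  outcomes <- data.frame(participant_id = covs$participant_id,
                         attainment8 = y,
                         passes = pmin(10, pmax(0, round(y / 9))),
                         stringsAsFactors = FALSE)
  diaries <- if (expand_diaries) {
    lapply(seq_len(n), function(i) {
      expand_to_diary(comps[i, ], truth, mapping = mapping,
                      participant_id = covs$participant_id[i],
                      day_type = truth$day_type,
                      seed = next_seed(s, 2 + i))
    })
  }
  structure(list(covariates = covs, compositions = comps,
                 compositions_replaced = comps_pos, outcomes = outcomes,
                 diaries = diaries, truth = truth, mapping = mapping,
                 impute = impute),
            class = "synthetic_cohort")
}

#' Analytic sample straight from an in-memory cohort
#'
#' Assembles the `analytic_sample` that the diary pipeline would produce
#' for an uncorrupted cohort, using the cohort's zero-replaced
#' compositions directly.  Convenient for simulation studies (parameter
#' recovery, confidence-interval calibration) that do not exercise the
#' diary layer.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outcome_name Outcome column, default `"attainment8"`.
#' @return An `analytic_sample` with strictly positive compositions.
#' @export
cohort_analytic_sample <- function(cohort, outcome_name = "attainment8") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  parts <- names(cohort$truth$target_geometric_mean)
  covariate_names <- names(cohort$truth$covariate_freqs)
  df <- data.frame(participant_id = cohort$covariates$participant_id,
                   cohort$compositions_replaced,
                   cohort$covariates[covariate_names],
                   stringsAsFactors = FALSE)
  df[[outcome_name]] <- cohort$outcomes[[outcome_name]]
  n <- nrow(df)
  structure(list(data = df,
                 removal_log = data.frame(
                   step = c("covariates", "diary", "outcome"),
                   removed = c(0L, 0L, 0L), remaining = c(n, n, n),
                   stringsAsFactors = FALSE),
                 parts = parts, day_type = cohort$truth$day_type,
                 outcome_name = outcome_name,
                 covariate_names = covariate_names),
            class = "analytic_sample")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$covariates), "participants (",
      x$truth$day_type, ")\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV/JSON files
#'
#' Writes `diaries.csv` (long format; blanked slots are omitted so they
#' parse back as missing), `covariates.csv`, `outcomes.csv`, `mapping.csv`,
#' and `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(cohort$diaries, function(d) {
    keep <- !is.na(d$slots)
    data.frame(participant_id = d$participant_id, day_type = d$day_type,
               slot_index = which(keep) - 1L,
               activity_code = d$slots[keep], stringsAsFactors = FALSE)
  }))
  paths <- c(diaries = file.path(dir, "diaries.csv"),
             covariates = file.path(dir, "covariates.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             mapping = file.path(dir, "mapping.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(long, paths[["diaries"]], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths[["covariates"]], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[["outcomes"]], row.names = FALSE)
  write_activity_mapping(cohort$mapping, paths[["mapping"]])
  tr <- cohort$truth
  tr$ilr_scale <- unclass(tr$ilr_scale)
  jsonlite::write_json(unclass(tr), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
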