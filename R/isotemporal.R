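# Compositional isotemporal substitution: predicted outcome differences for
# fixed-time reallocations between pairs of behaviour sets, around a base
# composition (by default the sample's compositional mean).  Because the
# covariate terms are identical at the base and the reallocated day, the
# predicted difference is a linear contrast of the ILR coefficients,
# `a'beta` with `a = ilr(substituted) - ilr(base)`, with Wald standard error
# `sqrt(a' Sigma a)` from the ILR block of the coefficient covariance and a
# t-based 95% confidence interval.

#' Reallocate minutes between two behaviour sets
#'
#' Moves `delta` minutes into `add_part` out of `remove_part`, leaving all
#' other parts unchanged, so the day still sums to 1440.  A negative
#' `delta` expresses the reverse move.  Reallocations that would drive any
#' part to zero or below are infeasible (ILR requires strict positivity).
#'
#' @param base Named, strictly positive composition summing to 1440.
#' @param add_part,remove_part Distinct part names present in `base`.
#' @param delta Minutes to move.
#' @return The reallocated composition.
#' @examples
#' base <- c(sleep = 897, physical_activity = 23, media = 143, school = 50,
#'           hobbies = 61, domestic = 266)
#' reallocate(base, "sleep", "media", 20)
#' @export
reallocate <- function(base, add_part, remove_part, delta) {
  if (is.null(names(base))) stop("base composition must be named")
  if (identical(add_part, remove_part)) {
    stop("add_part and remove_part must differ")
  }
  if (!all(c(add_part, remove_part) %in% names(base))) {
    stop("both parts must be present in the composition")
  }
  if (any(base <= 0)) stop("base composition must be strictly positive")
  out <- base
  out[add_part] <- out[add_part] + delta
  out[remove_part] <- out[remove_part] - delta
  if (out[add_part] <= 0 || out[remove_part] <= 0) {
    stop(infeasible_reallocation(add_part, remove_part, delta))
  }
  out
}

infeasible_reallocation <- function(add_part, remove_part, delta) {
  structure(
    class = c("codatime_infeasible", "error", "condition"),
    list(message = sprintf(
      "infeasible reallocation: moving %g min into '%s' from '%s' drives a part to or below zero",
      delta, add_part, remove_part), call = NULL)
  )
}

#' Predicted outcome difference for one time reallocation
#'
#' Computes the estimated difference in the outcome between the reallocated
#' day and the base day.  Covariate terms cancel exactly, so the estimate
#' is the linear contrast `a'beta_ilr`; the 95% CI uses the t distribution
#' with the model's residual degrees of freedom.
#'
#' @param model A `fitted_outcome_model`.
#' @param base Strictly positive named composition over the model's parts;
#'   default the compositional mean of the model's analytic sample.
#' @param add_part,remove_part Part names.
#' @param delta Minutes reallocated.
#' @return One-row data frame: add, remove, delta, beta, se, ci_low,
#'   ci_high, significant (95% CI excludes 0), feasible.
#' @export
predicted_difference <- function(model, base = NULL, add_part, remove_part,
                                 delta) {
  stopifnot(inherits(model, "fitted_outcome_model"))
  if (is.null(base)) base <- compositional_mean(model$compositions)
  if (!setequal(names(base), model$parts)) {
    stop("base composition parts do not match the fitted model's parts")
  }
  base <- base[model$parts]
  sub <- reallocate(base, add_part, remove_part, delta)
  a <- ilr(sub, model$basis) - ilr(base, model$basis)
  blk <- ilr_block(model)
  beta <- drop(a %*% blk$beta)
  se <- sqrt(drop(t(a) %*% blk$sigma %*% a))
  tcrit <- stats::qt(0.975, model$residual_df)
  ci_low <- beta - tcrit * se
  ci_high <- beta + tcrit * se
  data.frame(add = add_part, remove = remove_part, delta = delta,
             beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
             significant = ci_low > 0 | ci_high < 0, feasible = TRUE,
             stringsAsFactors = FALSE)
}

infeasible_row <- function(add_part, remove_part, delta) {
  data.frame(add = add_part, remove = remove_part, delta = delta,
             beta = NA_real_, se = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, significant = NA, feasible = FALSE,
             stringsAsFactors = FALSE)
}

#' Pairwise substitution table
#'
#' One row per ordered (add, remove) pair of behaviour sets at a fixed
#' reallocation of `delta` minutes: D(D-1) rows (30 for six weekday sets,
#' 12 for four weekend sets).  Infeasible pairs are flagged rather than
#' fatal.
#'
#' @param model A `fitted_outcome_model`.
#' @param base Base composition; default the sample's compositional mean.
#' @param delta Minutes reallocated (20 is the usual weekday choice, 30 the
#'   weekend one).
#' @return Data frame of substitution estimates.
#' @export
pairwise_table <- function(model, base = NULL, delta) {
  stopifnot(inherits(model, "fitted_outcome_model"))
  if (is.null(base)) base <- compositional_mean(model$compositions)
  parts <- model$parts
  rows <- list()
  for (add_part in parts) {
    for (remove_part in setdiff(parts, add_part)) {
      rows[[length(rows) + 1]] <- tryCatch(
        predicted_difference(model, base, add_part, remove_part, delta),
        codatime_infeasible = function(e) {
          infeasible_row(add_part, remove_part, delta)
        })
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Substitution estimates over a grid of reallocation durations
#'
#' For every ordered pair of behaviour sets and every `delta` in
#' `{-delta_max, ..., -step, 0, step, ..., delta_max}`, the predicted
#' outcome difference with its 95% CI.  Typical settings: +/-20 minutes in
#' 5-minute increments on weekdays, +/-30 at weekends.
#'
#' @param model A `fitted_outcome_model`.
#' @param base Base composition; default the sample's compositional mean.
#' @param delta_max Largest reallocation, a positive multiple of `step`.
#' @param step Grid increment in minutes, default 5.
#' @return Data frame of substitution estimates (infeasible cells flagged).
#' @export
substitution_grid <- function(model, base = NULL, delta_max, step = 5) {
  stopifnot(inherits(model, "fitted_outcome_model"))
  if (step <= 0) stop("step must be positive")
  if (delta_max %% step != 0) stop("delta_max must be a multiple of step")
  if (is.null(base)) base <- compositional_mean(model$compositions)
  deltas <- seq(-delta_max, delta_max, by = step)
  parts <- model$parts
  rows <- list()
  for (add_part in parts) {
    for (remove_part in setdiff(parts, add_part)) {
      for (d in deltas) {
        rows[[length(rows) + 1]] <- tryCatch(
          predicted_difference(model, base, add_part, remove_part, d),
          codatime_infeasible = function(e) {
            infeasible_row(add_part, remove_part, d)
          })
      }
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Express a predicted difference as a percentage of the outcome mean
#'
#' Small utility for reporting, e.g. a -0.81-point difference against a
#' mean score of 56.3 is about a 1.4% reduction.
#'
#' @param beta Predicted difference in outcome units.
#' @param outcome_mean Mean outcome of the sample.
#' @return Percentage (signed).
#' @export
percent_of_mean <- function(beta, outcome_mean) 100 * beta / outcome_mean
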