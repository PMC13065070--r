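# Covariate-adjusted linear model of academic attainment on ILR coordinates
# of the time-use composition, with a nested-model F test for the
# compositional block and descriptive/comparison tables.

#' Canonical covariate category orders
#'
#' Fixed level orders for the standard adjustment set (sex, six-category
#' ethnicity, free-school-meal eligibility, six-level maternal education).
#' Used to make dummy-column order deterministic.
#'
#' @return Named list of character vectors.
#' @export
covariate_levels <- function() {
  list(
    sex = c("female", "male"),
    ethnicity = c("white_british", "mixed", "indian",
                  "pakistani_bangladeshi", "black", "other"),
    fsm = c("no", "yes"),
    maternal_education = c("none", "overseas", "nvq1", "nvq2", "nvq3",
                           "nvq4_5")
  )
}

#' Dummy-encode covariates
#'
#' Treatment (reference-cell) coding with one column per non-reference
#' category, named `covariate_level`.  The reference is the modal category
#' of each covariate unless given explicitly.  Column order is
#' deterministic: covariates in `covariate_names` order, levels in
#' canonical order (or sorted order for non-canonical covariates).
#' Covariates constant in the data contribute no column (with a warning).
#'
#' @param df Data frame with complete covariate columns.
#' @param covariate_names Covariate columns to encode.
#' @param reference `"modal"` or a named character vector of reference
#'   levels.
#' @return Numeric 0/1 matrix with a `reference` attribute.
#' @export
encode_covariates <- function(df,
                              covariate_names = intersect(names(covariate_levels()),
                                                          names(df)),
                              reference = "modal") {
  stopifnot(is.data.frame(df))
  miss <- setdiff(covariate_names, names(df))
  if (length(miss)) stop("covariate column(s) not found: ",
                         paste(miss, collapse = ", "))
  canon <- covariate_levels()
  cols <- list()
  refs <- character(0)
  for (nm in covariate_names) {
    v <- as.character(df[[nm]])
    if (anyNA(v)) stop("covariate '", nm, "' contains missing values")
    levs <- if (nm %in% names(canon)) canon[[nm]] else sort(unique(v))
    unseen <- setdiff(unique(v), levs)
    if (length(unseen)) {
      stop("covariate '", nm, "' has unknown category: ",
           paste(unseen, collapse = ", "))
    }
    present <- levs[levs %in% v]
    if (length(present) < 2) {
      warning("covariate '", nm, "' is constant; dropped from the design")
      refs[nm] <- present
      next
    }
    ref <- if (identical(reference, "modal")) {
      tab <- table(factor(v, levels = present))
      present[which.max(tab)]  # ties: first in level order
    } else {
      if (!nm %in% names(reference)) {
        stop("no reference level given for covariate '", nm, "'")
      }
      if (!reference[[nm]] %in% present) {
        stop("reference level '", reference[[nm]], "' absent for '", nm, "'")
      }
      reference[[nm]]
    }
    refs[nm] <- ref
    for (lev in setdiff(present, ref)) {
      cols[[paste0(nm, "_", lev)]] <- as.numeric(v == lev)
    }
  }
  X <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(numeric(0), nrow = nrow(df), ncol = 0)
  }
  attr(X, "reference") <- refs
  X
}

#' Fit the attainment model on ILR coordinates plus covariates
#'
#' Ordinary least squares of the outcome on an intercept, the D-1 ILR
#' coordinates of the (strictly positive) behaviour composition, and
#' treatment-coded covariate dummies.  Coefficient covariance is the usual
#' `s^2 (X'X)^-1`.
#'
#' @param sample An `analytic_sample` (see [build_analytic_sample()]) whose
#'   compositions are strictly positive -- apply [replace_zeros()] to the
#'   part columns first if zeros are present.
#' @param basis ILR basis; default the pivot basis in the sample's part
#'   order.
#' @param outcome_name Outcome column; default the sample's.
#' @param covariate_names Covariates to adjust for; default the sample's.
#' @param reference Reference-category rule passed to [encode_covariates()].
#' @return A `fitted_outcome_model`: coefficients, covariance,
#'   `residual_df`, `n`, the basis, ILR coefficient names, the underlying
#'   `lm` fit, and the data used.
#' @export
fit_outcome_model <- function(sample, basis = NULL, outcome_name = NULL,
                              covariate_names = NULL, reference = "modal") {
  stopifnot(inherits(sample, "analytic_sample"))
  if (is.null(outcome_name)) outcome_name <- sample$outcome_name
  if (is.null(covariate_names)) covariate_names <- sample$covariate_names
  comp <- sample_compositions(sample)
  if (any(comp <= 0)) {
    stop("compositions contain zero parts; apply replace_zeros() before ",
         "fitting")
  }
  if (is.null(basis)) basis <- pivot_basis(sample$parts)
  z <- ilr(comp, basis)
  ilr_names <- colnames(z)
  X <- encode_covariates(sample$data, covariate_names = covariate_names,
                         reference = reference)
  y <- sample$data[[outcome_name]]
  if (is.null(y)) stop("outcome column not found: ", outcome_name)
  df <- data.frame(.outcome = y, z, X, check.names = FALSE)
  p <- ncol(df)  # intercept replaces outcome column in the count
  if (nrow(df) <= p) stop("need more observations than parameters (n > p)")
  fit <- stats::lm(.outcome ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  # a perfect (zero-residual) fit is a designed use: noiseless recovery
  vc <- withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(fit = fit, coefficients = cf, vcov = vc,
                 residual_df = fit$df.residual, n = nrow(df),
                 basis = basis, parts = sample$parts,
                 ilr_names = ilr_names,
                 covariate_columns = colnames(X),
                 reference = attr(X, "reference"),
                 outcome_name = outcome_name,
                 compositions = comp, model_data = df),
            class = "fitted_outcome_model")
}

#' @export
print.fitted_outcome_model <- function(x, ...) {
  cat("Attainment model: '", x$outcome_name, "' ~ ",
      length(x$ilr_names), " ILR coordinates + ",
      length(x$covariate_columns), " covariate dummies; n = ", x$n,
      ", residual df = ", x$residual_df, "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' ILR coefficient block of a fitted model
#' @param model A `fitted_outcome_model`.
#' @return List with `beta` (named vector) and `sigma` (covariance block).
#' @export
ilr_block <- function(model) {
  stopifnot(inherits(model, "fitted_outcome_model"))
  idx <- model$ilr_names
  list(beta = model$coefficients[idx],
       sigma = model$vcov[idx, idx, drop = FALSE])
}

#' Joint F test of the compositional block
#'
#' Nested-model F test comparing the full model against the covariates-only
#' model; tests whether the time-use composition is associated with the
#' outcome after covariate adjustment.  `df1` equals D-1.
#'
#' @param model A `fitted_outcome_model`.
#' @return An `ftest_result`: list with `F`, `df1`, `df2`, `p`.
#' @export
joint_composition_test <- function(model) {
  stopifnot(inherits(model, "fitted_outcome_model"))
  if (length(model$ilr_names) == 0) {
    stop("model contains no ILR coordinates; nothing to test")
  }
  df <- model$model_data
  reduced_cols <- c(".outcome", model$covariate_columns)
  reduced <- stats::lm(.outcome ~ ., data = df[, reduced_cols, drop = FALSE])
  a <- stats::anova(reduced, model$fit)
  res <- list(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
              p = a$`Pr(>F)`[2])
  structure(res, class = "ftest_result")
}

#' @export
print.ftest_result <- function(x, ...) {
  cat(sprintf("Composition block: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Descriptive summary of an analytic sample
#'
#' Frequencies with percentages for categorical columns and mean (SD) for
#' continuous columns, one row per category or variable.
#'
#' @param sample An `analytic_sample` or plain data frame.
#' @return List with data frames `categorical` (variable, level, n, pct)
#'   and `continuous` (variable, mean, sd).
#' @export
describe_sample <- function(sample) {
  df <- if (inherits(sample, "analytic_sample")) sample$data else sample
  stopifnot(is.data.frame(df), nrow(df) > 0)
  df <- df[, setdiff(names(df), "participant_id"), drop = FALSE]
  cats <- names(df)[vapply(df, function(v) is.character(v) || is.factor(v),
                           NA)]
  nums <- setdiff(names(df), cats)
  cat_tab <- do.call(rbind, lapply(cats, function(nm) {
    tab <- table(df[[nm]])
    data.frame(variable = nm, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / nrow(df), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  num_tab <- do.call(rbind, lapply(nums, function(nm) {
    data.frame(variable = nm, mean = mean(df[[nm]]),
               sd = stats::sd(df[[nm]]), stringsAsFactors = FALSE)
  }))
  list(categorical = cat_tab, continuous = num_tab)
}

#' Compare included and excluded participants
#'
#' Welch (unequal-variance) t tests for continuous variables and Pearson
#' chi-square tests (without continuity correction) for categorical
#' variables, on every column shared by the two tables.  Variables with
#' fewer than two observed categories across both groups are dropped with a
#' warning.
#'
#' @param included,excluded Data frames (e.g. analytic vs excluded
#'   participants).
#' @return Data frame: variable, test, statistic, df, p.
#' @export
compare_samples <- function(included, excluded) {
  if (inherits(included, "analytic_sample")) included <- included$data
  if (inherits(excluded, "analytic_sample")) excluded <- excluded$data
  stopifnot(is.data.frame(included), nrow(included) > 0,
            is.data.frame(excluded), nrow(excluded) > 0)
  vars <- setdiff(intersect(names(included), names(excluded)),
                  "participant_id")
  rows <- lapply(vars, function(nm) {
    a <- included[[nm]]
    b <- excluded[[nm]]
    if (is.numeric(a) && is.numeric(b)) {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(variable = nm, test = "welch_t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      val <- c(as.character(a), as.character(b))
      grp <- rep(c("included", "excluded"), c(length(a), length(b)))
      if (length(unique(val)) < 2) {
        warning("variable '", nm, "' has a single category; dropped")
        return(NULL)
      }
      ct <- stats::chisq.test(table(grp, val), correct = FALSE)
      data.frame(variable = nm, test = "chi_square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  row.names(out) <- NULL
  out
}
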