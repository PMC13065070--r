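# Isotemporal substitution: reallocation arithmetic, the closed-form
# contrast against a brute-force prediction oracle, basis invariance, and
# table/grid structure.

test_that("reallocation moves minutes between exactly two parts", {
  base <- weekday_gm
  expect_identical(reallocate(base, "sleep", "media", 0), base)
  got <- reallocate(base, "sleep", "media", 20)
  expect_equal(unname(got), c(917, 23, 123, 50, 61, 266))
  expect_equal(sum(got), 1440)
  # moving 30 min out of a 23-min part is infeasible
  expect_error(reallocate(base, "sleep", "physical_activity", 30),
               class = "codatime_infeasible")
  expect_error(reallocate(base, "sleep", "sleep", 10), "differ")
  expect_error(reallocate(base, "sleep", "tv", 10), "present")
})

test_that("zero-minute substitutions are exactly null", {
  fs <- fit_synthetic(n = 300, seed = 50)
  est <- predicted_difference(fs$model, add_part = "sleep",
                              remove_part = "media", delta = 0)
  expect_equal(est$beta, 0)
  expect_equal(est$se, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(0, 0))
  expect_false(est$significant)
})

# Brute-force oracle: difference of full-model predictions at the base and
# reallocated compositions, holding an arbitrary covariate profile fixed.
oracle_difference <- function(model, base, add, remove, delta, profile_row) {
  sub <- reallocate(base, add, remove, delta)
  nd <- function(comp) {
    z <- ilr(comp, model$basis)
    df <- model$model_data[profile_row, , drop = FALSE]
    df[names(z)] <- as.list(z)
    df
  }
  predict(model$fit, newdata = nd(sub)) - predict(model$fit,
                                                  newdata = nd(base))
}

test_that("closed-form estimates equal brute-force prediction differences", {
  set.seed(51)
  worst <- 0
  for (k in 1:4) {
    fs <- fit_synthetic(n = 250, seed = 510 + k,
                        day_type = if (k %% 2) "weekday" else "weekend")
    parts <- fs$model$parts
    base_pool <- sample_compositions(fs$sample)
    for (j in 1:25) {
      base <- base_pool[sample(nrow(base_pool), 1), ]
      pair <- sample(parts, 2)
      delta <- runif(1, -10, 10)
      est <- tryCatch(
        predicted_difference(fs$model, base, pair[1], pair[2], delta),
        codatime_infeasible = function(e) NULL)
      if (is.null(est)) next
      ora <- oracle_difference(fs$model, base, pair[1], pair[2], delta,
                               profile_row = sample(fs$model$n, 1))
      worst <- max(worst, abs(est$beta - unname(ora)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("the oracle difference does not depend on the covariate profile", {
  fs <- fit_synthetic(n = 200, seed = 52)
  base <- compositional_mean(fs$model$compositions)
  d1 <- oracle_difference(fs$model, base, "sleep", "media", 15, 1)
  d2 <- oracle_difference(fs$model, base, "sleep", "media", 15, 137)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-12)
})

test_that("substitution estimates are invariant to the pivot order", {
  tr <- synthetic_truth(seed = 53)
  cohort <- simulate_cohort(tr, 1000, expand_diaries = FALSE)
  sample <- cohort_analytic_sample(cohort)
  parts <- sample$parts
  m1 <- fit_outcome_model(sample, basis = pivot_basis(parts))
  m2 <- fit_outcome_model(sample, basis = pivot_basis(parts, rev(parts)))
  base <- compositional_mean(sample_compositions(sample))
  t1 <- pairwise_table(m1, base, delta = 20)
  t2 <- pairwise_table(m2, base, delta = 20)
  expect_lt(max(abs(t1$beta - t2$beta)), 1e-9)
  expect_lt(max(abs(t1$se - t2$se)), 1e-9)
})

test_that("pairwise tables enumerate every ordered pair once", {
  fs6 <- fit_synthetic(n = 200, seed = 54)
  tab6 <- pairwise_table(fs6$model, delta = 20)
  expect_equal(nrow(tab6), 30)
  expect_true(all(tab6$add != tab6$remove))
  expect_equal(nrow(unique(tab6[c("add", "remove")])), 30)

  fs4 <- fit_synthetic(n = 200, seed = 55, day_type = "weekend")
  tab4 <- pairwise_table(fs4$model, delta = 30)
  expect_equal(nrow(tab4), 12)
  expect_true(all(tab4$significant == (tab4$ci_low > 0 | tab4$ci_high < 0)))
  expect_true(all(tab4$ci_low <= tab4$beta & tab4$beta <= tab4$ci_high))
})

test_that("infeasible pairs are flagged, not fatal", {
  fs <- fit_synthetic(n = 200, seed = 56)
  # around the sample mean the shortest set has well under 60 minutes
  base <- compositional_mean(fs$model$compositions)
  stopifnot(min(base) < 60)
  tab <- pairwise_table(fs$model, base, delta = ceiling(min(base)) + 5)
  expect_true(any(!tab$feasible))
  expect_true(all(is.na(tab$beta[!tab$feasible])))
  expect_equal(nrow(tab), 30)
})

test_that("substitution grids cover the delta range consistently", {
  fs <- fit_synthetic(n = 200, seed = 57)
  base <- compositional_mean(fs$model$compositions)
  grid <- substitution_grid(fs$model, base, delta_max = 20, step = 5)
  one_pair <- grid[grid$add == "sleep" & grid$remove == "media", ]
  expect_equal(one_pair$delta, seq(-20, 20, 5))  # 9 grid points
  expect_true(all(grid$beta[grid$delta == 0] == 0))

  tab <- pairwise_table(fs$model, base, delta = 20)
  at20 <- grid[grid$delta == 20, c("add", "remove", "beta", "se")]
  merged <- merge(tab, at20, by = c("add", "remove"),
                  suffixes = c("_tab", "_grid"))
  expect_equal(merged$beta_tab, merged$beta_grid, tolerance = 1e-12)

  expect_error(substitution_grid(fs$model, base, delta_max = 20, step = 0),
               "positive")
  expect_error(substitution_grid(fs$model, base, delta_max = 22, step = 5),
               "multiple")
})

test_that("substitution effects are asymmetric in general", {
  fs <- fit_synthetic(n = 500, seed = 58)
  base <- compositional_mean(fs$model$compositions)
  ab <- predicted_difference(fs$model, base, "sleep", "physical_activity", 20)
  ba <- predicted_difference(fs$model, base, "physical_activity", "sleep", 20)
  expect_gt(abs(ab$beta + ba$beta), 1e-3)
})

test_that("percent_of_mean converts differences to percentages", {
  expect_equal(percent_of_mean(-0.81, 56.3), -100 * 0.81 / 56.3)
})
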