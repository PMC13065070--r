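# Pipeline orchestration: run the full analysis from a configuration (parse
# -> validate -> build sample -> zero-replace -> fit -> joint test ->
# substitution tables -> descriptive tables), writing deterministic CSV
# outputs and a removal log.  A thin command-line wrapper around these
# functions ships in inst/cli/codatime.

#' Build a pipeline configuration
#'
#' @param diaries,covariates,outcomes,mapping Paths to the input CSVs.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param out_dir Output directory.
#' @param impute_minutes Zero-replacement value, in (0, 10); default 5.
#' @param delta Fixed reallocation for the pairwise table; default 20
#'   minutes on weekdays, 30 at weekends.
#' @param grid_delta_max Largest grid reallocation; defaults to `delta`.
#' @param grid_step Grid increment, default 5 minutes.
#' @param outcome_name `"attainment8"` (default) or `"passes"`.
#' @param pivot_order Optional pivot order for the ILR basis (part names).
#' @param seed Integer seed recorded with the run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(diaries, covariates, outcomes, mapping,
                            day_type = c("weekday", "weekend"),
                            out_dir = ".",
                            impute_minutes = 5,
                            delta = NULL,
                            grid_delta_max = NULL,
                            grid_step = 5,
                            outcome_name = "attainment8",
                            pivot_order = NULL,
                            seed = 1L) {
  day_type <- match.arg(day_type)
  for (p in c(diaries = diaries, covariates = covariates,
              outcomes = outcomes, mapping = mapping)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (impute_minutes <= 0 || impute_minutes >= 10) {
    stop("impute_minutes must lie in (0, 10)")
  }
  if (is.null(delta)) delta <- if (day_type == "weekday") 20 else 30
  if (delta <= 0) stop("delta must be positive")
  if (is.null(grid_delta_max)) grid_delta_max <- delta
  structure(list(diaries = diaries, covariates = covariates,
                 outcomes = outcomes, mapping = mapping,
                 day_type = day_type, out_dir = out_dir,
                 impute_minutes = impute_minutes, delta = delta,
                 grid_delta_max = grid_delta_max, grid_step = grid_step,
                 outcome_name = outcome_name, pivot_order = pivot_order,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("diaries", "covariates", "outcomes", "mapping")) {
    if (!is.null(raw[[k]]) && !file.exists(raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes parse -> validate/filter -> zero replacement -> model fit ->
#' joint composition test -> pairwise substitution table -> substitution
#' grid -> descriptive tables, and writes CSV outputs plus a JSON run
#' summary under `config$out_dir`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every intermediate result (`sample`,
#'   `model`, `joint_test`, `pairwise`, `grid`, `composition_summary`,
#'   `descriptives`, `base`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mapping <- stage("mapping", read_activity_mapping(config$mapping))
  diaries <- stage("parse", parse_diary_table(config$diaries, mapping))
  covariates <- stage("covariates",
                      utils::read.csv(config$covariates,
                                      stringsAsFactors = FALSE))
  outcomes <- stage("outcomes",
                    utils::read.csv(config$outcomes,
                                    stringsAsFactors = FALSE))
  sample <- stage("build_sample",
                  build_analytic_sample(diaries, covariates, outcomes,
                                        mapping, day_type = config$day_type,
                                        outcome_name = config$outcome_name))
  raw_comp <- sample_compositions(sample)
  sample$data[, sample$parts] <- stage("zero_replacement",
                                       replace_zeros(raw_comp,
                                                     impute = config$impute_minutes))
  basis <- pivot_basis(sample$parts, pivot_order = config$pivot_order)
  model <- stage("fit", fit_outcome_model(sample, basis = basis))
  jt <- stage("joint_test", joint_composition_test(model))
  base <- compositional_mean(sample_compositions(sample))
  pw <- stage("pairwise", pairwise_table(model, base, delta = config$delta))
  grid <- stage("grid", substitution_grid(model, base,
                                          delta_max = config$grid_delta_max,
                                          step = config$grid_step))
  comp_summary <- data.frame(
    behaviour = sample$parts,
    raw_mean = colMeans(raw_comp),
    raw_sd = apply(raw_comp, 2, stats::sd),
    geometric_mean = base,
    stringsAsFactors = FALSE, row.names = NULL
  )
  desc <- describe_sample(sample)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    p <- file.path(out, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  coef_tab <- data.frame(term = names(model$coefficients),
                         estimate = model$coefficients,
                         se = sqrt(diag(model$vcov)),
                         stringsAsFactors = FALSE, row.names = NULL)
  paths <- c(
    removal_log = wcsv(sample$removal_log, "removal_log.csv"),
    sample = wcsv(sample$data, "analytic_sample.csv"),
    composition_summary = wcsv(comp_summary, "composition_summary.csv"),
    coefficients = wcsv(coef_tab, "model_coefficients.csv"),
    covariance = wcsv(as.data.frame(model$vcov), "model_covariance.csv"),
    pairwise = wcsv(pw, "pairwise_substitutions.csv"),
    grid = wcsv(grid, "substitution_grid.csv"),
    descriptives_categorical = wcsv(desc$categorical,
                                    "descriptives_categorical.csv"),
    descriptives_continuous = wcsv(desc$continuous,
                                   "descriptives_continuous.csv")
  )
  run_meta <- list(day_type = config$day_type,
                   outcome = config$outcome_name, n = model$n,
                   impute_minutes = config$impute_minutes,
                   delta = config$delta, seed = config$seed,
                   joint_test = list(F = jt$F, df1 = jt$df1, df2 = jt$df2,
                                     p = jt$p))
  meta_path <- file.path(out, "run_summary.json")
  jsonlite::write_json(run_meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, run_summary = meta_path)

  invisible(list(sample = sample, model = model, joint_test = jt,
                 pairwise = pw, grid = grid,
                 composition_summary = comp_summary, descriptives = desc,
                 base = base, paths = paths, config = config))
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Render report-style tables from pipeline results
#'
#' Formats the composition summary (raw arithmetic mean (SD) alongside the
#' adjusted geometric mean) and the pairwise substitution table (beta and
#' 95% CI at two decimal places with a significance flag) as
#' character-valued data frames suitable for CSV or markdown export.  Full
#' precision remains in the pipeline's CSV outputs.
#'
#' @param results The list returned by [run_pipeline()].
#' @return List with data frames `composition` and `substitution`.
#' @export
render_tables <- function(results) {
  cs <- results$composition_summary
  composition <- data.frame(
    behaviour = cs$behaviour,
    raw_mean_sd = sprintf("%.0f (%.2f)", cs$raw_mean, cs$raw_sd),
    geometric_mean = round(cs$geometric_mean),
    stringsAsFactors = FALSE
  )
  pw <- results$pairwise
  substitution <- data.frame(
    add = pw$add, remove = pw$remove, delta = pw$delta,
    beta = ifelse(pw$feasible, fmt2(pw$beta), "-"),
    ci_95 = ifelse(pw$feasible,
                   sprintf("(%s to %s)", fmt2(pw$ci_low), fmt2(pw$ci_high)),
                   "infeasible"),
    significant = pw$significant,
    stringsAsFactors = FALSE
  )
  list(composition = composition, substitution = substitution)
}
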