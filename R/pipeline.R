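#' Build a pipeline run configuration
#'
#' Collects every knob of the simulate -> filter -> split -> fit -> validate
#' -> compare -> kappa workflow into one validated list. Every stochastic
#' stage draws its own seed deterministically from `seed`, so runs with an
#' identical configuration produce byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param cohort_file Optional path to an existing cohort file; when `NULL`
#'   a cohort is simulated.
#' @param n Number of simulated subjects (ignored with `cohort_file` or
#'   `use_age_bands`).
#' @param use_age_bands Draw simulated ages to the packaged per-band counts
#'   ([willems_table1_age_bands()]) instead of uniformly (default `TRUE`).
#' @param max_age Strict upper age bound for eligibility (default 16).
#' @param test_fraction Test proportion for the stratified split.
#' @param weighting Fit weighting scheme (see [fit_coefficients()]).
#' @param ci_reps Bootstrap resamples for RMSE intervals.
#' @param kappa_weighting `"linear"` or `"quadratic"`.
#' @param disagree_prob Adjacent-stage disagreement probability for the
#'   simulated re-scoring used in the kappa stage.
#' @param compare_with_sa Also validate and compare against the packaged
#'   Saudi Arabian table (default `TRUE`).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, cohort_file = NULL, n = 1334,
                       use_age_bands = TRUE, max_age = 16,
                       test_fraction = 0.5,
                       weighting = c("inv_var_ageband", "uniform"),
                       ci_reps = 2000,
                       kappa_weighting = c("linear", "quadratic"),
                       disagree_prob = 0.05, compare_with_sa = TRUE) {
  weighting <- match.arg(weighting)
  kappa_weighting <- match.arg(kappa_weighting)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!is.null(cohort_file) && !file.exists(cohort_file)) {
    stop("cohort file not found: ", cohort_file, call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_file = cohort_file, n = as.integer(n),
                 use_age_bands = isTRUE(use_age_bands), max_age = max_age,
                 test_fraction = test_fraction, weighting = weighting,
                 ci_reps = as.integer(ci_reps),
                 kappa_weighting = kappa_weighting,
                 disagree_prob = disagree_prob,
                 compare_with_sa = isTRUE(compare_with_sa)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full estimation workflow
#'
#' Executes the configured stage chain -- simulate (or read) a cohort, apply
#' the eligibility filter, stratified train/test split, weighted-ANOVA fit
#' of a sex-specific coefficient table on the training half, validation of
#' the fitted table on the held-out half (ME/MAE/RMSE with bootstrap CIs and
#' Wilcoxon tests, per sex and overall), calibration slopes, a paired
#' comparison against the packaged Saudi Arabian table, and a weighted-kappa
#' observer-agreement analysis on a simulated re-scoring. All tabular
#' outputs are written as CSV under `config$out_dir` together with a JSON
#' manifest (inputs, seeds, per-stage record counts). Identical
#' configurations yield byte-identical outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "dentage",
                   version = as.character(utils::packageVersion("dentage")),
                   config = config[setdiff(names(config), "out_dir")],
                   stages = list())
  current_stage <- "init"
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  result <- tryCatch({
    current_stage <- "cohort"
    if (is.null(config$cohort_file)) {
      params <- default_params_like_study(seed = derive_seed(config$seed, 1))
      bands <- if (config$use_age_bands) willems_table1_age_bands() else NULL
      cohort <- generate_cohort(params, n = config$n,
                                seed = derive_seed(config$seed, 1),
                                band_counts = bands)
    } else {
      cohort <- read_cohort(config$cohort_file)
    }
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    manifest$stages$cohort <- list(n = nrow(cohort),
                                   source = config$cohort_file %||% "simulated")

    current_stage <- "filter"
    eligible <- filter_eligible(cohort, max_age = config$max_age)
    readr::write_csv(exclusion_log(eligible),
                     file.path(config$out_dir, "exclusions.csv"),
                     progress = FALSE)
    write_cohort(eligible, file.path(config$out_dir, "eligible.csv"))
    manifest$stages$filter <- list(
      n_in = nrow(cohort), n_retained = nrow(eligible),
      n_excluded = nrow(cohort) - nrow(eligible))

    current_stage <- "split"
    split <- stratified_split(eligible, test_fraction = config$test_fraction,
                              seed = derive_seed(config$seed, 2))
    write_cohort(split$train, file.path(config$out_dir, "train.csv"))
    write_cohort(split$test, file.path(config$out_dir, "test.csv"))
    manifest$stages$split <- list(n_train = nrow(split$train),
                                  n_test = nrow(split$test))

    current_stage <- "fit"
    fitted <- fit_both_sexes(split$train, weighting = config$weighting,
                             on_alias = "drop")
    write_coefficient_table(fitted,
                            file.path(config$out_dir, "fitted_table.csv"))
    manifest$stages$fit <- list(weighting = config$weighting,
                                n_coefficients = nrow(fitted))

    current_stage <- "predict"
    preds <- suppressWarnings(predict_cohort(fitted, split$test))
    readr::write_csv(preds, file.path(config$out_dir, "predictions.csv"),
                     progress = FALSE)
    manifest$stages$predict <- list(n = nrow(preds))

    current_stage <- "validate"
    groups <- c("M+F", intersect(c("M", "F"), unique(split$test$sex)))
    summaries <- dplyr::bind_rows(lapply(seq_along(groups), function(i) {
      g <- groups[i]
      sel <- if (g == "M+F") preds else preds[preds$sex == g, ]
      error_summary(sel, group = g, ci_reps = config$ci_reps,
                    seed = derive_seed(config$seed, 10 + i))
    }))
    readr::write_csv(summaries, file.path(config$out_dir, "validation.csv"),
                     progress = FALSE)
    manifest$stages$validate <- list(groups = groups)

    current_stage <- "calibrate"
    calib <- dplyr::bind_rows(lapply(
      intersect(c("M", "F"), unique(preds$sex)), function(g) {
        sub <- preds[preds$sex == g, ]
        cs <- calibration_slope(sub$chron_age, sub$estimated_age)
        tibble::tibble(sex = g, slope = cs$slope, intercept = cs$intercept)
      }))
    readr::write_csv(calib, file.path(config$out_dir, "calibration.csv"),
                     progress = FALSE)
    manifest$stages$calibrate <- list(sexes = calib$sex)

    if (config$compare_with_sa) {
      current_stage <- "compare"
      comp <- suppressWarnings(
        compare_methods(split$test, fitted, willems_sa_table(),
                        ci_reps = config$ci_reps,
                        seed = derive_seed(config$seed, 20)))
      readr::write_csv(comp, file.path(config$out_dir, "comparison.csv"),
                       progress = FALSE)
      manifest$stages$compare <- list(table_A = "fitted",
                                      table_B = "Willems SA")
    }

    current_stage <- "kappa"
    rescored <- simulate_rescoring(eligible,
                                   disagree_prob = config$disagree_prob,
                                   seed = derive_seed(config$seed, 30))
    r1 <- unlist(tibble::as_tibble(eligible)[, tooth_columns()],
                 use.names = FALSE)
    r2 <- unlist(tibble::as_tibble(rescored)[, tooth_columns()],
                 use.names = FALSE)
    kp <- weighted_kappa(r1, r2, weighting = config$kappa_weighting)
    readr::write_csv(tibble::tibble(kappa = kp$kappa,
                                    weighting = kp$weighting,
                                    n_items = kp$n_items),
                     file.path(config$out_dir, "kappa.csv"), progress = FALSE)
    manifest$stages$kappa <- list(kappa = kp$kappa,
                                  weighting = kp$weighting)

    manifest$status <- "ok"
    write_manifest()
    manifest
  }, error = function(e) {
    manifest$status <<- "error"
    manifest$failed_stage <<- current_stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
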