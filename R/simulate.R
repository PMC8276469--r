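#' Latent-maturation parameters for the cohort simulator
#'
#' The simulator models tooth development with a per-(sex, tooth, stage)
#' mean attainment age `mu` (years; strictly increasing across stages within
#' each tooth), a shared per-child maturation tempo deviation
#' (`sigma_child`, years) and an independent per-tooth timing deviation
#' (`sigma_tooth`, years). A child of age `a` shows the highest stage `s`
#' with `mu <= a + delta_child + eps_tooth`, and stage `"0"` before any
#' stage is attained, so stages are ordinal and monotone in age by
#' construction.
#'
#' @param mu Data frame with columns `sex`, `tooth`, `stage` (among
#'   `"A"`..`"H"`) and `age` (mean attainment age, years).
#' @param sigma_child Child-level tempo SD in years (default 0.5).
#' @param sigma_tooth Tooth-level timing SD in years (default 0.5).
#' @param age_range Sampled age range in years (default `c(4, 16)`, the
#'   range over which seven-tooth staging methods are used).
#' @param sex_ratio Proportion of males (default 0.528, matching a cohort of
#'   605 boys and 541 girls).
#' @param seed Default seed for [generate_cohort()].
#' @return A `maturation_params` object.
#' @export
maturation_params <- function(mu, sigma_child = 0.5, sigma_tooth = 0.5,
                              age_range = c(4, 16), sex_ratio = 0.528,
                              seed = 1) {
  mu <- tibble::as_tibble(mu)
  stopifnot(all(c("sex", "tooth", "stage", "age") %in% names(mu)))
  mu$sex <- toupper(as.character(mu$sex))
  mu$tooth <- as.integer(mu$tooth)
  mu$stage <- toupper(as.character(mu$stage))
  mu$age <- as.numeric(mu$age)
  if (!all(mu$stage %in% setdiff(stage_levels(), "0"))) {
    stop("mu stages must be among A..H", call. = FALSE)
  }
  if (sigma_child < 0 || sigma_tooth < 0) {
    stop("sigma_child and sigma_tooth must be non-negative", call. = FALSE)
  }
  if (!(length(age_range) == 2 && age_range[1] < age_range[2])) {
    stop("age_range must be an increasing pair of years", call. = FALSE)
  }
  if (!(sex_ratio >= 0 && sex_ratio <= 1)) {
    stop("sex_ratio must be in [0, 1]", call. = FALSE)
  }
  for (s in unique(mu$sex)) {
    for (t in unique(mu$tooth)) {
      sub <- mu[mu$sex == s & mu$tooth == t, ]
      sub <- sub[order(stage_rank(sub$stage)), ]
      if (nrow(sub) > 1 && any(diff(sub$age) <= 0)) {
        stop("mu must be strictly increasing in stage for sex ", s,
             ", tooth ", t, call. = FALSE)
      }
    }
  }
  structure(list(mu = mu, sigma_child = sigma_child,
                 sigma_tooth = sigma_tooth, age_range = age_range,
                 sex_ratio = sex_ratio, seed = seed),
            class = "maturation_params")
}

# ordered attainment-age vector for one (sex, tooth); names are stages
mu_vector <- function(params, sex, tooth) {
  sub <- params$mu[params$mu$sex == sex & params$mu$tooth == tooth, ]
  sub <- sub[order(stage_rank(sub$stage)), ]
  stats::setNames(sub$age, sub$stage)
}

#' Simulate a staged cohort
#'
#' Draws ages (uniform on the parameter age range, or to given per-1-year
#' band counts), sexes, per-child tempo and per-tooth timing deviations, and
#' derives each tooth's Demirjian stage from the latent maturation model in
#' [maturation_params()]. Deterministic given the seed.
#'
#' @param params A `maturation_params` object.
#' @param n Number of subjects (ignored when `band_counts` is given).
#' @param seed Seed (defaults to `params$seed`).
#' @param band_counts Optional data frame with columns `band` (integer year)
#'   and `n`, to mimic a study's per-age-band sample sizes; ages are drawn
#'   uniformly within each band.
#' @return A `dental_cohort`.
#' @export
generate_cohort <- function(params, n, seed = params$seed,
                            band_counts = NULL) {
  stopifnot(inherits(params, "maturation_params"))
  if (is.null(band_counts) && (!is.numeric(n) || n < 1)) {
    stop("n must be >= 1", call. = FALSE)
  }
  with_local_seed(seed, {
    if (!is.null(band_counts)) {
      band_counts <- tibble::as_tibble(band_counts)
      stopifnot(all(c("band", "n") %in% names(band_counts)))
      ages <- unlist(lapply(seq_len(nrow(band_counts)), function(i) {
        stats::runif(band_counts$n[i], band_counts$band[i],
                     band_counts$band[i] + 1)
      }))
      n <- length(ages)
    } else {
      ages <- stats::runif(n, params$age_range[1], params$age_range[2])
    }
    sex <- sample(c("M", "F"), n, replace = TRUE,
                  prob = c(params$sex_ratio, 1 - params$sex_ratio))
    delta <- stats::rnorm(n, 0, params$sigma_child)
    eps <- matrix(stats::rnorm(n * 7L, 0, params$sigma_tooth), nrow = n)
    stages <- matrix("0", nrow = n, ncol = 7L,
                     dimnames = list(NULL, tooth_columns()))
    for (s in c("M", "F")) {
      rows <- which(sex == s)
      if (length(rows) == 0) next
      for (j in seq_along(fdi_teeth())) {
        muv <- mu_vector(params, s, fdi_teeth()[j])
        if (length(muv) == 0) next
        latent <- ages[rows] + delta[rows] + eps[rows, j]
        idx <- findInterval(latent, muv)
        stages[rows, j] <- c("0", names(muv))[idx + 1L]
      }
    }
    rec <- tibble::as_tibble(as.data.frame(stages,
                                           stringsAsFactors = FALSE))
    rec$subject_id <- sprintf("S%05d", seq_len(n))
    rec$sex <- sex
    rec$chron_age <- ages
    dental_cohort(rec, provenance = sprintf("simulated (n=%d, seed=%s)", n,
                                            format(seed)))
  })
}

#' Marginal stage distribution of a cohort
#'
#' Percentage of subjects at each developmental stage, per sex and tooth.
#' Each (sex, tooth) column covers the full `0`..`H` scale and sums to 100.
#'
#' @param cohort A `dental_cohort`.
#' @return Tibble with columns `sex`, `tooth`, `stage`, `percent`.
#' @export
stage_distribution <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  rows <- list()
  for (s in intersect(c("M", "F"), unique(cohort$sex))) {
    sub <- cohort[cohort$sex == s, ]
    for (j in seq_along(fdi_teeth())) {
      st <- factor(sub[[tooth_columns()[j]]], levels = stage_levels())
      pct <- 100 * as.numeric(table(st)) / sum(!is.na(st))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = s, tooth = fdi_teeth()[j], stage = stage_levels(),
        percent = pct)
    }
  }
  dplyr::bind_rows(rows)
}

#' Packaged reference stage distribution
#'
#' Per-(sex, tooth) percentages of subjects at Demirjian stages A-H,
#' transcribed from the published distribution for Saudi Arabian children
#' aged 4-16; used to calibrate [default_params_like_study()].
#'
#' @return Tibble with columns `sex`, `tooth`, `stage`, `percent`.
#' @export
willems_table2_distribution <- function() {
  path <- system.file("extdata", "table2_stage_distribution.csv",
                      package = "dentage", mustWork = TRUE)
  readr::read_csv(path, col_types = "cicd", progress = FALSE)
}

#' Packaged reference age-band sample sizes
#'
#' Subjects per 1-year age band in the source study's sample (bands 4-17),
#' usable as `band_counts` in [generate_cohort()].
#'
#' @return Tibble with columns `band`, `n`.
#' @export
willems_table1_age_bands <- function() {
  path <- system.file("extdata", "table1_age_bands.csv",
                      package = "dentage", mustWork = TRUE)
  readr::read_csv(path, col_types = "ii", progress = FALSE)
}

# marginal probability that a uniform(lo, hi) age with Normal(0, sigma)
# latent noise has attained threshold m: E_a[ pnorm((a - m)/sigma) ]
marginal_attainment <- function(m, lo, hi, sigma) {
  G <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  (sigma / (hi - lo)) * (G((hi - m) / sigma) - G((lo - m) / sigma))
}

#' Calibrate simulator parameters to a reference stage distribution
#'
#' Chooses mean attainment ages `mu` so that, for ages uniform on
#' `age_range` with the given latent noise, the model-implied marginal
#' probability of having attained each stage matches the reference
#' cumulative stage frequencies. The inversion is deterministic (closed-form
#' marginal attainment probability, solved per cell by root finding);
#' cumulative targets are clamped away from 0 and 1, and attainment ages are
#' kept strictly increasing across stages.
#'
#' @param sex_tables Reference distribution as from
#'   [willems_table2_distribution()].
#' @param age_range,sigma_child,sigma_tooth,sex_ratio,seed Passed through to
#'   [maturation_params()].
#' @param clamp Cumulative-probability clamp (default 1e-3).
#' @param min_gap Minimum spacing between consecutive stage attainment ages
#'   in years (default 0.01).
#' @return A `maturation_params` object.
#' @export
default_params_like_study <- function(sex_tables = willems_table2_distribution(),
                                      age_range = c(4, 16),
                                      sigma_child = 0.5, sigma_tooth = 0.5,
                                      sex_ratio = 0.528, seed = 1,
                                      clamp = 1e-3, min_gap = 0.01) {
  sex_tables <- tibble::as_tibble(sex_tables)
  stopifnot(all(c("sex", "tooth", "stage", "percent") %in% names(sex_tables)))
  sigma <- sqrt(sigma_child^2 + sigma_tooth^2)
  if (sigma <= 0) sigma <- 1e-6
  lo <- age_range[1]; hi <- age_range[2]
  span <- c(lo - 10 * sigma - (hi - lo), hi + 10 * sigma)
  rows <- list()
  for (s in unique(sex_tables$sex)) {
    for (t in unique(sex_tables$tooth)) {
      sub <- sex_tables[sex_tables$sex == s & sex_tables$tooth == t, ]
      if (nrow(sub) == 0) next
      sub <- sub[order(stage_rank(sub$stage)), ]
      total <- sum(sub$percent)
      # cumulative probability of having reached stage >= s
      q <- rev(cumsum(rev(sub$percent))) / total
      q <- pmin(pmax(q, clamp), 1 - clamp)
      prev <- -Inf
      for (i in seq_len(nrow(sub))) {
        root <- stats::uniroot(function(m) {
          marginal_attainment(m, lo, hi, sigma) - q[i]
        }, interval = span, tol = 1e-9)$root
        m <- max(root, prev + min_gap)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sex = s, tooth = t, stage = sub$stage[i], age = m)
        prev <- m
      }
    }
  }
  maturation_params(dplyr::bind_rows(rows), sigma_child = sigma_child,
                    sigma_tooth = sigma_tooth, age_range = age_range,
                    sex_ratio = sex_ratio, seed = seed)
}

#' Overwrite ages with a known additive truth plus noise
#'
#' Parameter-recovery harness: replaces each chronological age with the
#' prediction of a known coefficient table for the subject's stages plus
#' Gaussian noise, so the cohort's true generating model is exactly that
#' table. Resulting ages at or below 0.1 years are floored at 0.1 (the count
#' is recorded in attribute `"n_clipped"`).
#'
#' @param cohort A `dental_cohort` without missing stages.
#' @param truth A `coef_table` with an explicit entry for every
#'   (sex, tooth, stage) present in the cohort.
#' @param noise_sd Age noise SD in years.
#' @param seed Seed for the noise draw.
#' @return The cohort with replaced `chron_age`.
#' @export
attach_additive_ages <- function(cohort, truth, noise_sd, seed = NULL) {
  stopifnot(inherits(cohort, "dental_cohort"), inherits(truth, "coef_table"))
  stages <- as.matrix(tibble::as_tibble(cohort)[, tooth_columns()])
  if (anyNA(stages)) stop("cohort has missing stages", call. = FALSE)
  n <- nrow(cohort)
  key <- unique(paste(rep(cohort$sex, 7L), rep(fdi_teeth(), each = n),
                      as.vector(stages)))
  known <- paste(truth$sex, truth$tooth, truth$stage)
  uncovered <- setdiff(key, known)
  if (length(uncovered) > 0) {
    stop("truth table does not cover observed stage(s): ",
         paste(utils::head(uncovered, 5), collapse = "; "), call. = FALSE)
  }
  est <- estimate_age(truth, cohort, warn_fallback = FALSE)
  new_age <- with_local_seed(seed, est + stats::rnorm(n, 0, noise_sd))
  clipped <- new_age < 0.1
  new_age[clipped] <- 0.1
  out <- cohort
  out$chron_age <- new_age
  class(out) <- class(cohort)
  attr(out, "provenance") <- paste0(attr(cohort, "provenance"),
                                    " + additive truth ages")
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Simulate a second scoring of the same radiographs
#'
#' Emulates observer disagreement for kappa analyses: each stage is
#' independently mis-scored by one adjacent stage with probability
#' `disagree_prob` (clamped at the ends of the scale).
#'
#' @param cohort A `dental_cohort`.
#' @param disagree_prob Per-tooth probability of an adjacent-stage
#'   disagreement (default 0.05).
#' @param seed Seed.
#' @param observer_id Label stored in the `observer_id` column.
#' @return A `dental_cohort` of re-scored records.
#' @export
simulate_rescoring <- function(cohort, disagree_prob = 0.05, seed = NULL,
                               observer_id = "obs2") {
  stopifnot(inherits(cohort, "dental_cohort"))
  out <- tibble::as_tibble(cohort)
  with_local_seed(seed, {
    for (col in tooth_columns()) {
      st <- out[[col]]
      r <- stage_rank(st)
      flip <- stats::runif(length(r)) < disagree_prob
      dir <- sample(c(-1L, 1L), length(r), replace = TRUE)
      r2 <- pmin(pmax(r + ifelse(flip, dir, 0L), 1L), length(stage_levels()))
      out[[col]] <- ifelse(is.na(st), NA_character_, stage_levels()[r2])
    }
  })
  out$observer_id <- observer_id
  dental_cohort(out, provenance = paste0(attr(cohort, "provenance"),
                                         " re-scored by ", observer_id))
}
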