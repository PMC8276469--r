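#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of symmetry of the paired differences about zero. Zero
#' differences are dropped (classic Wilcoxon convention) and counted. For
#' `n <= exact_max` non-zero differences the null distribution of the
#' positive-rank sum is computed exactly by enumerating it over all sign
#' assignments (dynamic programming over doubled midranks, so ties are
#' handled exactly); above that a normal approximation with continuity and
#' tie correction is used. If every difference is zero the test is
#' degenerate and `p = 1` is reported.
#'
#' @param x Numeric vector: first member of each pair, or the differences
#'   themselves when `y` is `NULL`.
#' @param y Optional numeric vector paired with `x`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) selects it automatically for `n <= exact_max`.
#' @param exact_max Largest `n` for the automatic exact path (default 25).
#' @return List with `statistic` (positive-rank sum W+), `p_value`,
#'   `n_used`, `n_zero`, `method` and a `degenerate` flag.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))   # exact two-sided p = 0.25
wilcoxon_signed_rank <- function(x, y = NULL, exact = NULL, exact_max = 25) {
  d <- if (is.null(y)) as.numeric(x) else {
    stopifnot(length(x) == length(y))
    as.numeric(x) - as.numeric(y)
  }
  if (length(d) < 1) stop("need at least one pair", call. = FALSE)
  if (anyNA(d)) stop("differences contain NA", call. = FALSE)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_used = 0L, n_zero = n_zero,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  use_exact <- if (is.null(exact)) n <= exact_max else isTRUE(exact)
  if (use_exact) {
    # distribution of 2*W+ over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    f <- numeric(sum(r2) + 1L)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
      f <- f + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(f[seq_len(w2 + 1L)]) / total
    p_ge <- sum(f[(w2 + 1L):length(f)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      return(list(statistic = W, p_value = 1, n_used = n, n_zero = n_zero,
                  method = "degenerate", degenerate = TRUE))
    }
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = W, p_value = p, n_used = n, n_zero = n_zero,
       method = method, degenerate = FALSE)
}

as_error_vector <- function(outcomes) {
  if (is.numeric(outcomes)) return(as.numeric(outcomes))
  outcomes <- tibble::as_tibble(outcomes)
  if (!"error" %in% names(outcomes)) {
    stop("outcomes must be numeric errors or carry an 'error' column",
         call. = FALSE)
  }
  as.numeric(outcomes$error)
}

#' Summarise prediction errors (ME, MAE, RMSE)
#'
#' For signed per-subject errors `e = chronological - estimated age`,
#' computes the mean error (direction of bias; negative means
#' overestimation), mean absolute error (magnitude), and root mean square
#' error (spread, weighting large errors more), with sample SDs, a
#' subject-level percentile-bootstrap 95% confidence interval for the RMSE,
#' and the two-sided Wilcoxon signed-rank p-value comparing chronological
#' with estimated age.
#'
#' @param outcomes Output of [predict_cohort()], or a numeric vector of
#'   signed errors.
#' @param group Label for the summarised group (e.g. `"M"`, `"F"`, `"M+F"`).
#' @param ci_reps Bootstrap resamples for the RMSE interval (default 2000).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `group`, `n`, `me`, `me_sd`, `mae`, `mae_sd`,
#'   `rmse`, `rmse_ci_low`, `rmse_ci_high`, `wilcoxon_p`, `note`.
#' @export
#' @examples
#' error_summary(c(3, -1, 2, -2, 0), seed = 1)
error_summary <- function(outcomes, group = "M+F", ci_reps = 2000,
                          seed = NULL) {
  e <- as_error_vector(outcomes)
  n <- length(e)
  if (n == 0) stop("cannot summarise zero outcomes", call. = FALSE)
  me <- mean(e)
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  wt <- wilcoxon_signed_rank(e)
  note <- if (wt$degenerate) "wilcoxon degenerate (all errors zero)" else ""
  if (n == 1) {
    return(tibble::tibble(group = group, n = n, me = me, me_sd = NA_real_,
                          mae = mae, mae_sd = NA_real_, rmse = rmse,
                          rmse_ci_low = NA_real_, rmse_ci_high = NA_real_,
                          wilcoxon_p = wt$p_value,
                          note = paste("single subject: SD/CI undefined;",
                                       note)))
  }
  ci <- bootstrap_rmse_ci(e, ci_reps = ci_reps, seed = seed)
  tibble::tibble(group = group, n = n, me = me, me_sd = stats::sd(e),
                 mae = mae, mae_sd = stats::sd(abs(e)), rmse = rmse,
                 rmse_ci_low = ci[1], rmse_ci_high = ci[2],
                 wilcoxon_p = wt$p_value, note = note)
}

# Percentile bootstrap over subjects for the RMSE.
bootstrap_rmse_ci <- function(e, ci_reps = 2000, seed = NULL, level = 0.95) {
  n <- length(e)
  boot <- with_local_seed(seed, {
    idx <- sample.int(n, n * ci_reps, replace = TRUE)
    sqrt(colMeans(matrix(e[idx]^2, nrow = n)))
  })
  alpha <- (1 - level) / 2
  as.numeric(stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE))
}

#' Paired comparison of two coefficient tables on one cohort
#'
#' Predicts every subject with both tables, then summarises the per-subject
#' paired differences in signed error and absolute error per sex and
#' overall, mirroring a method-comparison table: mean errors under each
#' method, the mean pairwise difference (`A - B`) with its SD and Wilcoxon
#' signed-rank p-value, and each method's RMSE with bootstrap confidence
#' intervals.
#'
#' @param cohort An eligible `dental_cohort`.
#' @param table_A,table_B `coef_table`s to compare.
#' @param ci_reps,seed Bootstrap controls for the RMSE intervals.
#' @return Tibble with one row per group (`"M+F"` and each sex present).
#' @export
compare_methods <- function(cohort, table_A, table_B, ci_reps = 2000,
                            seed = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) stop("cannot compare on an empty cohort", call. = FALSE)
  pa <- predict_cohort(table_A, cohort)
  pb <- predict_cohort(table_B, cohort)
  groups <- c("M+F", intersect(c("M", "F"), unique(cohort$sex)))
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    sel <- if (g == "M+F") rep(TRUE, nrow(cohort)) else cohort$sex == g
    ea <- pa$error[sel]; eb <- pb$error[sel]
    d <- ea - eb
    ad <- abs(ea) - abs(eb)
    wt_me <- wilcoxon_signed_rank(d)
    wt_mae <- wilcoxon_signed_rank(abs(ea), abs(eb))
    ci_a <- bootstrap_rmse_ci(ea, ci_reps, derive_seed(seed, 2 * gi))
    ci_b <- bootstrap_rmse_ci(eb, ci_reps, derive_seed(seed, 2 * gi + 1))
    tibble::tibble(
      group = g, n = length(ea),
      me_A = mean(ea), me_B = mean(eb),
      me_diff = mean(d), me_diff_sd = stats::sd(d), p_me = wt_me$p_value,
      mae_A = mean(abs(ea)), mae_B = mean(abs(eb)),
      mae_diff = mean(ad), mae_diff_sd = stats::sd(ad),
      p_mae = wt_mae$p_value,
      rmse_A = sqrt(mean(ea^2)), rmse_A_ci_low = ci_a[1],
      rmse_A_ci_high = ci_a[2],
      rmse_B = sqrt(mean(eb^2)), rmse_B_ci_low = ci_b[1],
      rmse_B_ci_high = ci_b[2],
      degenerate = wt_me$degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Calibration line of predicted on chronological age
#'
#' Ordinary least-squares fit of predicted age on chronological age; a slope
#' of 1 and intercept of 0 indicate perfect calibration.
#'
#' @param chron Chronological ages (years), `n >= 3`, non-constant.
#' @param predicted Predicted ages (years).
#' @return List with `slope` and `intercept`.
#' @export
calibration_slope <- function(chron, predicted) {
  stopifnot(length(chron) == length(predicted))
  if (length(chron) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(chron) == 0) {
    stop("chronological ages have zero variance", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ chron)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Weighted kappa for ordinal stage ratings
#'
#' Chance-corrected agreement between two raters on an ordered scale,
#' penalising disagreements by their distance: with `k` categories the
#' disagreement weight between categories `i` and `j` is `|i - j|/(k - 1)`
#' (linear) or its square (quadratic), and
#' `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed joint
#' proportion table and `E` the product of the marginals. With quadratic
#' weights on a 2-level scale this reduces to unweighted Cohen's kappa.
#'
#' @param r1,r2 Equal-length rating vectors on `levels`.
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @param levels Ordered category levels; defaults to the nine-stage dental
#'   scale [stage_levels()].
#' @return List with `kappa`, `weighting`, `n_items` and a `degenerate` flag
#'   (`TRUE`, with `kappa = NA`, when chance agreement is perfect because a
#'   rater shows no variation).
#' @export
weighted_kappa <- function(r1, r2, weighting = c("linear", "quadratic"),
                           levels = stage_levels()) {
  weighting <- match.arg(weighting)
  stopifnot(length(r1) == length(r2))
  f1 <- factor(as.character(r1), levels = levels)
  f2 <- factor(as.character(r2), levels = levels)
  if (anyNA(f1) || anyNA(f2)) {
    stop("ratings contain values outside the rating scale", call. = FALSE)
  }
  n <- length(f1)
  if (n == 0) stop("no ratings", call. = FALSE)
  k <- length(levels)
  O <- table(f1, f2) / n
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (weighting == "quadratic") w <- w^2
  E <- outer(rowSums(O), colSums(O))
  denom <- sum(w * E)
  if (denom == 0) {
    return(list(kappa = NA_real_, weighting = weighting, n_items = n,
                degenerate = TRUE))
  }
  list(kappa = 1 - sum(w * O) / denom, weighting = weighting, n_items = n,
       degenerate = FALSE)
}
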