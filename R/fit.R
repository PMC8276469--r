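#' Sex- and age-stratified train/test split
#'
#' Partitions a cohort into training and test sets at random within strata
#' defined by sex crossed with age bands (default 1 year), so both sets share
#' the cohort's sex and age structure. Each stratum of size `n` contributes
#' `floor(n * test_fraction + 0.5)` records (round half up) to the test set.
#' A stratum with a single record cannot be split and goes to training with a
#' warning. The split is deterministic given `seed`.
#'
#' @param cohort A `dental_cohort`.
#' @param test_fraction Proportion of each stratum assigned to the test set,
#'   in (0, 1). Default 0.5.
#' @param seed Integer seed controlling the within-stratum draw.
#' @param band_width Age band width in years (default 1).
#' @return List with elements `train` and `test`, both `dental_cohort`s in
#'   original row order.
#' @export
stratified_split <- function(cohort, test_fraction = 0.5, seed = 1,
                             band_width = 1) {
  stopifnot(inherits(cohort, "dental_cohort"))
  if (nrow(cohort) == 0) stop("cannot split an empty cohort", call. = FALSE)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  key <- paste(cohort$sex, floor(cohort$chron_age / band_width))
  test_rows <- integer(0)
  singletons <- 0L
  with_local_seed(seed, {
    for (k in sort(unique(key))) {
      idx <- which(key == k)
      n_s <- length(idx)
      if (n_s == 1L) {
        singletons <- singletons + 1L
        next
      }
      n_test <- floor(n_s * test_fraction + 0.5)
      if (n_test > 0) {
        test_rows <- c(test_rows, idx[sample.int(n_s, n_test)])
      }
    }
  })
  if (singletons > 0) {
    warning(singletons, " stratum/strata of size 1 assigned to training",
            call. = FALSE)
  }
  in_test <- sort(test_rows)
  subset_keep <- function(rows) {
    out <- cohort[rows, ]
    class(out) <- class(cohort)
    attr(out, "provenance") <- attr(cohort, "provenance")
    out
  }
  list(train = subset_keep(setdiff(seq_len(nrow(cohort)), in_test)),
       test = subset_keep(in_test))
}

# Build the dummy-coded design matrix for one sex: an intercept plus, per
# tooth, indicator columns for every observed stage above that tooth's
# lowest observed stage (the reference).
build_stage_design <- function(data) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  ref <- list()
  for (t in fdi_teeth()) {
    st <- data[[paste0("t", t)]]
    obs <- unique(st)
    obs <- obs[order(stage_rank(obs))]
    ref[[as.character(t)]] <- obs[1]
    for (s in obs[-1]) {
      cols[[paste0("t", t, ".", s)]] <- as.numeric(st == s)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, reference = ref)
}

#' Fit a single-sex coefficient table by weighted ANOVA
#'
#' Regresses chronological age on per-tooth Demirjian stage indicator blocks
#' by weighted least squares -- the weighted analysis-of-variance approach
#' used to build Willems-style score tables. Each tooth's lowest observed
#' stage is its reference level (coefficient 0); the intercept is folded into
#' tooth 31's coefficients (including its reference stage) so the fitted
#' table predicts by a pure seven-term sum via [estimate_age()].
#'
#' Two weighting schemes are available: `"uniform"` (ordinary least squares)
#' and `"inv_var_ageband"` (two-pass: residual variance of an OLS fit is
#' estimated per 1-year age band, and records are weighted by its inverse).
#'
#' @param train A `dental_cohort` of training records (no missing stages).
#' @param sex `"M"` or `"F"`: which records to fit.
#' @param weighting Weighting scheme id.
#' @param band_width Age band width in years for the `inv_var_ageband`
#'   scheme.
#' @param on_alias What to do when stage levels are perfectly confounded
#'   (rank-deficient design): `"error"` (default) stops naming the aliased
#'   levels; `"drop"` removes the aliased columns with a warning, so those
#'   levels get no coefficient and score 0 at prediction time.
#' @return A `dentage_fit`: list with the fitted `coef_table` (`$table`),
#'   the weight vector used, and diagnostics (residual SD, per-band counts,
#'   per-tooth reference stages).
#' @export
fit_coefficients <- function(train, sex,
                             weighting = c("inv_var_ageband", "uniform"),
                             band_width = 1,
                             on_alias = c("error", "drop")) {
  weighting <- match.arg(weighting)
  on_alias <- match.arg(on_alias)
  stopifnot(sex %in% c("M", "F"))
  data <- tibble::as_tibble(train)
  data <- data[data$sex == sex, ]
  if (nrow(data) == 0) stop("no training records for sex ", sex, call. = FALSE)
  stages <- as.matrix(data[, tooth_columns()])
  if (anyNA(stages)) {
    stop("training cohort contains missing stages; apply filter_eligible()",
         call. = FALSE)
  }
  design <- build_stage_design(data)
  X <- design$X
  if (ncol(X) == 1L) {
    stop("rank-deficient design: every record has the same stage vector; ",
         "no stage contrasts are estimable", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    if (on_alias == "error") {
      stop("rank-deficient design: aliased stage level(s) ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    warning("dropping aliased stage level(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    if (ncol(X) == 1L) {
      stop("rank-deficient design: no estimable stage contrasts remain",
           call. = FALSE)
    }
  }
  y <- data$chron_age
  w <- rep(1, nrow(data))
  band_tab <- NULL
  if (weighting == "inv_var_ageband") {
    ols <- stats::lm.fit(X, y)
    res <- ols$residuals
    band <- floor(y / band_width)
    overall <- stats::var(res)
    bv <- tapply(res, band, function(r) {
      if (length(r) < 2) return(NA_real_)
      stats::var(r)
    })
    bv[!is.finite(bv) | bv <= 0] <- overall
    if (!is.finite(overall) || overall <= 0) bv[] <- 1
    w <- 1 / as.numeric(bv[as.character(band)])
    band_tab <- tibble::tibble(band = as.numeric(names(bv)),
                               n = as.integer(table(band)),
                               residual_var = as.numeric(bv))
  }
  wfit <- stats::lm.wfit(X, y, w)
  beta <- wfit$coefficients
  b0 <- beta[["(Intercept)"]]
  entries <- list()
  for (t in fdi_teeth()) {
    st <- data[[paste0("t", t)]]
    obs <- unique(st)
    obs <- obs[order(stage_rank(obs))]
    for (s in obs) {
      coef_name <- paste0("t", t, ".", s)
      is_ref <- s == obs[1]
      if (!is_ref && !coef_name %in% names(beta)) next  # aliased, dropped
      b <- if (coef_name %in% names(beta)) beta[[coef_name]] else 0
      score <- b + if (t == 31L) b0 else 0
      entries[[length(entries) + 1L]] <-
        tibble::tibble(sex = sex, tooth = t, stage = s, score = score)
    }
  }
  tab <- coef_table(dplyr::bind_rows(entries),
                    name = paste0("fitted-", sex),
                    provenance = paste0("weighted ANOVA fit (", weighting,
                                        ") on ", nrow(data), " records"))
  attr(tab, "fitted") <- TRUE
  structure(list(
    table = tab,
    sex = sex,
    fitted_on = attr(train, "provenance"),
    weighting = weighting,
    weights_used = w,
    diagnostics = list(
      n = nrow(data),
      residual_sd = stats::sd(wfit$residuals),
      reference_stages = design$reference,
      age_band_weights = band_tab)
  ), class = "dentage_fit")
}

#' Fit both sexes into one coefficient table
#'
#' Runs [fit_coefficients()] independently for males and females and
#' concatenates the two tables; the sexes share no parameters, so the result
#' is identical to the two separate fits. If one sex is absent a partial
#' table is returned with a warning.
#'
#' @inheritParams fit_coefficients
#' @return A `coef_table` covering the sexes present in `train`, with the
#'   per-sex `dentage_fit` objects in attribute `"fits"`.
#' @export
fit_both_sexes <- function(train, weighting = c("inv_var_ageband", "uniform"),
                           band_width = 1, on_alias = c("error", "drop")) {
  weighting <- match.arg(weighting)
  on_alias <- match.arg(on_alias)
  present <- intersect(c("M", "F"), unique(train$sex))
  if (length(present) == 0) stop("no records to fit", call. = FALSE)
  if (length(present) == 1) {
    warning("only sex ", present, " present; returning a partial table",
            call. = FALSE)
  }
  fits <- lapply(present, function(s) {
    fit_coefficients(train, s, weighting = weighting,
                     band_width = band_width, on_alias = on_alias)
  })
  names(fits) <- present
  tab <- coef_table(dplyr::bind_rows(lapply(fits, function(f) {
    tibble::as_tibble(f$table)
  })), name = "fitted",
     provenance = paste0("weighted ANOVA fit (", weighting, "), sexes: ",
                         paste(present, collapse = "+")))
  attr(tab, "fitted") <- TRUE
  attr(tab, "fits") <- fits
  tab
}
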