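test_that("stratified split honours the round-half-up stratum counts", {
  # single stratum of 10, fraction 0.5 -> 5/5
  co <- make_cohort(rep(10.2, 10) + (0:9) * 0.05, "DDEEEGD")
  sp <- stratified_split(co, test_fraction = 0.5, seed = 3)
  expect_equal(nrow(sp$test), 5L)
  expect_equal(nrow(sp$train), 5L)
  # 4 strata (2 sexes x 2 bands) of 25, fraction 0.3 -> 8 each (7.5 rounds up)
  ages <- rep(c(rep(9.5, 25), rep(10.5, 25)), 2)
  sexes <- rep(c("M", "F"), each = 50)
  co <- make_cohort(ages + seq_along(ages) * 1e-4, "DDEEEGD", sex = sexes)
  sp <- stratified_split(co, test_fraction = 0.3, seed = 11)
  expect_equal(nrow(sp$test), 32L)
  expect_equal(nrow(sp$train), 68L)
})

test_that("splits partition the cohort and are reproducible", {
  co <- random_cohort(200, seed = 21)
  sp1 <- stratified_split(co, test_fraction = 0.4, seed = 99)
  sp2 <- stratified_split(co, test_fraction = 0.4, seed = 99)
  expect_identical(sp1$test$subject_id, sp2$test$subject_id)
  expect_identical(sp1$train$subject_id, sp2$train$subject_id)
  ids <- sort(c(sp1$train$subject_id, sp1$test$subject_id))
  expect_identical(ids, sort(co$subject_id))
  sp3 <- stratified_split(co, test_fraction = 0.4, seed = 100)
  expect_false(identical(sp1$test$subject_id, sp3$test$subject_id))
})

test_that("singleton strata go to training with a warning", {
  co <- make_cohort(c(10.5, 10.6, 14.2), "DDEEEGD")
  expect_warning(sp <- stratified_split(co, test_fraction = 0.5, seed = 1),
                 "size 1")
  expect_true("s003" %in% sp$train$subject_id)
})

test_that("noise-free additive ages are recovered exactly", {
  truth <- recovery_truth()
  co <- recovery_cohort(400, seed = 8)
  co <- attach_additive_ages(co, truth, noise_sd = 0, seed = 9)
  for (sx in c("M", "F")) {
    fit <- fit_coefficients(co, sx, weighting = "uniform")
    got <- tibble::as_tibble(fit$table)
    want <- tibble::as_tibble(truth)
    m <- dplyr::inner_join(got, want, by = c("sex", "tooth", "stage"),
                           suffix = c(".fit", ".true"))
    expect_equal(nrow(m), 63L)
    expect_lt(max(abs(m$score.fit - m$score.true)), 1e-8)
  }
})

test_that("fitted tables reproduce the weighted-least-squares fitted values", {
  truth <- recovery_truth()
  co <- attach_additive_ages(recovery_cohort(300, seed = 12), truth,
                             noise_sd = 0.4, seed = 13)
  for (scheme in c("uniform", "inv_var_ageband")) {
    fit <- fit_coefficients(co, "F", weighting = scheme)
    sub <- tibble::as_tibble(co[co$sex == "F", ])
    # independent oracle: stats::lm with per-tooth stage factors (reference
    # = lowest observed stage) and the fit's own weight vector
    d <- sub
    for (col in paste0("t", 31:37)) {
      lev <- intersect(stage_levels(), unique(d[[col]]))
      d[[col]] <- factor(d[[col]], levels = lev)
    }
    oracle <- stats::lm(chron_age ~ t31 + t32 + t33 + t34 + t35 + t36 + t37,
                        data = d, weights = fit$weights_used)
    est <- estimate_age(fit$table, sub, warn_fallback = FALSE)
    expect_lt(max(abs(est - unname(stats::fitted(oracle)))), 1e-8)
  }
})

test_that("intercept folding leaves predictions invariant and lands on t31", {
  truth <- recovery_truth()
  co <- attach_additive_ages(recovery_cohort(500, seed = 30), truth,
                             noise_sd = 0.3, seed = 31)
  fit <- fit_coefficients(co, "M", weighting = "uniform")
  sub <- co[co$sex == "M", ]
  est <- estimate_age(fit$table, sub, warn_fallback = FALSE)
  # shifting every training age by c shifts every t31 coefficient by c
  shifted <- co
  shifted$chron_age <- shifted$chron_age + 3
  fit2 <- fit_coefficients(shifted, "M", weighting = "uniform")
  a <- tibble::as_tibble(fit$table)
  b <- tibble::as_tibble(fit2$table)
  m <- dplyr::inner_join(a, b, by = c("sex", "tooth", "stage"))
  d31 <- m$score.y[m$tooth == 31] - m$score.x[m$tooth == 31]
  rest <- m$score.y[m$tooth != 31] - m$score.x[m$tooth != 31]
  expect_equal(d31, rep(3, length(d31)), tolerance = 1e-8)
  expect_lt(max(abs(rest)), 1e-8)
  # references of teeth 32..37 score exactly 0
  refs <- a[a$tooth != 31 & a$stage == "0", ]
  expect_equal(refs$score, rep(0, nrow(refs)))
  expect_equal(est, estimate_age(fit$table, sub, warn_fallback = FALSE))
})

test_that("degenerate designs raise rank-deficiency errors", {
  co <- make_cohort(ages = 8 + (1:20) * 0.1, stages = "DDEEEGD")
  expect_error(fit_coefficients(co, "M"), "rank-deficient")
  # two perfectly confounded stage levels across teeth
  co2 <- make_cohort(ages = c(8, 9, 8.5, 9.5), stages = c("DDEEEGD",
                     "EDEEEGD", "DDEEEGD", "EDEEEGD"))
  co2b <- tibble::as_tibble(co2)
  co2b$t32 <- ifelse(co2b$t31 == "E", "F", "D")  # t32=F iff t31=E
  expect_error(fit_coefficients(dental_cohort(co2b), "M"), "aliased")
  expect_error(fit_coefficients(co[0, ], "M"), "no training records")
})

test_that("fitting both sexes equals the two independent fits", {
  truth <- recovery_truth()
  co <- attach_additive_ages(recovery_cohort(400, seed = 44), truth,
                             noise_sd = 0.3, seed = 45)
  joint <- fit_both_sexes(co, weighting = "uniform")
  for (sx in c("M", "F")) {
    single <- fit_coefficients(co, sx, weighting = "uniform")
    a <- tibble::as_tibble(joint)
    a <- a[a$sex == sx, ]
    b <- tibble::as_tibble(single$table)
    m <- dplyr::inner_join(a, b, by = c("sex", "tooth", "stage"))
    expect_equal(nrow(m), nrow(b))
    expect_equal(m$score.x, m$score.y, tolerance = 1e-12)
  }
})

test_that("a single-sex cohort yields a partial table with a warning", {
  truth <- recovery_truth()
  co <- attach_additive_ages(recovery_cohort(200, seed = 50), truth,
                             noise_sd = 0.3, seed = 51)
  males <- co[co$sex == "M", ]
  class(males) <- class(co)
  expect_warning(tab <- fit_both_sexes(males, weighting = "uniform"),
                 "partial")
  expect_setequal(unique(tab$sex), "M")
})

test_that("recovery bias shrinks as the cohort grows", {
  truth <- recovery_truth()
  errs <- vapply(c(250, 1000, 4000), function(n) {
    co <- attach_additive_ages(recovery_cohort(n, seed = 60 + n), truth,
                               noise_sd = 0.25, seed = 61 + n)
    fit <- fit_coefficients(co, "M", weighting = "uniform")
    m <- dplyr::inner_join(tibble::as_tibble(fit$table),
                           tibble::as_tibble(truth),
                           by = c("sex", "tooth", "stage"))
    max(abs(m$score.x - m$score.y))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.08)
})
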