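test_that("ME/MAE/RMSE match hand arithmetic", {
  s <- error_summary(c(1, -1), ci_reps = 200, seed = 1)
  expect_equal(s$me, 0)
  expect_equal(s$mae, 1)
  expect_equal(s$rmse, 1)

  s <- error_summary(c(3, -1, 2, -2, 0), ci_reps = 200, seed = 1)
  expect_equal(s$me, 0.4, tolerance = 1e-12)
  expect_equal(s$mae, 1.6, tolerance = 1e-12)
  expect_equal(s$rmse, sqrt(18 / 5), tolerance = 1e-12)

  s <- error_summary(c(0, 0, 0), ci_reps = 200, seed = 1)
  expect_equal(s$me, 0)
  expect_equal(s$mae, 0)
  expect_equal(s$rmse, 0)
  expect_match(s$note, "degenerate")
  expect_equal(s$wilcoxon_p, 1)
})

test_that("rmse^2 decomposes into me^2 plus population variance", {
  set.seed(202)
  for (i in 1:50) {
    e <- rnorm(sample(3:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0, 3))
    s <- suppressWarnings(error_summary(e, ci_reps = 50, seed = i))
    pop_var <- mean((e - mean(e))^2)
    expect_equal(s$rmse^2, s$me^2 + pop_var, tolerance = 1e-10)
  }
})

test_that("error_summary is permutation-invariant and size-aware", {
  e <- c(1.2, -0.4, 0.3, 2.2, -1.7, 0.05)
  a <- error_summary(e, ci_reps = 500, seed = 42)
  b <- error_summary(sample(e), ci_reps = 500, seed = 42)
  expect_equal(a[, c("me", "me_sd", "mae", "mae_sd", "rmse", "wilcoxon_p")],
               b[, c("me", "me_sd", "mae", "mae_sd", "rmse", "wilcoxon_p")])
  expect_error(error_summary(numeric(0)), "zero")
  one <- error_summary(0.5)
  expect_true(is.na(one$me_sd))
  expect_match(one$note, "single subject")
})

test_that("bootstrap RMSE interval brackets the point estimate", {
  set.seed(9)
  e <- rnorm(100, 0, 1.5)
  s <- error_summary(e, ci_reps = 2000, seed = 10)
  expect_lte(s$rmse_ci_low, s$rmse)
  expect_gte(s$rmse_ci_high, s$rmse)
  expect_gte(s$mae, abs(s$me))
  expect_gte(s$rmse, s$mae)
})

test_that("wilcoxon exact path matches textbook cases and wilcox.test", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")

  expect_equal(wilcoxon_signed_rank(c(2, 2), c(2, 2))$p_value, 1)
  expect_true(wilcoxon_signed_rank(rep(0.5, 4), rep(0.5, 4))$degenerate)

  # cross-check against the reference implementation (no ties, exact)
  set.seed(77)
  for (i in 1:10) {
    d <- round(rnorm(15), 6)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("wilcoxon exact path equals brute-force sign enumeration", {
  set.seed(88)
  cases <- c(lapply(1:6, function(i) rnorm(sample(3:10, 1))),
             list(c(1, 1, 2, 3), c(-1, 1, 2, -2, 3),  # ties
                  c(0, 0, 1, -2, 3)))                 # zeros dropped
  for (d in cases) {
    expect_equal(wilcoxon_signed_rank(d, exact = TRUE)$p_value,
                 brute_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact path at moderate n", {
  set.seed(123)
  for (i in 1:8) {
    d <- rnorm(12, mean = runif(1, -0.5, 0.5))
    pe <- wilcoxon_signed_rank(d, exact = TRUE)$p_value
    pa <- wilcoxon_signed_rank(d, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("zero differences are dropped and counted", {
  r <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(r$n_zero, 2L)
  expect_equal(r$n_used, 3L)
  expect_equal(r$p_value, 0.25)
})

test_that("compare_methods on identical tables is degenerate", {
  tab <- willems_sa_table()
  co <- filter_eligible(random_cohort(60, seed = 14))
  cmp <- suppressWarnings(compare_methods(co, tab, tab, ci_reps = 100,
                                          seed = 2))
  expect_true(all(cmp$me_diff == 0))
  expect_true(all(cmp$mae_diff == 0))
  expect_true(all(cmp$degenerate))
})

test_that("a single perturbed cell shifts the mean error difference by it", {
  tab_a <- willems_sa_table()
  ent <- tibble::as_tibble(tab_a)
  ent$score[ent$sex == "M" & ent$tooth == 37 & ent$stage == "H"] <-
    ent$score[ent$sex == "M" & ent$tooth == 37 & ent$stage == "H"] + 0.5
  tab_b <- coef_table(ent)
  # every male subject has t37 at H, so error_B = error_A - 0.5 pairwise
  co <- make_cohort(ages = seq(8, 15, length.out = 12),
                    stages = "DDEEEGH", sex = "M")
  cmp <- suppressWarnings(compare_methods(co, tab_a, tab_b, ci_reps = 100,
                                          seed = 3))
  expect_equal(cmp$me_diff[cmp$group == "M+F"], 0.5, tolerance = 1e-12)
  expect_equal(cmp$me_diff_sd[cmp$group == "M+F"], 0, tolerance = 1e-12)
})

test_that("compare_methods equals a per-subject loop and is antisymmetric", {
  set.seed(15)
  ent_a <- expand.grid(sex = c("M", "F"), tooth = 31:37,
                       stage = stage_levels(), stringsAsFactors = FALSE)
  ent_a$score <- round(runif(nrow(ent_a), 0, 2), 3)
  ent_b <- ent_a
  ent_b$score <- round(runif(nrow(ent_b), 0, 2), 3)
  tab_a <- coef_table(ent_a)
  tab_b <- coef_table(ent_b)
  co <- random_cohort(200, seed = 16)
  cmp <- suppressWarnings(compare_methods(co, tab_a, tab_b, ci_reps = 100,
                                          seed = 4))
  # brute-force loop oracle
  ea <- vapply(seq_len(nrow(co)), function(i) {
    co$chron_age[i] - suppressWarnings(estimate_age(tab_a, co[i, ]))
  }, numeric(1))
  eb <- vapply(seq_len(nrow(co)), function(i) {
    co$chron_age[i] - suppressWarnings(estimate_age(tab_b, co[i, ]))
  }, numeric(1))
  row <- cmp[cmp$group == "M+F", ]
  expect_equal(row$me_A, mean(ea), tolerance = 1e-12)
  expect_equal(row$me_diff, mean(ea - eb), tolerance = 1e-12)
  expect_equal(row$mae_diff, mean(abs(ea) - abs(eb)), tolerance = 1e-12)
  expect_equal(row$rmse_B, sqrt(mean(eb^2)), tolerance = 1e-12)
  # antisymmetry
  rev <- suppressWarnings(compare_methods(co, tab_b, tab_a, ci_reps = 100,
                                          seed = 4))
  expect_equal(rev$me_diff, -cmp$me_diff, tolerance = 1e-12)
  expect_equal(rev$mae_diff, -cmp$mae_diff, tolerance = 1e-12)
  expect_equal(rev$p_mae, cmp$p_mae, tolerance = 1e-12)
})

test_that("calibration slope reproduces exact and noisy linear relations", {
  x <- seq(4, 16, length.out = 20)
  cs <- calibration_slope(x, x)
  expect_equal(cs$slope, 1, tolerance = 1e-12)
  expect_equal(cs$intercept, 0, tolerance = 1e-12)
  cs <- calibration_slope(x, 2 * x + 1)
  expect_equal(cs$slope, 2, tolerance = 1e-12)
  expect_equal(cs$intercept, 1, tolerance = 1e-12)
  # normal-equation oracle on noisy pairs
  set.seed(17)
  y <- 0.9 * x + 1.2 + rnorm(length(x), 0, 0.8)
  cs <- calibration_slope(x, y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(cs$slope, b, tolerance = 1e-10)
  expect_equal(cs$intercept, a, tolerance = 1e-10)
  expect_error(calibration_slope(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibration_slope(rep(5, 5), 1:5), "zero variance")
})

test_that("weighted kappa handles agreement, chance and hand-worked tables", {
  r <- sample(stage_levels(), 50, replace = TRUE)
  expect_equal(weighted_kappa(r, r)$kappa, 1)
  expect_equal(weighted_kappa(r, r, "quadratic")$kappa, 1)

  # hand-worked 3x3 contingency: counts rows (3,1,0),(0,2,1),(1,0,2)
  r1 <- c(rep("A", 4), rep("B", 3), rep("C", 3))
  r2 <- c("A", "A", "A", "B", "B", "B", "C", "A", "C", "C")
  k <- weighted_kappa(r1, r2, weighting = "linear", levels = c("A", "B", "C"))
  # sum(w*O) = 0.2, sum(w*E) = 0.45 -> kappa = 1 - 0.2/0.45 = 5/9
  expect_equal(k$kappa, 5 / 9, tolerance = 1e-12)

  # quadratic weights on a 2-level scale reduce to unweighted Cohen kappa
  set.seed(18)
  a <- sample(c("A", "B"), 200, replace = TRUE)
  b <- ifelse(runif(200) < 0.7, a, sample(c("A", "B"), 200, replace = TRUE))
  kq <- weighted_kappa(a, b, "quadratic", levels = c("A", "B"))$kappa
  tab <- table(factor(a, c("A", "B")), factor(b, c("A", "B"))) / 200
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  expect_equal(kq, (po - pe) / (1 - pe), tolerance = 1e-12)

  # independent raters with identical marginals -> kappa near 0
  set.seed(19)
  marg <- c(0.05, 0.05, 0.1, 0.1, 0.1, 0.2, 0.1, 0.15, 0.15)
  x <- sample(stage_levels(), 20000, replace = TRUE, prob = marg)
  y <- sample(stage_levels(), 20000, replace = TRUE, prob = marg)
  expect_lt(abs(weighted_kappa(x, y)$kappa), 0.02)

  # constant raters are flagged, not computed
  k0 <- weighted_kappa(rep("D", 5), rep("D", 5))
  expect_true(k0$degenerate)
  expect_true(is.na(k0$kappa))
})
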