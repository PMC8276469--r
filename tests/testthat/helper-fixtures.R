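# Shared fixtures built in code.

# Quick cohort builder: stages given as a 7-character string per record,
# e.g. "DDEEEGD" maps to t31..t37.
make_cohort <- function(ages, stages, sex = "M", ids = NULL, ...) {
  n <- length(ages)
  stages <- rep_len(stages, n)
  sex <- rep_len(sex, n)
  mat <- t(vapply(strsplit(stages, ""), function(s) {
    ifelse(s == ".", NA_character_, s)
  }, character(7)))
  colnames(mat) <- paste0("t", 31:37)
  df <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  df$subject_id <- if (is.null(ids)) sprintf("s%03d", seq_len(n)) else ids
  df$sex <- sex
  df$chron_age <- ages
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  dental_cohort(df)
}

# random valid cohort for property tests
random_cohort <- function(n, seed, p_missing = 0) {
  set.seed(seed)
  stages <- replicate(n, paste(sample(c(stage_levels(),
                                        if (p_missing > 0) "." else NULL),
                                      7, replace = TRUE,
                                      prob = c(rep(1, 9),
                                               if (p_missing > 0) {
                                                 9 * p_missing / (1 - p_missing)
                                               } else NULL)),
                              collapse = ""))
  make_cohort(ages = round(runif(n, 2, 18), 3), stages = stages,
              sex = sample(c("M", "F"), n, replace = TRUE))
}

# Cohort payload without bookkeeping attributes, for equality checks.
cohort_data <- function(x) {
  y <- tibble::as_tibble(x)
  attr(y, "provenance") <- NULL
  attr(y, "exclusion_log") <- NULL
  y
}

# Brute-force Wilcoxon signed-rank: enumerate all 2^n sign assignments of
# the non-zero differences and compute the two-sided p directly.
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Parameter-recovery harness: a designed cohort with independent, balanced
# stages per tooth (reference "0" over-represented for efficiency) and a
# truth table in the identifiable folded parameterization (per-tooth
# reference scores 0, baseline carried by tooth 31).
recovery_truth <- function() {
  grid <- expand.grid(sex = c("M", "F"), tooth = 31:37,
                      stage = stage_levels(), stringsAsFactors = FALSE)
  k <- match(grid$stage, LETTERS[1:8])
  male <- grid$sex == "M"
  grid$score <- ifelse(
    grid$stage == "0", ifelse(grid$tooth == 31, 1.5, 0),
    ifelse(grid$tooth == 31,
           ifelse(male, 2.0 + 0.7 * k, 2.3 + 0.68 * k),
           (ifelse(male, 0.10, 0.09) +
              ifelse(male, 0.02, 0.025) * (grid$tooth - 32)) * k))
  coef_table(grid, name = "recovery-truth")
}

recovery_cohort <- function(n_per_sex, seed) {
  counts <- c(n_per_sex - 8 * floor(n_per_sex * 0.0925),
              rep(floor(n_per_sex * 0.0925), 8))
  base <- rep(stage_levels(), counts)
  set.seed(seed)
  build_sex <- function(sx) {
    stages <- vapply(1:7, function(j) sample(base), character(n_per_sex))
    colnames(stages) <- paste0("t", 31:37)
    df <- tibble::as_tibble(as.data.frame(stages, stringsAsFactors = FALSE))
    df$sex <- sx
    df
  }
  df <- dplyr::bind_rows(build_sex("M"), build_sex("F"))
  df$subject_id <- sprintf("R%05d", seq_len(nrow(df)))
  df$chron_age <- 10  # replaced by attach_additive_ages()
  dental_cohort(df, provenance = "recovery harness")
}

# maturation parameters that span the whole stage scale over ages 2-17
harness_params <- function(sigma_child = 0.5, sigma_tooth = 1.0) {
  mu <- expand.grid(sex = c("M", "F"), tooth = 31:37, stage = LETTERS[1:8],
                    stringsAsFactors = FALSE)
  mu$age <- 3.2 + 1.35 * (match(mu$stage, LETTERS[1:8]) - 1) -
    0.3 * (mu$sex == "F")
  maturation_params(mu, sigma_child = sigma_child, sigma_tooth = sigma_tooth,
                    age_range = c(2, 17))
}
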