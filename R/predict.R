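#' Estimate dental age from staged teeth
#'
#' The Willems-style estimate is the sum, over the seven lower-left
#' permanent teeth, of the table score for the subject's sex, the tooth and
#' its observed stage. Stages without a table entry contribute 0 (reference
#' level). A missing stage cannot be scored and raises an error naming the
#' tooth.
#'
#' @param table A `coef_table`.
#' @param records A `dental_cohort` (or data frame with the cohort columns);
#'   one estimate per row.
#' @param warn_fallback Warn once per call when a scored stage has no
#'   explicit table entry and is not the lowest stage the table knows for
#'   that (sex, tooth). Defaults to `TRUE` for fitted tables (which carry
#'   explicit reference rows, so any absent key means a stage unseen in
#'   training) and `FALSE` otherwise.
#' @return Numeric vector of estimated ages in years. Estimates at or below
#'   zero are returned as computed, with a warning.
#' @export
#' @examples
#' rec <- data.frame(subject_id = "s1", sex = "M", chron_age = 10,
#'   t31 = "H", t32 = "H", t33 = "H", t34 = "H", t35 = "H",
#'   t36 = "H", t37 = "H")
#' estimate_age(willems_sa_table(), rec)
estimate_age <- function(table, records,
                         warn_fallback = isTRUE(attr(table, "fitted"))) {
  stopifnot(inherits(table, "coef_table"))
  records <- tibble::as_tibble(records)
  stage_cols <- tooth_columns()
  stopifnot(all(c("sex", stage_cols) %in% names(records)))
  n <- nrow(records)
  if (n == 0) return(numeric(0))
  stages <- as.matrix(records[, stage_cols])
  if (anyNA(stages)) {
    bad <- which(is.na(stages), arr.ind = TRUE)[1, ]
    id <- if ("subject_id" %in% names(records)) {
      paste0(" (subject ", records$subject_id[bad["row"]], ")")
    } else ""
    stop("cannot estimate age with a missing stage: tooth ",
         fdi_teeth()[bad["col"]], id, call. = FALSE)
  }
  sex <- rep(records$sex, times = 7L)
  tooth <- rep(fdi_teeth(), each = n)
  stage <- as.vector(stages)
  scores <- matrix(lookup_score(table, sex, tooth, stage), nrow = n)
  if (warn_fallback) {
    key <- paste(sex, tooth, stage)
    known <- paste(table$sex, table$tooth, table$stage)
    absent <- !(key %in% known)
    if (any(absent)) {
      uns <- unique(key[absent])
      warning("stage(s) without a fitted coefficient scored as 0: ",
              paste(utils::head(uns, 8), collapse = "; "),
              if (length(uns) > 8) " ..." else "", call. = FALSE)
    }
  }
  est <- rowSums(scores)
  if (any(est <= 0)) {
    warning(sum(est <= 0), " estimated age(s) at or below 0 years",
            call. = FALSE)
  }
  est
}

#' Predict a whole cohort and compute signed errors
#'
#' Applies [estimate_age()] to every record and reports the prediction error
#' with the convention `error = chron_age - estimated_age`: a negative error
#' means the method overestimates age, a positive one means it
#' underestimates.
#'
#' @param table A `coef_table`.
#' @param cohort A `dental_cohort`, normally already passed through
#'   [filter_eligible()].
#' @param ... Passed to [estimate_age()].
#' @return Tibble with columns `subject_id`, `sex`, `chron_age`,
#'   `estimated_age`, `error`, in input row order.
#' @export
predict_cohort <- function(table, cohort, ...) {
  cohort <- tibble::as_tibble(cohort)
  est <- estimate_age(table, cohort, ...)
  tibble::tibble(subject_id = cohort$subject_id, sex = cohort$sex,
                 chron_age = cohort$chron_age, estimated_age = est,
                 error = cohort$chron_age - est)
}
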