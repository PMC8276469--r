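#' Construct a staged dental cohort
#'
#' A cohort is a tibble with one row per scored dentition: a subject
#' identifier, sex (`"M"`/`"F"`), chronological age in decimal years, and the
#' Demirjian stage of each of the seven lower-left permanent teeth in columns
#' `t31`..`t37` (see [stage_levels()]; `NA` marks an absent/unscorable
#' tooth). Optional `observer_id` and `session` columns identify repeat
#' scorings of the same radiograph, as used for observer-agreement analyses.
#'
#' @param records Data frame with columns `subject_id`, `sex`, `chron_age`,
#'   `t31`..`t37` and optionally `observer_id`, `session`.
#' @param provenance Free-text label describing where the cohort came from.
#' @return A `dental_cohort` tibble.
#' @export
dental_cohort <- function(records, provenance = "") {
  records <- tibble::as_tibble(records)
  required <- c("subject_id", "sex", "chron_age", tooth_columns())
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- intersect(c("observer_id", "session"), names(records))
  records <- records[, c(required, optional)]
  records$subject_id <- as.character(records$subject_id)
  records$sex <- toupper(as.character(records$sex))
  records$chron_age <- as.numeric(records$chron_age)
  for (col in tooth_columns()) {
    st <- parse_stage_tokens(records[[col]])
    if (length(attr(st, "bad")) > 0) {
      stop("invalid stage code in column ", col, ", row(s) ",
           paste(attr(st, "bad"), collapse = ", "), call. = FALSE)
    }
    records[[col]] <- as.character(st)
  }
  if ("session" %in% names(records)) {
    records$session <- as.integer(records$session)
  }
  out <- validate_cohort(records)
  attr(out, "provenance") <- provenance
  class(out) <- c("dental_cohort", class(tibble::tibble()))
  out
}

validate_cohort <- function(records) {
  if (nrow(records) > 0) {
    bad_sex <- which(!records$sex %in% c("M", "F"))
    if (length(bad_sex) > 0) {
      stop("sex must be 'M' or 'F'; offending row(s): ",
           paste(utils::head(bad_sex, 5), collapse = ", "), call. = FALSE)
    }
    bad_age <- which(!is.finite(records$chron_age) | records$chron_age <= 0)
    if (length(bad_age) > 0) {
      stop("chron_age must be finite and positive; offending row(s): ",
           paste(utils::head(bad_age, 5), collapse = ", "), call. = FALSE)
    }
    key <- paste(records$subject_id,
                 if ("observer_id" %in% names(records)) records$observer_id else "",
                 if ("session" %in% names(records)) records$session else "")
    if (anyDuplicated(key) > 0) {
      stop("duplicate (subject_id, observer_id, session) in cohort: ",
           records$subject_id[anyDuplicated(key)], call. = FALSE)
    }
  }
  records
}

#' Read a staged cohort from delimited text
#'
#' Expects a header naming at least `subject_id`, `sex`, `chron_age` and
#' `t31`..`t37` (optionally `observer_id`, `session`). Stage tokens are
#' parsed case-insensitively; empty fields and `"NA"` become the missing
#' marker. Invalid stage tokens raise an error naming the file line and
#' column.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default `","`).
#' @return A `dental_cohort`.
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(),
    show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "sex", "chron_age", tooth_columns())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in tooth_columns()) {
    st <- parse_stage_tokens(raw[[col]])
    bad <- attr(st, "bad")
    if (length(bad) > 0) {
      # +1: file line number including the header row
      stop("unparseable stage token ", dQuote(raw[[col]][bad[1]]),
           " at line ", bad[1] + 1L, ", column ", col, " of ", path,
           call. = FALSE)
    }
    raw[[col]] <- as.character(st)
  }
  age <- suppressWarnings(as.numeric(raw$chron_age))
  if (anyNA(age) && nrow(raw) > 0) {
    stop("non-numeric chron_age at line ", which(is.na(age))[1] + 1L,
         " of ", path, call. = FALSE)
  }
  raw$chron_age <- age
  dental_cohort(raw, provenance = path)
}

#' Write a cohort as delimited text
#'
#' Columns are written in canonical order (`subject_id`, `sex`, `chron_age`,
#' `t31`..`t37`, then `observer_id`/`session` when present), stages as single
#' characters with `NA` for a missing tooth. `read_cohort()` applied to the
#' output reproduces the cohort.
#'
#' @param cohort A `dental_cohort`.
#' @param path Output file path.
#' @param delim Field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(inherits(cohort, "dental_cohort"))
  readr::write_delim(tibble::as_tibble(cohort), path, delim = delim, na = "NA",
                     progress = FALSE)
  invisible(path)
}

#' Apply the study eligibility filter
#'
#' Retains subjects who are under `max_age` years, have no missing stage
#' among teeth 31-37, and do not have all seven teeth fully developed
#' (stage H) -- the three inclusion rules used when validating age-estimation
#' models on children. The age boundary is strict: `chron_age == max_age` is
#' excluded. A subject can trigger several exclusion reasons; all are logged.
#'
#' @param cohort A `dental_cohort`.
#' @param max_age Strict upper age bound in years (default 16).
#' @return The retained `dental_cohort`, carrying the exclusion log as an
#'   attribute; retrieve it with [exclusion_log()].
#' @export
#' @examples
#' co <- dental_cohort(data.frame(
#'   subject_id = c("a", "b"), sex = "M", chron_age = c(10, 17),
#'   t31 = "H", t32 = "G", t33 = "G", t34 = "F", t35 = "F",
#'   t36 = "H", t37 = "E"))
#' kept <- filter_eligible(co)
#' exclusion_log(kept)
filter_eligible <- function(cohort, max_age = 16) {
  stopifnot(inherits(cohort, "dental_cohort"))
  if (max_age <= 0) stop("max_age must be positive", call. = FALSE)
  stages <- as.matrix(tibble::as_tibble(cohort)[, tooth_columns()])
  over_age <- cohort$chron_age >= max_age
  has_missing <- apply(stages, 1L, anyNA)
  fully_dev <- apply(stages, 1L, function(s) !anyNA(s) && all(s == "H"))
  reasons <- list(age = over_age, missing_tooth = has_missing,
                  fully_developed = fully_dev)
  log <- dplyr::bind_rows(lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    tibble::tibble(subject_id = cohort$subject_id[idx], reason = r)
  }))
  if (nrow(log) == 0) {
    log <- tibble::tibble(subject_id = character(), reason = character())
  }
  keep <- !(over_age | has_missing | fully_dev)
  out <- cohort[keep, ]
  class(out) <- class(cohort)
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "exclusion_log") <- log
  out
}

#' Exclusion log of a filtered cohort
#'
#' @param cohort A cohort returned by [filter_eligible()].
#' @return Tibble with one row per (subject, reason) pair.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    tibble::tibble(subject_id = character(), reason = character())
  } else {
    log
  }
}
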