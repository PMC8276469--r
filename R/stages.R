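#' Demirjian stage codes
#'
#' Permanent-tooth development is scored radiographically on Demirjian's
#' ordinal scale: `"0"` (crypt visible, no calcification) followed by `"A"`
#' through `"H"`, where `"H"` means the apical end of the root canal is
#' closed (development complete). An absent or unscorable tooth is
#' represented by `NA` and is *not* ordered with the rest of the scale.
#'
#' @return Character vector of the nine stage codes in developmental order.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() {
  c("0", "A", "B", "C", "D", "E", "F", "G", "H")
}

#' FDI numbers of the seven scored teeth
#'
#' The methods implemented here score the seven lower-left permanent
#' mandibular teeth, FDI 31 (central incisor) through 37 (second molar);
#' the third molar (38) is excluded.
#'
#' @return Integer vector `31:37`.
#' @export
fdi_teeth <- function() 31:37

# column names used for stages in cohort tables
tooth_columns <- function() paste0("t", fdi_teeth())

# rank of a stage on the ordinal scale (1..9); NA stays NA
stage_rank <- function(stage) {
  match(stage, stage_levels())
}

# Parse stage tokens case-insensitively; "", "NA" (any case) -> NA.
# Returns a character vector on the canonical scale; invalid tokens -> NA
# with attribute "bad" marking their positions (callers build row-addressed
# errors from it).
parse_stage_tokens <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(is.na(x) | x == "" | x == "NA", NA_character_, x)
  ok <- is.na(out) | out %in% stage_levels()
  structure(out, bad = which(!ok))
}
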