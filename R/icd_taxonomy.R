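#' ICD-10 cause taxonomy for fall-mortality quality analysis
#'
#' Cause codes are handled in the WHO Mortality Database convention: an
#' uppercase letter, two digits, and an optional fourth character written
#' without a decimal point ("Y872" is ICD-10 Y87.2). Categories are not
#' mutually exclusive; a fall is also an unintentional injury and an injury.
#'
#' The analysis categories are:
#' \describe{
#'   \item{unspecified_death}{R96, R98, R99 — deaths with no usable cause.}
#'   \item{injury}{external causes V01–Y89, including sequelae Y85–Y89.}
#'   \item{undetermined_intent}{Y30, Y31, Y34 (any 4th digit) plus the
#'     sequelae codes Y87.2 and Y89.9.}
#'   \item{unintentional}{unintentional injuries V01–X59.}
#'   \item{unspecified_unintentional}{X59, unintentional injury of
#'     unspecified mechanism.}
#'   \item{fall}{unintentional falls W00–W19.}
#'   \item{fall_unspecified_mechanism}{W19, fall of unspecified mechanism.}
#' }
#'
#' @name icd_taxonomy
NULL

#' Validate ICD-10 cause code syntax
#'
#' @param cause character vector of cause codes.
#' @return logical vector, `TRUE` where the code is an uppercase letter,
#'   two digits, and an optional fourth digit.
#' @examples
#' valid_cause(c("W19", "Y872", "w19", "AAA"))
#' @export
valid_cause <- function(cause) {
  grepl("^[A-Z][0-9]{2}[0-9]?$", cause)
}

#' Classify ICD-10 cause codes into analysis categories
#'
#' Vectorised classification into the (overlapping) categories used by the
#' coding-quality indicators and the redistribution stages. Implication
#' chains hold by construction: fall implies unintentional implies injury;
#' W19 implies fall; X59 implies unintentional; undetermined intent implies
#' injury; unspecified deaths (R codes) carry no injury flag.
#'
#' @param cause character vector of MDB-style cause codes (no decimal
#'   point, e.g. `"W059"`, `"Y872"`).
#' @return a tibble with one row per input code and logical columns
#'   `unspecified_death`, `injury`, `undetermined_intent`, `unintentional`,
#'   `unspecified_unintentional`, `fall`, `fall_unspecified_mechanism`.
#' @examples
#' classify_cause(c("R99", "Y872", "W051", "X59"))
#' @export
classify_cause <- function(cause) {
  bad <- !valid_cause(cause)
  if (any(bad)) {
    rlang::abort(
      paste0("malformed ICD-10 cause code(s): ",
             paste(unique(cause[bad]), collapse = ", ")),
      class = "fallcoding_bad_cause"
    )
  }
  letter <- substr(cause, 1, 1)
  num <- as.integer(substr(cause, 2, 3))
  stem <- substr(cause, 1, 3)

  # V00 is not a valid external-cause code: the injury span starts at V01
  injury <- (letter == "V" & num >= 1) | letter %in% c("W", "X") |
    (letter == "Y" & num <= 89)
  unintentional <- (letter == "V" & num >= 1) | letter == "W" |
    (letter == "X" & num <= 59)
  fall <- letter == "W" & num <= 19
  tibble::tibble(
    cause = cause,
    unspecified_death = stem %in% c("R96", "R98", "R99"),
    injury = injury,
    undetermined_intent = stem %in% c("Y30", "Y31", "Y34") |
      cause %in% c("Y872", "Y899"),
    unintentional = unintentional,
    unspecified_unintentional = stem == "X59",
    fall = fall,
    fall_unspecified_mechanism = stem == "W19"
  )
}

#' Place of occurrence recorded in a fall code's fourth digit
#'
#' For unintentional falls (W00–W19) the fourth character of the ICD-10
#' code records where the fall occurred; the digit 9 means the place was
#' unspecified. Three-character fall codes carry no place information and
#' are treated as unknown place under the default policy, since the place
#' is unrecoverable either way.
#'
#' @param cause character vector of cause codes.
#' @param missing_is_unknown treat a fall code without a fourth character
#'   as unknown place (default `TRUE`).
#' @return character vector over `"known"`, `"unknown"`,
#'   `"not_applicable"` (non-fall codes).
#' @examples
#' place_of_occurrence(c("W009", "W010", "W19", "C509"))
#' @export
place_of_occurrence <- function(cause, missing_is_unknown = TRUE) {
  cls <- classify_cause(cause)
  d4 <- substr(cause, 4, 4)
  unknown <- d4 == "9" | (d4 == "" & missing_is_unknown)
  out <- rep("not_applicable", length(cause))
  out[cls$fall] <- ifelse(unknown[cls$fall], "unknown", "known")
  out
}

#' Machine-readable table of the category code ranges
#'
#' @return a tibble with columns `category`, `codes` documenting the
#'   compiled-in ICD-10 ranges behind [classify_cause()].
#' @export
icd_category_table <- function() {
  tibble::tribble(
    ~category, ~codes,
    "unspecified_death", "R96, R98, R99",
    "injury", "V01-Y89",
    "undetermined_intent", "Y30, Y31, Y34, Y87.2, Y89.9",
    "unintentional", "V01-X59",
    "unspecified_unintentional", "X59",
    "fall", "W00-W19",
    "fall_unspecified_mechanism", "W19"
  )
}

#' Infer the ICD revision from an MDB list tag
#'
#' @param list_id character vector of WHO MDB `List` tags (e.g. `"104"`,
#'   `"10M"`, `"09B"`).
#' @return character vector `"ICD-10"`, `"ICD-9"`, `"ICD-8"`, `"ICD-7"`
#'   or `"other"` (with a warning for unrecognised prefixes).
#' @export
icd_revision <- function(list_id) {
  out <- rep("other", length(list_id))
  out[startsWith(list_id, "10")] <- "ICD-10"
  out[startsWith(list_id, "09") | startsWith(list_id, "9")] <- "ICD-9"
  out[startsWith(list_id, "08") | startsWith(list_id, "8")] <- "ICD-8"
  out[startsWith(list_id, "07") | startsWith(list_id, "7")] <- "ICD-7"
  if (any(out == "other")) {
    rlang::warn(paste0(
      "unrecognised ICD list tag(s), revision set to 'other': ",
      paste(unique(list_id[out == "other"]), collapse = ", ")
    ))
  }
  out
}

#' @rdname icd_revision
#' @export
is_icd10_list <- function(list_id) startsWith(list_id, "10")
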