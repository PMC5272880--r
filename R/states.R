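#' Labour-market positions and analysis states
#'
#' Person-years are classified in two steps: first into one of nine
#' fine-grained labour-market positions (plus death and emigration), then the
#' positions are collapsed into four mutually exclusive analysis states.
#' `positions()` and `states()` return the canonical level sets used
#' throughout the package; `collapse_to_state()` is the (total) second-step
#' mapping.
#'
#' The four states are:
#' \describe{
#'   \item{JOBLESS}{long-term registered unemployed, social-assistance
#'     recipients, and people with no or minimal income.}
#'   \item{SELF_SUFFICIENT}{employed (main income from work), long-term
#'     parental leave, students.}
#'   \item{DISABLED}{long-term sickness absence or disability pension
#'     (medically certified work incapacity).}
#'   \item{CENSORED}{death, emigration, or old-age pension; absorbing.}
#' }
#'
#' @return `positions()` and `states()` return character vectors of level
#'   names. `collapse_to_state()` returns a character vector of states, same
#'   length as `position`.
#' @examples
#' collapse_to_state(c("STUDENT", "DIED", "DISABILITY_PENSION"))
#' @name states
NULL

#' @rdname states
#' @export
positions <- function() {
  c("LONG_TERM_UNEMPLOYED", "SOCIAL_ASSISTANCE", "MINIMAL_INCOME",
    "EMPLOYED", "PARENTAL_LEAVE", "STUDENT",
    "DISABILITY_PENSION", "LONG_TERM_SICK",
    "OLD_AGE_PENSION", "DIED", "EMIGRATED")
}

#' @rdname states
#' @export
states <- function() {
  # display order used in all tables: S, J, D, C
  c("SELF_SUFFICIENT", "JOBLESS", "DISABLED", "CENSORED")
}

#' @rdname states
#' @export
origin_states <- function() {
  c("SELF_SUFFICIENT", "JOBLESS", "DISABLED")
}

# position -> state lookup (total on positions())
.state_of_position <- c(
  LONG_TERM_UNEMPLOYED = "JOBLESS",
  SOCIAL_ASSISTANCE    = "JOBLESS",
  MINIMAL_INCOME       = "JOBLESS",
  EMPLOYED             = "SELF_SUFFICIENT",
  PARENTAL_LEAVE       = "SELF_SUFFICIENT",
  STUDENT              = "SELF_SUFFICIENT",
  DISABILITY_PENSION   = "DISABLED",
  LONG_TERM_SICK       = "DISABLED",
  OLD_AGE_PENSION      = "CENSORED",
  DIED                 = "CENSORED",
  EMIGRATED            = "CENSORED"
)

#' @rdname states
#' @param position character vector of position names (see `positions()`).
#' @export
collapse_to_state <- function(position) {
  bad <- setdiff(unique(position), positions())
  if (length(bad)) {
    stop("unknown labour-market position(s): ", paste(bad, collapse = ", "))
  }
  unname(.state_of_position[position])
}

# factor level orders for model covariates (reference level first)
.sex_levels <- c("MALE", "FEMALE")
.age_levels <- c("20-25", "26-30", "31-35", "36-40")
.edu_levels <- c("HIGH_SCHOOL", "LOWER", "HIGHER")
.country_levels <- c("SWEDEN", "OTHER")
.inpatient_levels <- c("NONE", "LE_MEDIAN", "GT_MEDIAN")
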