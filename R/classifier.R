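#' Classification settings
#'
#' Thresholds for the first-step classification of register person-years into
#' labour-market positions.
#'
#' @param earnings_threshold Earnings level above which a person counts as
#'   employed. Currency units are abstract; earnings in the synthetic registry
#'   are scaled so that the default threshold is 1.
#' @param long_term_days Day cut operationalising "at least six months" of
#'   compensated benefit days; default 183 (half of 366), must lie in
#'   \[150, 200\].
#' @param income_share_cut Fraction of annual disposable income above which a
#'   single transfer source (social assistance, student allowance, old-age
#'   pension) classifies the year; default 0.5 ("more than half").
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(earnings_threshold = 1,
                                  long_term_days = 183L,
                                  income_share_cut = 0.5) {
  if (!is.numeric(earnings_threshold) || length(earnings_threshold) != 1 ||
      !is.finite(earnings_threshold) || earnings_threshold <= 0) {
    stop("earnings_threshold must be a single positive number")
  }
  if (!is.numeric(long_term_days) || length(long_term_days) != 1 ||
      long_term_days < 150 || long_term_days > 200) {
    stop("long_term_days must lie in [150, 200]")
  }
  if (!is.numeric(income_share_cut) || length(income_share_cut) != 1 ||
      income_share_cut <= 0 || income_share_cut >= 1) {
    stop("income_share_cut must lie in (0, 1)")
  }
  structure(list(earnings_threshold = earnings_threshold,
                 long_term_days = as.integer(long_term_days),
                 income_share_cut = income_share_cut),
            class = "classification_config")
}

# Register field names the classifier reads. `records` data.frames must carry
# these columns (plus person_id/year for cohort-level functions).
.register_fields <- c(
  "earnings", "unemployment_days", "sickness_days", "disability_days",
  "parental_days", "social_assistance_income", "student_allowance_income",
  "oldage_pension_income", "disposable_income",
  "died_this_year", "emigrated_this_year"
)

.check_register_fields <- function(records) {
  miss <- setdiff(.register_fields, names(records))
  if (length(miss)) {
    stop("records are missing register fields: ", paste(miss, collapse = ", "))
  }
}

#' Classify person-years into labour-market positions
#'
#' First classification step. Each person-year is assigned exactly one of the
#' nine labour-market positions (or DIED / EMIGRATED) by a fixed precedence
#' chain of rule families:
#'
#' 1. death; 2. emigration;
#' 3. benefit-day rule: if the sum of compensated days across the four
#'    programmes (unemployment, sickness, disability pension, parental leave)
#'    is at least `long_term_days`, the year is assigned to the programme with
#'    the most days (ties broken disability > sickness > unemployment >
#'    parental);
#' 4. income-share rule: if more than `income_share_cut` of disposable income
#'    comes from social assistance, student allowance, or old-age pension, the
#'    year is assigned to that source (largest share wins; ties broken social
#'    assistance > student > old-age pension);
#' 5. employed: earnings above `earnings_threshold`;
#' 6. residual: minimal income.
#'
#' `classify_positions()` is vectorised over the rows of a records
#' data.frame; `classify_position()` is the single-record convenience wrapper.
#'
#' @param records data.frame of register person-years (see
#'   [generate_cohort()] for the column set).
#' @param config a [classification_config()].
#' @return `classify_positions()`: data.frame with columns `position` and
#'   `triggered_rule` (one of "death", "emigration", "benefit_days",
#'   "income_share", "earnings", "residual"), one row per input row.
#'   `classify_position()`: a single position string.
#' @examples
#' cfg <- classification_config()
#' r <- data.frame(earnings = 0, unemployment_days = 200, sickness_days = 0,
#'                 disability_days = 0, parental_days = 0,
#'                 social_assistance_income = 0, student_allowance_income = 0,
#'                 oldage_pension_income = 0, disposable_income = 0.2,
#'                 died_this_year = FALSE, emigrated_this_year = FALSE)
#' classify_position(r, cfg) # "LONG_TERM_UNEMPLOYED"
#' @export
classify_positions <- function(records, config = classification_config()) {
  stopifnot(inherits(config, "classification_config"))
  .check_register_fields(records)
  n <- nrow(records)
  pos <- character(n)
  rule <- character(n)

  day_mat <- cbind(disability = records$disability_days,
                   sickness = records$sickness_days,
                   unemployment = records$unemployment_days,
                   parental = records$parental_days)
  if (any(!is.finite(day_mat)) || any(day_mat < 0)) {
    stop("benefit day fields must be finite and non-negative")
  }
  benefit_sum <- rowSums(day_mat)
  # which programme has the most days; column order encodes tie precedence
  prog <- c("DISABILITY_PENSION", "LONG_TERM_SICK",
            "LONG_TERM_UNEMPLOYED", "PARENTAL_LEAVE")[max.col(day_mat, "first")]

  share_mat <- cbind(sa = records$social_assistance_income,
                     student = records$student_allowance_income,
                     oap = records$oldage_pension_income)
  if (any(!is.finite(share_mat)) || any(share_mat < 0)) {
    stop("income fields must be finite and non-negative")
  }
  src_any <- rowSums(share_mat) > 0
  disp <- records$disposable_income
  shares <- share_mat
  pos_disp <- is.finite(disp) & disp > 0
  shares[pos_disp, ] <- share_mat[pos_disp, , drop = FALSE] / disp[pos_disp]
  shares[!pos_disp, ] <- 0
  share_src <- c("SOCIAL_ASSISTANCE", "STUDENT",
                 "OLD_AGE_PENSION")[max.col(shares, "first")]
  share_max <- pmax(shares[, 1], shares[, 2], shares[, 3])

  died <- as.logical(records$died_this_year)
  emig <- as.logical(records$emigrated_this_year)
  long_benefit <- benefit_sum >= config$long_term_days
  share_hit <- share_max > config$income_share_cut
  employed <- records$earnings > config$earnings_threshold

  # income-share rule needed but disposable income unusable -> explicit error
  need_share <- !died & !emig & !long_benefit & src_any
  bad_disp <- need_share & (!is.finite(disp) | disp <= 0)
  if (any(bad_disp)) {
    stop(sum(bad_disp), " record(s) have transfer income but missing or ",
         "non-positive disposable income; cannot evaluate the income-share rule")
  }

  # precedence chain, later assignments never overwrite earlier ones
  todo <- rep(TRUE, n)
  assign_rule <- function(mask, p, r) {
    sel <- todo & mask
    pos[sel] <<- p[sel]
    rule[sel] <<- r
    todo[sel] <<- FALSE
  }
  assign_rule(died, rep("DIED", n), "death")
  assign_rule(emig, rep("EMIGRATED", n), "emigration")
  assign_rule(long_benefit, prog, "benefit_days")
  assign_rule(share_hit, share_src, "income_share")
  assign_rule(employed, rep("EMPLOYED", n), "earnings")
  assign_rule(rep(TRUE, n), rep("MINIMAL_INCOME", n), "residual")

  data.frame(position = pos, triggered_rule = rule, stringsAsFactors = FALSE)
}

#' @rdname classify_positions
#' @param record a single-row records data.frame.
#' @export
classify_position <- function(record, config = classification_config()) {
  if (nrow(record) != 1) stop("record must have exactly one row")
  classify_positions(record, config)$position
}

#' Classify a cohort into yearly state sequences with absorbing censoring
#'
#' Applies [classify_positions()] and [collapse_to_state()] to every
#' person-year, then enforces absorbing censoring: from the first year a
#' person is CENSORED (death, emigration, old-age pension), all later years
#' are CENSORED, regardless of any later records (a person who re-immigrates
#' is not re-introduced). Every person's sequence is completed through
#' `max(years)`; years after the last record are filled as CENSORED only if
#' the person was censored by then, otherwise a gap is an error.
#'
#' @param records data.frame of register person-years with `person_id` and
#'   `year` columns in addition to the register fields.
#' @param config a [classification_config()].
#' @param years years the output must cover; default
#'   `min(records$year):max(records$year)`.
#' @return data.frame with columns `person_id`, `year`, `position`,
#'   `triggered_rule`, `state`, sorted by person and year. Filled-in
#'   post-censoring years carry position `NA` and rule `"censored_carryforward"`.
#' @export
classify_cohort <- function(records, config = classification_config(),
                            years = NULL) {
  if (!all(c("person_id", "year") %in% names(records))) {
    stop("records must have person_id and year columns")
  }
  if (anyDuplicated(records[c("person_id", "year")])) {
    stop("duplicate (person_id, year) rows in records")
  }
  if (is.null(years)) years <- seq(min(records$year), max(records$year))
  years <- sort(unique(as.integer(years)))

  cls <- classify_positions(records, config)
  dt <- data.table::data.table(
    person_id = records$person_id,
    year = as.integer(records$year),
    position = cls$position,
    triggered_rule = cls$triggered_rule,
    state = collapse_to_state(cls$position)
  )
  data.table::setkey(dt, person_id, year)

  # complete each person's sequence over `years`
  full <- data.table::CJ(person_id = unique(dt$person_id), year = years)
  out <- dt[full]

  # absorbing censoring: CENSORED from its first occurrence onward
  state <- position <- triggered_rule <- person_id <- NULL # NSE notes
  out[, state := {
    cens <- cumsum(!is.na(state) & state == "CENSORED") > 0
    s <- state
    s[cens] <- "CENSORED"
    s
  }, by = person_id]
  filled <- is.na(out$position) & out$state == "CENSORED"
  out[filled, triggered_rule := "censored_carryforward"]
  gap <- is.na(out$state)
  if (any(gap)) {
    bad <- unique(out$person_id[gap])
    stop("missing records before censoring for person(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  data.table::setDF(out)
  out
}
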