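#' Period-to-year map for the unequally spaced follow-up design
#'
#' The follow-up design measures states at a small set of calendar years
#' chosen to bracket national unemployment cycles rather than at every year.
#' The default maps periods p = 0..5 to 1995, 1997, 2001, 2005, 2008, 2010.
#'
#' @param years strictly increasing calendar years; the first is the baseline
#'   (p = 0).
#' @return data.frame with columns `p` (0-based period index) and `year`,
#'   class `period_map`.
#' @export
period_map <- function(years = c(1995L, 1997L, 2001L, 2005L, 2008L, 2010L)) {
  years <- as.integer(years)
  if (length(years) < 2 || any(diff(years) <= 0)) {
    stop("years must be strictly increasing with at least two entries")
  }
  structure(data.frame(p = seq_along(years) - 1L, year = years),
            class = c("period_map", "data.frame"))
}

#' Select the baseline cohort
#'
#' The study population is everyone whose state at the baseline year is
#' JOBLESS.
#'
#' @param states data.frame as returned by [classify_cohort()] (needs
#'   `person_id`, `year`, `state`).
#' @param baseline_year calendar year defining the baseline.
#' @return vector of person ids.
#' @export
select_baseline <- function(states, baseline_year) {
  at_base <- states[states$year == baseline_year, , drop = FALSE]
  if (!nrow(at_base)) stop("no states recorded at baseline_year ", baseline_year)
  at_base$person_id[at_base$state == "JOBLESS"]
}

#' Categorise inpatient-care days against a period median
#'
#' Days of (countable) inpatient hospital care in the two years before the
#' outcome year are split into three categories: 0 days, at most the median,
#' and above the median, where the median is computed among those with any
#' such care in the period.
#'
#' @param days_prev_2yrs non-negative integer vector of summed days.
#' @param period_median positive median among rows with any care.
#' @return character vector in \{"NONE", "LE_MEDIAN", "GT_MEDIAN"\}.
#' @export
categorize_inpatient <- function(days_prev_2yrs, period_median) {
  if (any(days_prev_2yrs < 0)) stop("inpatient days must be non-negative")
  if (!is.finite(period_median) || period_median <= 0) {
    stop("period_median must be a positive number")
  }
  ifelse(days_prev_2yrs == 0, "NONE",
         ifelse(days_prev_2yrs <= period_median, "LE_MEDIAN", "GT_MEDIAN"))
}

#' Build the person-period estimation panel
#'
#' One row is produced per person and period p >= 1 whose previous-period
#' state is not CENSORED (the absorbing state is never an origin). Covariates
#' follow the model definitions: sex, age group (from age at the baseline
#' year, groups 20-25, 26-30, 31-35, 36-40), and country of birth are fixed at
#' baseline; education is taken at the calendar year of the previous period;
#' inpatient care is the sum of countable hospital days over the two calendar
#' years before the outcome year, categorised against the per-period median
#' among rows with any care ([categorize_inpatient()]).
#'
#' @param states data.frame from [classify_cohort()].
#' @param covariates per person-year data.frame with columns `person_id`,
#'   `year`, `sex`, `birth_year`, `country_of_birth`, `education`.
#' @param inpatient per person-year data.frame with `person_id`, `year`,
#'   `inpatient_days_countable`. Years without a row count as 0 days (e.g.
#'   after death or emigration).
#' @param pmap a [period_map()].
#' @param cohort_ids persons to include (default: the baseline JOBLESS cohort
#'   selected with [select_baseline()]).
#' @return data.frame of class `person_period_panel`: one row per transition
#'   observation with columns `person_id`, `p`, `year`, `state`, `state_prev`,
#'   `sex`, `age_group`, `country`, `education_prev`, `inpatient_days`,
#'   `inpatient_cat`, and attribute `period_medians`. Rows with a missing
#'   covariate are dropped; the count of dropped rows is recorded in attribute
#'   `n_dropped`.
#' @export
build_person_periods <- function(states, covariates, inpatient, pmap,
                                 cohort_ids = NULL) {
  stopifnot(inherits(pmap, "period_map"))
  if (is.null(cohort_ids)) {
    cohort_ids <- select_baseline(states, pmap$year[pmap$p == 0])
  }
  cohort_ids <- sort(unique(cohort_ids))
  st <- data.table::as.data.table(states)[person_id %in% cohort_ids]
  cov <- data.table::as.data.table(covariates)[person_id %in% cohort_ids]
  inp <- data.table::as.data.table(inpatient)[person_id %in% cohort_ids]
  data.table::setkey(st, person_id, year)
  data.table::setkey(cov, person_id, year)
  data.table::setkey(inp, person_id, year)

  base_year <- pmap$year[pmap$p == 0]
  base_cov <- cov[.(cohort_ids, base_year)]
  if (anyNA(base_cov$birth_year)) {
    stop("baseline covariates missing for some cohort members")
  }
  age <- base_year - base_cov$birth_year
  age_group <- cut(age, breaks = c(19, 25, 30, 35, 40),
                   labels = .age_levels, right = TRUE)
  base_dt <- data.table::data.table(
    person_id = base_cov$person_id,
    sex = as.character(base_cov$sex),
    age_group = as.character(age_group),
    country = as.character(base_cov$country_of_birth)
  )
  data.table::setkey(base_dt, person_id)

  # wide state lookup at mapped years
  get_states <- function(yr) {
    s <- st[.(cohort_ids, yr)]
    if (anyNA(s$state)) stop("state sequence does not cover year ", yr)
    s$state
  }
  window_days <- function(yr) {
    d1 <- inp[.(cohort_ids, yr - 1L)]$inpatient_days_countable
    d2 <- inp[.(cohort_ids, yr - 2L)]$inpatient_days_countable
    d1[is.na(d1)] <- 0L
    d2[is.na(d2)] <- 0L
    d1 + d2
  }

  rows <- vector("list", nrow(pmap) - 1L)
  n_dropped <- 0L
  medians <- numeric(0)
  for (i in seq_len(nrow(pmap) - 1L)) {
    p <- pmap$p[i + 1L]
    t_out <- pmap$year[i + 1L]
    t_prev <- pmap$year[i]
    s_out <- get_states(t_out)
    s_prev <- get_states(t_prev)
    edu_prev <- cov[.(cohort_ids, t_prev)]$education
    keep <- s_prev != "CENSORED"
    dat <- data.table::data.table(
      person_id = cohort_ids[keep],
      p = p,
      year = t_out,
      state = s_out[keep],
      state_prev = s_prev[keep],
      education_prev = as.character(edu_prev[keep]),
      inpatient_days = window_days(t_out)[keep]
    )
    dat <- base_dt[dat, on = "person_id"]
    miss <- !stats::complete.cases(dat)
    if (any(miss)) {
      n_dropped <- n_dropped + sum(miss)
      dat <- dat[!miss]
    }
    pos_days <- dat$inpatient_days[dat$inpatient_days > 0]
    med <- if (length(pos_days)) stats::median(pos_days) else NA_real_
    medians[as.character(p)] <- med
    dat[, inpatient_cat := if (is.na(med)) "NONE" else
          categorize_inpatient(inpatient_days, med)]
    rows[[i]] <- dat
  }
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("person_id", "p", "year", "state",
                                 "state_prev", "sex", "age_group", "country",
                                 "education_prev", "inpatient_days",
                                 "inpatient_cat"))
  data.table::setDF(out)
  attr(out, "period_medians") <- medians
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("person_period_panel", "data.frame")
  out
}

#' Empirical transition table between two follow-up years
#'
#' Cross-tabulates origin states (Self-sufficient, Jobless, Disabled) at
#' `from_year` against destination states (including Censored) at `to_year`
#' and expresses each origin column in per cent, mirroring the layout of
#' column-per-cent transition tables.
#'
#' @param states data.frame from [classify_cohort()].
#' @param from_year,to_year mapped calendar years, `from_year < to_year`.
#' @param cohort_ids persons to include.
#' @return 4 x 3 matrix of column percentages (rows S, J, D, C; columns S, J,
#'   D), class `transition_table`, with attribute `n` giving origin counts.
#' @export
empirical_transition_table <- function(states, from_year, to_year,
                                       cohort_ids = NULL) {
  if (from_year >= to_year) stop("from_year must precede to_year")
  if (is.null(cohort_ids)) cohort_ids <- unique(states$person_id)
  st <- data.table::as.data.table(states)[person_id %in% cohort_ids]
  data.table::setkey(st, person_id, year)
  from <- st[.(cohort_ids, as.integer(from_year))]$state
  to <- st[.(cohort_ids, as.integer(to_year))]$state
  if (anyNA(from) || anyNA(to)) stop("states do not cover the requested years")
  keep <- from != "CENSORED"
  tab <- table(factor(to[keep], levels = states()),
               factor(from[keep], levels = origin_states()))
  n <- colSums(tab)
  pct <- sweep(tab, 2, pmax(n, 1), "/") * 100
  pct <- unclass(pct)
  structure(pct, class = c("transition_table", class(pct)),
            n = n, type = "empirical",
            from_year = from_year, to_year = to_year)
}

#' @export
print.transition_table <- function(x, digits = 1, ...) {
  type <- attr(x, "type")
  if (identical(type, "empirical")) {
    cat(sprintf("Empirical transitions %d -> %d (column %%):\n",
                attr(x, "from_year"), attr(x, "to_year")))
  }
  print(round(unclass(x), digits))
  invisible(x)
}
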