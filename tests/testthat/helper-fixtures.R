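# fixtures are built in code; no data files

# a register person-year with everything zeroed, fields overridable
blank_record <- function(...) {
  rec <- data.frame(
    person_id = 1L, year = 1995L, earnings = 0,
    unemployment_days = 0L, sickness_days = 0L, disability_days = 0L,
    parental_days = 0L, social_assistance_income = 0,
    student_allowance_income = 0, oldage_pension_income = 0,
    disposable_income = 0, inpatient_days_countable = 0L,
    inpatient_days_excluded = 0L, sex = "MALE", birth_year = 1970L,
    country_of_birth = "SWEDEN", education = "HIGH_SCHOOL",
    died_this_year = FALSE, emigrated_this_year = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# random register records stressing every rule family
random_records <- function(n, seed) {
  set.seed(seed)
  days <- function() sample(c(0L, sample(0:366, n, TRUE)), n, TRUE)
  inc <- function() sample(c(0, round(runif(n, 0, 2), 3)), n, TRUE)
  data.frame(
    person_id = seq_len(n), year = 1995L,
    earnings = sample(c(0, round(runif(n, 0, 3), 3)), n, TRUE),
    unemployment_days = days(), sickness_days = days(),
    disability_days = days(), parental_days = days(),
    social_assistance_income = inc(), student_allowance_income = inc(),
    oldage_pension_income = inc(),
    disposable_income = round(runif(n, 0.5, 3), 3),
    inpatient_days_countable = 0L, inpatient_days_excluded = 0L,
    sex = "MALE", birth_year = 1970L, country_of_birth = "SWEDEN",
    education = "HIGH_SCHOOL",
    died_this_year = runif(n) < 0.03, emigrated_this_year = runif(n) < 0.03,
    stringsAsFactors = FALSE)
}

# independent scalar re-implementation of the classification rules, used as
# a brute-force oracle: evaluates all rule families separately, then applies
# the documented precedence
oracle_classify_one <- function(r, cfg) {
  if (isTRUE(r$died_this_year)) return("DIED")
  if (isTRUE(r$emigrated_this_year)) return("EMIGRATED")
  d <- c(disability = r$disability_days, sickness = r$sickness_days,
         unemployment = r$unemployment_days, parental = r$parental_days)
  if (sum(d) >= cfg$long_term_days) {
    top <- names(d)[which(d == max(d))][1] # vector order = tie precedence
    return(switch(top, disability = "DISABILITY_PENSION",
                  sickness = "LONG_TERM_SICK",
                  unemployment = "LONG_TERM_UNEMPLOYED",
                  parental = "PARENTAL_LEAVE"))
  }
  src <- c(SOCIAL_ASSISTANCE = r$social_assistance_income,
           STUDENT = r$student_allowance_income,
           OLD_AGE_PENSION = r$oldage_pension_income)
  if (any(src > 0)) {
    if (!is.finite(r$disposable_income) || r$disposable_income <= 0) {
      return("ERROR")
    }
    sh <- src / r$disposable_income
    if (max(sh) > cfg$income_share_cut) {
      return(names(sh)[which(sh == max(sh))][1])
    }
  }
  if (r$earnings > cfg$earnings_threshold) return("EMPLOYED")
  "MINIMAL_INCOME"
}

# homogeneous four-state kernel used across simulation tests
# (origins J, S, D x destinations S, J, D, C)
test_kernel <- function() {
  rbind(c(0.40, 0.45, 0.08, 0.07),
        c(0.70, 0.15, 0.10, 0.05),
        c(0.15, 0.20, 0.60, 0.05))
}

# covariate table drawn from the generator's default marginals
random_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sex = sample(c("MALE", "FEMALE"), n, TRUE, c(0.526, 0.474)),
    age_group = sample(c("20-25", "26-30", "31-35", "36-40"), n, TRUE),
    country = sample(c("SWEDEN", "OTHER"), n, TRUE, c(0.747, 0.253)),
    education = sample(c("HIGH_SCHOOL", "LOWER", "HIGHER"), n, TRUE,
                       c(0.589, 0.249, 0.162)),
    stringsAsFactors = FALSE)
}

# panel with exact origin-destination counts (covariates all at reference);
# counts: named list J = c(S, J, D, C), S = ..., D = ...
panel_from_counts <- function(counts) {
  dest <- c("SELF_SUFFICIENT", "JOBLESS", "DISABLED", "CENSORED")
  origin <- c(J = "JOBLESS", S = "SELF_SUFFICIENT", D = "DISABLED")
  rows <- list()
  for (o in names(counts)) {
    for (k in seq_along(dest)) {
      m <- counts[[o]][k]
      if (m == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        person_id = seq_len(m), p = 1L, state = dest[k],
        state_prev = origin[[o]], sex = "MALE", age_group = "20-25",
        country = "SWEDEN", education_prev = "HIGH_SCHOOL",
        inpatient_cat = "NONE", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$person_id <- seq_len(nrow(out))
  out
}
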