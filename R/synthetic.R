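#' Configuration for the synthetic register generator
#'
#' Defines a seeded synthetic cohort with known ground-truth transition
#' dynamics. Defaults emulate the register cohort the package's models are
#' designed for: everyone aged 20-40 at the end of the baseline year, baseline
#' state frequencies and covariate marginals matching the published cohort
#' description, and state dynamics governed by the published Model 3 odds
#' ratios ([reference_ors()]).
#'
#' @param n_persons number of persons (>= 0).
#' @param baseline_year first calendar year (default 1995).
#' @param follow_up_years strictly increasing calendar years after baseline at
#'   which transitions are simulated (default 1997, 2001, 2005, 2008, 2010).
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @param covariate_marginals list of named probability vectors for `sex`,
#'   `age_group`, `country`, `education`; each must sum to 1.
#' @param baseline_state_probs probabilities of the four states at baseline
#'   (defaults from the published position counts: about 25.4% Jobless, 71.4%
#'   Self-sufficient, 3.2% Disabled, 0.04% old-age pensioners).
#' @param education_upgrade_prob per-year probability that education moves one
#'   level up (Lower -> High school -> Higher); default 0.02, which takes the
#'   Higher share from about 16% to about 31% over 15 years.
#' @param true_coefficients 3 x K log-odds coefficient matrix governing the
#'   state dynamics (columns a subset of the Model 3 terms); default
#'   `coefficients_from_ors(reference_ors(3))`.
#' @param censoring_rates named per-year probabilities `death` and
#'   `emigration` applied every follow-up year on top of the kernel's
#'   Censored outcome.
#' @param earnings_threshold employment earnings threshold; currency is
#'   abstract and earnings are scaled relative to it (default 1).
#' @param long_term_days day cut used when rendering long-benefit positions
#'   (must match the classification config; default 183).
#' @param inpatient_model list with `p_any` (named per-state per-year
#'   probability of any inpatient care), `geom_prob` (geometric parameter for
#'   positive day counts, days = 1 + Geom(geom_prob)), and `p_excluded`
#'   (probability of additionally having excluded-diagnosis days, e.g.
#'   childbirth). Default `p_any` for Jobless makes about 86% of baseline
#'   two-year windows care-free.
#' @param position_weights list of named sampling weights for the fine
#'   positions within each state; defaults proportional to the published
#'   position counts (Censored split between death, emigration, and the rare
#'   old-age pension).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_persons,
                             baseline_year = 1995L,
                             follow_up_years = c(1997L, 2001L, 2005L, 2008L, 2010L),
                             seed = 1L,
                             covariate_marginals = list(
                               sex = c(MALE = 0.526, FEMALE = 0.474),
                               age_group = c(`20-25` = 0.30, `26-30` = 0.27,
                                             `31-35` = 0.23, `36-40` = 0.20),
                               country = c(SWEDEN = 0.747, OTHER = 0.253),
                               education = c(HIGH_SCHOOL = 0.589,
                                             LOWER = 0.249, HIGHER = 0.162)),
                             baseline_state_probs = c(
                               JOBLESS = 638622, SELF_SUFFICIENT = 1794403,
                               DISABLED = 80411, CENSORED = 1023) / 2514459,
                             education_upgrade_prob = 0.02,
                             true_coefficients =
                               coefficients_from_ors(reference_ors(3)),
                             censoring_rates = c(death = 0.001,
                                                 emigration = 0.002),
                             earnings_threshold = 1,
                             long_term_days = 183L,
                             inpatient_model = list(
                               p_any = c(SELF_SUFFICIENT = 0.05,
                                         JOBLESS = 0.0705,
                                         DISABLED = 0.30,
                                         CENSORED = 0.02),
                               geom_prob = 0.25,
                               p_excluded = 0.03),
                             position_weights = list(
                               JOBLESS = c(LONG_TERM_UNEMPLOYED = 392035,
                                           SOCIAL_ASSISTANCE = 42041,
                                           MINIMAL_INCOME = 204546),
                               SELF_SUFFICIENT = c(EMPLOYED = 1529669,
                                                   PARENTAL_LEAVE = 116983,
                                                   STUDENT = 147751),
                               DISABLED = c(DISABILITY_PENSION = 44429,
                                            LONG_TERM_SICK = 35982),
                               CENSORED = c(DIED = 0.35, EMIGRATED = 0.64,
                                            OLD_AGE_PENSION = 0.01))) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 0) {
    stop("n_persons must be a single non-negative count")
  }
  follow_up_years <- as.integer(follow_up_years)
  if (any(diff(follow_up_years) <= 0)) {
    stop("follow_up_years must be strictly increasing")
  }
  if (baseline_year >= follow_up_years[1]) {
    stop("baseline_year must precede all follow_up_years")
  }
  for (f in names(covariate_marginals)) {
    p <- covariate_marginals[[f]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
      stop("covariate_marginals$", f, " must be probabilities summing to 1")
    }
    covariate_marginals[[f]] <- p / sum(p)
  }
  if (abs(sum(baseline_state_probs) - 1) > 1e-6 || any(baseline_state_probs < 0)) {
    stop("baseline_state_probs must be probabilities summing to 1")
  }
  baseline_state_probs <- baseline_state_probs / sum(baseline_state_probs)
  if (any(!is.finite(true_coefficients))) {
    stop("true_coefficients must be finite")
  }
  if (!all(colnames(true_coefficients) %in% model_terms(3)) ||
      !"(Intercept)" %in% colnames(true_coefficients)) {
    stop("true_coefficients columns must be a subset of the Model 3 terms ",
         "and include the intercept")
  }
  if (any(censoring_rates < 0) || any(censoring_rates >= 1) ||
      !all(c("death", "emigration") %in% names(censoring_rates))) {
    stop("censoring_rates must name death and emigration probabilities in [0, 1)")
  }
  if (earnings_threshold <= 0) {
    stop("earnings_threshold must be positive (rendering cannot be ",
         "classification-consistent otherwise)")
  }
  if (long_term_days < 150 || long_term_days > 200) {
    stop("long_term_days must lie in [150, 200]")
  }
  structure(list(n_persons = as.integer(n_persons),
                 baseline_year = as.integer(baseline_year),
                 follow_up_years = follow_up_years, seed = as.integer(seed),
                 covariate_marginals = covariate_marginals,
                 baseline_state_probs = baseline_state_probs,
                 education_upgrade_prob = education_upgrade_prob,
                 true_coefficients = true_coefficients,
                 censoring_rates = censoring_rates,
                 earnings_threshold = earnings_threshold,
                 long_term_days = as.integer(long_term_days),
                 inpatient_model = inpatient_model,
                 position_weights = position_weights),
            class = "generator_config")
}

.sample_level <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# vectorised categorical draw from an n x m probability matrix
.draw_categorical <- function(P, labels) {
  stopifnot(ncol(P) == length(labels))
  u <- stats::runif(nrow(P))
  cum <- P[, 1]
  idx <- rep(1L, nrow(P))
  for (j in 2:ncol(P)) {
    idx <- idx + (u > cum)
    if (j < ncol(P)) cum <- cum + P[, j]
  }
  idx[idx > length(labels)] <- length(labels) # guard rounding at the top
  labels[idx]
}

# n x 4 transition probabilities (columns S, J, D, C) from a coefficient
# matrix and a design matrix of active covariates
.transition_probs <- function(B, X) {
  eta <- X %*% t(B) # n x 3 (S, D, C)
  pr <- .mlogit_probs(eta)
  cbind(pr$P[, 1], pr$p0, pr$P[, 2], pr$P[, 3])
}

# design matrix for simulation: columns = colnames(B); covars is a list of
# character vectors (state_prev, sex, age_group, country, education,
# inpatient_cat, period scalar)
.sim_design <- function(terms, n, covars) {
  X <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  X[, "(Intercept)"] <- 1
  set_dummy <- function(col, hit) if (col %in% terms) X[, col] <<- as.numeric(hit)
  set_dummy("prev_SELF_SUFFICIENT", covars$state_prev == "SELF_SUFFICIENT")
  set_dummy("prev_DISABLED", covars$state_prev == "DISABLED")
  if (!is.null(covars$sex)) set_dummy("sex_FEMALE", covars$sex == "FEMALE")
  if (!is.null(covars$age_group)) {
    for (a in .age_levels[-1]) set_dummy(paste0("age_", a), covars$age_group == a)
  }
  if (!is.null(covars$education)) {
    for (e in .edu_levels[-1]) set_dummy(paste0("edu_", e), covars$education == e)
  }
  if (!is.null(covars$country)) set_dummy("country_OTHER", covars$country == "OTHER")
  if (!is.null(covars$inpatient_cat)) {
    for (i in .inpatient_levels[-1]) {
      set_dummy(paste0("inpatient_", i), covars$inpatient_cat == i)
    }
  }
  if (!is.null(covars$period)) {
    for (p in 2:5) set_dummy(paste0("period_", p), covars$period == p)
  }
  X
}

#' Convert a one-step transition kernel to Model 1 coefficients
#'
#' For a homogeneous four-state chain the saturated Model 1 coefficients have
#' a closed form: `alpha_k = log(P(J -> k) / P(J -> J))` and the
#' previous-state effect for origin o is
#' `log(P(o -> k) / P(o -> J)) - alpha_k`.
#'
#' @param kernel 3 x 4 matrix of transition probabilities, rows origins
#'   JOBLESS, SELF_SUFFICIENT, DISABLED; columns destinations
#'   SELF_SUFFICIENT, JOBLESS, DISABLED, CENSORED. Rows must sum to 1 and all
#'   entries must be strictly positive.
#' @return 3 x 3 Model 1 coefficient matrix.
#' @export
kernel_to_coefficients <- function(kernel) {
  if (!is.matrix(kernel) || !identical(dim(kernel), c(3L, 4L))) {
    stop("kernel must be a 3 x 4 matrix (origins J, S, D x destinations S, J, D, C)")
  }
  if (any(kernel <= 0) || any(abs(rowSums(kernel) - 1) > 1e-8)) {
    stop("kernel rows must be strictly positive probabilities summing to 1")
  }
  rownames(kernel) <- c("JOBLESS", "SELF_SUFFICIENT", "DISABLED")
  colnames(kernel) <- states()
  alpha <- log(kernel["JOBLESS", c("SELF_SUFFICIENT", "DISABLED", "CENSORED")] /
                 kernel["JOBLESS", "JOBLESS"])
  beta <- sapply(c("SELF_SUFFICIENT", "DISABLED"), function(o) {
    log(kernel[o, c("SELF_SUFFICIENT", "DISABLED", "CENSORED")] /
          kernel[o, "JOBLESS"]) - alpha
  })
  B <- cbind(alpha, beta)
  dimnames(B) <- list(c("SELF_SUFFICIENT", "DISABLED", "CENSORED"),
                      model_terms(1))
  B
}

#' Simulate state trajectories from known coefficients
#'
#' Forward-simulates the assumed first-order discrete-time chain: every person
#' starts Jobless (the cohort entry condition), successive states are drawn
#' from the four-way probabilities given the current state and covariates, and
#' Censored is absorbing. Used for parameter-recovery studies.
#'
#' @param coeffs 3 x K log-odds coefficient matrix (columns a subset of the
#'   Model 3 terms).
#' @param covariates data.frame with one row per person; columns `sex`,
#'   `age_group`, `country`, `education` as required by the terms of
#'   `coeffs` (ignored otherwise). Covariates are held fixed over periods.
#' @param n_periods number of transitions to simulate (default 5).
#' @param seed RNG seed.
#' @param inpatient_probs probabilities of the three inpatient categories,
#'   drawn independently each person-period when `coeffs` includes inpatient
#'   terms (default roughly the published baseline split).
#' @return list with `states` (matrix, n x (n_periods + 1), column j is the
#'   state at period j - 1) and `rows` (person-period data.frame ready for
#'   [fit_multistate()], origins Censored excluded).
#' @export
simulate_trajectories <- function(coeffs, covariates, n_periods = 5,
                                  seed = 1L,
                                  inpatient_probs = c(NONE = 0.864,
                                                      LE_MEDIAN = 0.074,
                                                      GT_MEDIAN = 0.062)) {
  if (any(!is.finite(coeffs))) stop("coefficients must be finite")
  terms <- colnames(coeffs)
  if (is.numeric(covariates) && length(covariates) == 1) {
    covariates <- data.frame(row.names = seq_len(covariates))
  }
  n <- nrow(covariates)
  set.seed(seed)
  states_mat <- matrix(NA_character_, n, n_periods + 1)
  states_mat[, 1] <- "JOBLESS"
  need_inp <- any(startsWith(terms, "inpatient_"))
  inpatient_probs <- inpatient_probs / sum(inpatient_probs)
  rows <- vector("list", n_periods)
  for (p in seq_len(n_periods)) {
    prev <- states_mat[, p]
    alive <- prev != "CENSORED"
    states_mat[!alive, p + 1] <- "CENSORED"
    if (!any(alive)) next
    inp <- if (need_inp) .sample_level(sum(alive), inpatient_probs) else NULL
    covs <- list(state_prev = prev[alive],
                 sex = covariates$sex[alive],
                 age_group = covariates$age_group[alive],
                 country = covariates$country[alive],
                 education = covariates$education[alive],
                 inpatient_cat = inp,
                 period = min(p, 5L))
    X <- .sim_design(terms, sum(alive), covs)
    P <- .transition_probs(coeffs, X)
    new_state <- .draw_categorical(P, states())
    states_mat[alive, p + 1] <- new_state
    rows[[p]] <- data.frame(
      person_id = which(alive), p = min(p, 5L), state = new_state,
      state_prev = prev[alive],
      sex = if (is.null(covariates$sex)) "MALE" else covariates$sex[alive],
      age_group = if (is.null(covariates$age_group)) "20-25" else
        covariates$age_group[alive],
      country = if (is.null(covariates$country)) "SWEDEN" else
        covariates$country[alive],
      education_prev = if (is.null(covariates$education)) "HIGH_SCHOOL" else
        covariates$education[alive],
      inpatient_cat = if (need_inp) inp else "NONE",
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  list(states = states_mat, rows = rows)
}

#' Draw baseline covariates from the configured marginals
#'
#' Factors are drawn independently (the joint distribution of the register
#' covariates is not published; only marginals are).
#' @keywords internal
.draw_persons <- function(config) {
  n <- config$n_persons
  m <- config$covariate_marginals
  age_group <- .sample_level(n, m$age_group)
  age_lo <- c(`20-25` = 20L, `26-30` = 26L, `31-35` = 31L, `36-40` = 36L)
  age_hi <- c(`20-25` = 25L, `26-30` = 30L, `31-35` = 35L, `36-40` = 40L)
  age <- age_lo[age_group] +
    floor(stats::runif(n) * (age_hi[age_group] - age_lo[age_group] + 1L))
  data.frame(
    person_id = seq_len(n),
    sex = .sample_level(n, m$sex),
    age_group = age_group,
    birth_year = config$baseline_year - as.integer(age),
    country_of_birth = .sample_level(n, m$country),
    education = .sample_level(n, m$education),
    stringsAsFactors = FALSE)
}

# zero-inflated geometric day counts for one year, given state
.draw_inpatient <- function(state, model) {
  n <- length(state)
  p_any <- model$p_any[state]
  p_any[is.na(p_any)] <- 0.05
  any_care <- stats::runif(n) < p_any
  days <- integer(n)
  days[any_care] <- 1L + stats::rgeom(sum(any_care), model$geom_prob)
  days
}

# render intended positions into register variables; returns a data.frame of
# the monetary/day fields (flags handled by the caller)
.render_positions <- function(position, config) {
  n <- length(position)
  thr <- config$earnings_threshold
  cut <- config$long_term_days
  z <- numeric(n)
  out <- data.frame(
    earnings = z, unemployment_days = integer(n), sickness_days = integer(n),
    disability_days = integer(n), parental_days = integer(n),
    social_assistance_income = z, student_allowance_income = z,
    oldage_pension_income = z, disposable_income = z)
  ri <- function(m, lo, hi) lo + floor(stats::runif(m) * (hi - lo + 1))
  ru <- function(m, lo, hi) stats::runif(m, lo, hi)
  for (pos in unique(position)) {
    i <- which(position == pos)
    m <- length(i)
    small_days <- function(hi = 40L) as.integer(ri(m, 0L, hi))
    switch(pos,
      LONG_TERM_UNEMPLOYED = {
        out$unemployment_days[i] <- as.integer(ri(m, cut, 320L))
        out$sickness_days[i] <- small_days()
        out$parental_days[i] <- small_days()
        out$earnings[i] <- ru(m, 0, 0.8 * thr)
        out$disposable_income[i] <- ru(m, 0.2, 1) * thr
      },
      SOCIAL_ASSISTANCE = {
        out$unemployment_days[i] <- small_days(30L)
        out$sickness_days[i] <- small_days(30L)
        out$disposable_income[i] <- ru(m, 0.3, 1.2) * thr
        out$social_assistance_income[i] <-
          out$disposable_income[i] * ru(m, 0.55, 0.9)
        out$earnings[i] <- ru(m, 0, 0.5 * thr)
      },
      MINIMAL_INCOME = {
        out$unemployment_days[i] <- small_days(20L)
        out$earnings[i] <- ru(m, 0, 0.9 * thr)
        out$disposable_income[i] <- out$earnings[i] + ru(m, 0, 0.2) * thr
        out$social_assistance_income[i] <-
          out$disposable_income[i] * ru(m, 0, 0.45)
      },
      EMPLOYED = {
        out$earnings[i] <- thr * ru(m, 1.1, 5)
        out$unemployment_days[i] <- small_days()
        out$sickness_days[i] <- small_days()
        out$parental_days[i] <- small_days()
        out$disposable_income[i] <- out$earnings[i] * ru(m, 0.6, 0.9)
      },
      PARENTAL_LEAVE = {
        out$parental_days[i] <- as.integer(ri(m, cut, 320L))
        out$sickness_days[i] <- small_days()
        out$earnings[i] <- ru(m, 0, 2 * thr)
        out$disposable_income[i] <- ru(m, 0.5, 2) * thr
      },
      STUDENT = {
        out$disposable_income[i] <- ru(m, 0.3, 1.2) * thr
        out$student_allowance_income[i] <-
          out$disposable_income[i] * ru(m, 0.55, 0.9)
        out$unemployment_days[i] <- small_days(30L)
        out$earnings[i] <- ru(m, 0, 0.8 * thr)
      },
      DISABILITY_PENSION = {
        out$disability_days[i] <- as.integer(ri(m, cut, 340L))
        out$sickness_days[i] <- small_days()
        out$earnings[i] <- ru(m, 0, 0.5 * thr)
        out$disposable_income[i] <- ru(m, 0.3, 1) * thr
      },
      LONG_TERM_SICK = {
        out$sickness_days[i] <- as.integer(ri(m, cut, 320L))
        out$disability_days[i] <- small_days()
        out$unemployment_days[i] <- small_days()
        out$earnings[i] <- ru(m, 0, 0.5 * thr)
        out$disposable_income[i] <- ru(m, 0.3, 1) * thr
      },
      OLD_AGE_PENSION = {
        out$disposable_income[i] <- ru(m, 0.3, 1.2) * thr
        out$oldage_pension_income[i] <-
          out$disposable_income[i] * ru(m, 0.55, 0.9)
        out$earnings[i] <- ru(m, 0, 0.5 * thr)
      },
      DIED = NULL,
      EMIGRATED = NULL,
      stop("cannot render position ", pos))
  }
  out
}

#' Generate a synthetic register cohort
#'
#' Simulates each person's state trajectory over the follow-up design from
#' the configured ground-truth coefficients, then renders every alive
#' person-year into register variables that [classify_positions()] maps back
#' to the intended position. Between follow-up years the current state (and
#' fine position) is carried forward; per-year death/emigration hazards act in
#' addition to the kernel's Censored outcome, and no records exist after a
#' person dies or emigrates.
#'
#' The inpatient-care covariate entering the transition kernel is the
#' two-year window sum of the drawn hospital days, categorised against the
#' per-period median among windows with any care (computed over persons still
#' under follow-up), matching how the panel builder later recomputes it.
#'
#' @param config a [generator_config()].
#' @return list of class `register_cohort`: `records` (one row per alive,
#'   non-emigrated person-year, all register fields), `persons` (baseline
#'   covariates plus the pre-baseline inpatient window), `intended` (one row
#'   per person-year with the ground-truth position and state, including
#'   post-censoring years), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  years <- seq(config$baseline_year, max(config$follow_up_years))
  period_years <- config$follow_up_years
  B <- config$true_coefficients
  terms <- colnames(B)
  need_inp <- any(startsWith(terms, "inpatient_"))
  pw <- config$position_weights

  persons <- .draw_persons(config)
  n <- config$n_persons
  empty_records <- data.frame(
    person_id = integer(0), year = integer(0), earnings = numeric(0),
    unemployment_days = integer(0), sickness_days = integer(0),
    disability_days = integer(0), parental_days = integer(0),
    social_assistance_income = numeric(0), student_allowance_income = numeric(0),
    oldage_pension_income = numeric(0), disposable_income = numeric(0),
    inpatient_days_countable = integer(0), inpatient_days_excluded = integer(0),
    sex = character(0), birth_year = integer(0), country_of_birth = character(0),
    education = character(0), died_this_year = logical(0),
    emigrated_this_year = logical(0))
  if (n == 0) {
    return(structure(list(records = empty_records, persons = persons,
                          intended = data.frame(person_id = integer(0),
                                                year = integer(0),
                                                state = character(0),
                                                position = character(0)),
                          config = config),
                     class = "register_cohort"))
  }

  # baseline state and fine position
  state <- .sample_level(n, config$baseline_state_probs)
  position <- character(n)
  for (s in unique(state)) {
    i <- which(state == s)
    w <- pw[[s]]
    if (s == "CENSORED") {
      # at baseline the only live censor category is old-age pension
      position[i] <- "OLD_AGE_PENSION"
    } else {
      position[i] <- .sample_level(length(i), w / sum(w))
    }
  }
  # pre-baseline inpatient window (descriptive, e.g. baseline marginals)
  persons$baseline_inpatient_window <-
    .draw_inpatient(state, config$inpatient_model) +
    .draw_inpatient(state, config$inpatient_model)

  education <- persons$education
  edu_at_last_period <- education
  has_records <- rep(TRUE, n)  # FALSE once dead or emigrated
  died_year <- rep(NA_integer_, n)
  emig_year <- rep(NA_integer_, n)
  days_countable <- matrix(0L, n, length(years),
                           dimnames = list(NULL, as.character(years)))

  rec_list <- vector("list", length(years))
  int_list <- vector("list", length(years))

  for (yi in seq_along(years)) {
    y <- years[yi]
    if (y > config$baseline_year) {
      # education upgrades happen each year
      up <- stats::runif(n) < config$education_upgrade_prob
      education[up & education == "LOWER"] <- "HIGH_SCHOOL_PENDING"
      education[up & education == "HIGH_SCHOOL"] <- "HIGHER"
      education[education == "HIGH_SCHOOL_PENDING"] <- "HIGH_SCHOOL"

      # per-year censoring hazards for those still in follow-up
      at_risk <- has_records & state != "CENSORED"
      die <- at_risk & stats::runif(n) < config$censoring_rates["death"]
      emig <- at_risk & !die & stats::runif(n) < config$censoring_rates["emigration"]
      state[die | emig] <- "CENSORED"
      position[die] <- "DIED"
      position[emig] <- "EMIGRATED"
      died_year[die] <- y
      emig_year[emig] <- y
    }
    if (y %in% period_years) {
      alive <- state != "CENSORED"
      if (any(alive)) {
        p_idx <- min(match(y, period_years), 5L)
        inp_cat <- NULL
        if (need_inp) {
          w1 <- if ((y - 1) >= years[1]) days_countable[, as.character(y - 1)] else 0L
          w2 <- if ((y - 2) >= years[1]) days_countable[, as.character(y - 2)] else 0L
          window <- w1 + w2
          pos_win <- window[alive & window > 0]
          med <- if (length(pos_win)) stats::median(pos_win) else 1
          inp_cat <- categorize_inpatient(window[alive], max(med, 1))
        }
        covs <- list(state_prev = state[alive], sex = persons$sex[alive],
                     age_group = persons$age_group[alive],
                     country = persons$country_of_birth[alive],
                     education = edu_at_last_period[alive],
                     inpatient_cat = inp_cat, period = p_idx)
        X <- .sim_design(terms, sum(alive), covs)
        P <- .transition_probs(B, X)
        new_state <- .draw_categorical(P, states())
        idx <- which(alive)
        state[idx] <- new_state
        # realise new positions
        for (s in unique(new_state)) {
          j <- idx[new_state == s]
          if (s == "CENSORED") {
            w <- pw$CENSORED / sum(pw$CENSORED)
            kind <- .sample_level(length(j), w)
            position[j] <- kind
            died_year[j[kind == "DIED"]] <- y
            emig_year[j[kind == "EMIGRATED"]] <- y
          } else {
            w <- pw[[s]]
            position[j] <- .sample_level(length(j), w / sum(w))
          }
        }
      }
      edu_at_last_period <- education
    }
    # draw this year's inpatient days (given current state)
    days_countable[, yi] <- .draw_inpatient(state, config$inpatient_model)
    excl <- stats::runif(n) < config$inpatient_model$p_excluded
    days_excl <- integer(n)
    days_excl[excl] <- 1L + stats::rgeom(sum(excl),
                                         config$inpatient_model$geom_prob)

    # emit records for persons still generating them
    emit <- has_records
    if (any(emit)) {
      i <- which(emit)
      flds <- .render_positions(position[i], config)
      rec_list[[yi]] <- data.frame(
        person_id = persons$person_id[i], year = y, flds,
        inpatient_days_countable = days_countable[i, yi],
        inpatient_days_excluded = days_excl[i],
        sex = persons$sex[i], birth_year = persons$birth_year[i],
        country_of_birth = persons$country_of_birth[i],
        education = education[i],
        died_this_year = !is.na(died_year[i]) & died_year[i] == y,
        emigrated_this_year = !is.na(emig_year[i]) & emig_year[i] == y,
        stringsAsFactors = FALSE)
    }
    int_list[[yi]] <- data.frame(person_id = persons$person_id, year = y,
                                 state = state, position = position,
                                 stringsAsFactors = FALSE)
    # stop records after the death/emigration year
    has_records <- has_records &
      !((!is.na(died_year) & died_year <= y) |
          (!is.na(emig_year) & emig_year <= y))
  }

  records <- do.call(rbind, rec_list)
  if (is.null(records)) records <- empty_records
  records <- records[order(records$person_id, records$year), ]
  rownames(records) <- NULL
  intended <- do.call(rbind, int_list)
  intended <- intended[order(intended$person_id, intended$year), ]
  rownames(intended) <- NULL
  structure(list(records = records, persons = persons, intended = intended,
                 config = config),
            class = "register_cohort")
}

#' @export
print.register_cohort <- function(x, ...) {
  cat(sprintf("Synthetic register cohort: %d persons, %d person-year records, %d-%d\n",
              x$config$n_persons, nrow(x$records), x$config$baseline_year,
              max(x$config$follow_up_years)))
  invisible(x)
}
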