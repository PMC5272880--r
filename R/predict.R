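#' Reference odds-ratio sets for the four-state transition model
#'
#' Published two-decimal odds ratios for the three nested transition models
#' estimated on the full Swedish register cohort of people jobless at
#' baseline. They serve as a reference coefficient set: worked examples,
#' probability-grid reproduction, and the synthetic generator's default
#' ground-truth dynamics all use them. Exponentials of the model
#' coefficients; the intercept rows are on the exp scale too.
#'
#' Because the values are rounded to two decimals, downstream probabilities
#' carry roughly one percentage point of uncertainty (the Disabled intercept
#' 0.02 alone spans 0.015-0.025).
#'
#' @param model 1, 2 or 3.
#' @return 3 x K matrix of odds ratios (rows SELF_SUFFICIENT, DISABLED,
#'   CENSORED; columns `model_terms(model)`).
#' @examples
#' log(reference_ors(3))  # coefficients on the log-odds scale
#' @export
reference_ors <- function(model = 3) {
  if (!model %in% 1:3) stop("model must be 1, 2 or 3")
  m1 <- rbind(
    SELF_SUFFICIENT = c(0.82, 10.94, 1.40),
    DISABLED        = c(0.10,  3.77, 68.66),
    CENSORED        = c(0.08,  1.46, 2.34)
  )
  m2 <- rbind(
    SELF_SUFFICIENT = c(1.20, 9.36, 1.39, 1.17, 0.75, 0.65, 0.58, 0.58, 1.47, 0.66),
    DISABLED        = c(0.06, 3.90, 65.31, 1.56, 1.26, 1.47, 1.73, 1.09, 0.81, 0.82),
    CENSORED        = c(0.06, 1.42, 2.44, 0.97, 0.89, 0.79, 0.74, 1.13, 2.04, 2.01)
  )
  m3 <- rbind(
    SELF_SUFFICIENT = c(1.14, 9.88, 1.53, 1.19, 0.75, 0.64, 0.58, 0.57, 1.48,
                        0.66, 0.86, 0.65, 1.44, 0.82, 1.29, 0.86),
    DISABLED        = c(0.02, 2.64, 49.37, 1.56, 1.25, 1.45, 1.70, 1.04, 0.83,
                        0.81, 1.64, 3.13, 5.73, 5.93, 5.18, 2.62),
    CENSORED        = c(0.04, 1.22, 2.51, 0.98, 0.87, 0.77, 0.72, 1.10, 2.06,
                        1.95, 0.54, 1.34, 2.80, 2.31, 2.23, 0.95)
  )
  out <- switch(model, m1, m2, m3)
  colnames(out) <- model_terms(model)
  out
}

#' Convert an odds-ratio table to a coefficient set
#'
#' Coefficients are the natural logarithms of the supplied odds ratios
#' (intercept columns included). Intended for injecting published,
#' two-decimal OR tables; a note about the rounding-induced uncertainty is
#' attached as an attribute.
#'
#' @param or_table 3 x K matrix of odds ratios with outcome rows
#'   SELF_SUFFICIENT, DISABLED, CENSORED and term columns (see
#'   [model_terms()]).
#' @return 3 x K coefficient matrix (log-odds), attribute
#'   `provenance = "printed_ors"`.
#' @export
coefficients_from_ors <- function(or_table) {
  if (!is.matrix(or_table) || nrow(or_table) != 3) {
    stop("or_table must be a 3-row matrix (outcomes S, D, C)")
  }
  if (any(!is.finite(or_table)) || any(or_table <= 0)) {
    stop("odds ratios must be positive and finite")
  }
  out <- log(or_table)
  rownames(out) <- c("SELF_SUFFICIENT", "DISABLED", "CENSORED")
  attr(out, "provenance") <- "printed_ors"
  out
}

#' Linear predictors for a covariate profile
#'
#' Sums the coefficients over the profile's active dummies, one value per
#' non-reference outcome; the reference outcome (Jobless) implicitly has
#' predictor 0.
#'
#' @param coeffs 3 x K coefficient matrix (log-odds), columns a subset of the
#'   Model 3 term set.
#' @param profile named list with elements `previous_state`, and, as required
#'   by the terms present, `sex`, `age_group`, `education`, `country`,
#'   `inpatient_cat`, `period`.
#' @return named length-3 vector (SELF_SUFFICIENT, DISABLED, CENSORED).
#' @export
linear_predictors <- function(coeffs, profile) {
  x <- .profile_design(profile, colnames(coeffs))
  eta <- as.vector(coeffs %*% x)
  names(eta) <- rownames(coeffs)
  eta
}

# 0/1 design vector for a profile, in the order of `terms`
.profile_design <- function(profile, terms) {
  if (identical(profile$previous_state, "CENSORED")) {
    stop("CENSORED cannot be a previous state")
  }
  active <- "(Intercept)"
  add_level <- function(value, levels, prefix, what) {
    if (is.null(value)) stop("profile is missing ", what)
    value <- as.character(value)
    if (!value %in% levels) {
      stop("invalid ", what, ": ", value)
    }
    if (value != levels[1]) paste0(prefix, "_", value) else character(0)
  }
  active <- c(active, add_level(profile$previous_state,
                                c("JOBLESS", "SELF_SUFFICIENT", "DISABLED"),
                                "prev", "previous_state"))
  need <- function(prefix) any(startsWith(terms, paste0(prefix, "_")))
  if (need("sex")) active <- c(active, add_level(profile$sex, .sex_levels,
                                                 "sex", "sex"))
  if (need("age")) active <- c(active, add_level(profile$age_group,
                                                 .age_levels, "age",
                                                 "age_group"))
  if (need("edu")) active <- c(active, add_level(profile$education,
                                                 .edu_levels, "edu",
                                                 "education"))
  if (need("country")) active <- c(active, add_level(profile$country,
                                                     .country_levels,
                                                     "country", "country"))
  if (need("inpatient")) active <- c(active, add_level(profile$inpatient_cat,
                                                       .inpatient_levels,
                                                       "inpatient",
                                                       "inpatient_cat"))
  if (need("period")) active <- c(active, add_level(as.character(profile$period),
                                                    as.character(1:5),
                                                    "period", "period"))
  bad <- setdiff(active, terms)
  if (length(bad)) {
    stop("profile needs term(s) absent from the coefficient set: ",
         paste(bad, collapse = ", "))
  }
  as.numeric(terms %in% active)
}

#' Four-way transition probabilities from linear predictors
#'
#' The sum-to-one constraint of the jointly estimated equations is enforced by
#' construction: `p = (exp(eta_S), 1, exp(eta_D), exp(eta_C)) / (1 + sum(exp(eta)))`,
#' numerically stabilised by subtracting the maximum predictor.
#'
#' @param eta length-3 numeric vector of linear predictors
#'   (SELF_SUFFICIENT, DISABLED, CENSORED); the Jobless predictor is 0.
#' @return named length-4 probability vector in display order
#'   SELF_SUFFICIENT, JOBLESS, DISABLED, CENSORED, summing to 1.
#' @examples
#' softmax_probabilities(c(0, 0, 0)) # rep(0.25, 4)
#' @export
softmax_probabilities <- function(eta) {
  if (length(eta) != 3 || any(!is.finite(eta))) {
    stop("eta must be a finite length-3 vector")
  }
  m <- max(0, eta)
  e <- exp(c(eta[1], 0, eta[2], eta[3]) - m)
  p <- e / sum(e)
  names(p) <- states()
  p
}

#' Model-based transition-probability table over strata
#'
#' Computes four-way transition probabilities for a fixed socio-demographic
#' profile, stratified by follow-up period and inpatient-care category, for
#' each origin state - the layout of the published stratified probability
#' table (fixed profile: male, born in Sweden, age 26-30, high-school
#' education).
#'
#' @param coeffs 3 x K coefficient matrix (fitted, or injected from printed
#'   ORs via [coefficients_from_ors()]).
#' @param base_profile named list of the fixed covariates (`sex`,
#'   `age_group`, `country`, `education`). Defaults to the published profile.
#' @param periods period indices to stratify over (default 2:5, i.e. the
#'   1997-2001, 2001-2005, 2005-2008 and 2008-2010 intervals).
#' @param inpatient inpatient categories to stratify over.
#' @param origins origin states (default all three non-absorbing states).
#' @return data.frame of class `probability_table`, long format: `origin`,
#'   `period`, `period_label`, `inpatient`, `destination`, `probability`
#'   (percent, unrounded). Use [format_probability_table()] for the wide
#'   one-decimal layout.
#' @export
probability_table <- function(coeffs,
                              base_profile = list(sex = "MALE",
                                                  age_group = "26-30",
                                                  country = "SWEDEN",
                                                  education = "HIGH_SCHOOL"),
                              periods = 2:5,
                              inpatient = c("NONE", "LE_MEDIAN", "GT_MEDIAN"),
                              origins = c("SELF_SUFFICIENT", "JOBLESS",
                                          "DISABLED")) {
  period_labels <- c(`1` = "1995-1997 increasing",
                     `2` = "1997-2001 decreasing",
                     `3` = "2001-2005 increasing",
                     `4` = "2005-2008 decreasing",
                     `5` = "2008-2010 increasing")
  grid <- expand.grid(inpatient = inpatient, period = periods,
                      origin = origins, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    prof <- c(base_profile,
              list(previous_state = grid$origin[i],
                   period = grid$period[i],
                   inpatient_cat = grid$inpatient[i]))
    p <- softmax_probabilities(linear_predictors(coeffs, prof)) * 100
    data.frame(origin = grid$origin[i],
               period = grid$period[i],
               period_label = unname(period_labels[as.character(grid$period[i])]),
               inpatient = grid$inpatient[i],
               destination = names(p),
               probability = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("probability_table", "data.frame")
  out
}

# round half up, mirroring one-decimal published tables
.round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Wide one-decimal layout of a probability table
#'
#' @param tab a `probability_table`.
#' @return data.frame with one row per origin -> destination transition and
#'   one column per (period, inpatient) stratum, percentages rounded half-up
#'   to one decimal.
#' @export
format_probability_table <- function(tab) {
  stopifnot(inherits(tab, "probability_table"))
  tab$transition <- paste0(substr(tab$origin, 1, 1), " -> ",
                           substr(tab$destination, 1, 1))
  tab$stratum <- paste0(tab$period_label, " / ", tab$inpatient)
  strata <- unique(tab$stratum)
  trans <- unique(tab$transition)
  wide <- data.frame(transition = trans, stringsAsFactors = FALSE)
  for (s in strata) {
    sub <- tab[tab$stratum == s, ]
    wide[[s]] <- .round_half_up(sub$probability[match(trans, sub$transition)])
  }
  wide
}
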