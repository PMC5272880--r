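#' Write / read a synthetic registry as tidy CSV
#'
#' One row per person-year with the register field names as header, plus a
#' JSON sidecar echoing the full generator configuration and seed.
#'
#' @param cohort a `register_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_registry <- function(cohort, dir) {
  stopifnot(inherits(cohort, "register_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "registry.csv")
  side <- file.path(dir, "registry_config.json")
  data.table::fwrite(cohort$records, csv)
  cfg <- unclass(cohort$config)
  cfg$true_coefficients <- list(
    terms = colnames(cfg$true_coefficients),
    outcomes = rownames(cfg$true_coefficients),
    values = unname(as.data.frame(cfg$true_coefficients)))
  jsonlite::write_json(cfg, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(registry = csv, config = side))
}

#' @rdname write_registry
#' @param path path to a registry CSV.
#' @export
read_registry <- function(path) {
  rec <- data.table::fread(path, data.table = FALSE)
  .check_register_fields(rec)
  rec
}

#' Validate a person-period panel
#'
#' Asserts the panel invariants: no Censored origins, period indices >= 1, no
#' duplicate (person, period) rows, valid factor levels throughout, and
#' reproducible inpatient categorisation (recomputing the per-period median
#' among rows with any care yields the stored categories, so row order cannot
#' matter).
#'
#' @param panel a `person_period_panel` (or a data.frame with its columns).
#' @return list of class `panel_validation` with elements `checks` (named
#'   logical vector), `messages` (per failed check), and `ok`.
#' @export
validate_panel <- function(panel) {
  checks <- c(no_censored_origin = TRUE, periods_positive = TRUE,
              no_duplicates = TRUE, valid_levels = TRUE,
              states_valid = TRUE, median_reproducible = TRUE)
  msgs <- character(0)
  fail <- function(name, msg) {
    checks[name] <<- FALSE
    msgs[name] <<- msg
  }
  if (any(panel$state_prev == "CENSORED")) {
    fail("no_censored_origin",
         sprintf("%d row(s) with CENSORED origin", sum(panel$state_prev == "CENSORED")))
  }
  if (any(panel$p < 1)) fail("periods_positive", "period indices below 1")
  if (anyDuplicated(panel[c("person_id", "p")])) {
    fail("no_duplicates", "duplicate (person_id, p) rows")
  }
  lev_ok <- all(panel$sex %in% .sex_levels) &&
    all(panel$age_group %in% .age_levels) &&
    all(panel$country %in% .country_levels) &&
    all(panel$education_prev %in% .edu_levels) &&
    all(panel$inpatient_cat %in% .inpatient_levels)
  if (!lev_ok) fail("valid_levels", "invalid factor level(s)")
  if (!all(panel$state %in% states()) ||
      !all(panel$state_prev %in% origin_states())) {
    fail("states_valid", "invalid state value(s)")
  }
  if (!is.null(panel$inpatient_days)) {
    for (p in unique(panel$p)) {
      sub <- panel[panel$p == p, ]
      pos <- sub$inpatient_days[sub$inpatient_days > 0]
      if (!length(pos)) next
      med <- stats::median(pos)
      expect <- categorize_inpatient(sub$inpatient_days, med)
      if (!all(expect == sub$inpatient_cat)) {
        fail("median_reproducible",
             sprintf("inpatient categories do not reproduce at period %s", p))
        break
      }
    }
  }
  structure(list(checks = checks, messages = msgs, ok = all(checks)),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  status <- ifelse(x$checks, "PASS", "FAIL")
  for (nm in names(x$checks)) {
    cat(sprintf("  [%s] %s%s\n", status[nm], nm,
                if (!x$checks[nm]) paste0(": ", x$messages[nm]) else ""))
  }
  cat(if (x$ok) "panel OK\n" else "panel INVALID\n")
  invisible(x)
}

#' Run the full synthetic-register analysis pipeline
#'
#' generate -> classify -> select baseline -> build panel -> fit models ->
#' predict, writing every artifact (registry, states, panel, empirical
#' transition tables, odds-ratio tables, model-based probability table, run
#' manifest) as CSV/JSON under `out_dir`. Deterministic under a fixed seed.
#'
#' @param gen_config a [generator_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param class_config a [classification_config()] (its `earnings_threshold`
#'   and `long_term_days` should match the generator's).
#' @param pmap a [period_map()]; defaults to the generator's baseline and
#'   follow-up years.
#' @param models which of models 1-3 to fit.
#' @return (invisibly) list with `cohort`, `states`, `baseline_ids`, `panel`,
#'   `fits`, `or_tables`, `empirical_tables`, `prob_table`, `manifest`.
#' @export
run_pipeline <- function(gen_config, out_dir = NULL,
                         class_config = classification_config(
                           earnings_threshold = gen_config$earnings_threshold,
                           long_term_days = gen_config$long_term_days),
                         pmap = period_map(c(gen_config$baseline_year,
                                             gen_config$follow_up_years)),
                         models = 1:3) {
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(gen_config)
  states_df <- classify_cohort(cohort$records, class_config,
                               years = pmap$year[1]:max(pmap$year))
  base_ids <- select_baseline(states_df, pmap$year[pmap$p == 0])
  covars <- cohort$records[, c("person_id", "year", "sex", "birth_year",
                               "country_of_birth", "education")]
  inpat <- cohort$records[, c("person_id", "year", "inpatient_days_countable")]
  panel <- build_person_periods(states_df, covars, inpat, pmap,
                                cohort_ids = base_ids)
  val <- validate_panel(panel)
  if (!val$ok) stop("panel validation failed: ",
                    paste(val$messages, collapse = "; "))

  fits <- list()
  or_tables <- list()
  for (m in models) {
    fits[[as.character(m)]] <- fit_multistate(panel, model = m)
    or_tables[[as.character(m)]] <- odds_ratios(fits[[as.character(m)]])
  }

  emp <- list()
  for (i in seq_len(nrow(pmap) - 1)) {
    key <- sprintf("%d_%d", pmap$year[i], pmap$year[i + 1])
    emp[[key]] <- empirical_transition_table(states_df, pmap$year[i],
                                             pmap$year[i + 1],
                                             cohort_ids = base_ids)
  }

  prob_tab <- NULL
  last <- as.character(max(models))
  if ("3" %in% names(fits)) {
    prob_tab <- probability_table(fits[["3"]]$coefficients)
  } else if (length(fits)) {
    prob_tab <- probability_table(
      fits[[last]]$coefficients,
      periods = if (any(startsWith(fits[[last]]$terms, "period_"))) 2:5 else 1,
      inpatient = if (any(startsWith(fits[[last]]$terms, "inpatient_")))
        c("NONE", "LE_MEDIAN", "GT_MEDIAN") else "NONE")
  }

  manifest <- list(
    seed = gen_config$seed,
    n_persons = gen_config$n_persons,
    package_version = as.character(utils::packageVersion("labmarkov")),
    n_records = nrow(cohort$records),
    n_baseline_jobless = length(base_ids),
    n_panel_rows = nrow(panel),
    n_panel_dropped = attr(panel, "n_dropped"),
    period_medians = as.list(attr(panel, "period_medians")),
    models = lapply(fits, function(f) list(
      model = f$model, loglik = f$loglik, minus2ll = -2 * f$loglik,
      n_rows = f$n_rows, n_iter = f$n_iter, converged = f$converged,
      pseudo_r2 = pseudo_r2(f))))

  if (write_out) {
    write_registry(cohort, out_dir)
    data.table::fwrite(states_df, file.path(out_dir, "states.csv"))
    data.table::fwrite(panel, file.path(out_dir, "panel.csv"))
    for (key in names(emp)) {
      data.table::fwrite(as.data.frame(unclass(emp[[key]])),
                         file.path(out_dir, sprintf("empirical_%s.csv", key)),
                         row.names = TRUE)
    }
    for (m in names(or_tables)) {
      data.table::fwrite(or_tables[[m]],
                         file.path(out_dir, sprintf("or_table_model%s.csv", m)))
    }
    if (!is.null(prob_tab)) {
      data.table::fwrite(format_probability_table(prob_tab),
                         file.path(out_dir, "probability_table.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(cohort = cohort, states = states_df, baseline_ids = base_ids,
                 panel = panel, fits = fits, or_tables = or_tables,
                 empirical_tables = emp, prob_table = prob_tab,
                 manifest = manifest))
}

#' Stratified probability table from the reference odds ratios
#'
#' "Paper mode": no data are generated or fitted; the published Model 3 odds
#' ratios are injected via [coefficients_from_ors()] and rendered as the
#' stratified probability grid for the fixed reference profile (male, born in
#' Sweden, age 26-30, high-school education).
#'
#' @param out_file optional CSV path for the wide one-decimal layout.
#' @return the long-format `probability_table` (invisibly if written).
#' @export
reference_table <- function(out_file = NULL) {
  tab <- probability_table(coefficients_from_ors(reference_ors(3)))
  if (!is.null(out_file)) {
    data.table::fwrite(format_probability_table(tab), out_file)
    return(invisible(tab))
  }
  tab
}
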