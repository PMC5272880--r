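# shared small cohort for panel tests: generated once, classified once
local_cohort <- local({
  cfg <- generator_config(n_persons = 1500, seed = 77)
  coh <- generate_cohort(cfg)
  st <- classify_cohort(coh$records)
  list(cfg = cfg, coh = coh, states = st,
       pmap = period_map(),
       ids = select_baseline(st, 1995))
})

test_that("period map validates ordering and indexing", {
  pm <- period_map()
  expect_equal(pm$p, 0:5)
  expect_equal(pm$year, c(1995, 1997, 2001, 2005, 2008, 2010))
  expect_error(period_map(c(1995, 1995)), "strictly increasing")
  expect_error(period_map(2001), "at least two")
})

test_that("baseline selection returns exactly the jobless at baseline", {
  st <- data.frame(person_id = rep(1:10, each = 1), year = 1995,
                   state = c(rep("JOBLESS", 4), rep("SELF_SUFFICIENT", 6)))
  expect_equal(select_baseline(st, 1995), 1:4)
  st$state <- "SELF_SUFFICIENT"
  expect_length(select_baseline(st, 1995), 0)
  expect_error(select_baseline(st, 1990), "baseline_year")
})

test_that("inpatient categorisation matches its definition and a sort oracle", {
  expect_equal(categorize_inpatient(0, 3), "NONE")
  # a value equal to the median falls in the <= median category
  expect_equal(categorize_inpatient(3, 3), "LE_MEDIAN")
  expect_equal(categorize_inpatient(4, 3), "GT_MEDIAN")
  expect_error(categorize_inpatient(-1, 3), "non-negative")
  expect_error(categorize_inpatient(1, 0), "positive")
  set.seed(55)
  for (rep in 1:20) {
    days <- rpois(200, 2)
    pos <- sort(days[days > 0])
    if (!length(pos)) next
    med <- if (length(pos) %% 2) pos[(length(pos) + 1) / 2] else
      (pos[length(pos) / 2] + pos[length(pos) / 2 + 1]) / 2
    got <- categorize_inpatient(days, med)
    want <- ifelse(days == 0, "NONE",
                   ifelse(days <= med, "LE_MEDIAN", "GT_MEDIAN"))
    expect_identical(got, want)
  }
})

test_that("panel rows stop at the first censored outcome", {
  # hand-built state sequence: censored at the 2001 follow-up
  years <- c(1995, 1997, 2001, 2005, 2008, 2010)
  st <- data.frame(person_id = 1L, year = 1995:2010)
  st$state <- ifelse(st$year >= 2001, "CENSORED",
                     ifelse(st$year >= 1997, "SELF_SUFFICIENT", "JOBLESS"))
  covar <- data.frame(person_id = 1L, year = 1995:2010, sex = "MALE",
                      birth_year = 1970L, country_of_birth = "SWEDEN",
                      education = "HIGH_SCHOOL")
  inp <- data.frame(person_id = 1L, year = 1995:2010,
                    inpatient_days_countable = 0L)
  panel <- build_person_periods(st, covar, inp, period_map(),
                                cohort_ids = 1L)
  expect_equal(panel$p, c(1L, 2L))
  expect_equal(panel$state, c("SELF_SUFFICIENT", "CENSORED"))
  expect_equal(panel$state_prev, c("JOBLESS", "SELF_SUFFICIENT"))
  expect_equal(panel$age_group, rep("20-25", 2)) # age 25 at baseline
})

test_that("panel row count equals a brute-force per-person recount", {
  lc <- local_cohort
  covars <- lc$coh$records[, c("person_id", "year", "sex", "birth_year",
                               "country_of_birth", "education")]
  inp <- lc$coh$records[, c("person_id", "year", "inpatient_days_countable")]
  panel <- build_person_periods(lc$states, covars, inp, lc$pmap,
                                cohort_ids = lc$ids)
  # oracle: per person, count periods p >= 1 whose previous state is alive
  years <- lc$pmap$year
  st <- lc$states
  expected <- 0L
  for (id in lc$ids) {
    s <- st$state[st$person_id == id & st$year %in% years]
    expected <- expected + sum(s[-length(s)] != "CENSORED")
  }
  expect_equal(nrow(panel) + attr(panel, "n_dropped"), expected)
  expect_equal(attr(panel, "n_dropped"), 0L)
  # invariants
  expect_false(any(panel$state_prev == "CENSORED"))
  expect_true(all(panel$p >= 1))
  val <- validate_panel(panel)
  expect_true(val$ok)
})

test_that("panel covariates and medians are invariant to input row order", {
  lc <- local_cohort
  covars <- lc$coh$records[, c("person_id", "year", "sex", "birth_year",
                               "country_of_birth", "education")]
  inp <- lc$coh$records[, c("person_id", "year", "inpatient_days_countable")]
  p1 <- build_person_periods(lc$states, covars, inp, lc$pmap,
                             cohort_ids = lc$ids)
  set.seed(1)
  shuf <- function(d) d[sample(nrow(d)), ]
  p2 <- build_person_periods(shuf(lc$states), shuf(covars), shuf(inp),
                             lc$pmap, cohort_ids = sample(lc$ids))
  expect_equal(p1$inpatient_cat, p2$inpatient_cat)
  expect_equal(attr(p1, "period_medians"), attr(p2, "period_medians"))
  expect_equal(p1$education_prev, p2$education_prev)
})

test_that("empirical transition table equals a hand tally and normalises", {
  # single person J -> S
  st <- data.frame(person_id = 1L, year = c(1995L, 1997L),
                   state = c("JOBLESS", "SELF_SUFFICIENT"))
  tab <- empirical_transition_table(st, 1995, 1997)
  expect_equal(unname(tab[, "JOBLESS"]), c(100, 0, 0, 0))

  lc <- local_cohort
  # 1997 -> 2001: by then the baseline-jobless cohort occupies all origins
  tab <- empirical_transition_table(lc$states, 1997, 2001,
                                    cohort_ids = lc$ids)
  occupied <- attr(tab, "n") > 0
  expect_true(all(abs(colSums(tab)[occupied] - 100) < 0.1))
  # independent tally
  from <- lc$states[lc$states$year == 1997 & lc$states$person_id %in% lc$ids, ]
  to <- lc$states[lc$states$year == 2001 & lc$states$person_id %in% lc$ids, ]
  m <- merge(from, to, by = "person_id")
  for (o in origin_states()[occupied]) {
    sub <- m[m$state.x == o, ]
    for (d in states()) {
      expect_equal(tab[d, o], 100 * mean(sub$state.y == d),
                   tolerance = 1e-12)
    }
  }
  expect_error(empirical_transition_table(lc$states, 1997, 1995), "precede")
})

test_that("panel validation flags censored origins and broken categories", {
  lc <- local_cohort
  covars <- lc$coh$records[, c("person_id", "year", "sex", "birth_year",
                               "country_of_birth", "education")]
  inp <- lc$coh$records[, c("person_id", "year", "inpatient_days_countable")]
  panel <- build_person_periods(lc$states, covars, inp, lc$pmap,
                                cohort_ids = lc$ids)
  expect_true(validate_panel(panel)$ok)
  broken <- panel
  broken$state_prev[1] <- "CENSORED"
  v <- validate_panel(broken)
  expect_false(v$ok)
  expect_false(v$checks["no_censored_origin"])
  broken2 <- panel
  i <- which(broken2$inpatient_days > 0)[1]
  if (!is.na(i)) {
    broken2$inpatient_cat[i] <- "NONE"
    v2 <- validate_panel(broken2)
    expect_false(v2$checks["median_reproducible"] && v2$checks["valid_levels"] &&
                   v2$ok)
  }
})
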