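test_that("design matrix uses reference coding with deterministic columns", {
  rows <- panel_from_counts(list(J = c(2, 2, 1, 1), S = c(1, 1, 1, 1),
                                 D = c(1, 1, 1, 1)))
  X1 <- design_matrix(rows, 1)
  expect_equal(colnames(X1), c("(Intercept)", "prev_SELF_SUFFICIENT",
                               "prev_DISABLED"))
  # reference-profile row is (1, 0, ..., 0)
  ref <- rows[1, ]
  ref$state_prev <- "JOBLESS"
  x <- design_matrix(ref, 3)
  expect_equal(unname(x[1, ]), c(1, rep(0, 15)))
  expect_error(design_matrix(rows[0, ], 1), "non-empty")
  bad <- rows
  bad$state_prev[1] <- "CENSORED"
  expect_error(design_matrix(bad, 1), "CENSORED")
})

test_that("design matrix matches a naive per-row dictionary oracle", {
  sim <- simulate_trajectories(coefficients_from_ors(reference_ors(3)),
                               random_covariates(150, seed = 8),
                               n_periods = 4, seed = 8)
  rows <- sim$rows
  X <- design_matrix(rows, 3)
  terms <- model_terms(3)
  for (i in sample(nrow(rows), 40)) {
    r <- rows[i, ]
    active <- c("(Intercept)",
                if (r$state_prev != "JOBLESS") paste0("prev_", r$state_prev),
                if (r$sex == "FEMALE") "sex_FEMALE",
                if (r$age_group != "20-25") paste0("age_", r$age_group),
                if (r$education_prev != "HIGH_SCHOOL")
                  paste0("edu_", r$education_prev),
                if (r$country == "OTHER") "country_OTHER",
                if (r$inpatient_cat != "NONE")
                  paste0("inpatient_", r$inpatient_cat),
                if (r$p != 1) paste0("period_", r$p))
    expect_equal(unname(X[i, ]), as.numeric(terms %in% active))
  }
})

test_that("negative log-likelihood matches direct probability enumeration", {
  rows <- panel_from_counts(list(J = c(5, 6, 2, 1), S = c(3, 2, 1, 1),
                                 D = c(1, 1, 3, 1)))
  X <- design_matrix(rows, 1)
  y <- attr(X, "y")
  B0 <- matrix(0, 3, 3, dimnames = list(c("SELF_SUFFICIENT", "DISABLED",
                                          "CENSORED"), colnames(X)))
  # all-zero coefficients: uniform four-way probabilities
  expect_equal(negative_loglik(B0, X, y), nrow(X) * log(4))
  set.seed(21)
  for (rep in 1:10) {
    B <- matrix(rnorm(9), 3, 3, dimnames = dimnames(B0))
    # brute force: per row, the four unnormalised weights
    nll <- 0
    for (i in seq_len(nrow(X))) {
      eta <- as.vector(B %*% X[i, ])
      w <- c(JOBLESS = 1, SELF_SUFFICIENT = exp(eta[1]),
             DISABLED = exp(eta[2]), CENSORED = exp(eta[3]))
      nll <- nll - log(w[as.character(y[i])] / sum(w))
    }
    expect_equal(negative_loglik(B, X, y), unname(nll), tolerance = 1e-10)
  }
  expect_error(negative_loglik(B0 * NA, X, y), "finite")
})

test_that("saturated Model 1 reproduces the count-ratio closed form", {
  counts <- list(J = c(82, 100, 10, 8), S = c(50, 20, 5, 5),
                 D = c(5, 10, 30, 5))
  rows <- panel_from_counts(counts)
  fit <- fit_multistate(rows, model = 1)
  expect_true(fit$converged)
  ors <- exp(fit$coefficients)
  # exp(intercepts) = N(J -> k) / N(J -> J): forced to (0.82, 0.10, 0.08)
  expect_equal(unname(ors[, "(Intercept)"]), c(0.82, 0.10, 0.08),
               tolerance = 1e-6)
  # previous-state odds ratios from the contingency table
  expect_equal(ors["SELF_SUFFICIENT", "prev_SELF_SUFFICIENT"],
               (50 / 20) / (82 / 100), tolerance = 1e-6)
  expect_equal(ors["DISABLED", "prev_DISABLED"],
               (30 / 10) / (10 / 100), tolerance = 1e-6)
  # fitted probabilities equal pooled empirical origin-destination fractions
  for (o in c("JOBLESS", "SELF_SUFFICIENT", "DISABLED")) {
    prof <- list(previous_state = o)
    p <- softmax_probabilities(linear_predictors(fit$coefficients, prof))
    cnt <- counts[[substr(o, 1, 1)]]
    names(cnt) <- c("S", "J", "D", "C")
    emp <- c(SELF_SUFFICIENT = cnt[["S"]], JOBLESS = cnt[["J"]],
             DISABLED = cnt[["D"]], CENSORED = cnt[["C"]]) / sum(cnt)
    expect_equal(p, emp[names(p)], tolerance = 1e-7)
  }
})

test_that("estimates are invariant to row order and person relabelling", {
  sim <- simulate_trajectories(kernel_to_coefficients(test_kernel()),
                               600, n_periods = 3, seed = 44)
  rows <- sim$rows
  f1 <- fit_multistate(rows, model = 1)
  set.seed(9)
  rows2 <- rows[sample(nrow(rows)), ]
  rows2$person_id <- match(rows2$person_id, unique(rows2$person_id))
  f2 <- fit_multistate(rows2, model = 1)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  rows <- panel_from_counts(list(J = c(5, 6, 2, 1), S = c(3, 2, 1, 1),
                                 D = c(1, 1, 3, 1)))
  # constant sex column makes sex_FEMALE all zero only if FEMALE absent;
  # force collinearity instead: everyone female
  rows$sex <- "FEMALE"
  rows$age_group <- "20-25"
  rows$education_prev <- "HIGH_SCHOOL"
  rows$country <- "SWEDEN"
  expect_error(fit_multistate(rows, model = 2), "rank deficient")
})

test_that("odds ratios carry Wald intervals that match a quantile oracle", {
  sim <- simulate_trajectories(kernel_to_coefficients(test_kernel()),
                               800, n_periods = 3, seed = 11)
  fit <- fit_multistate(sim$rows, model = 1)
  tab <- odds_ratios(fit, level = 0.95)
  z <- qnorm(0.975)
  for (i in sample(nrow(tab), 5)) {
    b <- log(tab$or[i])
    expect_equal(tab$lo[i], exp(b - z * tab$se[i]), tolerance = 1e-10)
    expect_equal(tab$hi[i], exp(b + z * tab$se[i]), tolerance = 1e-10)
  }
  # se = 0 collapses the interval onto the point estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  tab0 <- odds_ratios(fit0)
  expect_equal(tab0$lo, tab0$or, tolerance = 1e-12)
  expect_equal(tab0$hi, tab0$or, tolerance = 1e-12)
})

test_that("likelihood-ratio test handles identity and nesting", {
  sim <- simulate_trajectories(kernel_to_coefficients(test_kernel()),
                               random_covariates(500, seed = 13),
                               n_periods = 3, seed = 13)
  f1 <- fit_multistate(sim$rows, model = 1)
  lr0 <- likelihood_ratio_test(f1, f1)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  f2 <- fit_multistate(sim$rows, model = 2)
  lr <- likelihood_ratio_test(f1, f2)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 21) # 7 extra terms x 3 equations
  expect_error(likelihood_ratio_test(f2, f1), "nested")
})

test_that("McFadden pseudo R2 matches its definition and bounds", {
  sim <- simulate_trajectories(kernel_to_coefficients(test_kernel()),
                               700, n_periods = 3, seed = 17)
  fit <- fit_multistate(sim$rows, model = 1)
  counts <- fit$outcome_counts
  ll0 <- sum(counts[counts > 0] * log(counts[counts > 0] / sum(counts)))
  expect_equal(pseudo_r2(fit), 1 - fit$loglik / ll0, tolerance = 1e-12)
  expect_gte(pseudo_r2(fit), 0)
  expect_lt(pseudo_r2(fit), 1)
  # an intercept-only-equivalent fit scores zero: all origins jobless
  rows_j <- sim$rows[sim$rows$state_prev == "JOBLESS", ]
  fj <- fit_multistate(rows_j, model = 1, ridge = 1e-8)
  expect_equal(pseudo_r2(fj), 0, tolerance = 1e-6)
})

test_that("coefficients agree with an established multinomial-logit fit", {
  worst <- 0
  used <- 0
  seed <- 0
  while (used < 20 && seed < 100) {
    seed <- seed + 1
    cov <- random_covariates(800, seed = seed)
    sim <- simulate_trajectories(coefficients_from_ors(reference_ors(2)),
                                 cov, n_periods = 4, seed = 1000 + seed)
    tab <- table(factor(sim$rows$state, levels = c("JOBLESS", "SELF_SUFFICIENT",
                                                   "DISABLED", "CENSORED")),
                 factor(sim$rows$state_prev, levels = origin_states()))
    if (any(tab < 5)) next # sparse cells risk separation in both fitters
    used <- used + 1
    f <- fit_multistate(sim$rows, model = 2)
    X <- design_matrix(sim$rows, 2)
    y <- attr(X, "y")
    nn <- nnet::multinom(y ~ X - 1, trace = FALSE, maxit = 5000,
                         reltol = 1e-14)
    worst <- max(worst, max(abs(unname(coef(nn)) -
                                  unname(f$coefficients))))
  }
  expect_equal(used, 20)
  expect_lt(worst, 1e-6)
})
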