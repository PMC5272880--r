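#' Model term sets
#'
#' Three nested model specifications are supported:
#' \describe{
#'   \item{Model 1}{previous state only (pure first-order Markov chain with
#'     homogeneous transition probabilities).}
#'   \item{Model 2}{adds sex, baseline age group, education at the previous
#'     period, and country of birth.}
#'   \item{Model 3}{adds the inpatient-care category and period dummies for
#'     the unequally spaced follow-up intervals.}
#' }
#' Reference levels: outcome JOBLESS, previous state JOBLESS, male, age 20-25,
#' high-school education, born in Sweden, no inpatient care, period 1
#' (1995-1997).
#'
#' @param model_id 1, 2 or 3.
#' @return character vector of design-matrix term labels, intercept first.
#' @export
model_terms <- function(model_id) {
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3")
  t1 <- c("(Intercept)", "prev_SELF_SUFFICIENT", "prev_DISABLED")
  t2 <- c("sex_FEMALE", "age_26-30", "age_31-35", "age_36-40",
          "edu_LOWER", "edu_HIGHER", "country_OTHER")
  t3 <- c("inpatient_LE_MEDIAN", "inpatient_GT_MEDIAN",
          "period_2", "period_3", "period_4", "period_5")
  switch(model_id, t1, c(t1, t2), c(t1, t2, t3))
}

# outcome equations: one per non-reference state
.outcomes <- c("SELF_SUFFICIENT", "DISABLED", "CENSORED")

.dummy <- function(x, levels, prefix) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop("invalid level(s) for ", prefix, ": ", paste(bad, collapse = ", "))
  }
  m <- sapply(levels[-1], function(l) as.numeric(x == l))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
  colnames(m) <- paste0(prefix, "_", levels[-1])
  m
}

#' Design matrix for the transition models
#'
#' Dummy-codes a person-period panel against the declared reference levels
#' with a deterministic column order (intercept first, then the Model 1-3
#' blocks in order).
#'
#' @param rows a `person_period_panel` (or any data.frame with the panel
#'   columns).
#' @param model_id 1, 2 or 3.
#' @return numeric matrix with column names `model_terms(model_id)` and
#'   attribute `y`, the outcome-state factor.
#' @export
design_matrix <- function(rows, model_id = 1) {
  if (!nrow(rows)) stop("rows must be non-empty")
  if (any(rows$state_prev == "CENSORED")) {
    stop("CENSORED cannot be an origin state")
  }
  parts <- list("(Intercept)" = matrix(1, nrow(rows), 1,
                                       dimnames = list(NULL, "(Intercept)")),
                .dummy(rows$state_prev,
                       c("JOBLESS", "SELF_SUFFICIENT", "DISABLED"), "prev"))
  if (model_id >= 2) {
    parts <- c(parts, list(
      .dummy(rows$sex, .sex_levels, "sex"),
      .dummy(rows$age_group, .age_levels, "age"),
      .dummy(rows$education_prev, .edu_levels, "edu"),
      .dummy(rows$country, .country_levels, "country")))
  }
  if (model_id >= 3) {
    parts <- c(parts, list(
      .dummy(rows$inpatient_cat, .inpatient_levels, "inpatient"),
      .dummy(as.character(rows$p), as.character(1:5), "period")))
  }
  X <- do.call(cbind, parts)
  stopifnot(identical(colnames(X), model_terms(model_id)))
  attr(X, "y") <- factor(rows$state,
                         levels = c("JOBLESS", .outcomes))
  X
}

# four-way probabilities given linear predictors eta (n x 3, outcomes S,D,C;
# reference J has predictor 0); returns list(P = n x 3 non-reference probs,
# p0 = reference prob, logdenom = log(1 + sum exp(eta)))
.mlogit_probs <- function(eta) {
  m <- pmax(0, eta[, 1], eta[, 2], eta[, 3])
  E <- exp(eta - m)
  e0 <- exp(-m)
  denom <- e0 + E[, 1] + E[, 2] + E[, 3]
  list(P = E / denom, p0 = e0 / denom, logdenom = m + log(denom))
}

#' Negative log-likelihood of the four-outcome multinomial logit
#'
#' The three non-reference equations are evaluated jointly: for row i the
#' probability of outcome k is the normalised exponential of the linear
#' predictors, with the reference outcome (Jobless) fixed at predictor 0, so
#' the four probabilities always sum to one.
#'
#' @param coeffs 3 x K coefficient matrix (rows SELF_SUFFICIENT, DISABLED,
#'   CENSORED; columns matching `colnames(X)`).
#' @param X design matrix from [design_matrix()].
#' @param y outcome factor with levels JOBLESS, SELF_SUFFICIENT, DISABLED,
#'   CENSORED (defaults to `attr(X, "y")`).
#' @return the scalar negative log-likelihood.
#' @export
negative_loglik <- function(coeffs, X, y = attr(X, "y")) {
  if (any(!is.finite(coeffs))) stop("coefficients must be finite")
  eta <- X %*% t(coeffs) # n x 3
  pr <- .mlogit_probs(eta)
  k <- match(as.character(y), .outcomes) # NA for reference outcome
  eta_y <- rep(0, nrow(X))
  nonref <- !is.na(k)
  eta_y[nonref] <- eta[cbind(which(nonref), k[nonref])]
  -sum(eta_y - pr$logdenom)
}

#' Fit a transition model by maximum likelihood
#'
#' Newton-Raphson on the joint multinomial-logit likelihood with analytic
#' gradient and Hessian. Person-period rows are treated as independent, per
#' the first-order Markov assumption of conditional independence. Step
#' halving guards against likelihood decreases; convergence is declared when
#' the gradient max-norm falls below `tol`.
#'
#' @param rows a `person_period_panel`.
#' @param model 1, 2 or 3 (see [model_terms()]).
#' @param tol gradient max-norm tolerance (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @param ridge optional small ridge added to the negative Hessian diagonal to
#'   resolve separation or near-rank-deficiency; 0 (off) by default, its use
#'   is recorded in the fit.
#' @return object of class `multistate_fit`: list with `coefficients` (3 x K
#'   matrix), `vcov`, `loglik`, `n_rows`, `n_iter`, `converged`, `model`,
#'   `terms`, `ridge`.
#' @examples
#' # a panel where every origin/destination pair has known counts yields
#' # closed-form intercepts: exp(alpha_k) = N(J->k) / N(J->J)
#' @export
fit_multistate <- function(rows, model = 1, tol = 1e-8, max_iter = 100,
                           ridge = 0) {
  X <- design_matrix(rows, model)
  y <- attr(X, "y")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    if (ridge <= 0) {
      stop("design matrix is rank deficient; offending column(s): ",
           paste(dep, collapse = ", "),
           " (a small ridge > 0 can be supplied to proceed)")
    }
  }
  fit <- .fit_mlogit(X, y, tol = tol, max_iter = max_iter, ridge = ridge)
  structure(c(fit, list(model = model, terms = colnames(X))),
            class = "multistate_fit")
}

# core Newton-Raphson; X: n x K, y: factor with reference level first
.fit_mlogit <- function(X, y, tol = 1e-8, max_iter = 100, ridge = 0,
                        start = NULL) {
  n <- nrow(X)
  K <- ncol(X)
  Y <- sapply(.outcomes, function(s) as.numeric(y == s)) # n x 3
  B <- if (is.null(start)) matrix(0, 3, K) else start
  ll <- -negative_loglik(`dimnames<-`(B, list(.outcomes, colnames(X))), X, y)
  converged <- FALSE
  iter <- 0
  grad_stack <- function(P) {
    as.vector(sapply(1:3, function(k) crossprod(X, Y[, k] - P[, k])))
  }
  for (iter in seq_len(max_iter)) {
    eta <- X %*% t(B)
    P <- .mlogit_probs(eta)$P
    g <- grad_stack(P)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    # Hessian of the LOG-likelihood: block (k,l) = -X' diag(w_kl) X
    H <- matrix(0, 3 * K, 3 * K)
    for (k in 1:3) for (l in k:3) {
      w <- P[, k] * ((k == l) - P[, l])
      blk <- -crossprod(X, X * w)
      ik <- (k - 1) * K + 1:K
      il <- (l - 1) * K + 1:K
      H[ik, il] <- blk
      if (l > k) H[il, ik] <- t(blk)
    }
    if (ridge > 0) diag(H) <- diag(H) - ridge
    step <- tryCatch(solve(H, -g), error = function(e) {
      stop("Newton step failed (singular Hessian); possible separation or ",
           "rank deficiency: ", conditionMessage(e))
    })
    # step-halving on likelihood decrease
    lambda <- 1
    repeat {
      B_new <- B + matrix(step, 3, K, byrow = TRUE) * lambda
      ll_new <- -negative_loglik(
        `dimnames<-`(B_new, list(.outcomes, colnames(X))), X, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-10) stop("step halving failed to improve likelihood")
    }
    B <- B_new
    ll <- ll_new
  }
  # final quantities at the optimum
  eta <- X %*% t(B)
  P <- .mlogit_probs(eta)$P
  g <- grad_stack(P)
  H <- matrix(0, 3 * K, 3 * K)
  for (k in 1:3) for (l in k:3) {
    w <- P[, k] * ((k == l) - P[, l])
    blk <- -crossprod(X, X * w)
    ik <- (k - 1) * K + 1:K
    il <- (l - 1) * K + 1:K
    H[ik, il] <- blk
    if (l > k) H[il, ik] <- t(blk)
  }
  vcov <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, 3 * K, 3 * K)
  })
  # vec order is by equation (all K terms of S, then D, then C)
  par_names <- as.vector(sapply(.outcomes, function(o)
    paste(o, colnames(X), sep = ":")))
  dimnames(vcov) <- list(par_names, par_names)
  dimnames(B) <- list(.outcomes, colnames(X))
  list(coefficients = B, vcov = vcov, loglik = ll, n_rows = n,
       n_iter = iter, converged = converged && max(abs(g)) < tol,
       ridge = ridge,
       outcome_counts = table(factor(as.character(y),
                                     levels = c("JOBLESS", .outcomes))))
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat(sprintf("Multi-state transition model %d (multinomial logit, ref: JOBLESS)\n",
              x$model))
  cat(sprintf("  n = %d person-period rows, logLik = %.2f, -2LL = %.1f\n",
              x$n_rows, x$loglik, -2 * x$loglik))
  cat(sprintf("  converged: %s in %d iterations\n",
              x$converged, x$n_iter))
  cat("Odds ratios (exp(coef)):\n")
  print(round(exp(x$coefficients), 3))
  invisible(x)
}

#' @export
logLik.multistate_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients), class = "logLik")
}

#' @export
coef.multistate_fit <- function(object, ...) object$coefficients

#' @export
vcov.multistate_fit <- function(object, ...) object$vcov

#' Odds ratios with Wald confidence intervals
#'
#' Exponentiates the fitted log-odds coefficients and attaches symmetric Wald
#' intervals `exp(coef +/- z * se)`, laid out as three outcome blocks
#' (Self-sufficient, Disabled, Censored, each contrasted against Jobless).
#'
#' @param fit a converged `multistate_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `outcome`, `term`, `or`, `lo`, `hi`, `se`.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "multistate_fit"))
  if (!fit$converged) warning("fit did not converge; intervals unreliable")
  z <- stats::qnorm(1 - (1 - level) / 2)
  K <- length(fit$terms)
  se <- matrix(sqrt(diag(fit$vcov)), 3, K, byrow = TRUE,
               dimnames = dimnames(fit$coefficients))
  out <- expand.grid(term = fit$terms, outcome = .outcomes,
                     stringsAsFactors = FALSE)[, 2:1]
  b <- t(fit$coefficients)
  s <- t(se)
  out$or <- exp(as.vector(b))
  out$lo <- exp(as.vector(b - z * s))
  out$hi <- exp(as.vector(b + z * s))
  out$se <- as.vector(s)
  out
}

#' Likelihood-ratio test between nested transition models
#'
#' @param small,large `multistate_fit` objects fitted to the same rows, with
#'   `small`'s terms a subset of `large`'s.
#' @return list with `statistic` (2 * (LL_large - LL_small)), `df`
#'   (difference in free coefficients) and `p` (chi-square upper tail).
#' @export
likelihood_ratio_test <- function(small, large) {
  stopifnot(inherits(small, "multistate_fit"), inherits(large, "multistate_fit"))
  if (!all(small$terms %in% large$terms)) {
    stop("small model terms are not nested in the large model")
  }
  if (small$n_rows != large$n_rows) {
    stop("models were fitted to different numbers of rows")
  }
  stat <- max(0, 2 * (large$loglik - small$loglik))
  df <- length(large$coefficients) - length(small$coefficients)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' McFadden pseudo R-squared
#'
#' `1 - LL(fit) / LL(intercept-only)` on the same rows; the intercept-only
#' log-likelihood has the closed form `sum_k n_k log(n_k / n)` over the four
#' outcome states.
#'
#' @param fit a `multistate_fit`.
#' @param counts optional named outcome counts (levels JOBLESS,
#'   SELF_SUFFICIENT, DISABLED, CENSORED); defaults to the counts stored in
#'   the fit.
#' @return pseudo R-squared in \[0, 1).
#' @export
pseudo_r2 <- function(fit, counts = fit$outcome_counts) {
  stopifnot(inherits(fit, "multistate_fit"))
  if (is.null(counts)) stop("outcome counts unavailable")
  counts <- counts[counts > 0]
  n <- sum(counts)
  ll0 <- sum(counts * log(counts / n))
  max(0, 1 - fit$loglik / ll0)
}
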