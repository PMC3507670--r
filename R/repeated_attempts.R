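# Attempt-level model of nonresponse: each phone call (attempts 1..10) and
# the email attempt (attempt 11) has its own intercept, covariate effects are
# shared across attempts, and the outcome enters every attempt through the
# common coefficient beta2.  The full likelihood marginalises the unobserved
# outcome of nonresponders over their entire failed attempt history.

# linear predictor helper tolerating zero covariates
qm_lp <- function(X, b) {
  if (length(b)) drop(X %*% b) else numeric(nrow(X))
}

# One row per attempt actually made: phone calls 1..t_i, plus the email
# (attempt 11) when attempted.  Row order is irrelevant to the likelihood;
# index structures used repeatedly during optimisation are precomputed here.
expand_attempts <- function(records, covariates = covariate_names()) {
  t <- records$phone_calls
  e <- records$email_attempted
  n <- nrow(records)
  idx <- c(rep(seq_len(n), t), which(e))
  m <- as.integer(c(sequence(t), rep(11L, sum(e))))
  sa <- records$success_attempt[idx]
  X <- qm_design(records, covariates)
  obs_i <- records$r == 1L
  obs_row <- obs_i[idx]
  nr_rows <- which(!obs_row)
  list(idx = idx, m = m,
       success = as.integer(!is.na(sa) & sa == m),
       t_email = ifelse(m == 11L, t[idx], 0),
       Xrow = X[idx, , drop = FALSE], X = X,
       y = records$y, r = records$r, n = n,
       obs_i = obs_i, obs_row = which(obs_row), nr_rows = nr_rows,
       y_row = records$y[idx], idx_nr = idx[nr_rows],
       ids_nr = sort(unique(idx[nr_rows])))
}

# log P(S = s) for a Bernoulli with logit eta: s*eta - log(1 + exp(eta))
qm_bern_ll <- function(s, eta) {
  sum(s * eta) + sum(stats::plogis(eta, log.p = TRUE, lower.tail = FALSE))
}

att_ll_core <- function(a0, a1, b0m, b1, b2, gam, E) {
  lp0 <- b0m[E$m] + qm_lp(E$Xrow, b1)
  if (gam != 0) lp0 <- lp0 + gam * E$t_email
  if (anyNA(lp0)) stop("attempt intercept undefined for an attempt present in the data")
  eta_y <- a0 + qm_lp(E$X, a1)
  ll <- 0
  if (any(E$obs_i)) {
    ll <- ll + qm_bern_ll(E$y[E$obs_i], eta_y[E$obs_i])
    or <- E$obs_row
    ll <- ll + qm_bern_ll(E$success[or], lp0[or] + b2 * E$y_row[or])
  }
  if (length(E$nr_rows)) {
    lpn <- lp0[E$nr_rows]
    lf <- stats::plogis(cbind(lpn, lpn + b2), log.p = TRUE,
                        lower.tail = FALSE)
    S <- rowsum(lf, E$idx_nr, reorder = TRUE)
    ids <- E$ids_nr
    t0 <- stats::plogis(eta_y[ids], log.p = TRUE, lower.tail = FALSE) + S[, 1]
    t1 <- stats::plogis(eta_y[ids], log.p = TRUE) + S[, 2]
    mm <- pmax(t0, t1)
    ll <- ll + sum(mm + log1p(exp(pmin(t0, t1) - mm)))
  }
  ll
}

# Analytic score in the order (a0, a1[p], b0m[11], b1[p], b2, gamma).
att_score_core <- function(a0, a1, b0m, b1, b2, gam, E) {
  lp0 <- b0m[E$m] + qm_lp(E$Xrow, b1)
  if (gam != 0) lp0 <- lp0 + gam * E$t_email
  eta_y <- a0 + qm_lp(E$X, a1)
  p_y <- stats::plogis(eta_y)
  e_a <- numeric(E$n)
  e_row <- numeric(length(E$m))
  g_b2 <- 0
  if (any(E$obs_i)) {
    e_a[E$obs_i] <- E$y[E$obs_i] - p_y[E$obs_i]
    or <- E$obs_row
    e_row[or] <- E$success[or] - stats::plogis(lp0[or] + b2 * E$y_row[or])
    g_b2 <- g_b2 + sum(e_row[or] * E$y_row[or])
  }
  if (length(E$nr_rows)) {
    lpn <- lp0[E$nr_rows]
    lf <- stats::plogis(cbind(lpn, lpn + b2), log.p = TRUE,
                        lower.tail = FALSE)
    S <- rowsum(lf, E$idx_nr, reorder = TRUE)
    ids <- E$ids_nr
    t0 <- stats::plogis(eta_y[ids], log.p = TRUE, lower.tail = FALSE) + S[, 1]
    t1 <- stats::plogis(eta_y[ids], log.p = TRUE) + S[, 2]
    mm <- pmax(t0, t1)
    lse <- mm + log1p(exp(pmin(t0, t1) - mm))
    w1_i <- numeric(E$n)
    w1_i[ids] <- exp(t1 - lse)
    e_a[ids] <- w1_i[ids] - p_y[ids]
    w1_row <- w1_i[E$idx_nr]
    q0 <- stats::plogis(lpn)
    q1 <- stats::plogis(lpn + b2)
    e_row[E$nr_rows] <- -((1 - w1_row) * q0 + w1_row * q1)
    g_b2 <- g_b2 - sum(w1_row * q1)
  }
  g_b0 <- numeric(11)
  agg <- rowsum(e_row, E$m, reorder = TRUE)
  g_b0[as.integer(rownames(agg))] <- agg[, 1]
  g_gam <- sum(e_row * E$t_email)
  c(sum(e_a), drop(crossprod(E$X, e_a)), g_b0,
    drop(crossprod(E$Xrow, e_row)), g_b2, g_gam)
}

#' Per-attempt success probability
#'
#' `P(R'_m = 1 | Y = y, x) = logit^{-1}(beta0_m + beta1' x + beta2 * y)`,
#' with the email attempt indexed `m = 11`.  When the robustness variant is
#' enabled (`gamma_email_calls != 0`) and `m = 11`, the predictor gains
#' `gamma_email_calls * phone_calls`.
#'
#' @param params An [attempt_params()] object.
#' @param m Attempt index in 1..11.
#' @param x Covariate vector or matrix (rows = participants).
#' @param y Outcome value(s) 0/1.
#' @param phone_calls Number of phone calls made, used only for the email
#'   attempt under the robustness variant.
#' @return Probability vector.
#' @export
attempt_probability <- function(params, m, x, y, phone_calls = 0) {
  if (!m %in% 1:11) stop("attempt index m must lie in 1..11")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(params$beta1)) stop("covariate dimension mismatch")
  extra <- if (m == 11L) params$gamma_email_calls * phone_calls else 0
  stats::plogis(params$beta0_m[[m]] + qm_lp(X, params$beta1) +
                  params$beta2 * y + extra)
}

#' Full log-likelihood of the repeated-attempts model
#'
#' Four participant types contribute: phone responders (success at their
#' final call, failures before), email responders (all calls fail, email
#' succeeds), email nonresponders (calls and email all fail, outcome summed
#' out) and phone-only nonresponders (all calls fail, outcome summed out).
#' Empty failure products equal one.
#'
#' @param params An [attempt_params()] object.
#' @param records A `quitmiss_cohort`.
#' @return Scalar log-likelihood; an error signals overflow.
#' @export
attempts_loglik <- function(params, records) {
  E <- expand_attempts(records, params$covariates)
  ll <- att_ll_core(params$alpha0, params$alpha1, params$beta0_m,
                    params$beta1, params$beta2, params$gamma_email_calls, E)
  if (!is.finite(ll)) stop("non-finite log-likelihood: parameter overflow")
  ll
}

att_theta_names <- function(covariates, m_present, free_beta2, email_calls) {
  nm <- c("alpha0",
          if (length(covariates)) paste0("alpha1.", covariates),
          paste0("beta0.", c(paste0("call", 1:10), "email")[m_present]),
          if (length(covariates)) paste0("beta1.", covariates))
  if (free_beta2) nm <- c(nm, "beta2")
  if (email_calls) nm <- c(nm, "gamma_email_calls")
  nm
}

#' Fit the MAR repeated-attempts model as separate logistic regressions
#'
#' With `beta2 = 0` the likelihood separates into a complete-case logistic
#' regression of the outcome on the covariates and an attempt-level logistic
#' regression (one row per attempt made) of attempt success on per-attempt
#' indicators plus the covariates.
#'
#' @param records A `quitmiss_cohort`.
#' @param covariates Covariate subset (possibly empty).
#' @param email_calls Include the phone-call count in the email attempt's
#'   predictor (robustness variant).
#' @return A `quitmiss_fit` with `fixed_beta2 = 0`.  Attempt numbers absent
#'   from the data get `NA` intercepts and are flagged in `$notes`.
#' @export
fit_mar_attempts <- function(records, covariates = covariate_names(),
                             email_calls = FALSE) {
  y <- records$y; r <- records$r
  if (!any(r == 1L)) stop("degenerate cohort: no responders")
  ycc <- y[r == 1L]
  if (length(unique(ycc)) < 2L) stop("both outcome classes must be present among responders")
  E <- expand_attempts(records, covariates)
  dat_cc <- as.data.frame(records)[r == 1L, , drop = FALSE]
  m_present <- sort(unique(E$m))
  adat <- data.frame(success = E$success)
  # explicit per-attempt indicator columns (a one-level factor would trip
  # glm's contrasts machinery when only a single attempt number occurs)
  att_cols <- paste0("attempt", m_present)
  for (m in m_present) adat[[paste0("attempt", m)]] <- as.numeric(E$m == m)
  if (length(covariates)) adat <- cbind(adat, as.data.frame(E$Xrow))
  if (email_calls) adat$email_t <- E$t_email
  notes <- character()
  withCallingHandlers({
    fit_y <- stats::glm(stats::reformulate(if (length(covariates)) covariates else "1",
                                           response = "y"),
                        family = stats::binomial(), data = dat_cc)
    terms_r <- c("0", att_cols, covariates, if (email_calls) "email_t")
    fit_r <- stats::glm(stats::reformulate(terms_r, response = "success"),
                        family = stats::binomial(), data = adat)
  }, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  ca <- stats::coef(fit_y)
  cb <- stats::coef(fit_r)
  if (anyNA(cb)) notes <- c(notes, "inestimable attempt-level coefficients")
  b0m <- rep(NA_real_, 11)
  b0m[m_present] <- cb[paste0("attempt", m_present)]
  if (any(is.na(b0m[m_present]))) notes <- c(notes, "attempt intercept undefined for an observed attempt")
  absent <- setdiff(1:11, m_present)
  if (length(absent)) {
    notes <- c(notes, paste0("no data for attempt(s) ",
                             paste(absent, collapse = ","),
                             "; intercepts undefined"))
  }
  b1 <- if (length(covariates)) cb[covariates] else numeric(0)
  gam <- if (email_calls) cb[["email_t"]] else 0
  params <- attempt_params(ca[1], if (length(covariates)) ca[covariates] else numeric(0),
                           b0m, b1, 0, gam, covariates)
  nm <- att_theta_names(covariates, m_present, FALSE, email_calls)
  k <- length(nm)
  V <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  py <- length(ca)
  V[1:py, 1:py] <- stats::vcov(fit_y)
  keep <- c(paste0("attempt", m_present), covariates, if (email_calls) "email_t")
  keep <- keep[keep %in% names(cb)[!is.na(cb)]]
  Vr <- stats::vcov(fit_r)[keep, keep, drop = FALSE]
  pos <- (py + 1):(py + length(keep))
  V[pos, pos] <- Vr
  se <- sqrt(diag(V))
  ll <- attempts_loglik(params, records)
  fit <- new_fit_result(params, se, V, ll, fit_y$converged && fit_r$converged,
                        nrow(records), model = "attempts", fixed_beta2 = 0,
                        notes = notes)
  fit$component_loglik <- c(outcome_cc = as.numeric(stats::logLik(fit_y)),
                            attempts = as.numeric(stats::logLik(fit_r)))
  fit$m_present <- m_present
  fit
}

#' Fit the MNAR repeated-attempts model by full maximum likelihood
#'
#' Jointly maximises the attempt-level likelihood over the outcome model,
#' the per-attempt intercepts, the shared covariate effects and the
#' outcome-missingness coefficient `beta2` (unless `fixed_beta2` is given).
#' Standard errors come from the numerically differenced observed
#' information; a Wald 95\% CI for `beta2` is attached as `$beta2_ci`.
#'
#' @inheritParams fit_mar_attempts
#' @param start A `quitmiss_fit` or [attempt_params()] starting point;
#'   defaults to [fit_mar_attempts()].
#' @param fixed_beta2 Optional value at which to hold `beta2` fixed.
#' @param grad_tol Gradient-norm convergence tolerance.
#' @return A `quitmiss_fit`; non-convergence and information-matrix
#'   problems are flagged, not raised.
#' @export
fit_mnar_attempts <- function(records, start = NULL,
                              covariates = covariate_names(),
                              email_calls = FALSE, fixed_beta2 = NULL,
                              grad_tol = 1e-6) {
  if (is.null(start)) start <- fit_mar_attempts(records, covariates, email_calls)
  sp <- if (inherits(start, "quitmiss_fit")) start$params else start
  E <- expand_attempts(records, covariates)
  m_present <- sort(unique(E$m))
  p <- length(covariates)
  free_b2 <- is.null(fixed_beta2)
  std <- qm_standardize(E$X)
  Estd <- E; Estd$X <- std$Z; Estd$Xrow <- std$Z[E$idx, , drop = FALSE]

  shift <- function(b1) sum(b1 * std$mu)            # raw -> std intercept shift
  b0m0 <- sp$beta0_m
  b0m0[is.na(b0m0)] <- 0
  theta0 <- c(sp$alpha0 + shift(sp$alpha1), sp$alpha1 * std$sigma,
              b0m0[m_present] + shift(sp$beta1), sp$beta1 * std$sigma,
              if (free_b2) sp$beta2,
              if (email_calls) sp$gamma_email_calls)
  theta0[!is.finite(theta0)] <- 0

  unpack <- function(th, raw) {
    i <- 1
    a0s <- th[i]; i <- i + 1
    a1s <- if (p) th[i:(i + p - 1)] else numeric(0); i <- i + p
    b0s <- th[i:(i + length(m_present) - 1)]; i <- i + length(m_present)
    b1s <- if (p) th[i:(i + p - 1)] else numeric(0); i <- i + p
    b2 <- if (free_b2) { v <- th[i]; i <- i + 1; v } else fixed_beta2
    gam <- if (email_calls) th[i] else 0
    b0m <- rep(NA_real_, 11)
    if (raw) {
      b0m[m_present] <- b0s
      list(a0 = a0s, a1 = a1s, b0m = b0m, b1 = b1s, b2 = b2, gam = gam)
    } else {
      b0m[m_present] <- b0s
      list(a0 = a0s, a1 = a1s, b0m = b0m, b1 = b1s, b2 = b2, gam = gam)
    }
  }
  sub_score <- function(g) {
    keep <- c(1, if (p) 1 + seq_len(p), 1 + p + m_present,
              if (p) 12 + p + seq_len(p), if (free_b2) 13 + 2 * p,
              if (email_calls) 14 + 2 * p)
    g[keep]
  }
  ll_std <- function(th) {
    u <- unpack(th, raw = FALSE)
    att_ll_core(u$a0, u$a1, u$b0m, u$b1, u$b2, u$gam, Estd)
  }
  sc_std <- function(th) {
    u <- unpack(th, raw = FALSE)
    sub_score(att_score_core(u$a0, u$a1, u$b0m, u$b1, u$b2, u$gam, Estd))
  }
  res <- qm_maximize(theta0, ll_std, sc_std, grad_tol = grad_tol)

  # back-transform to the raw covariate scale (exact: the map is linear)
  u <- unpack(res$theta, raw = FALSE)
  a1 <- u$a1 / std$sigma
  b1 <- u$b1 / std$sigma
  theta_raw <- c(u$a0 - sum(a1 * std$mu), a1,
                 u$b0m[m_present] - sum(b1 * std$mu), b1,
                 if (free_b2) u$b2, if (email_calls) u$gam)
  sc_raw <- function(th) {
    v <- unpack(th, raw = TRUE)
    sub_score(att_score_core(v$a0, v$a1, v$b0m, v$b1, v$b2, v$gam, E))
  }
  H <- qm_num_hessian(sc_raw, theta_raw)
  nm <- att_theta_names(covariates, m_present, free_b2, email_calls)
  vc <- qm_vcov_from_hessian(H, nm)
  v <- unpack(theta_raw, raw = TRUE)
  params <- attempt_params(v$a0, v$a1, v$b0m, v$b1, v$b2, v$gam, covariates)
  notes <- vc$notes
  if (!res$converged) notes <- c(notes, "optimiser did not meet the convergence criteria")
  fit <- new_fit_result(params, vc$se, vc$vcov, res$loglik, res$converged,
                        nrow(records), model = "attempts",
                        fixed_beta2 = fixed_beta2, notes = notes)
  fit$m_present <- m_present
  if (free_b2) {
    se2 <- vc$se[["beta2"]]
    fit$beta2_ci <- if (is.finite(se2)) {
      params$beta2 + c(-1, 1) * stats::qnorm(0.975) * se2
    } else c(NA_real_, NA_real_)
  }
  fit
}

#' Attempt-by-covariate interaction diagnostics for the MAR model
#'
#' Likelihood-ratio tests against the no-interaction MAR attempt-level
#' regression: for each covariate, (i) an interaction with the attempt
#' number (email counted as attempt 11), and (ii) an interaction with the
#' email attempt indicator alone.  The latter targets the possibility that
#' the email channel recruits a different kind of respondent (e.g. more
#' educated participants).
#'
#' @inheritParams fit_mar_attempts
#' @return Data frame with one row per covariate: `p_attempt` and `p_email`
#'   interaction p-values, the email-interaction log odds ratio
#'   `email_logor`, and an `estimable` flag.
#' @export
interaction_diagnostics <- function(records, covariates = covariate_names()) {
  if (!length(covariates)) stop("no covariates to test")
  E <- expand_attempts(records, covariates)
  adat <- data.frame(success = E$success,
                     attempt = factor(E$m, levels = sort(unique(E$m))),
                     attempt_num = as.numeric(E$m),
                     is_email = as.numeric(E$m == 11L))
  adat <- cbind(adat, as.data.frame(E$Xrow))
  base <- stats::glm(stats::reformulate(c("0", "attempt", covariates),
                                        response = "success"),
                     family = stats::binomial(), data = adat)
  rows <- lapply(covariates, function(cv) {
    if (stats::var(adat[[cv]]) == 0) {
      return(data.frame(covariate = cv, p_attempt = NA_real_,
                        p_email = NA_real_, email_logor = NA_real_,
                        estimable = FALSE))
    }
    lrt <- function(extra) {
      alt <- stats::glm(stats::reformulate(c("0", "attempt", covariates, extra),
                                           response = "success"),
                        family = stats::binomial(), data = adat)
      cf <- stats::coef(alt)
      if (anyNA(cf)) return(list(p = NA_real_, est = NA_real_))
      dev <- base$deviance - alt$deviance
      dfree <- base$df.residual - alt$df.residual
      list(p = stats::pchisq(dev, dfree, lower.tail = FALSE),
           est = cf[[length(cf)]])
    }
    a <- lrt(paste0("attempt_num:", cv))
    e <- lrt(paste0("is_email:", cv))
    data.frame(covariate = cv, p_attempt = a$p, p_email = e$p,
               email_logor = e$est,
               estimable = is.finite(a$p) && is.finite(e$p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Complete-case trend of the outcome over phone-call attempts
#'
#' Grouped-binomial logistic regression of the quit proportion on the number
#' of phone calls, over the phone-responder rows of an attempt summary table
#' (email rows excluded).
#'
#' @param table An `attempt_summary` (see [load_fixture()] /
#'   [tabulate_attempts()]).
#' @return Named vector `c(slope, se)` on the log-odds-per-attempt scale.
#' @export
attempt_trend_regression <- function(table) {
  ph <- table[!table$email_attempted & table$responders > 0, , drop = FALSE]
  if (length(unique(ph$phone_calls)) < 2L) {
    stop("need at least two distinct phone-call counts with responders")
  }
  fit <- stats::glm(cbind(quitters, responders - quitters) ~ phone_calls,
                    family = stats::binomial(), data = ph)
  sm <- summary(fit)$coefficients
  c(slope = sm["phone_calls", "Estimate"], se = sm["phone_calls", "Std. Error"])
}

#' Robustness / subgroup specification for the repeated-attempts model
#'
#' @param label Row label.
#' @param covariates One of `"all"`, `"smoking"`, `"nonsmoking"`, `"none"`,
#'   `"all_except_sex"`.
#' @param participants One of `"all"`, `"younger"` (age 36 or under),
#'   `"older"` (37 and over), `"men"`, `"women"`, `"le5calls"` (at most five
#'   phone calls).
#' @param email_calls Let the email attempt's success depend on the number
#'   of failed phone calls.
#' @return A `robustness_spec` list.
#' @export
robustness_spec <- function(label, covariates = "all", participants = "all",
                            email_calls = FALSE) {
  covariates <- match.arg(covariates,
                          c("all", "smoking", "nonsmoking", "none",
                            "all_except_sex"))
  participants <- match.arg(participants,
                            c("all", "younger", "older", "men", "women",
                              "le5calls"))
  structure(list(label = label, covariates = covariates,
                 participants = participants, email_calls = email_calls),
            class = "robustness_spec")
}

#' The nine standard robustness specifications
#'
#' Covariate subsets (smoking-related, non-smoking-related, none), subgroup
#' splits at the median age (36 or under versus 37 and over), by sex (with
#' the sex covariate dropped), a restriction to participants receiving at
#' most five phone calls, and the variant where the email attempt depends on
#' the number of failed telephone calls.
#'
#' @return List of [robustness_spec()] objects.
#' @export
default_robustness_specs <- function() {
  list(
    robustness_spec("smoking-related covariates", "smoking", "all"),
    robustness_spec("non-smoking-related covariates", "nonsmoking", "all"),
    robustness_spec("no covariates", "none", "all"),
    robustness_spec("younger (36 and under)", "all", "younger"),
    robustness_spec("older (37 and over)", "all", "older"),
    robustness_spec("men", "all_except_sex", "men"),
    robustness_spec("women", "all_except_sex", "women"),
    robustness_spec("five calls or fewer", "all", "le5calls"),
    robustness_spec("email depends on failed calls", "all", "all",
                    email_calls = TRUE)
  )
}

resolve_robustness_spec <- function(records, spec) {
  smoke <- smoking_related_covariates()
  covs <- switch(spec$covariates,
                 all = covariate_names(),
                 smoking = smoke,
                 nonsmoking = setdiff(covariate_names(), smoke),
                 none = character(0),
                 all_except_sex = setdiff(covariate_names(), "sex"))
  keep <- switch(spec$participants,
                 all = rep(TRUE, nrow(records)),
                 younger = records$age <= 36,
                 older = records$age >= 37,
                 men = records$sex == 0,
                 women = records$sex == 1,
                 le5calls = records$phone_calls <= 5)
  if (spec$participants %in% c("men", "women")) covs <- setdiff(covs, "sex")
  list(covariates = covs, keep = keep)
}

#' Refit the MNAR repeated-attempts model under robustness specifications
#'
#' Runs [fit_mnar_attempts()] for each specification; per-row failures are
#' recorded and the suite continues.
#'
#' @param records A `quitmiss_cohort`.
#' @param specs List of [robustness_spec()]s (default
#'   [default_robustness_specs()]).
#' @return A data frame (`robustness_table`) with one row per spec: label,
#'   subset size, `beta2`, `se`, convergence flag and any error message;
#'   fits attached as `attr(, "fits")`.
#' @export
robustness_suite <- function(records, specs = default_robustness_specs()) {
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(k) {
    spec <- specs[[k]]
    rs <- resolve_robustness_spec(records, spec)
    sub <- records[rs$keep, , drop = FALSE]
    class(sub) <- class(records)
    res <- tryCatch(
      fit_mnar_attempts(sub, covariates = rs$covariates,
                        email_calls = spec$email_calls),
      error = function(e) e)
    fits[[k]] <<- res
    if (inherits(res, "quitmiss_fit")) {
      data.frame(label = spec$label, n = nrow(sub),
                 beta2 = res$params$beta2, se = res$se[["beta2"]],
                 converged = res$converged, error = NA_character_)
    } else {
      data.frame(label = spec$label, n = nrow(sub), beta2 = NA_real_,
                 se = NA_real_, converged = FALSE,
                 error = conditionMessage(res))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("robustness_table", "data.frame")
  out
}
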