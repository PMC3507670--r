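# Selection model for a possibly missing binary outcome: logistic outcome and
# missingness models, the full marginal likelihood with the unobserved outcome
# summed out of the nonresponder contributions, MAR / fixed-beta2 / full MNAR
# fits, observed-information standard errors, and the IMOR conversion.

#' Outcome-model probability
#'
#' `P(Y = 1 | x) = logit^{-1}(alpha0 + alpha1' x)`, numerically stable for
#' extreme linear predictors.
#'
#' @param params A [selection_params()] or [attempt_params()] object (only
#'   the outcome coefficients are used).
#' @param x A covariate vector, or a matrix with one row per participant in
#'   the order of `params$covariates`.
#' @return Probability vector.
#' @export
outcome_probability <- function(params, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(params$alpha1)) stop("covariate dimension mismatch")
  stats::plogis(drop(params$alpha0 + X %*% params$alpha1))
}

#' Missingness-model (response) probability
#'
#' `P(R = 1 | Y = y, x) = logit^{-1}(beta0 + beta1' x + beta2 * y)`.
#' With `beta2 = 0` the value does not depend on `y` (MAR).
#'
#' @inheritParams outcome_probability
#' @param y Outcome value(s) 0/1.
#' @return Probability vector.
#' @export
response_probability <- function(params, x, y) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(params$beta1)) stop("covariate dimension mismatch")
  stats::plogis(drop(params$beta0 + X %*% params$beta1) + params$beta2 * y)
}

# Scalar log-likelihood from raw components.  Responders contribute
# log P(Y=y|x) + log P(R=1|y,x); nonresponders contribute
# log sum_y P(Y=y|x) P(R=0|y,x), evaluated via log-sum-exp.
sel_ll_core <- function(a0, a1, b0, b1, b2, X, y, r) {
  eta_y <- drop(a0 + X %*% a1)
  eta_r0 <- drop(b0 + X %*% b1)
  obs <- r == 1L
  ll <- 0
  if (any(obs)) {
    lpy <- ifelse(y[obs] == 1,
                  stats::plogis(eta_y[obs], log.p = TRUE),
                  stats::plogis(eta_y[obs], log.p = TRUE, lower.tail = FALSE))
    lpr <- stats::plogis(eta_r0[obs] + b2 * y[obs], log.p = TRUE)
    ll <- ll + sum(lpy) + sum(lpr)
  }
  if (any(!obs)) {
    e_y <- eta_y[!obs]; e_r <- eta_r0[!obs]
    t0 <- stats::plogis(e_y, log.p = TRUE, lower.tail = FALSE) +
      stats::plogis(e_r, log.p = TRUE, lower.tail = FALSE)
    t1 <- stats::plogis(e_y, log.p = TRUE) +
      stats::plogis(e_r + b2, log.p = TRUE, lower.tail = FALSE)
    m <- pmax(t0, t1)
    ll <- ll + sum(m + log(exp(t0 - m) + exp(t1 - m)))
  }
  ll
}

# Analytic score of sel_ll_core in the order (a0, a1, b0, b1, b2).
sel_score_core <- function(a0, a1, b0, b1, b2, X, y, r) {
  eta_y <- drop(a0 + X %*% a1)
  eta_r0 <- drop(b0 + X %*% b1)
  p_y <- stats::plogis(eta_y)
  obs <- r == 1L
  e_a <- numeric(length(y))
  e_b <- numeric(length(y))
  g_b2 <- 0
  if (any(obs)) {
    e_a[obs] <- y[obs] - p_y[obs]
    e_b[obs] <- 1 - stats::plogis(eta_r0[obs] + b2 * y[obs])
    g_b2 <- g_b2 + sum(e_b[obs] * y[obs])
  }
  if (any(!obs)) {
    e_y <- eta_y[!obs]; e_r <- eta_r0[!obs]
    t0 <- stats::plogis(e_y, log.p = TRUE, lower.tail = FALSE) +
      stats::plogis(e_r, log.p = TRUE, lower.tail = FALSE)
    t1 <- stats::plogis(e_y, log.p = TRUE) +
      stats::plogis(e_r + b2, log.p = TRUE, lower.tail = FALSE)
    m <- pmax(t0, t1)
    lse <- m + log(exp(t0 - m) + exp(t1 - m))
    w1 <- exp(t1 - lse)
    q0 <- stats::plogis(e_r)
    q1 <- stats::plogis(e_r + b2)
    e_a[!obs] <- w1 - p_y[!obs]
    e_b[!obs] <- -((1 - w1) * q0 + w1 * q1)
    g_b2 <- g_b2 - sum(w1 * q1)
  }
  c(sum(e_a), drop(crossprod(X, e_a)), sum(e_b), drop(crossprod(X, e_b)), g_b2)
}

#' Full marginal log-likelihood of the selection model
#'
#' Responders contribute the joint probability of their observed outcome and
#' response; nonresponders contribute the marginal probability of nonresponse
#' with the unobserved outcome summed out, stabilised by log-sum-exp.
#'
#' @param params A [selection_params()] object.
#' @param records A `quitmiss_cohort` (its covariates must include
#'   `params$covariates`).
#' @return The log-likelihood (scalar); an error is raised if it is not
#'   finite, which signals parameter overflow.
#' @export
selection_loglik <- function(params, records) {
  X <- qm_design(records, params$covariates)
  ll <- sel_ll_core(params$alpha0, params$alpha1, params$beta0, params$beta1,
                    params$beta2, X, records$y, records$r)
  if (!is.finite(ll)) stop("non-finite log-likelihood: parameter overflow")
  ll
}

# --- fitting ---------------------------------------------------------------

sel_theta_names <- function(covariates, free_beta2) {
  nm <- c("alpha0", paste0("alpha1.", covariates),
          "beta0", paste0("beta1.", covariates))
  if (free_beta2) nm <- c(nm, "beta2") else nm
}

# theta layout: c(alpha0, alpha1[p], beta0, beta1[p], beta2 if free)
sel_unpack <- function(theta, p, free_beta2, beta2_fixed) {
  list(a0 = theta[1], a1 = theta[2:(p + 1)], b0 = theta[p + 2],
       b1 = theta[(p + 3):(2 * p + 2)],
       b2 = if (free_beta2) theta[2 * p + 3] else beta2_fixed)
}

# Maximise the marginal likelihood over all parameters (optionally with
# beta2 held fixed).  Optimisation runs on internally standardised
# covariates; coefficients and the observed information are reported on the
# raw scale.
fit_selection_ml <- function(records, beta2 = NULL, start = NULL,
                             covariates = covariate_names(),
                             grad_tol = 1e-6) {
  free_beta2 <- is.null(beta2)
  X <- qm_design(records, covariates)
  p <- ncol(X)
  y <- records$y; r <- records$r
  if (!any(r == 1L)) stop("degenerate cohort: no responders")
  if (is.null(start)) start <- fit_mar(records, covariates = covariates)$params
  std <- qm_standardize(X)

  to_std <- function(a0, a1, b0, b1) {
    c(a0 + sum(a1 * std$mu), a1 * std$sigma,
      b0 + sum(b1 * std$mu), b1 * std$sigma)
  }
  from_std <- function(th) {
    a1 <- th[2:(p + 1)] / std$sigma
    b1 <- th[(p + 3):(2 * p + 2)] / std$sigma
    c(th[1] - sum(a1 * std$mu), a1, th[p + 2] - sum(b1 * std$mu), b1,
      if (free_beta2) th[2 * p + 3])
  }
  theta0 <- to_std(start$alpha0, start$alpha1, start$beta0, start$beta1)
  if (free_beta2) theta0 <- c(theta0, start$beta2)

  ll_std <- function(th) {
    u <- sel_unpack(th, p, free_beta2, beta2)
    sel_ll_core(u$a0, u$a1, u$b0, u$b1, u$b2, std$Z, y, r)
  }
  sc_std <- function(th) {
    u <- sel_unpack(th, p, free_beta2, beta2)
    g <- sel_score_core(u$a0, u$a1, u$b0, u$b1, u$b2, std$Z, y, r)
    if (free_beta2) g else g[-(2 * p + 3)]
  }
  res <- qm_maximize(theta0, ll_std, sc_std, grad_tol = grad_tol)

  theta_raw <- from_std(res$theta)
  sc_raw <- function(th) {
    u <- sel_unpack(th, p, free_beta2, beta2)
    g <- sel_score_core(u$a0, u$a1, u$b0, u$b1, u$b2, X, y, r)
    if (free_beta2) g else g[-(2 * p + 3)]
  }
  H <- qm_num_hessian(sc_raw, theta_raw)
  nm <- sel_theta_names(covariates, free_beta2)
  vc <- qm_vcov_from_hessian(H, nm)
  u <- sel_unpack(theta_raw, p, free_beta2, beta2)
  params <- selection_params(u$a0, u$a1, u$b0, u$b1, u$b2, covariates)
  notes <- vc$notes
  if (!res$converged) notes <- c(notes, "optimiser did not meet the convergence criteria")
  new_fit_result(params, vc$se, vc$vcov, res$loglik, res$converged,
                 nrow(records), model = "selection",
                 fixed_beta2 = if (free_beta2) NULL else beta2, notes = notes)
}

#' Fit the MAR model as two separate logistic regressions
#'
#' With `beta2 = 0` the full likelihood separates: the outcome model is a
#' complete-case logistic regression of `y` on the covariates, and the
#' missingness model is a logistic regression of `r` on the covariates over
#' all participants.  The combined log-likelihood equals
#' [selection_loglik()] at the stacked estimates.
#'
#' @param records A `quitmiss_cohort`.
#' @param covariates Covariate subset to adjust for.
#' @return A `quitmiss_fit` with `fixed_beta2 = 0`.  Separation or
#'   non-convergence in either regression is recorded in `$notes` and
#'   raised as a warning, never silently ignored.
#' @export
fit_mar <- function(records, covariates = covariate_names()) {
  y <- records$y; r <- records$r
  if (all(r == 1L)) stop("degenerate cohort: every outcome observed, the missingness regression cannot be fitted")
  if (!any(r == 1L)) stop("degenerate cohort: no responders")
  ycc <- y[r == 1L]
  if (length(unique(ycc)) < 2L) stop("both outcome classes must be present among responders")
  dat <- as.data.frame(records)
  fml_y <- stats::reformulate(covariates, response = "y")
  fml_r <- stats::reformulate(covariates, response = "r")
  notes <- character()
  withCallingHandlers({
    fit_y <- stats::glm(fml_y, family = stats::binomial(),
                        data = dat[r == 1L, , drop = FALSE])
    fit_r <- stats::glm(fml_r, family = stats::binomial(), data = dat)
  }, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (!fit_y$converged) notes <- c(notes, "outcome regression did not converge")
  if (!fit_r$converged) notes <- c(notes, "missingness regression did not converge")
  if (length(notes)) warning("MAR fit: ", paste(notes, collapse = "; "))
  ca <- stats::coef(fit_y); cb <- stats::coef(fit_r)
  params <- selection_params(ca[1], ca[-1], cb[1], cb[-1], 0, covariates)
  nm <- sel_theta_names(covariates, free_beta2 = FALSE)
  p <- length(covariates)
  V <- matrix(NA_real_, 2 * p + 2, 2 * p + 2, dimnames = list(nm, nm))
  V[1:(p + 1), 1:(p + 1)] <- stats::vcov(fit_y)
  V[(p + 2):(2 * p + 2), (p + 2):(2 * p + 2)] <- stats::vcov(fit_r)
  se <- sqrt(diag(V))
  ll <- selection_loglik(params, records)
  fit <- new_fit_result(params, se, V, ll,
                        fit_y$converged && fit_r$converged,
                        nrow(records), model = "selection", fixed_beta2 = 0,
                        notes = notes)
  fit$component_loglik <- c(outcome_cc = as.numeric(stats::logLik(fit_y)),
                            missingness = as.numeric(stats::logLik(fit_r)))
  fit
}

#' Fit the selection model with the sensitivity parameter held fixed
#'
#' Maximises the full marginal likelihood over all parameters except
#' `beta2`, which is constrained to the supplied value.  Standard errors
#' come from the numerically differenced observed information of the reduced
#' parameterisation.
#'
#' @inheritParams fit_mar
#' @param beta2 The fixed sensitivity-parameter value.
#' @param start Optional [selection_params()] starting point (defaults to
#'   the MAR fit, whose `beta2` entry is ignored).
#' @return A `quitmiss_fit` with `fixed_beta2 = beta2`; non-convergence is
#'   flagged in the result rather than raised.
#' @export
fit_fixed_beta2 <- function(records, beta2, start = NULL,
                            covariates = covariate_names()) {
  stopifnot(is.numeric(beta2), length(beta2) == 1L, is.finite(beta2))
  fit_selection_ml(records, beta2 = beta2, start = start,
                   covariates = covariates)
}

#' Fit the full MNAR selection model, estimating the sensitivity parameter
#'
#' Joint maximisation of the marginal likelihood including `beta2`.  The
#' model is only weakly identified by the linearity and no-interaction
#' assumptions of the missingness model, so the reported standard error of
#' `beta2` is typically very large; a Wald 95\% confidence interval for
#' `beta2` is attached as `$beta2_ci`.
#'
#' @inheritParams fit_fixed_beta2
#' @param start Starting values, typically the MAR fit's parameters.
#' @return A `quitmiss_fit`; a near-singular information matrix is reported
#'   via `$notes`, not an error.
#' @export
fit_full_mnar <- function(records, start = NULL,
                          covariates = covariate_names()) {
  fit <- fit_selection_ml(records, beta2 = NULL, start = start,
                          covariates = covariates)
  se2 <- fit$se[["beta2"]]
  fit$beta2_ci <- if (is.finite(se2)) {
    fit$params$beta2 + c(-1, 1) * stats::qnorm(0.975) * se2
  } else c(NA_real_, NA_real_)
  fit
}

#' Convert the sensitivity parameter to an implied abstention probability
#' among nonresponders
#'
#' `beta2` is the adjusted log odds ratio between outcome and response;
#' equivalently `beta2 = -log(IMOR)`, where the IMOR is the informatively
#' missing odds ratio comparing the outcome odds of nonresponders with
#' responders.  For a typical participant whose complete-case abstention
#' probability is `p_cc`, the implied abstention probability among
#' nonresponders is `logit^{-1}(logit(p_cc) - beta2)`; it is strictly
#' decreasing in `beta2`, equals `p_cc` at `beta2 = 0` (MAR), and tends to
#' the "missing = smoking" limit 0 as `beta2` grows.
#'
#' @param beta2 Sensitivity-parameter value(s).
#' @param p_cc Complete-case abstention probability, strictly inside (0, 1).
#'   The packaged fixture convention is 162/722 (0.2244, printed as 0.22).
#' @return Implied probability, vectorised over `beta2`.
#' @export
beta2_to_missing_abstention <- function(beta2, p_cc = 162 / 722) {
  if (!is.numeric(p_cc) || length(p_cc) != 1L || p_cc <= 0 || p_cc >= 1) {
    stop("p_cc must lie strictly inside (0, 1)")
  }
  stats::plogis(stats::qlogis(p_cc) - beta2)
}

#' Sensitivity analysis over a grid of fixed sensitivity-parameter values
#'
#' Fits [fit_fixed_beta2()] at each grid value, expanding outward from the
#' anchor (default 0, the MAR fit): the anchor fit provides starting values
#' for its immediate neighbours, each converged fit seeds the next value
#' outward, and so on.  Per-row convergence failures are recorded and the
#' grid continues.
#'
#' @inheritParams fit_mar
#' @param beta2_values Grid of fixed values; must contain the anchor.
#' @param anchor Grid value used as the warm-start origin (default 0).
#' @param p_cc Complete-case abstention probability used for the implied
#'   nonresponder abstention column; defaults to the observed complete-case
#'   rate of `records`.
#' @return A `sensitivity_table`: one row per grid value with the implied
#'   `p_a`, the log-likelihood, a convergence flag, estimate/SE columns for
#'   each missingness-model covariate coefficient, and a significance flag
#'   (`|estimate/SE| > 1.96`) per coefficient.  The underlying fits are
#'   attached as `attr(, "fits")`.
#' @export
sensitivity_grid <- function(records, beta2_values = -4:4, anchor = 0,
                             p_cc = NULL, covariates = covariate_names()) {
  if (!anchor %in% beta2_values) stop("the grid must contain the anchor value")
  if (is.null(p_cc)) p_cc <- mean(records$y[records$r == 1L])
  mar <- fit_mar(records, covariates = covariates)
  ord <- order(abs(beta2_values - anchor), beta2_values)
  grid <- beta2_values[ord]
  fits <- vector("list", length(grid))
  names(fits) <- format(grid, trim = TRUE)
  last_up <- mar$params; last_down <- mar$params
  for (k in seq_along(grid)) {
    b2 <- grid[k]
    if (b2 == anchor && anchor == 0) {
      fits[[k]] <- mar
      next
    }
    start <- if (b2 >= anchor) last_up else last_down
    fit <- tryCatch(
      fit_fixed_beta2(records, b2, start = start, covariates = covariates),
      error = function(e) e)
    fits[[k]] <- fit
    if (inherits(fit, "quitmiss_fit") && fit$converged) {
      if (b2 >= anchor) last_up <- fit$params
      if (b2 <= anchor) last_down <- fit$params
    }
  }
  ord_back <- order(grid)
  grid <- grid[ord_back]; fits <- fits[ord_back]
  rows <- lapply(seq_along(grid), function(k) {
    fit <- fits[[k]]
    base <- data.frame(beta2 = grid[k],
                       p_a = beta2_to_missing_abstention(grid[k], p_cc))
    if (!inherits(fit, "quitmiss_fit")) {
      base$loglik <- NA_real_; base$converged <- FALSE
      for (cv in covariates) {
        base[[paste0("est.", cv)]] <- NA_real_
        base[[paste0("se.", cv)]] <- NA_real_
        base[[paste0("sig.", cv)]] <- NA
      }
      return(base)
    }
    base$loglik <- fit$loglik; base$converged <- fit$converged
    for (cv in covariates) {
      est <- fit$params$beta1[[cv]]
      se <- fit$se[[paste0("beta1.", cv)]]
      base[[paste0("est.", cv)]] <- est
      base[[paste0("se.", cv)]] <- se
      base[[paste0("sig.", cv)]] <- is.finite(se) && abs(est / se) > 1.96
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "p_cc") <- p_cc
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("Sensitivity analysis over fixed beta2 (significance = |z| > 1.96)\n")
  df <- as.data.frame(x)
  print(cbind(df[, c("beta2", "p_a", "loglik", "converged")],
              round(df[, grep("^est\\.", names(df))], 3)))
  invisible(x)
}

#' Covariate-coding adequacy diagnostics
#'
#' For each categorical (score) covariate, a deviance (likelihood-ratio)
#' test compares logistic regressions treating the covariate as categorical
#' versus continuous, for both the complete-case outcome regression and the
#' all-participant missingness regression.  For the continuous covariates
#' (age, conscientiousness) a quadratic-term test is performed instead.
#' Binary covariates are skipped (the two codings coincide).  These MAR
#' regressions justify using the score covariates as continuous in the
#' likelihood fits.
#'
#' @inheritParams fit_mar
#' @param collapse_min Categories observed fewer than this many times are
#'   collapsed into the adjacent category, with a warning.
#' @return Data frame with columns `covariate`, `model` (`"outcome"` /
#'   `"missingness"`), `test`, `df`, `deviance`, `p_value`.
#' @export
coding_adequacy_tests <- function(records, collapse_min = 5L) {
  covs <- covariate_names()
  info <- covariate_info()
  dat <- as.data.frame(records)
  cc <- dat[records$r == 1L, , drop = FALSE]
  if (length(unique(cc$y)) < 2L) stop("complete-case subset is degenerate")
  rows <- list()
  run_lrt <- function(data, response, cov, kind) {
    base_fml <- stats::reformulate(covs, response = response)
    base <- stats::glm(base_fml, family = stats::binomial(), data = data)
    if (kind == "categorical_vs_continuous") {
      v <- data[[cov]]
      counts <- table(v)
      if (any(counts < collapse_min)) {
        warning("collapsing sparse categories of '", cov, "'")
        lev <- as.numeric(names(counts))
        grp <- cumsum(counts >= collapse_min)
        grp[grp == 0] <- 1          # leading sparse levels join the first kept one
        v <- lev[match(grp[match(v, lev)], grp)]
        data$.cat <- factor(v)
      } else data$.cat <- factor(v)
      if (nlevels(data$.cat) < 2L) {
        return(data.frame(covariate = cov, model = response, test = kind,
                          df = NA, deviance = NA, p_value = NA))
      }
      alt_fml <- stats::reformulate(c(setdiff(covs, cov), ".cat"),
                                    response = response)
    } else {
      data$.quad <- data[[cov]]^2
      alt_fml <- stats::reformulate(c(covs, ".quad"), response = response)
    }
    alt <- stats::glm(alt_fml, family = stats::binomial(), data = data)
    dev <- base$deviance - alt$deviance
    dfree <- base$df.residual - alt$df.residual
    data.frame(covariate = cov,
               model = if (response == "y") "outcome" else "missingness",
               test = kind, df = dfree, deviance = dev,
               p_value = stats::pchisq(dev, dfree, lower.tail = FALSE))
  }
  for (cov in covs) {
    type <- info$type[info$name == cov]
    if (type == "binary") next
    kind <- if (type == "score") "categorical_vs_continuous" else "quadratic"
    rows[[length(rows) + 1L]] <- run_lrt(cc, "y", cov, kind)
    rows[[length(rows) + 1L]] <- run_lrt(dat, "r", cov, kind)
  }
  out <- do.call(rbind, rows)
  out$model[out$model == "y"] <- "outcome"
  out$model[out$model == "r"] <- "missingness"
  rownames(out) <- NULL
  out
}
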