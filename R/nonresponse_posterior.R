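# Bayes posterior prediction of the unobserved outcome for nonresponders,
# given their entire failed attempt history.

#' Posterior abstention probability given a failed attempt history
#'
#' By Bayes' theorem, the posterior odds that a nonresponder abstained are
#' the prior (covariate-conditional) odds multiplied by the likelihood ratio
#' of the failed attempts:
#' `odds = P(Y=1|x)/P(Y=0|x) * P(all attempts fail | Y=1, x) /
#' P(all attempts fail | Y=0, x)`,
#' with the failure products taken over exactly the attempts made (phone
#' calls 1..t, plus the email attempt when it was made).  With `beta2 = 0`
#' the likelihood ratio is one and the posterior equals the prior; the
#' posterior is strictly decreasing in `beta2`.
#'
#' @param params An [attempt_params()] object.
#' @param x Covariate vector, or matrix with one row per participant.
#' @param phone_calls Number of failed phone calls per participant (1..10).
#' @param email_attempted Logical, whether the (failed) email attempt was
#'   made.
#' @param success_attempt Optional; if supplied, any non-missing entry is an
#'   error since the posterior is defined only for nonresponders.
#' @return Vector of posterior probabilities `P(Y = 1 | all fail, x)`.
#' @export
posterior_abstention <- function(params, x, phone_calls, email_attempted,
                                 success_attempt = NULL) {
  if (!is.null(success_attempt) && any(!is.na(success_attempt))) {
    stop("posterior_abstention is defined only for failed attempt histories")
  }
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- nrow(X)
  phone_calls <- rep_len(phone_calls, n)
  email_attempted <- rep_len(as.logical(email_attempted), n)
  if (any(phone_calls < 1 | phone_calls > 10)) stop("phone_calls must lie in 1..10")
  idx <- c(rep(seq_len(n), phone_calls), which(email_attempted))
  m <- c(sequence(phone_calls), rep(11L, sum(email_attempted)))
  lp0 <- params$beta0_m[m] + qm_lp(X, params$beta1)[idx] +
    ifelse(m == 11L, params$gamma_email_calls * phone_calls[idx], 0)
  if (anyNA(lp0)) stop("attempt intercept undefined for an attempt in the history")
  lf0 <- stats::plogis(lp0, log.p = TRUE, lower.tail = FALSE)
  lf1 <- stats::plogis(lp0 + params$beta2, log.p = TRUE, lower.tail = FALSE)
  llr <- as.numeric(rowsum(lf1 - lf0, idx))
  prior_logodds <- params$alpha0 + qm_lp(X, params$alpha1)
  unname(stats::plogis(prior_logodds + llr))
}

qm_attempt_params_of <- function(fit) {
  p <- if (inherits(fit, "quitmiss_fit")) fit$params else fit
  if (!inherits(p, "attempt_params")) {
    stop("an attempt_params object (or a repeated-attempts fit) is required")
  }
  p
}

#' Marginal abstention probability among nonresponders
#'
#' Evaluates [posterior_abstention()] for every nonresponder in the cohort
#' at the fitted parameters and averages (unweighted).
#'
#' @param fit A repeated-attempts `quitmiss_fit` or [attempt_params()].
#' @param records A `quitmiss_cohort` containing nonresponders.
#' @return Scalar probability.
#' @export
marginal_nonresponse_abstention <- function(fit, records) {
  params <- qm_attempt_params_of(fit)
  nr <- records[records$r == 0L, , drop = FALSE]
  if (nrow(nr) == 0L) stop("no nonresponders in the cohort")
  mean(posterior_abstention(params, qm_design(nr, params$covariates),
                            nr$phone_calls, nr$email_attempted))
}

#' Per-participant posterior table for nonresponders
#'
#' @inheritParams marginal_nonresponse_abstention
#' @return Data frame `id`, `phone_calls`, `email_attempted`, `posterior`.
#' @export
nonresponder_posteriors <- function(fit, records) {
  params <- qm_attempt_params_of(fit)
  nr <- records[records$r == 0L, , drop = FALSE]
  if (nrow(nr) == 0L) stop("no nonresponders in the cohort")
  data.frame(id = nr$id, phone_calls = nr$phone_calls,
             email_attempted = nr$email_attempted,
             posterior = posterior_abstention(
               params, qm_design(nr, params$covariates),
               nr$phone_calls, nr$email_attempted))
}

#' Sensitivity band for the marginal nonresponder abstention probability
#'
#' Recomputes [marginal_nonresponse_abstention()] with `beta2` replaced by
#' its estimate plus/minus `k` standard errors, all other parameters held at
#' their maximum-likelihood values (the default construction; set
#' `refit = TRUE` to re-maximise the remaining parameters at each shifted
#' `beta2` instead).  Because the posterior decreases in `beta2`, the lower
#' endpoint comes from `+k` SEs and the upper endpoint from `-k` SEs.
#'
#' @param fit A converged repeated-attempts `quitmiss_fit` whose `beta2`
#'   standard error is defined.
#' @param records A `quitmiss_cohort`.
#' @param k Number of standard errors (default 2).
#' @param refit Re-fit the nuisance parameters at each shifted `beta2`.
#' @return Named vector `c(low, high)` with the point estimate attached as
#'   `attr(, "point")`.
#' @export
beta2_band <- function(fit, records, k = 2, refit = FALSE) {
  if (!inherits(fit, "quitmiss_fit") || fit$model != "attempts") {
    stop("a repeated-attempts fit is required")
  }
  se2 <- fit$se[["beta2"]]
  if (!is.finite(se2)) stop("standard error of beta2 is undefined")
  point <- marginal_nonresponse_abstention(fit, records)
  at_beta2 <- function(b2) {
    if (refit) {
      f <- fit_mnar_attempts(records, start = fit,
                             covariates = fit$params$covariates,
                             email_calls = fit$params$gamma_email_calls != 0,
                             fixed_beta2 = b2)
      marginal_nonresponse_abstention(f, records)
    } else {
      p <- fit$params
      p$beta2 <- b2
      marginal_nonresponse_abstention(p, records)
    }
  }
  out <- c(low = at_beta2(fit$params$beta2 + k * se2),
           high = at_beta2(fit$params$beta2 - k * se2))
  attr(out, "point") <- point
  out
}
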