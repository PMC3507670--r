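# Independent brute-force oracles and small fixture builders.  The oracles
# use longhand exp/(1+exp) arithmetic and explicit loops on purpose: they
# share no code with the package's vectorised log-sum-exp implementations.

inv_logit <- function(z) exp(z) / (1 + exp(z))

oracle_selection_loglik <- function(params, records) {
  ll <- 0
  for (i in seq_len(nrow(records))) {
    x <- as.numeric(records[i, params$covariates])
    py1 <- inv_logit(params$alpha0 + sum(params$alpha1 * x))
    pr1 <- function(y) {
      inv_logit(params$beta0 + sum(params$beta1 * x) + params$beta2 * y)
    }
    if (records$r[i] == 1L) {
      y <- records$y[i]
      ll <- ll + log((if (y == 1) py1 else 1 - py1) * pr1(y))
    } else {
      tot <- 0
      for (y in 0:1) {
        tot <- tot + (if (y == 1) py1 else 1 - py1) * (1 - pr1(y))
      }
      ll <- ll + log(tot)
    }
  }
  ll
}

oracle_attempts_loglik <- function(params, records) {
  ll <- 0
  for (i in seq_len(nrow(records))) {
    x <- as.numeric(records[i, params$covariates])
    py1 <- inv_logit(params$alpha0 + sum(params$alpha1 * x))
    t <- records$phone_calls[i]
    ms <- c(seq_len(t), if (records$email_attempted[i]) 11L)
    p_m <- function(m, y) {
      extra <- if (m == 11L) params$gamma_email_calls * t else 0
      inv_logit(params$beta0_m[[m]] + sum(params$beta1 * x) +
                  params$beta2 * y + extra)
    }
    history_prob <- function(y) {
      pr <- 1
      for (m in ms) {
        sm <- !is.na(records$success_attempt[i]) &&
          records$success_attempt[i] == m
        pr <- pr * if (sm) p_m(m, y) else 1 - p_m(m, y)
      }
      pr
    }
    if (records$r[i] == 1L) {
      y <- records$y[i]
      ll <- ll + log((if (y == 1) py1 else 1 - py1) * history_prob(y))
    } else {
      ll <- ll + log(py1 * history_prob(1) + (1 - py1) * history_prob(0))
    }
  }
  ll
}

oracle_posterior_abstention <- function(params, x, t, email) {
  py1 <- inv_logit(params$alpha0 + sum(params$alpha1 * x))
  ms <- c(seq_len(t), if (email) 11L)
  fail_prob <- function(y) {
    pr <- 1
    for (m in ms) {
      extra <- if (m == 11L) params$gamma_email_calls * t else 0
      pr <- pr * (1 - inv_logit(params$beta0_m[[m]] + sum(params$beta1 * x) +
                                  params$beta2 * y + extra))
    }
    pr
  }
  py1 * fail_prob(1) / (py1 * fail_prob(1) + (1 - py1) * fail_prob(0))
}

# Hand-built mixed-branch cohort covering all four likelihood branches:
# phone responder, email responder, email nonresponder, phone-only
# nonresponder, with varying covariates.
toy_mixed_cohort <- function() {
  covs <- covariate_names()
  base <- data.frame(
    treatment = c(1, 0, 1, 0, 1, 0),
    age = c(25, 40, 33, 51, 47, 29),
    sex = c(1, 1, 0, 1, 0, 0),
    qualifications = c(2, 4, 3, 5, 1, 3),
    deprivation = c(0, 2, 1, 3, 5, 1),
    conscientiousness = c(2.5, 3.75, 3, 4.25, 1.75, 3.5),
    determination = c(5, 4, 3, 5, 2, 4),
    support = c(3, 1, 4, 5, 2, 3),
    dependence = c(6, 3, 5, 8, 2, 4),
    previous = c(1, 0, 0, 1, 1, 0)
  )
  base$y <- c(1, 0, NA, NA, 1, NA)
  base$phone_calls <- c(1L, 3L, 2L, 4L, 2L, 10L)
  base$email_attempted <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  base$success_attempt <- c(1L, 11L, NA, NA, 2L, NA)
  as_cohort(base)
}

# Random parameter draws of plausible magnitude (deterministic per `k`).
random_selection_params <- function(k, covariates = covariate_names()) {
  set.seed(1000 + k)
  p <- length(covariates)
  selection_params(stats::rnorm(1, 0, 0.5), stats::rnorm(p, 0, 0.2),
                   stats::rnorm(1, 0, 0.5), stats::rnorm(p, 0, 0.2),
                   stats::rnorm(1, 0, 1), covariates)
}

random_attempt_params <- function(k, covariates = covariate_names(),
                                  gamma = 0) {
  set.seed(2000 + k)
  p <- length(covariates)
  attempt_params(stats::rnorm(1, 0, 0.5), stats::rnorm(p, 0, 0.2),
                 stats::rnorm(11, -1, 0.5), stats::rnorm(p, 0, 0.2),
                 stats::rnorm(1, 0, 1), gamma, covariates)
}

# Config shortcuts for generated test cohorts.
test_config <- function(n = 2000, beta2 = NULL, alpha1 = NULL,
                        beta1 = NULL, single_attempt = FALSE,
                        beta0_1 = NULL) {
  cfg <- default_iquit_config()
  cfg$n <- as.integer(n)
  if (!is.null(beta2)) cfg$attempt$beta2 <- beta2
  if (!is.null(alpha1)) cfg$alpha1[] <- alpha1
  if (!is.null(beta1)) cfg$attempt$beta1[] <- beta1
  if (single_attempt) {
    cfg$censoring <- list(call_budget_probs = c(1, rep(0, 9)), email_prob = 0)
    cfg$attempt$beta0_m[1] <- if (is.null(beta0_1)) -1.5 else beta0_1
  }
  cfg
}

# Selection-model parameters matching a single-attempt generator config.
config_selection_params <- function(cfg) {
  selection_params(cfg$alpha0, cfg$alpha1, cfg$attempt$beta0_m[1],
                   cfg$attempt$beta1, cfg$attempt$beta2)
}

config_attempt_params <- function(cfg) {
  attempt_params(cfg$alpha0, cfg$alpha1, cfg$attempt$beta0_m,
                 cfg$attempt$beta1, cfg$attempt$beta2,
                 cfg$attempt$gamma_email_calls)
}
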