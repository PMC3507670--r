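one_row_cohort <- function(y, r) {
  df <- toy_mixed_cohort()[1, ]
  df <- as.data.frame(df)
  df$y <- y
  df$r <- r
  df$success_attempt <- if (r == 1L) 1L else NA_integer_
  df$phone_calls <- 1L
  df$email_attempted <- FALSE
  as_cohort(df)
}

zero_params <- function() {
  selection_params(0, rep(0, 10), 0, rep(0, 10), 0)
}

test_that("outcome and response probabilities match longhand arithmetic", {
  expect_equal(outcome_probability(zero_params(), rep(1, 10)), 0.5)
  p22 <- selection_params(qlogis(0.22), rep(0, 10), 0, rep(0, 10), 0)
  expect_equal(outcome_probability(p22, rnorm(10)), 0.22)
  for (k in 1:5) {
    pars <- random_selection_params(k)
    x <- as.numeric(toy_mixed_cohort()[((k - 1) %% 6) + 1, covariate_names()])
    expect_equal(outcome_probability(pars, x),
                 inv_logit(pars$alpha0 + sum(pars$alpha1 * x)),
                 tolerance = 1e-12)
    # log-odds gap between y = 1 and y = 0 is exactly beta2
    lo <- qlogis(response_probability(pars, x, 1)) -
      qlogis(response_probability(pars, x, 0))
    expect_equal(lo, pars$beta2, tolerance = 1e-8)
  }
  # MAR: independence of y; extreme beta2 drives the probability to 1
  mar <- zero_params()
  expect_equal(response_probability(mar, rnorm(10), 1),
               response_probability(mar, rnorm(10), 0))
  big <- selection_params(0, rep(0, 10), 0, rep(0, 10), 40)
  expect_equal(response_probability(big, rep(0, 10), 1), 1)
  expect_error(outcome_probability(zero_params(), rep(0, 3)), "dimension")
})

test_that("selection_loglik has the closed-form values and matches enumeration", {
  expect_equal(selection_loglik(zero_params(), one_row_cohort(1L, 1L)),
               log(0.5) + log(0.5))
  expect_equal(selection_loglik(zero_params(), one_row_cohort(NA, 0L)),
               log(0.5))
  co <- toy_mixed_cohort()[c(1, 2, 3, 4, 6), ]
  for (k in 1:8) {
    pars <- random_selection_params(k)
    expect_equal(selection_loglik(pars, co),
                 oracle_selection_loglik(pars, co), tolerance = 1e-10)
  }
})

test_that("the MAR fit separates, recovers truth and flags degeneracies", {
  cfg <- test_config(n = 20000, beta2 = 0, single_attempt = TRUE)
  co <- generate_cohort(cfg, 21)
  fit <- fit_mar(co)
  # separation identity at beta2 = 0
  expect_equal(fit$loglik, sum(fit$component_loglik), tolerance = 1e-8)
  # parameter recovery within 3 reported SEs
  truth <- config_selection_params(cfg)
  est <- coef(fit)
  tv <- c(truth$alpha0, truth$alpha1, truth$beta0, truth$beta1, 0)
  z <- abs(est - tv) / fit$se[names(est)]
  expect_true(all(z[names(z) != "beta2"] < 3))
  # local optimality of the combined likelihood at the stacked estimates
  base <- selection_loglik(fit$params, co)
  for (eps in c(0.02, -0.02)) {
    pert <- fit$params
    pert$beta1[["age"]] <- pert$beta1[["age"]] + eps
    expect_gt(base, selection_loglik(pert, co))
  }
  # degenerate inputs
  full <- as.data.frame(co)
  full$y[full$r == 0L] <- 0L
  full$r <- 1L
  full$success_attempt <- ifelse(full$email_attempted, 11L, full$phone_calls)
  expect_error(fit_mar(as_cohort(full)), "degenerate")
})

test_that("fit_fixed_beta2 at zero reproduces the MAR fit", {
  cfg <- test_config(n = 1500, single_attempt = TRUE)
  co <- generate_cohort(cfg, 22)
  mar <- fit_mar(co)
  f0 <- fit_fixed_beta2(co, 0)
  expect_true(f0$converged)
  expect_equal(f0$loglik, mar$loglik, tolerance = 1e-7)
  expect_equal(coef(f0), coef(mar), tolerance = 1e-4)
  expect_equal(f0$se, mar$se, tolerance = 1e-3)
})

test_that("fit_fixed_beta2 agrees with an exhaustive grid-search oracle", {
  # 50 participants, one covariate, beta2 fixed: 4 free parameters
  cfg <- test_config(n = 50, beta2 = 0.5, single_attempt = TRUE)
  co <- generate_cohort(cfg, 23)
  fit <- fit_fixed_beta2(co, 0.5, covariates = "treatment")
  # oracle: longhand likelihood over a coarse parameter box
  x <- co$treatment; y <- co$y; r <- co$r
  ll_oracle <- function(a0, a1, b0, b1) {
    py1 <- inv_logit(a0 + a1 * x)
    pr1 <- function(yy) inv_logit(b0 + b1 * x + 0.5 * yy)
    obs <- r == 1
    sum(log(ifelse(y[obs] == 1, py1[obs], 1 - py1[obs]) * pr1(y[obs])[obs])) +
      sum(log(py1[!obs] * (1 - pr1(1)[!obs]) +
                (1 - py1[!obs]) * (1 - pr1(0)[!obs])))
  }
  grid <- seq(-3, 3, by = 0.25)
  best <- -Inf; arg <- NULL
  for (a0 in grid) for (a1 in grid) {
    py1 <- inv_logit(a0 + a1 * x)
    for (b0 in grid) for (b1 in grid) {
      pr1y <- inv_logit(b0 + b1 * x + 0.5 * y)
      pr10 <- inv_logit(b0 + b1 * x)
      pr11 <- inv_logit(b0 + b1 * x + 0.5)
      obs <- r == 1
      ll <- sum(log(ifelse(y[obs] == 1, py1[obs], 1 - py1[obs]) * pr1y[obs])) +
        sum(log(py1[!obs] * (1 - pr11[!obs]) +
                  (1 - py1[!obs]) * (1 - pr10[!obs])))
      if (ll > best) { best <- ll; arg <- c(a0, a1, b0, b1) }
    }
  }
  expect_gte(fit$loglik, best - 1e-9)
  mle <- c(fit$params$alpha0, fit$params$alpha1, fit$params$beta0,
           fit$params$beta1)
  expect_true(all(abs(mle - arg) <= 0.25), info = paste(mle, collapse = " "))
})

test_that("fit_fixed_beta2 recovers parameters at the true beta2", {
  cfg <- test_config(n = 20000, beta2 = -1, single_attempt = TRUE)
  co <- generate_cohort(cfg, 24)
  fit <- fit_fixed_beta2(co, -1)
  expect_true(fit$converged)
  truth <- config_selection_params(cfg)
  est <- coef(fit)
  tv <- c(truth$alpha0, truth$alpha1, truth$beta0, truth$beta1)
  z <- abs(est[names(est) != "beta2"] - tv) / fit$se[names(est)[names(est) != "beta2"]]
  expect_true(all(z < 3))
})

test_that("sensitivity_grid expands from the anchor and tracks the MAR row", {
  cfg <- test_config(n = 1500, single_attempt = TRUE)
  co <- generate_cohort(cfg, 25)
  tab <- sensitivity_grid(co)
  expect_s3_class(tab, "sensitivity_table")
  expect_equal(tab$beta2, -4:4)
  expect_true(all(tab$converged))
  expect_true(all(tab$p_a >= 0 & tab$p_a <= 1))
  mar <- fit_mar(co)
  expect_equal(tab$loglik[tab$beta2 == 0], mar$loglik)
  expect_equal(tab$est.age[tab$beta2 == 0], mar$params$beta1[["age"]])
  # age effect (generated strongly positive) keeps its sign across the grid
  expect_true(all(tab$est.age > 0))
  expect_error(sensitivity_grid(co, beta2_values = c(-1, 1)), "anchor")
})

test_that("the full MNAR fit nests the grid and flags degenerate cohorts", {
  cfg <- test_config(n = 1500, single_attempt = TRUE)
  co <- generate_cohort(cfg, 26)
  tab <- sensitivity_grid(co, beta2_values = -2:2)
  full <- fit_full_mnar(co)
  expect_true(full$converged)
  expect_gte(full$loglik, max(tab$loglik) - 1e-8)
  expect_length(full$beta2_ci, 2L)
  expect_lt(full$beta2_ci[1], full$params$beta2)
  nobody <- as.data.frame(co)
  nobody$y <- NA_integer_; nobody$r <- 0L
  nobody$success_attempt <- NA_integer_
  nobody$email_attempted <- FALSE
  expect_error(fit_full_mnar(as_cohort(nobody)), "no responders")
})

test_that("beta2_to_missing_abstention implements the IMOR identities", {
  expect_equal(round(beta2_to_missing_abstention(-4, 0.22), 2), 0.94)
  expect_equal(round(beta2_to_missing_abstention(-2, 0.22), 2), 0.68)
  for (p in c(0.1, 0.22, 0.5, 0.9)) {
    expect_equal(beta2_to_missing_abstention(0, p), p)
  }
  vals <- beta2_to_missing_abstention(seq(-5, 5, by = 0.5), 0.22)
  expect_true(all(diff(vals) < 0))
  expect_error(beta2_to_missing_abstention(1, 0), "p_cc")
  expect_error(beta2_to_missing_abstention(1, 1), "p_cc")
  # odds-ratio symmetry on a full 2x2 joint law: the log OR between R and Y
  # computed in either direction equals beta2
  pars <- random_selection_params(3)
  x <- as.numeric(toy_mixed_cohort()[2, covariate_names()])
  py1 <- outcome_probability(pars, x)
  joint <- matrix(0, 2, 2) # rows y = 0/1, cols r = 0/1
  for (y in 0:1) {
    pr1 <- response_probability(pars, x, y)
    py <- if (y == 1) py1 else 1 - py1
    joint[y + 1, ] <- py * c(1 - pr1, pr1)
  }
  lor_r_given_y <- qlogis(joint[2, 2] / sum(joint[2, ])) -
    qlogis(joint[1, 2] / sum(joint[1, ]))
  lor_y_given_r <- -(qlogis(joint[2, 1] / sum(joint[, 1])) -
                       qlogis(joint[2, 2] / sum(joint[, 2])))
  expect_equal(lor_r_given_y, pars$beta2, tolerance = 1e-10)
  expect_equal(lor_y_given_r, pars$beta2, tolerance = 1e-10)
})

test_that("coding adequacy diagnostics calibrate under the null and detect curvature", {
  cfg <- test_config(n = 8000)
  co <- generate_cohort(cfg, 27)
  # sparse tail categories (deprivation 5) are collapsed, with a warning
  w <- capture_warnings(tab <- coding_adequacy_tests(co))
  expect_true(any(grepl("collapsing sparse", w)))
  # binary covariates are skipped
  expect_false(any(tab$covariate %in% c("treatment", "sex", "previous")))
  expect_true(all(c("categorical_vs_continuous", "quadratic") %in% tab$test))
  # generated effects are linear: no mass rejection expected
  expect_gte(mean(tab$p_value > 0.05, na.rm = TRUE), 0.5)
  # a strong U-shaped age effect must trip the quadratic test
  sh <- shadow_truth(co)
  bent <- as.data.frame(co)
  set.seed(28)
  py <- plogis(-1.5 + 0.004 * (bent$age - 38)^2)
  y_new <- rbinom(nrow(bent), 1, py)
  keep <- rbinom(nrow(bent), 1, 0.6)
  bent$y <- ifelse(keep == 1, y_new, NA_integer_)
  bent$r <- keep
  bent$phone_calls <- 1L
  bent$email_attempted <- FALSE
  bent$success_attempt <- ifelse(keep == 1, 1L, NA_integer_)
  bent <- as_cohort(bent)
  tab2 <- suppressWarnings(coding_adequacy_tests(bent))
  p_quad <- tab2$p_value[tab2$covariate == "age" & tab2$model == "outcome"]
  expect_lt(p_quad, 0.001)
})
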