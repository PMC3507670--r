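zero_att_params <- function() {
  attempt_params(0, rep(0, 10), rep(0, 11), rep(0, 10), 0)
}

test_that("attempt_probability applies the per-attempt predictor", {
  pars <- zero_att_params()
  x <- rnorm(10)
  for (m in c(1, 5, 11)) expect_equal(attempt_probability(pars, m, x, 1), 0.5)
  expect_error(attempt_probability(pars, 12, x, 1), "1..11")
  expect_error(attempt_probability(pars, 0, x, 1), "1..11")
  for (k in 1:4) {
    rp <- random_attempt_params(k)
    x <- as.numeric(toy_mixed_cohort()[(k %% 6) + 1, covariate_names()])
    # with beta2 = 0 and fixed x the probability varies only through the
    # attempt intercepts
    rp0 <- rp; rp0$beta2 <- 0
    probs <- sapply(1:11, function(m) attempt_probability(rp0, m, x, 1))
    expect_equal(qlogis(probs) - rp0$beta0_m, rep(sum(rp0$beta1 * x), 11),
                 ignore_attr = TRUE)
    # log-odds gap between outcomes is beta2 at every attempt
    for (m in c(2, 11)) {
      gap <- qlogis(attempt_probability(rp, m, x, 1, phone_calls = 3)) -
        qlogis(attempt_probability(rp, m, x, 0, phone_calls = 3))
      expect_equal(gap, rp$beta2, tolerance = 1e-8)
    }
  }
  # the robustness variant shifts only the email attempt
  rp <- random_attempt_params(5, gamma = 0.3)
  x <- rep(0, 10)
  expect_equal(qlogis(attempt_probability(rp, 11, x, 0, phone_calls = 4)) -
                 qlogis(attempt_probability(rp, 11, x, 0, phone_calls = 0)),
               1.2, tolerance = 1e-8)
  expect_equal(attempt_probability(rp, 3, x, 0, phone_calls = 4),
               attempt_probability(rp, 3, x, 0, phone_calls = 0))
})

test_that("attempts_loglik matches closed forms and the enumeration oracle", {
  pars <- zero_att_params()
  # phone responder at call 1: empty failure product
  co1 <- toy_mixed_cohort()[1, ]
  expect_equal(attempts_loglik(pars, co1), log(0.5) + log(0.5))
  # email nonresponder with two failed calls and a failed email
  df <- as.data.frame(toy_mixed_cohort()[3, ])
  df$phone_calls <- 2L
  co2 <- as_cohort(df)
  expect_equal(attempts_loglik(pars, co2), log(0.5 * 0.5^3 + 0.5 * 0.5^3))
  # mixed six-record toy against the brute-force oracle
  co <- toy_mixed_cohort()
  for (k in 1:8) {
    rp <- random_attempt_params(k, gamma = if (k %% 2) 0 else 0.25)
    expect_equal(attempts_loglik(rp, co), oracle_attempts_loglik(rp, co),
                 tolerance = 1e-10)
  }
})

test_that("the MAR attempts fit separates and recovers truth", {
  cfg <- test_config(n = 20000, beta2 = 0)
  co <- generate_cohort(cfg, 31)
  fit <- fit_mar_attempts(co)
  expect_equal(fit$loglik, sum(fit$component_loglik), tolerance = 1e-8)
  truth <- config_attempt_params(cfg)
  z <- abs(fit$params$beta1 - truth$beta1) /
    fit$se[paste0("beta1.", covariate_names())]
  expect_true(all(z < 3))
  # attempt-level expansion conserves counts
  E <- quitmiss:::expand_attempts(co)
  expect_equal(length(E$m), sum(co$phone_calls) + sum(co$email_attempted))
  # cohort in which everyone answers call 1 leaves one identifiable intercept
  cfg1 <- test_config(n = 400, single_attempt = TRUE, beta0_1 = 8)
  co1 <- generate_cohort(cfg1, 32)
  fit1 <- fit_mar_attempts(co1)
  expect_equal(fit1$m_present, 1L)
  expect_true(all(is.na(fit1$params$beta0_m[2:11])))
})

test_that("the MNAR attempts fit estimates beta2 and nests the MAR fit", {
  cfg <- test_config(n = 20000, beta2 = 0.2)
  co <- generate_cohort(cfg, 33)
  mar <- fit_mar_attempts(co)
  fit <- fit_mnar_attempts(co, start = mar)
  expect_true(fit$converged)
  expect_gte(fit$loglik, mar$loglik)
  z <- abs(fit$params$beta2 - 0.2) / fit$se[["beta2"]]
  expect_lt(z, 3)
  expect_length(fit$beta2_ci, 2L)
})

test_that("with a single attempt the attempts model reduces to the selection model", {
  cfg <- test_config(n = 1200, single_attempt = TRUE)
  co <- generate_cohort(cfg, 34)
  # likelihood identity at arbitrary matching parameters
  for (k in 1:4) {
    sp <- random_selection_params(k)
    ap <- attempt_params(sp$alpha0, sp$alpha1,
                         c(sp$beta0, rep(0, 10)), sp$beta1, sp$beta2)
    expect_equal(attempts_loglik(ap, co), selection_loglik(sp, co),
                 tolerance = 1e-10)
  }
  # and the fitted models coincide
  fa <- fit_mnar_attempts(co)
  fs <- fit_full_mnar(co)
  expect_equal(fa$loglik, fs$loglik, tolerance = 1e-6)
  expect_equal(fa$params$beta2, fs$params$beta2, tolerance = 1e-3)
  expect_equal(fa$params$beta0_m[[1]], fs$params$beta0, tolerance = 1e-3)
  expect_equal(fa$params$beta1, fs$params$beta1, tolerance = 1e-3)
  expect_equal(fa$se[["beta2"]], fs$se[["beta2"]], tolerance = 1e-3)
})

test_that("interaction diagnostics calibrate under the null and find planted effects", {
  cfg <- test_config(n = 20000)
  co <- generate_cohort(cfg, 35)
  tab <- interaction_diagnostics(co)
  expect_equal(tab$covariate, covariate_names())
  expect_true(all(tab$estimable))
  # no interactions were generated: gross rejection would indicate a bug
  expect_gte(sum(tab$p_attempt > 0.01), 8)
  # plant an email-by-qualifications effect by re-drawing email successes
  sh <- shadow_truth(co)
  pars <- config_attempt_params(cfg)
  df <- as.data.frame(co)
  em <- which(df$email_attempted)
  set.seed(36)
  lp <- pars$beta0_m[11] +
    as.matrix(df[em, covariate_names()]) %*% pars$beta1 +
    pars$beta2 * sh$y_true[em] + 0.38 * (df$qualifications[em] - 3)
  hit <- runif(length(em)) < plogis(lp)
  df$success_attempt[em] <- ifelse(hit, 11L, NA_integer_)
  df$r[em] <- as.integer(hit)
  df$y[em] <- ifelse(hit, sh$y_true[em], NA_integer_)
  planted <- as_cohort(df)
  tab2 <- interaction_diagnostics(planted)
  expect_lt(tab2$p_email[tab2$covariate == "qualifications"], 0.01)
  expect_gt(tab2$email_logor[tab2$covariate == "qualifications"], 0.2)
  # constant covariate flagged inestimable
  df2 <- as.data.frame(generate_cohort(test_config(n = 500), 37))
  df2$sex <- 1
  tab3 <- interaction_diagnostics(as_cohort(df2))
  expect_false(tab3$estimable[tab3$covariate == "sex"])
})

test_that("attempt_trend_regression reproduces the fixture trend", {
  t3 <- load_fixture("table3")
  tr <- attempt_trend_regression(t3)
  expect_equal(round(tr[["slope"]], 2), -0.03)
  expect_equal(round(tr[["se"]], 2), 0.04)
  # constant quit proportions give slope zero
  flat <- as.data.frame(t3[!t3$email_attempted, ])
  flat$quitters <- 20L
  flat$responders <- 100L
  flat$participants <- 100L
  class(flat) <- c("attempt_summary", "data.frame")
  tr0 <- attempt_trend_regression(flat)
  expect_equal(tr0[["slope"]], 0, tolerance = 1e-8)
  expect_error(attempt_trend_regression(t3[1:2, ]), "distinct")
})

test_that("robustness_suite refits under every specification", {
  cfg <- test_config(n = 4000)
  co <- generate_cohort(cfg, 38)
  tab <- robustness_suite(co)
  expect_equal(nrow(tab), 9L)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$converged))
  expect_true(all(is.finite(tab$beta2)))
  # disjoint subgroup estimates agree with the pooled fit on homogeneous data
  pooled <- fit_mnar_attempts(co)
  for (lab in c("younger (36 and under)", "older (37 and over)")) {
    row <- tab[tab$label == lab, ]
    expect_lt(abs(row$beta2 - pooled$params$beta2), 3 * row$se)
  }
  # the no-covariate spec fits an intercepts-plus-beta2 model
  none <- attr(tab, "fits")[[3]]
  expect_length(none$params$beta1, 0L)
  expect_length(none$params$alpha1, 0L)
})
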