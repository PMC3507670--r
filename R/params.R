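# Parameter containers and shared numerical machinery for the likelihood fits.

#' Selection-model parameters
#'
#' The outcome model is `logit P(Y = 1 | x) = alpha0 + alpha1' x` and the
#' missingness (selection) model is
#' `logit P(R = 1 | Y = y, x) = beta0 + beta1' x + beta2 * y`.
#' `beta2` is the adjusted log odds ratio between outcome and response:
#' `beta2 = 0` is missing at random (MAR), large positive `beta2` approaches
#' the "missing = smoking" convention.
#'
#' @param alpha0,beta0 Intercepts.
#' @param alpha1,beta1 Covariate coefficient vectors, one entry per covariate
#'   in `covariates` order.
#' @param beta2 Outcome coefficient in the missingness model.
#' @param covariates Character vector naming the covariates; defaults to the
#'   full set of [covariate_names()].
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(alpha0, alpha1, beta0, beta1, beta2,
                             covariates = covariate_names()) {
  alpha1 <- as.numeric(alpha1); beta1 <- as.numeric(beta1)
  if (length(alpha1) != length(covariates) ||
      length(beta1) != length(covariates)) {
    stop("alpha1 and beta1 must have one entry per covariate")
  }
  vals <- c(alpha0, alpha1, beta0, beta1, beta2)
  if (!all(is.finite(vals))) stop("parameters must be finite")
  structure(list(alpha0 = as.numeric(alpha0),
                 alpha1 = stats::setNames(alpha1, covariates),
                 beta0 = as.numeric(beta0),
                 beta1 = stats::setNames(beta1, covariates),
                 beta2 = as.numeric(beta2),
                 covariates = covariates),
            class = "selection_params")
}

#' Repeated-attempts model parameters
#'
#' The outcome model is shared with [selection_params()]; the attempt-level
#' missingness model is
#' `logit P(R'_m = 1 | Y = y, x) = beta0_m + beta1' x + beta2 * y`,
#' for attempts m = 1..10 (phone calls) and m = 11 (the email attempt,
#' always indexed 11 regardless of how many calls preceded it).  When
#' `gamma_email_calls` is non-zero the email attempt's linear predictor
#' additionally includes `gamma_email_calls * t` where `t` is the number of
#' failed phone calls (a robustness variant).
#'
#' @param alpha0 Outcome intercept.
#' @param alpha1,beta1 Covariate coefficient vectors.
#' @param beta0_m Length-11 vector of per-attempt intercepts (index 11 =
#'   email).  Entries may be `NA` for attempts that are absent from a
#'   dataset and hence unidentified.
#' @param beta2 Outcome coefficient shared across attempts.
#' @param gamma_email_calls Coefficient of the phone-call count in the email
#'   attempt's predictor (default 0 = disabled).
#' @param covariates Covariate names, defaults to [covariate_names()].
#' @return An object of class `attempt_params`.
#' @export
attempt_params <- function(alpha0, alpha1, beta0_m, beta1, beta2,
                           gamma_email_calls = 0,
                           covariates = covariate_names()) {
  alpha1 <- as.numeric(alpha1); beta1 <- as.numeric(beta1)
  beta0_m <- as.numeric(beta0_m)
  if (length(beta0_m) != 11L) stop("beta0_m must have length 11")
  if (length(alpha1) != length(covariates) ||
      length(beta1) != length(covariates)) {
    stop("alpha1 and beta1 must have one entry per covariate")
  }
  structure(list(alpha0 = as.numeric(alpha0),
                 alpha1 = stats::setNames(alpha1, covariates),
                 beta0_m = stats::setNames(beta0_m,
                                           c(paste0("call", 1:10), "email")),
                 beta1 = stats::setNames(beta1, covariates),
                 beta2 = as.numeric(beta2),
                 gamma_email_calls = as.numeric(gamma_email_calls),
                 covariates = covariates),
            class = "attempt_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat("Selection-model parameters (", length(x$covariates), " covariates)\n",
      sep = "")
  cat("  alpha0 =", format(x$alpha0, digits = 4),
      " beta0 =", format(x$beta0, digits = 4),
      " beta2 =", format(x$beta2, digits = 4), "\n")
  invisible(x)
}

#' @export
print.attempt_params <- function(x, ...) {
  cat("Repeated-attempts model parameters (",
      length(x$covariates), " covariates)\n", sep = "")
  cat("  alpha0 =", format(x$alpha0, digits = 4),
      " beta2 =", format(x$beta2, digits = 4), "\n")
  cat("  attempt intercepts:",
      paste(format(x$beta0_m, digits = 3), collapse = " "), "\n")
  invisible(x)
}

new_fit_result <- function(params, se, vcov, loglik, converged, n_used,
                           model, fixed_beta2 = NULL, notes = character()) {
  structure(list(params = params, se = se, vcov = vcov, loglik = loglik,
                 converged = converged, n_used = n_used, model = model,
                 fixed_beta2 = fixed_beta2, notes = notes),
            class = "quitmiss_fit")
}

#' @export
print.quitmiss_fit <- function(x, ...) {
  cat(sprintf("quitmiss %s-model fit: n = %d, loglik = %.3f, converged = %s\n",
              x$model, x$n_used, x$loglik, x$converged))
  if (!is.null(x$fixed_beta2)) {
    cat(sprintf("  beta2 fixed at %g\n", x$fixed_beta2))
  }
  est <- coef(x)
  tab <- data.frame(estimate = est, se = x$se[names(est)])
  print(round(tab, 4))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.quitmiss_fit <- function(object, ...) {
  p <- object$params
  if (inherits(p, "selection_params")) {
    c(alpha0 = p$alpha0,
      stats::setNames(p$alpha1, paste0("alpha1.", names(p$alpha1))),
      beta0 = p$beta0,
      stats::setNames(p$beta1, paste0("beta1.", names(p$beta1))),
      beta2 = p$beta2)
  } else {
    out <- c(alpha0 = p$alpha0,
             stats::setNames(p$alpha1, paste0("alpha1.", names(p$alpha1))),
             stats::setNames(p$beta0_m, paste0("beta0.", names(p$beta0_m))),
             stats::setNames(p$beta1, paste0("beta1.", names(p$beta1))),
             beta2 = p$beta2)
    if (p$gamma_email_calls != 0 || "gamma_email_calls" %in% names(object$se)) {
      out <- c(out, gamma_email_calls = p$gamma_email_calls)
    }
    out
  }
}

#' @export
logLik.quitmiss_fit <- function(object, ...) {
  structure(object$loglik, df = sum(!is.na(object$se)), class = "logLik")
}

# --- internal numerics -----------------------------------------------------

# Design matrix of the requested covariates (no intercept column).
qm_design <- function(records, covariates = covariate_names()) {
  as.matrix(as.data.frame(records)[, covariates, drop = FALSE])
}

# Central-difference Hessian of the log-likelihood, obtained by differencing
# the analytic score; step scaled per coordinate.
qm_num_hessian <- function(score_fn, theta, h_rel = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  h <- h_rel * pmax(1, abs(theta))
  for (j in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    H[, j] <- (score_fn(tp) - score_fn(tm)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

# Maximise a log-likelihood with analytic score: BFGS followed by a Newton
# polish so that the gradient at the reported optimum is essentially zero.
qm_maximize <- function(theta0, loglik_fn, score_fn,
                        grad_tol = 1e-6, max_polish = 25L) {
  # BFGS takes the iterate close; the damped Newton polish below supplies the
  # final quadratic convergence, so a moderate reltol suffices here
  opt <- stats::optim(theta0, fn = function(th) -loglik_fn(th),
                      gr = function(th) -score_fn(th), method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-9))
  theta <- opt$par
  ll <- -opt$value
  g <- score_fn(theta)
  polish_ok <- TRUE
  for (it in seq_len(max_polish)) {
    if (max(abs(g)) < grad_tol) break
    H <- qm_num_hessian(score_fn, theta)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) { polish_ok <- FALSE; break }
    # damped Newton: halve until the log-likelihood does not decrease
    lam <- 1
    repeat {
      cand <- theta + lam * step
      ll_cand <- loglik_fn(cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-9) break
      lam <- lam / 2
      if (lam < 1e-6) { polish_ok <- FALSE; break }
    }
    if (!polish_ok) break
    theta <- theta + lam * step
    ll <- loglik_fn(theta)
    g <- score_fn(theta)
  }
  list(theta = theta, loglik = ll, score = g,
       converged = opt$convergence == 0 && max(abs(g)) < grad_tol,
       optim_code = opt$convergence)
}

# Standardisation map used internally during optimisation: covariates are
# centred and scaled, coefficients back-transformed exactly (the map is
# linear).  Returns centre/scale vectors with scale 1 for constant columns.
qm_standardize <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(Z = sweep(sweep(X, 2, mu), 2, sg, "/"), mu = mu, sigma = sg)
}

# SEs and covariance from the observed information (negative Hessian of the
# log-likelihood at the optimum).  A non-invertible or non-positive-definite
# information matrix yields NA SEs plus a diagnostic note, never an error.
qm_vcov_from_hessian <- function(H, names) {
  p <- nrow(H)
  info <- -H
  V <- tryCatch(solve(info), error = function(e) NULL)
  notes <- character()
  if (is.null(V) || !all(is.finite(V))) {
    V <- matrix(NA_real_, p, p)
    notes <- "observed information matrix is singular; SEs undefined"
  } else if (any(diag(V) <= 0)) {
    notes <- "observed information matrix not positive definite; some SEs undefined"
    diag(V)[diag(V) <= 0] <- NA_real_
  } else {
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev)) {
      notes <- "observed information matrix is near-singular"
    }
  }
  dimnames(V) <- list(names, names)
  se <- suppressWarnings(sqrt(diag(V)))
  names(se) <- names
  list(vcov = V, se = se, notes = notes)
}
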