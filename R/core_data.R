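# Domain types and delimited-text I/O for participant-level trial data.

#' The ten baseline covariates, in their canonical order
#'
#' Coefficient vectors throughout the package (`alpha1`, `beta1`) are indexed
#' by this order.  Categorical scores (qualifications, deprivation,
#' determination, support, dependence) are stored as numeric values and used
#' as continuous covariates; see [coding_adequacy_tests()] for the
#' diagnostics that justify this coding.
#'
#' @return Character vector of length 10.
#' @export
covariate_names <- function() {
  c("treatment", "age", "sex", "qualifications", "deprivation",
    "conscientiousness", "determination", "support", "dependence", "previous")
}

#' Covariate metadata
#'
#' @return A data frame with one row per baseline covariate: its `name`,
#'   storage `type` (`"binary"`, `"continuous"` or `"score"`), whether it is
#'   considered smoking related, and the admissible `min`/`max`.
#' @export
covariate_info <- function() {
  data.frame(
    name = covariate_names(),
    type = c("binary", "continuous", "binary", "score", "score",
             "continuous", "score", "score", "score", "binary"),
    smoking_related = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                        FALSE, TRUE, TRUE, TRUE, TRUE),
    min = c(0, 0, 0, 1, 0, 1, 1, 1, 1, 0),
    max = c(1, Inf, 1, 5, 5, 5, 5, 5, 8, 1),
    stringsAsFactors = FALSE
  )
}

#' @rdname covariate_info
#' @export
smoking_related_covariates <- function() {
  info <- covariate_info()
  info$name[info$smoking_related]
}

qm_required_columns <- function() {
  c("id", covariate_names(), "y", "r",
    "phone_calls", "email_attempted", "success_attempt")
}

#' Validate and classify a participant-level cohort table
#'
#' A cohort is a data frame with one row per participant: an `id`, the ten
#' baseline covariates of [covariate_names()], a binary outcome `y` (`NA`
#' when missing), a response indicator `r`, and the attempt history
#' (`phone_calls` in 1..10, logical `email_attempted`, and `success_attempt`
#' in 1..10 for a phone response, 11 for an email response, `NA` for a
#' nonresponder).
#'
#' Invariants enforced:
#' * `r == 1` exactly when `y` is observed, and exactly when
#'   `success_attempt` is non-missing;
#' * all covariates complete (the models assume complete baseline data);
#' * binary covariates in \{0, 1\} and `age > 0`;
#' * a phone success occurs at the last call made (`success_attempt ==
#'   phone_calls`) with no email attempted; an email success implies
#'   `email_attempted`.
#'
#' @param x A data frame with the columns above (`r` may be omitted, in which
#'   case it is derived as `!is.na(y)`).
#' @return `x` with class `quitmiss_cohort` prepended, columns in canonical
#'   order.
#' @export
as_cohort <- function(x) {
  x <- as.data.frame(x)
  if (!"r" %in% names(x) && "y" %in% names(x)) {
    x$r <- as.integer(!is.na(x$y))
  }
  if (!"id" %in% names(x)) {
    x$id <- seq_len(nrow(x))
  }
  missing_cols <- setdiff(qm_required_columns(), names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$email_attempted <- as.logical(x$email_attempted)
  x$r <- as.integer(x$r)
  validate_cohort(x)
  x <- x[, union(qm_required_columns(), names(x)), drop = FALSE]
  class(x) <- c("quitmiss_cohort", "data.frame")
  x
}

#' @rdname as_cohort
#' @export
validate_cohort <- function(x) {
  covs <- covariate_names()
  if (anyNA(x[covs])) {
    bad <- covs[vapply(x[covs], anyNA, logical(1))]
    stop("covariate missing values violate the complete-baseline assumption: ",
         paste(bad, collapse = ", "))
  }
  info <- covariate_info()
  for (j in which(info$type == "binary")) {
    v <- x[[info$name[j]]]
    if (!all(v %in% c(0, 1))) {
      stop("binary covariate '", info$name[j], "' must be 0/1")
    }
  }
  if (any(x$age <= 0)) stop("age must be positive")
  r_from_y <- as.integer(!is.na(x$y))
  if (!identical(as.integer(x$r), r_from_y)) {
    stop("inconsistent response indicator: r must equal 1 iff y is observed")
  }
  if (anyNA(x$phone_calls) || any(x$phone_calls < 1L | x$phone_calls > 10L)) {
    stop("phone_calls must lie in 1..10")
  }
  if (anyNA(x$email_attempted)) stop("email_attempted must be TRUE/FALSE")
  sa <- x$success_attempt
  if (!identical(as.integer(x$r), as.integer(!is.na(sa)))) {
    stop("inconsistent response indicator: r must equal 1 iff success_attempt is set")
  }
  ok <- is.na(sa) |
    (sa <= 10L & sa == x$phone_calls & !x$email_attempted) |
    (sa == 11L & x$email_attempted)
  if (!all(ok)) {
    stop("invalid attempt history: a phone success must occur at the last ",
         "call made with no email; an email success requires email_attempted")
  }
  if (!all(x$y %in% c(0, 1, NA))) stop("y must be 0, 1 or missing")
  invisible(x)
}

#' Read a participant-level trial table from delimited text
#'
#' Comma-separated values with a header row; the outcome column may contain
#' an empty field or the token `NA` to mark a missing outcome.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the column names used in the file (values).
#' @return A [as_cohort()] validated `quitmiss_cohort`, rows in file order.
#' @export
read_trial_table <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    pos <- match(schema, names(raw))
    if (anyNA(pos)) {
      stop("schema refers to absent column(s): ",
           paste(schema[is.na(pos)], collapse = ", "))
    }
    names(raw)[pos] <- names(schema)
  }
  as_cohort(raw)
}

#' Write a cohort (and optionally its shadow truth) to delimited text
#'
#' The missing-outcome marker on disk is an empty field.  If the cohort
#' carries generator ground truth (see [generate_cohort()]) it can be written
#' to a sidecar file; it is never part of the main table.
#'
#' @param records A `quitmiss_cohort`.
#' @param path Output CSV path.
#' @param shadow_path Optional path for the shadow-truth sidecar.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(records, path, shadow_path = NULL) {
  out <- as.data.frame(records)[, qm_required_columns()]
  out$email_attempted <- as.integer(out$email_attempted)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(shadow_path)) {
    sh <- shadow_truth(records)
    if (is.null(sh)) stop("records carry no shadow truth")
    utils::write.csv(sh, shadow_path, row.names = FALSE)
  }
  invisible(path)
}

#' Summarise the missingness pattern of the primary outcome
#'
#' @param records A `quitmiss_cohort` (non-empty).
#' @return An object of class `missingness_summary`: totals `n_total`,
#'   `n_missing`, `n_abstained`, `n_not_abstained`, a `by_arm` count matrix
#'   (status by arm), and the derived proportions `prop_missing` (missing
#'   outcomes among all participants) and `prop_abstained_cc` (abstention
#'   among responders, the complete cases).
#' @export
summarize_missingness <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort")
  status <- ifelse(is.na(records$y), "missing",
                   ifelse(records$y == 1, "abstained", "not_abstained"))
  status <- factor(status, levels = c("not_abstained", "abstained", "missing"))
  arm <- factor(ifelse(records$treatment == 1, "treatment", "control"),
                levels = c("treatment", "control"))
  new_missingness_summary(table(status, arm))
}

new_missingness_summary <- function(by_arm) {
  by_arm <- as.matrix(by_arm)
  totals <- rowSums(by_arm)
  n_resp <- totals[["not_abstained"]] + totals[["abstained"]]
  out <- list(
    n_total = sum(by_arm),
    n_missing = totals[["missing"]],
    n_abstained = totals[["abstained"]],
    n_not_abstained = totals[["not_abstained"]],
    by_arm = by_arm,
    prop_missing = totals[["missing"]] / sum(by_arm),
    prop_abstained_cc = if (n_resp > 0) totals[["abstained"]] / n_resp else NaN
  )
  structure(out, class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat("Missingness pattern for the primary outcome\n")
  print(x$by_arm)
  cat(sprintf("missing: %d/%d (%.0f%%); abstained among responders: %d/%d (%.0f%%)\n",
              x$n_missing, x$n_total, 100 * x$prop_missing,
              x$n_abstained, x$n_abstained + x$n_not_abstained,
              100 * x$prop_abstained_cc))
  invisible(x)
}

new_attempt_summary <- function(df) {
  stopifnot(all(c("phone_calls", "email_attempted", "participants",
                  "responders", "quitters") %in% names(df)))
  if (any(df$responders > df$participants) || any(df$quitters > df$responders)) {
    stop("invalid attempt summary: counts must nest")
  }
  class(df) <- c("attempt_summary", "data.frame")
  df
}

#' Load a packaged fixture table
#'
#' Two delimited fixtures ship with the package: `"table1"`, the
#' missingness pattern of the motivating cessation trial (1758 participants,
#' 1036 missing outcomes), and `"table3"`, the outcome by number and type of
#' contact attempt (participants / responders / quitters per cell of
#' phone-call count 1..10 crossed with whether an email was attempted).
#'
#' @param name `"table1"` or `"table3"`.
#' @return A `missingness_summary` (table1) or `attempt_summary` (table3).
#' @export
load_fixture <- function(name) {
  if (identical(name, "table1")) {
    df <- utils::read.csv(system.file("extdata", "table1_missingness.csv",
                                      package = "quitmiss"))
    by_arm <- as.matrix(df[, c("treatment", "control")])
    rownames(by_arm) <- df$status
    return(new_missingness_summary(by_arm))
  }
  if (identical(name, "table3")) {
    df <- utils::read.csv(system.file("extdata", "table3_attempts.csv",
                                      package = "quitmiss"))
    df$email_attempted <- as.logical(df$email_attempted)
    return(new_attempt_summary(df))
  }
  stop("unknown fixture name: ", name)
}
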