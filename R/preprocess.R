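#' Encode the 2 x 2 session/trial-type design as condition indicators
#'
#' Dummy codes the crossed design with the neutral trials of the
#' smoke-as-usual session as baseline: (smoke_as_usual, neutral) maps to
#' (0,0,0); (abstinent, neutral) to (1,0,0); (smoke_as_usual, reward) to
#' (0,1,0); (abstinent, reward) to (0,0,1).
#'
#' @param session Character vector with levels `"smoke_as_usual"`,
#'   `"abstinent"`.
#' @param trial_type Character vector with levels `"neutral"`, `"reward"`.
#' @return An n x 3 indicator matrix with columns `g1`, `g2`, `g3`
#'   (neutral-abstinent, reward-smoke-as-usual, reward-abstinent) and the
#'   cell index 1..4 as attribute `"cell"`.
#' @export
encode_condition <- function(session, trial_type) {
  session <- as.character(session); trial_type <- as.character(trial_type)
  if (!all(session %in% .later_sessions))
    stop("unknown session level(s): ",
         paste(setdiff(session, .later_sessions), collapse = ", "),
         "; accepted: ", paste(.later_sessions, collapse = ", "))
  if (!all(trial_type %in% .later_trial_types))
    stop("unknown trial_type level(s): ",
         paste(setdiff(trial_type, .later_trial_types), collapse = ", "),
         "; accepted: ", paste(.later_trial_types, collapse = ", "))
  if (length(session) != length(trial_type))
    stop("session and trial_type lengths differ")
  cell <- 1L + (session == "abstinent") + 2L * (trial_type == "reward")
  g <- .later_g[cell, , drop = FALSE]
  dimnames(g) <- list(NULL, c("g1", "g2", "g3"))
  attr(g, "cell") <- cell
  g
}

#' Exclude premature responses
#'
#' Drops trials with latencies strictly below the threshold (default
#' 150 ms), the standard guard against anticipatory responses that are not
#' reactions to the stimulus. A latency exactly at the threshold is
#' retained. Input order is preserved and retained rows are unmodified.
#'
#' @param trials A data frame with an `rt` column in seconds.
#' @param threshold Exclusion threshold in seconds (default 0.150).
#' @return The filtered data frame, with the number of excluded trials in
#'   attribute `"excluded"`.
#' @export
filter_min_rt <- function(trials, threshold = 0.150) {
  stopifnot(is.data.frame(trials), "rt" %in% names(trials))
  rt <- trials$rt
  bad <- which(!is.finite(rt) | rt <= 0)
  if (length(bad))
    stop("non-positive or missing rt at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  keep <- rt >= threshold
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Center and scale covariate columns
#'
#' Standardizes each non-intercept column to sample mean 0 and sample SD 1
#' (denominator n-1). Fitted coefficients are therefore on the
#' standardized scale; the returned centers and scales support
#' back-transformation via [destandardize_beta()].
#'
#' @param X Numeric matrix (or data frame) of covariates; a column named
#'   `"(Intercept)"` is passed through untouched.
#' @return A list with elements `X` (standardized matrix), `center` and
#'   `scale` (named vectors; 0/1 for the intercept column).
#' @export
standardize_covariates <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("covariates must be numeric")
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  names(center) <- names(scale) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    if (identical(colnames(X)[j], "(Intercept)")) next
    s <- stats::sd(X[, j])
    if (!is.finite(s) || s == 0)
      stop("covariate column ", colnames(X)[j] %||% j,
           " is constant and cannot be scaled")
    center[j] <- mean(X[, j]); scale[j] <- s
    X[, j] <- (X[, j] - center[j]) / scale[j]
  }
  list(X = X, center = center, scale = scale)
}

#' Back-transform standardized regression weights
#'
#' Converts weights estimated on standardized covariates to the raw
#' covariate scale, so that `X_raw %*% beta_raw == X_std %*% beta_std`.
#'
#' @param beta Weight vector on the standardized scale (leading intercept).
#' @param center,scale Centers and scales from [standardize_covariates()].
#' @return The weight vector on the raw covariate scale.
#' @export
destandardize_beta <- function(beta, center, scale) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) == length(center), length(center) == length(scale))
  out <- beta / scale
  out[1] <- beta[1] - sum(beta[-1] * center[-1] / scale[-1])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trial table
#'
#' Reads a delimited text table with columns `person_id`, `session`,
#' `trial_type`, `rt` (header required). Latencies may be recorded in
#' milliseconds; set `rt_unit = "ms"` to convert to seconds on ingestion.
#'
#' @param path Path to a comma-separated file.
#' @param rt_unit Unit of the `rt` column: `"s"` (default) or `"ms"`.
#' @return A data frame of trials with `rt` in seconds.
#' @export
read_trials <- function(path, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "session", "trial_type", "rt")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  tr$person_id <- as.character(tr$person_id)
  tr$rt <- as.numeric(tr$rt)
  if (rt_unit == "ms") tr$rt <- tr$rt / 1000
  tr
}

#' Read a person-covariate table
#'
#' Reads a delimited text table with a `person_id` column plus one numeric
#' column per covariate; the intercept is added internally at preparation.
#'
#' @param path Path to a comma-separated file.
#' @return A data frame with `person_id` and covariate columns.
#' @export
read_covariates <- function(path) {
  cv <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"person_id" %in% names(cv))
    stop("covariate table must contain a person_id column")
  cv$person_id <- as.character(cv$person_id)
  cv
}

#' Prepare trial and covariate tables for fitting
#'
#' Validates levels, applies the premature-response exclusion (< 150 ms by
#' default), enforces the response window's upper edge, attaches condition
#' indicators, and builds the standardized person-covariate design matrix
#' with a leading intercept.
#'
#' @param trials Data frame with columns `person_id`, `session`,
#'   `trial_type`, `rt` (seconds); see [read_trials()].
#' @param covariates Optional data frame with `person_id` plus numeric
#'   covariate columns (binary covariates as 0/1); `NULL` gives an
#'   intercept-only design.
#' @param rt_min Lower exclusion threshold in seconds (default 0.150);
#'   latencies strictly below are dropped. `NULL` skips the exclusion
#'   entirely (for exactness studies on unwindowed simulated data, where
#'   the Gaussian latency model is fit to raw draws).
#' @param rt_max Upper edge of the response window in seconds (default
#'   0.800); latencies above it are impossible under the task and raise an
#'   error by default.
#' @param over_window `"error"` (default) or `"warn"`; with `"warn"` the
#'   offending trials are dropped with a warning instead.
#' @return An object of class `"later_data"`: trials with cell indices,
#'   the standardized covariate matrix `X` (persons x (K+1)), the raw
#'   matrix and its centers/scales, the person index, and an exclusion log.
#' @export
prepare_later_data <- function(trials, covariates = NULL,
                               rt_min = 0.150, rt_max = 0.800,
                               over_window = c("error", "warn")) {
  over_window <- match.arg(over_window)
  stopifnot(is.data.frame(trials))
  need <- c("person_id", "session", "trial_type", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  trials <- trials[need]
  trials$person_id <- as.character(trials$person_id)

  n_over <- 0L
  if (!is.null(rt_max) && any(trials$rt > rt_max)) {
    n_over <- sum(trials$rt > rt_max)
    msg <- paste0(n_over, " trial(s) exceed the ", round(rt_max * 1000),
                  " ms response window")
    if (over_window == "error")
      stop(msg, "; latencies above the window are impossible under the task")
    warning(msg, "; dropping them")
    trials <- trials[trials$rt <= rt_max, , drop = FALSE]
  }
  if (!is.null(rt_min)) {
    trials <- filter_min_rt(trials, threshold = rt_min)
    n_below <- attr(trials, "excluded")
  } else {
    n_below <- 0L
  }

  g <- encode_condition(trials$session, trials$trial_type)
  trials$cell <- attr(g, "cell")
  rownames(trials) <- NULL

  persons <- sort(unique(trials$person_id))
  if (is.null(covariates)) {
    X_raw <- matrix(1, nrow = length(persons), ncol = 1L,
                    dimnames = list(persons, "(Intercept)"))
  } else {
    stopifnot(is.data.frame(covariates), "person_id" %in% names(covariates))
    covariates$person_id <- as.character(covariates$person_id)
    missing_p <- setdiff(persons, covariates$person_id)
    if (length(missing_p))
      stop("covariates missing for person(s): ",
           paste(missing_p, collapse = ", "))
    cv <- covariates[match(persons, covariates$person_id),
                     setdiff(names(covariates), "person_id"), drop = FALSE]
    if (anyNA(cv)) stop("covariate table contains missing entries")
    X_raw <- cbind("(Intercept)" = 1, as.matrix(cv))
    rownames(X_raw) <- persons
  }
  std <- standardize_covariates(X_raw)

  structure(list(trials = trials, G = g[, , drop = FALSE],
                 X = std$X, X_raw = X_raw,
                 center = std$center, scale = std$scale,
                 persons = persons,
                 exclusions = list(below_min = n_below, above_max = n_over),
                 rt_window = c(rt_min %||% -Inf, rt_max %||% Inf)),
            class = "later_data")
}

#' @export
print.later_data <- function(x, ...) {
  cat("Prepared LATER trial data\n")
  cat("  persons:", length(x$persons), "  trials:", nrow(x$trials), "\n")
  cat("  covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  tab <- table(factor(x$trials$cell, levels = 1:4,
                      labels = paste(.later_cells$session,
                                     .later_cells$trial_type, sep = "/")))
  cat("  trials per design cell:\n")
  print(tab)
  cat("  excluded: ", x$exclusions$below_min, " below ",
      round(x$rt_window[1] * 1000), " ms, ", x$exclusions$above_max,
      " above the window\n", sep = "")
  invisible(x)
}
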