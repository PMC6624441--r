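#' Prior specification for the hierarchical LATER model
#'
#' Weakly informative defaults: independent Gaussian priors on every
#' regression weight (group-level `beta` and condition deviation `delta`)
#' and half-Gaussian priors on the person-level residual scales. All
#' locations/scales are on the modeled parameter scale (accretion in
#' evidence units per second of threshold, caution in threshold units).
#'
#' @param beta_location,beta_scale Gaussian prior location and scale for
#'   every component of the group regression weights `beta_v`, `beta_theta`.
#' @param delta_location,delta_scale Gaussian prior location and scale for
#'   every condition-deviation coefficient `delta_v`, `delta_theta`.
#' @param sigma_scale Scale of the half-Gaussian prior on the person-level
#'   residual standard deviations `sigma_v`, `sigma_theta`.
#' @param flat If `TRUE`, all prior terms contribute zero to the log
#'   posterior (improper flat priors; scales are still required positive).
#' @return An object of class `"later_prior"`.
#' @export
later_prior <- function(beta_location = 0, beta_scale = 10,
                        delta_location = 0, delta_scale = 10,
                        sigma_scale = 5, flat = FALSE) {
  stopifnot(beta_scale > 0, delta_scale > 0, sigma_scale > 0,
            is.logical(flat), length(flat) == 1L)
  structure(list(beta_location = beta_location, beta_scale = beta_scale,
                 delta_location = delta_location, delta_scale = delta_scale,
                 sigma_scale = sigma_scale, flat = flat),
            class = "later_prior")
}

#' Model configuration for the hierarchical LATER model
#'
#' Fixes the likelihood form, the prior block, the policy for non-positive
#' composed parameters, and whether the two person-level random effects are
#' allowed to correlate.
#'
#' The two likelihood forms correspond to the two readings of the
#' rise-to-threshold latency distribution:
#' \describe{
#'   \item{`"direct"`}{the latency itself is Gaussian,
#'     `y ~ N(v/theta, 1/theta^2)`; generatively `y = z/theta` with the
#'     trial-wise rate `z ~ N(v, 1)`. This is the default, and the only
#'     form consistent with the sub-second worked example `v = 1`,
#'     `theta = 4` giving a 250 ms mean latency.}
#'   \item{`"reciprocal"`}{the classic recinormal reading: the reciprocal
#'     latency is Gaussian, `1/y ~ N(v/theta, 1/theta^2)`; generatively
#'     `y = theta/z` (time for a signal rising at rate `z` to cover
#'     threshold `theta`).}
#' }
#'
#' @param form Likelihood form, `"direct"` (default) or `"reciprocal"`.
#' @param prior A [later_prior()] object.
#' @param positivity How a non-positive composed caution (or composed mean
#'   latency) is handled when evaluating the posterior: `"reject"` returns
#'   `-Inf` (soft rejection inside the sampler, the default), `"error"`
#'   throws.
#' @param correlated_effects If `TRUE`, person-level accretion and caution
#'   residuals are modeled as bivariate normal with a correlation sampled
#'   under a uniform prior; default `FALSE` (independent residuals).
#' @return An object of class `"later_model"`.
#' @export
later_model <- function(form = c("direct", "reciprocal"),
                        prior = later_prior(),
                        positivity = c("reject", "error"),
                        correlated_effects = FALSE) {
  form <- match.arg(form)
  positivity <- match.arg(positivity)
  stopifnot(inherits(prior, "later_prior"),
            is.logical(correlated_effects), length(correlated_effects) == 1L)
  structure(list(form = form, prior = prior, positivity = positivity,
                 correlated_effects = correlated_effects),
            class = "later_model")
}

#' Group-level parameter block
#'
#' Container for the estimands of the hierarchical LATER model: group
#' regression weights on accretion and caution, person-level residual
#' scales, and the three condition-deviation coefficients per parameter.
#'
#' @param beta_v,beta_theta Numeric vectors of length K+1 (leading
#'   intercept) of regression weights for accretion and caution.
#' @param sigma_v,sigma_theta Positive person-level residual SDs.
#' @param delta_v,delta_theta Numeric vectors of length 3: condition
#'   deviations for (neutral-abstinent, reward-smoke-as-usual,
#'   reward-abstinent) relative to the neutral/smoke-as-usual baseline.
#' @param rho Optional correlation between the two person-level residuals
#'   (used only when the model has `correlated_effects = TRUE`).
#' @return An object of class `"group_parameters"`.
#' @export
group_parameters <- function(beta_v, beta_theta, sigma_v, sigma_theta,
                             delta_v, delta_theta, rho = 0) {
  beta_v <- as.numeric(beta_v); beta_theta <- as.numeric(beta_theta)
  if (length(beta_v) != length(beta_theta))
    stop("beta_v and beta_theta must have the same length")
  if (length(delta_v) != 3L || length(delta_theta) != 3L)
    stop("delta_v and delta_theta must each have length 3")
  stopifnot(sigma_v > 0, sigma_theta > 0, abs(rho) < 1,
            all(is.finite(beta_v)), all(is.finite(beta_theta)))
  structure(list(beta_v = beta_v, beta_theta = beta_theta,
                 sigma_v = sigma_v, sigma_theta = sigma_theta,
                 delta_v = as.numeric(delta_v),
                 delta_theta = as.numeric(delta_theta),
                 rho = rho),
            class = "group_parameters")
}

## Condition cells, fixed for the 2 (session) x 2 (trial type) design.
## Baseline = (smoke_as_usual, neutral) = all-zero indicator vector.
.later_sessions <- c("smoke_as_usual", "abstinent")
.later_trial_types <- c("neutral", "reward")
.later_cells <- data.frame(
  cell = 1:4,
  session = c("smoke_as_usual", "abstinent", "smoke_as_usual", "abstinent"),
  trial_type = c("neutral", "neutral", "reward", "reward"),
  stringsAsFactors = FALSE
)
## rows: cell 1..4; cols: g1..g3
.later_g <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
.later_condition_labels <- c("neutral_abstinent", "reward_smoke_as_usual",
                             "reward_abstinent")

.check_g <- function(g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  if (ncol(g) != 3L) stop("condition indicator must have 3 components")
  if (!all(g %in% c(0, 1))) stop("condition indicators must be 0/1")
  if (any(rowSums(g) > 1)) stop("at most one condition indicator may be 1")
  g
}

#' Compose the trial-level accretion rate
#'
#' Adds the selected condition deviation to a person's accretion rate:
#' `v_n = v_p + sum(g * delta_v)`. The all-zero indicator (the
#' neutral/smoke-as-usual baseline) leaves the person effect unchanged.
#'
#' @param v Person-specific accretion rate(s).
#' @param g Condition indicator vector of length 3, or an n x 3 matrix of
#'   indicators (at most one 1 per row).
#' @param delta_v Length-3 vector of accretion condition deviations.
#' @return The composed trial-level accretion rate(s).
#' @export
compose_accretion <- function(v, g, delta_v) {
  g <- .check_g(g)
  stopifnot(length(delta_v) == 3L)
  drop(v + g %*% as.numeric(delta_v))
}

#' Compose the trial-level caution threshold
#'
#' `theta_n = theta_p + sum(g * delta_theta)`. Because the deviations are
#' additive, the composed threshold can go non-positive; a warning flags
#' that case and the likelihood assigns such parameter regions `-Inf`.
#'
#' @param theta Person-specific caution threshold(s).
#' @param g Condition indicator vector (length 3) or n x 3 matrix.
#' @param delta_theta Length-3 vector of caution condition deviations.
#' @return The composed trial-level caution threshold(s).
#' @export
compose_caution <- function(theta, g, delta_theta) {
  g <- .check_g(g)
  stopifnot(length(delta_theta) == 3L)
  out <- drop(theta + g %*% as.numeric(delta_theta))
  if (any(out <= 0))
    warning("composed caution is non-positive; the likelihood will reject ",
            "this parameter region")
  out
}

#' Model-implied expected latency
#'
#' Mean latency implied by an accretion rate and caution threshold. Under
#' the direct form the latency distribution is `N(v/theta, 1/theta^2)`, so
#' the expected latency is `v/theta` seconds; under the reciprocal form the
#' latency at the mean rise rate is `theta/v`. A rate of 1 against a
#' threshold of 4 gives 0.25 s either way.
#'
#' @param v Accretion rate(s).
#' @param theta Caution threshold(s); must be positive.
#' @param form `"direct"` or `"reciprocal"`.
#' @return Expected latency in seconds.
#' @export
expected_latency <- function(v, theta, form = c("direct", "reciprocal")) {
  form <- match.arg(form)
  if (any(theta <= 0)) stop("caution threshold must be positive")
  if (form == "direct") v / theta
  else {
    if (any(v == 0)) stop("accretion rate must be non-zero for the reciprocal form")
    theta / v
  }
}

#' Trial-level log-density of an observed latency
#'
#' Under the direct form the latency is Gaussian,
#' `y ~ N(v/theta, 1/theta^2)`. Under the reciprocal (recinormal) form the
#' reciprocal latency is Gaussian, so the density of `y` picks up the
#' change-of-variables Jacobian `1/y^2`.
#'
#' @param y Observed latency(ies) in seconds; strictly positive.
#' @param v Composed trial-level accretion rate.
#' @param theta Composed trial-level caution threshold.
#' @param form `"direct"` or `"reciprocal"`.
#' @return Log-density value(s); `-Inf` when `theta <= 0` (excluded
#'   parameter region).
#' @export
trial_log_density <- function(y, v, theta, form = c("direct", "reciprocal")) {
  form <- match.arg(form)
  if (any(y <= 0)) stop("latencies must be strictly positive")
  n <- max(length(y), length(v), length(theta))
  y <- rep_len(y, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  out <- rep(-Inf, n)
  ok <- theta > 0
  if (any(ok)) {
    if (form == "direct") {
      out[ok] <- stats::dnorm(y[ok], v[ok] / theta[ok], 1 / theta[ok], log = TRUE)
    } else {
      out[ok] <- stats::dnorm(1 / y[ok], v[ok] / theta[ok], 1 / theta[ok],
                              log = TRUE) - 2 * log(y[ok])
    }
  }
  out
}

#' Group-level linear predictor
#'
#' Inner product of a person's covariate vector (leading intercept) with a
#' group regression weight vector: the group-level mean of that person's
#' accretion or caution parameter.
#'
#' @param x Covariate vector of length K+1 with `x[1] = 1`, or a matrix of
#'   such rows.
#' @param beta Weight vector of matching length.
#' @return The linear predictor value(s).
#' @export
person_level_mean <- function(x, beta) {
  beta <- as.numeric(beta)
  if (is.matrix(x)) {
    if (ncol(x) != length(beta))
      stop("covariate and weight lengths differ (", ncol(x), " vs ",
           length(beta), ")")
    return(drop(x %*% beta))
  }
  if (length(x) != length(beta))
    stop("covariate and weight lengths differ (", length(x), " vs ",
         length(beta), ")")
  sum(x * beta)
}

## log-density of the pair of person effects under the group model
.person_effect_logdens <- function(v, theta, mu_v, mu_t, sv, st, rho = 0) {
  if (rho == 0)
    return(stats::dnorm(v, mu_v, sv, log = TRUE) +
             stats::dnorm(theta, mu_t, st, log = TRUE))
  zv <- (v - mu_v) / sv
  zt <- (theta - mu_t) / st
  -log(2 * pi) - log(sv) - log(st) - 0.5 * log1p(-rho^2) -
    (zv^2 - 2 * rho * zv * zt + zt^2) / (2 * (1 - rho^2))
}

## prior log-density of a group-parameter block under a later_prior
.prior_logdens <- function(group, prior) {
  if (prior$flat) return(0)
  sum(stats::dnorm(c(group$beta_v, group$beta_theta),
                   prior$beta_location, prior$beta_scale, log = TRUE)) +
    sum(stats::dnorm(c(group$delta_v, group$delta_theta),
                     prior$delta_location, prior$delta_scale, log = TRUE)) +
    ## half-Gaussian on the scales: 2 * N(s; 0, scale) on s > 0
    sum(log(2) + stats::dnorm(c(group$sigma_v, group$sigma_theta),
                              0, prior$sigma_scale, log = TRUE))
}

#' Joint log-posterior of the hierarchical LATER model
#'
#' Reference evaluation of the (unnormalized) joint log posterior: the sum
#' of all trial log-densities at the composed trial-level parameters, the
#' person-effect log-densities under the group regression, and the prior
#' log-densities. This is the target distribution of [later_fit()]'s
#' sampler; it is written for clarity (it loops over trials via
#' [trial_log_density()]) rather than speed.
#'
#' @param data A `later_data` object (see [prepare_later_data()]).
#' @param params A list with elements `group` (a [group_parameters()]
#'   object) and `v`, `theta`: named numeric vectors of person effects,
#'   names matching `data$persons`.
#' @param model A [later_model()] configuration.
#' @return A single number; `-Inf` when any composed caution (or, under
#'   the direct form, composed mean latency) is non-positive and the
#'   positivity policy is `"reject"`.
#' @export
joint_log_posterior <- function(data, params, model = later_model()) {
  stopifnot(inherits(data, "later_data"), inherits(model, "later_model"))
  group <- params$group
  stopifnot(inherits(group, "group_parameters"))
  v <- params$v[data$persons]
  theta <- params$theta[data$persons]
  if (anyNA(v) || anyNA(theta))
    stop("person effects must be named vectors covering every person")
  if (length(group$beta_v) != ncol(data$X))
    stop("beta length does not match the covariate matrix")

  ## composed trial-level parameters
  idx <- match(data$trials$person_id, data$persons)
  dv <- c(0, group$delta_v)[data$trials$cell]
  dt <- c(0, group$delta_theta)[data$trials$cell]
  v_n <- v[idx] + dv
  t_n <- theta[idx] + dt

  bad <- any(t_n <= 0) || (model$form == "direct" && any(v_n <= 0))
  if (bad) {
    if (model$positivity == "error")
      stop("non-positive composed caution or mean latency")
    return(-Inf)
  }
  data_term <- if (nrow(data$trials))
    sum(trial_log_density(data$trials$rt, v_n, t_n, model$form)) else 0

  mu_v <- person_level_mean(data$X, group$beta_v)
  mu_t <- person_level_mean(data$X, group$beta_theta)
  rho <- if (isTRUE(model$correlated_effects)) group$rho else 0
  effect_term <- sum(.person_effect_logdens(v, theta, mu_v, mu_t,
                                            group$sigma_v, group$sigma_theta,
                                            rho))
  data_term + effect_term + .prior_logdens(group, model$prior)
}
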