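# Trial-level likelihood, parameter composition and the joint posterior.

test_that("condition deviations compose additively onto person effects", {
  dv <- c(-0.3638, 0.1231, -0.2494)
  dt <- c(-0.0655, 0.0835, -0.0068)

  # baseline leaves the person effect unchanged, whatever the deltas
  expect_identical(compose_accretion(1.2, c(0, 0, 0), dv), 1.2)
  expect_identical(compose_caution(4, c(0, 0, 0), dt), 4)

  # the indicator selects exactly one coefficient
  expect_equal(compose_accretion(1.2, c(1, 0, 0), dv), 1.2 - 0.3638)
  expect_equal(compose_accretion(1.2, c(1, 0, 0), dv), 0.8362)
  expect_equal(compose_accretion(0, c(0, 1, 0), dv), dv[2])
  expect_equal(compose_caution(4, c(0, 1, 0), dt), 4.0835)

  # matrix of indicators composes row-wise
  g <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(compose_accretion(1, g, dv), 1 + c(0, dv[1], dv[3]))

  # a small threshold can be pushed non-positive; that is flagged
  expect_warning(out <- compose_caution(0.01, c(1, 0, 0), dt),
                 "non-positive")
  expect_equal(out, 0.01 - 0.0655)

  # malformed indicators are rejected
  expect_error(compose_accretion(1, c(1, 1, 0), dv), "at most one")
  expect_error(compose_accretion(1, c(0, 2, 0), dv), "0/1")
})

test_that("expected latency is the caution-to-accretion ratio", {
  # a rate of 1 against a threshold of 4 takes a quarter second,
  # and a faster rate with proportionally higher caution takes the same
  expect_equal(expected_latency(1, 4), 0.250)
  expect_equal(expected_latency(1.5, 6), 0.250)
  expect_equal(expected_latency(1, 4), expected_latency(1.5, 6))
  expect_equal(expected_latency(1, 1, "direct"), 1.0)
  expect_equal(expected_latency(1, 1, "reciprocal"), 1.0)

  # scale invariance: (v, theta) -> (cv, c*theta) leaves the mean alone
  for (c_ in c(0.5, 2, 7.3))
    expect_equal(expected_latency(c_ * 1.2, c_ * 4), expected_latency(1.2, 4))

  expect_error(expected_latency(1, 0), "positive")
  expect_error(expected_latency(1, -2), "positive")
  expect_error(expected_latency(0, 4, "reciprocal"), "non-zero")
})

test_that("direct-form density is Gaussian with the stated moments", {
  # at the mean, the log-density is log(theta) - log(sqrt(2*pi)):
  # oracle computed from the normal pdf directly
  expect_equal(trial_log_density(0.25, 1, 4, "direct"),
               log(4) - 0.5 * log(2 * pi))
  expect_equal(trial_log_density(0.25, 1, 4, "direct"), 0.4674, tolerance = 1e-4)

  # Gaussian symmetry about v/theta
  for (d in c(0.01, 0.1, 0.2))
    expect_equal(trial_log_density(0.25 + d, 1, 4, "direct"),
                 trial_log_density(0.25 - d, 1, 4, "direct"))

  # quadrature: the density integrates to 1, and its variance is
  # 1/theta^2, strictly decreasing in theta
  vars <- sapply(c(2, 4, 6), function(th) {
    m <- 1 / th; s <- 1 / th
    y <- seq(m - 10 * s, m + 10 * s, length.out = 20001)
    f <- exp(trial_log_density(pmax(y, 1e-12), 1, th, "direct"))
    f[y <= 0] <- stats::dnorm(y[y <= 0], m, s)  # analytic continuation
    mass <- sum((f[-1] + f[-length(f)]) / 2 * diff(y))
    expect_equal(mass, 1, tolerance = 1e-6)
    sum((f[-1] * (y[-1] - m)^2 + f[-length(f)] * (y[-length(y)] - m)^2) /
          2 * diff(y))
  })
  expect_equal(vars, 1 / c(2, 4, 6)^2, tolerance = 1e-4)
  expect_true(all(diff(vars) < 0))

  expect_identical(trial_log_density(0.3, 1, -1, "direct"), -Inf)
  expect_identical(trial_log_density(0.3, 1, 0, "direct"), -Inf)
  expect_error(trial_log_density(-0.1, 1, 4), "positive")
})

test_that("reciprocal form equals the direct form at 1/y plus the Jacobian", {
  for (y in c(0.2, 0.5, 1.3)) {
    expect_equal(trial_log_density(y, 1, 4, "reciprocal"),
                 trial_log_density(1 / y, 1, 4, "direct") - 2 * log(y))
  }
  # spot value against the change-of-variables oracle written out long-hand
  y <- 0.5
  oracle <- stats::dnorm(1 / y, 1 / 4, 1 / 4, log = TRUE) - 2 * log(y)
  expect_equal(trial_log_density(y, 1, 4, "reciprocal"), oracle)
})

test_that("group-level linear predictor is the covariate inner product", {
  expect_equal(person_level_mean(c(1, 0, 0), c(2.5, 1, -1)), 2.5)
  expect_equal(person_level_mean(c(1, 2), c(1, 0.5)), 2.0)
  expect_equal(person_level_mean(c(1, 3, -2), c(0, 0, 0)), 0)
  X <- cbind(1, c(0.5, -0.5))
  expect_equal(person_level_mean(X, c(1, 2)), c(2, 0))
  expect_error(person_level_mean(c(1, 2, 3), c(1, 2)), "lengths differ")
})

make_jlp_fixture <- function(trials) {
  data <- prepare_later_data(trials, rt_min = NULL, rt_max = NULL)
  params <- list(
    group = group_parameters(beta_v = 1.1, beta_theta = 4,
                             sigma_v = 0.2, sigma_theta = 0.8,
                             delta_v = c(-0.35, 0.12, -0.25),
                             delta_theta = c(-0.07, 0.08, 0)),
    v = stats::setNames(c(1.0, 1.3), data$persons),
    theta = stats::setNames(c(3.5, 4.5), data$persons))
  list(data = data, params = params)
}

test_that("joint log-posterior decomposes into data, effect and prior terms", {
  fx <- make_jlp_fixture(toy_trials(n_per_cell = 2, rt = c(0.25, 0.3, 0.35)))
  flat <- later_model(prior = later_prior(flat = TRUE))

  # empty trial set: only person-effect (and prior) terms remain
  empty <- fx$data; empty$trials <- empty$trials[0, ]
  g <- fx$params$group
  re_oracle <- sum(stats::dnorm(fx$params$v, g$beta_v, g$sigma_v, log = TRUE)) +
    sum(stats::dnorm(fx$params$theta, g$beta_theta, g$sigma_theta, log = TRUE))
  expect_equal(joint_log_posterior(empty, fx$params, flat), re_oracle)

  # term-by-term oracle on one person, one trial
  one <- toy_trials(n_per_cell = 1, persons = "A", rt = 0.28)
  one <- one[one$session == "abstinent" & one$trial_type == "neutral", ]
  d1 <- prepare_later_data(one, rt_min = NULL, rt_max = NULL)
  p1 <- list(group = g, v = c(A = 1.0), theta = c(A = 3.5))
  oracle <- trial_log_density(0.28, 1.0 + g$delta_v[1], 3.5 + g$delta_theta[1],
                              "direct") +
    stats::dnorm(1.0, g$beta_v, g$sigma_v, log = TRUE) +
    stats::dnorm(3.5, g$beta_theta, g$sigma_theta, log = TRUE)
  expect_equal(joint_log_posterior(d1, p1, flat), oracle)

  # duplicating every trial doubles the data term exactly
  base <- joint_log_posterior(fx$data, fx$params, flat)
  doubled_trials <- rbind(fx$data$trials[1:4], fx$data$trials[1:4])
  dd <- prepare_later_data(doubled_trials, rt_min = NULL, rt_max = NULL)
  re <- joint_log_posterior(empty, fx$params, flat)
  expect_equal(joint_log_posterior(dd, fx$params, flat) - re,
               2 * (base - re))

  # priors add the configured Gaussian/half-Gaussian terms
  informative <- later_model()
  pr <- informative$prior
  prior_oracle <- sum(stats::dnorm(c(g$beta_v, g$beta_theta), 0, 10, TRUE)) +
    sum(stats::dnorm(c(g$delta_v, g$delta_theta), 0, 10, TRUE)) +
    sum(log(2) + stats::dnorm(c(g$sigma_v, g$sigma_theta), 0, 5, TRUE))
  expect_equal(joint_log_posterior(fx$data, fx$params, informative),
               base + prior_oracle)
})

test_that("non-positive composed caution is soft-rejected, not an error", {
  fx <- make_jlp_fixture(toy_trials(n_per_cell = 2, rt = 0.3))
  bad <- fx$params
  bad$theta <- stats::setNames(c(0.05, 4), names(bad$theta))  # 0.05 - 0.07 < 0
  expect_identical(joint_log_posterior(fx$data, bad), -Inf)
  expect_error(
    joint_log_posterior(fx$data, bad, later_model(positivity = "error")),
    "non-positive")
})

test_that("reciprocal data term equals direct on reciprocal data plus Jacobian", {
  set.seed(17)
  trials <- toy_trials(n_per_cell = 5,
                       rt = round(stats::runif(40, 0.18, 0.6), 4))
  fx <- make_jlp_fixture(trials)
  flat <- later_model(prior = later_prior(flat = TRUE))
  recip <- later_model(form = "reciprocal", prior = later_prior(flat = TRUE))

  inv <- trials; inv$rt <- 1 / trials$rt
  d_inv <- prepare_later_data(inv, rt_min = NULL, rt_max = NULL)
  jac <- -2 * sum(log(fx$data$trials$rt))
  expect_equal(joint_log_posterior(fx$data, fx$params, recip),
               joint_log_posterior(d_inv, fx$params, flat) + jac,
               tolerance = 1e-10)
})

test_that("joint log-posterior is finite on a grid around plausible values", {
  fx <- make_jlp_fixture(toy_trials(n_per_cell = 3, rt = c(0.2, 0.3, 0.5)))
  for (b_v in c(0.9, 1.1, 1.4)) for (s_v in c(0.1, 0.3)) {
    p <- fx$params
    p$group$beta_v <- b_v; p$group$sigma_v <- s_v
    val <- joint_log_posterior(fx$data, p)
    expect_true(is.finite(val))
  }
})
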