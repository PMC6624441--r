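# Sampler correctness, convergence diagnostics, posterior summaries.

test_that("split-chain rhat behaves as the Gelman-Rubin diagnostic", {
  set.seed(101)
  # two long chains from the same distribution converge to 1
  same <- cbind(stats::rnorm(10000), stats::rnorm(10000))
  expect_true(rhat(same) > 0.99 && rhat(same) < 1.01)

  # well-separated chains are flagged far above the 1.1 criterion
  apart <- cbind(stats::rnorm(1000, 0, 1), stats::rnorm(1000, 10, 1))
  expect_true(rhat(apart) > 1.1)

  # duplicated chains: equals the split formula evaluated directly
  x <- stats::rnorm(2000)
  dup <- cbind(x, x)
  half <- 1000L
  sp <- cbind(dup[1:half, ], dup[half + (1:half), ])
  W <- mean(apply(sp, 2, stats::var))
  B_over_n <- stats::var(colMeans(sp))
  oracle <- sqrt(((half - 1) / half * W + B_over_n) / W)
  expect_equal(rhat(dup), oracle)
  expect_true(abs(rhat(dup) - 1) < 0.01)

  # degenerate chains yield a flagged sentinel
  expect_warning(r0 <- rhat(cbind(rep(1, 100), rep(1, 100))), "undefined")
  expect_true(is.na(r0))

  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
  expect_error(rhat(matrix(1:6, ncol = 2)), "4 retained")
})

test_that("posterior summaries report pooled moments and central intervals", {
  f <- fake_fit(list(c(1, 2), c(3, 4)))
  s <- summarize_parameter(f, "x")
  expect_equal(s$mean, 2.5)

  # constant draws collapse to a point with an undefined rhat
  fc <- fake_fit(list(rep(7, 10), rep(7, 10)))
  sc <- summarize_parameter(fc, "x")
  expect_equal(sc$mean, 7)
  expect_equal(sc$sd, 0)
  expect_equal(c(sc$q2.5, sc$q97.5), c(7, 7))
  expect_true(is.na(sc$rhat))

  # large-sample Gaussian draws: the 95% CrI approaches +/- 1.96
  set.seed(5)
  fg <- fake_fit(list(stats::rnorm(50000), stats::rnorm(50000)))
  sg <- summarize_parameter(fg, "x")
  expect_equal(sg$q2.5, -1.96, tolerance = 0.03)
  expect_equal(sg$q97.5, 1.96, tolerance = 0.03)
  expect_true(sg$q2.5 <= sg$median && sg$median <= sg$q97.5)

  expect_error(summarize_parameter(f, "nope"), "candidates")
})

test_that("reduced single-person model matches the conjugate normal posterior", {
  # with caution pinned at theta and a Gaussian prior on accretion, the
  # posterior of v is available in closed form: the likelihood in v has
  # precision n and maximum-likelihood value theta * mean(y)
  theta0 <- 4; mu0 <- 1; tau0 <- 0.5; n <- 60
  set.seed(31)
  y <- stats::rnorm(n, 1.05 / theta0, 1 / theta0)
  tr <- data.frame(person_id = "solo", session = "smoke_as_usual",
                   trial_type = "neutral", rt = y)
  d <- prepare_later_data(tr, rt_min = NULL, rt_max = NULL)
  fit <- later_fit(d, sampler = later_sampler(
    chains = 4, iter = 1500, warmup = 500, seed = 2,
    fix = list(beta_v = mu0, sigma_v = tau0, beta_theta = theta0,
               sigma_theta = 0, delta_v = c(0, 0, 0),
               delta_theta = c(0, 0, 0))))
  draws <- as.vector(fit$draws[, , "v[solo]"])

  prec <- n + 1 / tau0^2
  post_mean <- (theta0 * sum(y) + mu0 / tau0^2) / prec
  post_sd <- 1 / sqrt(prec)
  n_draws <- length(draws)
  expect_lt(abs(mean(draws) - post_mean), 3 * post_sd / sqrt(n_draws))
  expect_lt(abs(stats::sd(draws) - post_sd), 3 * post_sd / sqrt(2 * n_draws))
})

test_that("fitting is deterministic under a fixed seed", {
  st <- small_study()
  f1 <- later_fit(st$data, sampler = quick_sampler(chains = 2, iter = 200,
                                                   warmup = 100, seed = 77))
  f2 <- later_fit(st$data, sampler = quick_sampler(chains = 2, iter = 200,
                                                   warmup = 100, seed = 77))
  expect_identical(f1$draws, f2$draws)
  s1 <- summary(f1)$table; s2 <- summary(f2)$table
  expect_identical(s1, s2)

  f3 <- later_fit(st$data, sampler = quick_sampler(chains = 2, iter = 200,
                                                   warmup = 100, seed = 78))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the fit exposes every model parameter with ordered intervals", {
  fit <- small_fit()
  labels <- dimnames(fit$draws)[[3]]
  persons <- small_study()$data$persons
  expect_true(all(c("sigma_v", "sigma_theta",
                    paste0("v[", persons, "]"),
                    paste0("theta[", persons, "]")) %in% labels))
  expect_length(grep("^delta_v\\[", labels), 3L)
  expect_length(grep("^delta_theta\\[", labels), 3L)
  expect_length(grep("^beta_v\\[", labels), ncol(small_study()$data$X))

  tab <- summary(fit)$table
  expect_true(all(tab$q2.5 <= tab$median & tab$median <= tab$q97.5))
  expect_true(all(tab$sd > 0))

  # methods built on the draws
  expect_length(fitted(fit), nrow(fit$data$trials))
  expect_equal(residuals(fit), fit$data$trials$rt - fitted(fit))
  pred <- predict(fit)
  expect_equal(nrow(pred), length(persons) * 4L)
  expect_true(all(pred$q2.5 <= pred$latency & pred$latency <= pred$q97.5))
  expect_true(all(grepl("^(beta|sigma|delta|rho)", names(coef(fit)))))
})

test_that("degenerate inputs are rejected with informative errors", {
  st <- small_study()
  empty <- st$data; empty$trials <- empty$trials[0, ]
  expect_error(later_fit(empty), "empty")

  solo <- toy_trials(n_per_cell = 5, persons = "A", rt = 0.3)
  d <- prepare_later_data(solo)
  expect_error(later_fit(d), "at least 2 persons")

  expect_error(later_sampler(chains = 1), "2 chains")
  expect_error(later_sampler(iter = 100, warmup = 100), "smaller")
  expect_error(later_sampler(fix = list(nu = 1)), "unknown fix")
})

test_that("person-effect spread tracks the generating residual scale", {
  # shrinkage: as sigma_v shrinks, estimated person accretion effects
  # collapse toward the covariate-predicted means
  spread <- sapply(c(0.02, 0.15, 0.5), function(s) {
    st <- simulate_study(seed = 12,
                         design = study_design(n_persons = 8,
                                               runs_per_session = 1),
                         truth = study_truth(sigma_v = s),
                         window = FALSE)
    fit <- later_fit(st$data, sampler = quick_sampler(seed = 3))
    v_hat <- coef(fit, "person")[paste0("v[", st$data$persons, "]")]
    b_hat <- coef(fit)[paste0("beta_v[", colnames(st$data$X), "]")]
    stats::sd(v_hat - person_level_mean(st$data$X, b_hat))
  })
  expect_true(all(diff(spread) > 0))
})

test_that("more trials per person tighten person-effect posteriors", {
  sd_at <- function(runs) {
    st <- simulate_study(seed = 8,
                         design = study_design(n_persons = 6,
                                               runs_per_session = runs),
                         window = FALSE)
    fit <- later_fit(st$data, sampler = quick_sampler(seed = 4))
    tab <- summary(fit, pars = grep("^(v|theta)\\[",
                                    dimnames(fit$draws)[[3]], value = TRUE))
    mean(tab$table$sd)
  }
  expect_lt(sd_at(7L), sd_at(1L))   # 525 vs 75 trials per session
})

test_that("the bivariate random-effect option samples a bounded correlation", {
  st <- simulate_study(seed = 19,
                       design = study_design(n_persons = 8,
                                             runs_per_session = 2),
                       truth = study_truth(rho = 0.6), window = FALSE)
  fit <- later_fit(st$data,
                   model = later_model(correlated_effects = TRUE),
                   sampler = quick_sampler(seed = 6))
  expect_true("rho" %in% dimnames(fit$draws)[[3]])
  r <- as.vector(fit$draws[, , "rho"])
  expect_true(all(r > -1 & r < 1))
  expect_true(stats::var(r) > 0)   # the correlation is actually sampled
})
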