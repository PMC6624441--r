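#' Go/No-Go study design
#'
#' Shape of the two-session incentivized Go/No-Go study the simulator
#' emulates: each person completes both sessions; a session has
#' `runs_per_session` runs of `trials_per_run` trials, of which a
#' `frequent_go_fraction` are the frequent-go trials modeled here, and a
#' `reward_run_fraction` of runs are monetarily rewarded (the remainder
#' neutral). Defaults give 10 x 100 x 0.75 = 750 frequent-go trials per
#' person per session, half under reward. Responses are only observable
#' inside the `rt_window` (150-800 ms).
#'
#' @param n_persons Number of participants (default 17).
#' @param runs_per_session Runs per session (default 10).
#' @param trials_per_run Trials per run (default 100).
#' @param frequent_go_fraction Fraction of frequent-go trials (default 0.75).
#' @param reward_run_fraction Fraction of rewarded runs (default 0.5).
#' @param rt_window Observable latency window in seconds.
#' @return An object of class `"later_design"`.
#' @export
study_design <- function(n_persons = 17L, runs_per_session = 10L,
                         trials_per_run = 100L,
                         frequent_go_fraction = 0.75,
                         reward_run_fraction = 0.5,
                         rt_window = c(0.150, 0.800)) {
  stopifnot(n_persons >= 1, runs_per_session >= 1, trials_per_run >= 1,
            frequent_go_fraction >= 0, frequent_go_fraction <= 1,
            reward_run_fraction >= 0, reward_run_fraction <= 1,
            length(rt_window) == 2L, rt_window[1] < rt_window[2])
  fgo <- round(runs_per_session * trials_per_run * frequent_go_fraction)
  n_reward <- round(fgo * reward_run_fraction)
  structure(list(n_persons = as.integer(n_persons),
                 runs_per_session = as.integer(runs_per_session),
                 trials_per_run = as.integer(trials_per_run),
                 frequent_go_fraction = frequent_go_fraction,
                 reward_run_fraction = reward_run_fraction,
                 rt_window = rt_window,
                 fgo_per_session = fgo,
                 reward_per_session = n_reward,
                 neutral_per_session = fgo - n_reward),
            class = "later_design")
}

#' True generating parameters for the study emulator
#'
#' Defaults place the group intercepts at the centers of typical estimate
#' ranges for this task (accretion around 1.15, caution around 4, giving
#' a ~290 ms mean latency at baseline), with residual scales spreading
#' person effects over roughly 0.7-1.6 (accretion) and 2-6 (caution), no
#' covariate effects, and condition deviations at the smoking-study
#' posterior means: abstinence speeds accretion and lowers caution in both
#' trial types; reward under smoking-as-usual raises both.
#'
#' @param K Number of covariates (slopes are set to 0).
#' @param beta_v0,beta_theta0 Group intercepts for accretion and caution.
#' @param sigma_v,sigma_theta Person-level residual SDs.
#' @param delta_v,delta_theta Condition deviations (neutral-abstinent,
#'   reward-smoke-as-usual, reward-abstinent).
#' @param rho Correlation between the person-level residuals.
#' @return A [group_parameters()] object.
#' @export
study_truth <- function(K = 4L, beta_v0 = 1.15, beta_theta0 = 4,
                        sigma_v = 0.2, sigma_theta = 0.9,
                        delta_v = c(-0.3638, 0.1231, -0.2494),
                        delta_theta = c(-0.0655, 0.0835, -0.0068),
                        rho = 0) {
  group_parameters(beta_v = c(beta_v0, rep(0, K)),
                   beta_theta = c(beta_theta0, rep(0, K)),
                   sigma_v = sigma_v, sigma_theta = sigma_theta,
                   delta_v = delta_v, delta_theta = delta_theta, rho = rho)
}

#' Draw person-specific accretion and caution effects
#'
#' Person effects are the covariate-predicted group means plus Gaussian
#' residuals: `v_p = x_p beta_v + e_v`, `theta_p = x_p beta_theta + e_t`,
#' with residual SDs `sigma_v`, `sigma_theta` (bivariate normal with
#' correlation `rho` when non-zero). Caution draws are redrawn until
#' positive; the redraw count is recorded in attribute `"redraws"`.
#'
#' @param group A [group_parameters()] object.
#' @param X Person covariate matrix (persons x (K+1), leading intercept);
#'   row names are used as person ids.
#' @param seed Optional integer seed.
#' @return A data frame with columns `person_id`, `v`, `theta`.
#' @export
simulate_person_effects <- function(group, X, seed = NULL) {
  stopifnot(inherits(group, "group_parameters"))
  X <- as.matrix(X)
  if (ncol(X) != length(group$beta_v))
    stop("covariate matrix and beta length differ")
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(X)
  mu_v <- drop(X %*% group$beta_v)
  mu_t <- drop(X %*% group$beta_theta)
  e_t <- stats::rnorm(P)
  e_v <- group$rho * e_t + sqrt(1 - group$rho^2) * stats::rnorm(P)
  v <- mu_v + group$sigma_v * e_v
  theta <- mu_t + group$sigma_theta * e_t
  redraws <- 0L
  guard <- 0L
  while (any(theta <= 0)) {
    bad <- which(theta <= 0)
    redraws <- redraws + length(bad)
    theta[bad] <- mu_t[bad] + group$sigma_theta * stats::rnorm(length(bad))
    guard <- guard + 1L
    if (guard > 10000L) stop("caution redraws did not terminate; ",
                             "check beta_theta and sigma_theta")
  }
  ids <- rownames(X) %||% sprintf("P%02d", seq_len(P))
  structure(data.frame(person_id = ids, v = v, theta = theta,
                       row.names = NULL),
            redraws = redraws)
}

## trial generator over a persons x 4 cell count matrix; window = NULL
## draws from the raw generative process, otherwise redraws outside the
## window until inside (the observable-support emulation)
.simulate_cells <- function(effects, delta_v, delta_theta, counts, form,
                            window = NULL) {
  P <- nrow(effects)
  dv_full <- c(0, as.numeric(delta_v))
  dt_full <- c(0, as.numeric(delta_theta))
  rows <- list()
  redraws <- 0L
  for (ci in 1:4) {
    n_c <- counts[, ci]
    if (!any(n_c > 0)) next
    t_n <- effects$theta + dt_full[ci]
    bad <- n_c > 0 & t_n <= 0
    if (any(bad))
      stop("composed caution is non-positive in cell (",
           .later_cells$session[ci], ", ", .later_cells$trial_type[ci],
           ") for person ", effects$person_id[which(bad)[1L]])
    v_n <- effects$v + dv_full[ci]
    idx <- rep.int(seq_len(P), n_c)
    z <- stats::rnorm(length(idx), v_n[idx], 1)
    y <- if (form == "direct") z / t_n[idx] else t_n[idx] / z
    if (!is.null(window)) {
      guard <- 0L
      out_w <- which(y < window[1] | y > window[2] | !is.finite(y))
      while (length(out_w)) {
        redraws <- redraws + length(out_w)
        z2 <- stats::rnorm(length(out_w), v_n[idx[out_w]], 1)
        y[out_w] <- if (form == "direct") z2 / t_n[idx[out_w]]
                    else t_n[idx[out_w]] / z2
        out_w <- out_w[y[out_w] < window[1] | y[out_w] > window[2] |
                         !is.finite(y[out_w])]
        guard <- guard + 1L
        if (guard > 10000L)
          stop("window redraws did not terminate; the window mass is ",
               "vanishing at these parameters")
      }
    }
    rows[[ci]] <- data.frame(person_id = effects$person_id[idx],
                             session = .later_cells$session[ci],
                             trial_type = .later_cells$trial_type[ci],
                             rt = y, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, redraws = redraws)
}

#' Simulate frequent-go trials from the generative LATER process
#'
#' For each trial a rise rate `z ~ N(v_n, 1)` is drawn at the composed
#' trial-level accretion `v_n`, and the latency is `z / theta_n` (direct
#' form) or `theta_n / z` (reciprocal form). With `window = TRUE`, draws
#' outside the design's observable latency window are redrawn until
#' inside, emulating the recorded data's support (redraw count in
#' attribute `"redraws"`); with `window = FALSE` the raw draws are
#' returned, which under the direct form can include non-positive
#' latencies — that mode exists for exactness checks and recovery studies
#' on the untruncated model.
#'
#' @param effects Data frame of person effects (`person_id`, `v`,
#'   `theta`), as from [simulate_person_effects()].
#' @param delta_v,delta_theta Length-3 condition deviations.
#' @param design A [study_design()].
#' @param model A [later_model()]; only the likelihood form is used.
#' @param seed Optional integer seed.
#' @param window Redraw latencies outside the design window (default TRUE).
#' @return A data frame of trials (`person_id`, `session`, `trial_type`,
#'   `rt` in seconds).
#' @export
simulate_trials <- function(effects, delta_v, delta_theta,
                            design = study_design(), model = later_model(),
                            seed = NULL, window = TRUE) {
  stopifnot(is.data.frame(effects),
            all(c("person_id", "v", "theta") %in% names(effects)))
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(effects)
  ## crossed 2x2: per session, neutral and reward frequent-go counts
  counts <- matrix(c(design$neutral_per_session, design$neutral_per_session,
                     design$reward_per_session, design$reward_per_session),
                   P, 4L, byrow = TRUE)
  .simulate_cells(effects, delta_v, delta_theta, counts, model$form,
                  window = if (isTRUE(window)) design$rt_window else NULL)
}

## moment-matched covariate table: Gaussian draws rescaled so the sample
## mean and SD equal the published sample statistics exactly
.study_covariates <- function(n, moments = NULL) {
  if (is.null(moments))
    moments <- list(age = c(31.06, 13.82),
                    age_first_use = c(19.63, 5.34),
                    ftnd = c(2.61, 2.35),
                    cigs_per_day = c(11.08, 5.5))
  out <- data.frame(person_id = sprintf("P%02d", seq_len(n)))
  for (nm in names(moments)) {
    x <- stats::rnorm(n)
    x <- (x - mean(x)) / stats::sd(x)
    out[[nm]] <- moments[[nm]][1] + moments[[nm]][2] * x
  }
  out
}

#' Simulate a complete two-session Go/No-Go study
#'
#' Emulates the smoking-abstinence study the model was designed for:
#' 17 persons by default, each with 750 frequent-go trials per session in
#' a crossed session (smoke-as-usual / abstinent) x trial-type
#' (neutral / reward) design, person covariates (age, age of first use,
#' FTND nicotine-dependence score, cigarettes per day) drawn to match the
#' published sample moments exactly, and latencies generated from the
#' hierarchical LATER process at the recorded true parameters.
#'
#' @param seed Integer seed governing covariates, effects and trials.
#' @param design A [study_design()].
#' @param truth A [group_parameters()] object; `NULL` uses [study_truth()]
#'   matched to the covariate count.
#' @param covariates Optional covariate data frame (`person_id` + numeric
#'   columns); `NULL` generates the moment-matched table.
#' @param model A [later_model()].
#' @param window Emulate the observable 150-800 ms window (default TRUE);
#'   `FALSE` yields raw generative draws and skips the ingestion
#'   exclusions, for exactness studies.
#' @return An object of class `"later_study"`: a list with the prepared
#'   `data` (a `later_data`), the raw `trials` and `covariates` tables,
#'   and `truth` (the generating group parameters plus realized person
#'   effects) for recovery scoring.
#' @export
simulate_study <- function(seed = 1L, design = study_design(),
                           truth = NULL, covariates = NULL,
                           model = later_model(), window = TRUE) {
  set.seed(seed)
  if (is.null(covariates)) covariates <- .study_covariates(design$n_persons)
  cv_cols <- setdiff(names(covariates), "person_id")
  if (is.null(truth)) truth <- study_truth(K = length(cv_cols))
  X_raw <- cbind("(Intercept)" = 1,
                 as.matrix(covariates[cv_cols]))
  rownames(X_raw) <- covariates$person_id
  X_std <- standardize_covariates(X_raw)$X
  effects <- simulate_person_effects(truth, X_std)
  trials <- simulate_trials(effects, truth$delta_v, truth$delta_theta,
                            design = design, model = model, window = window)
  data <- if (isTRUE(window)) {
    prepare_later_data(trials, covariates,
                       rt_min = design$rt_window[1],
                       rt_max = design$rt_window[2])
  } else {
    prepare_later_data(trials, covariates, rt_min = NULL, rt_max = NULL)
  }
  structure(list(data = data, trials = trials, covariates = covariates,
                 truth = list(group = truth, effects = effects),
                 design = design, seed = seed, window = isTRUE(window),
                 redraws = attr(trials, "redraws") %||% 0L),
            class = "later_study")
}

#' @export
print.later_study <- function(x, ...) {
  cat("Simulated two-session Go/No-Go study (seed ", x$seed, ")\n", sep = "")
  cat("  persons:", x$design$n_persons,
      " frequent-go trials/person/session:", x$design$fgo_per_session, "\n")
  cat("  window:", if (x$window) paste0("[",
      paste(round(x$design$rt_window * 1000), collapse = ", "), "] ms (",
      x$redraws, " redraws)") else "disabled (raw generative draws)", "\n")
  print(x$data)
  invisible(x)
}

#' Write a simulated study to delimited-text files
#'
#' Writes the trial table, covariate table, and the generating truth
#' (group parameters as key-value YAML plus realized person effects as
#' CSV) to a directory.
#'
#' @param study A `later_study` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "later_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth_group = file.path(dir, "truth_group.yaml"),
             truth_effects = file.path(dir, "truth_effects.csv"))
  utils::write.csv(study$trials, paths["trials"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$covariates, paths["covariates"], row.names = FALSE,
                   quote = FALSE)
  g <- study$truth$group
  yaml::write_yaml(list(beta_v = g$beta_v, beta_theta = g$beta_theta,
                        sigma_v = g$sigma_v, sigma_theta = g$sigma_theta,
                        delta_v = g$delta_v, delta_theta = g$delta_theta,
                        rho = g$rho),
                   paths["truth_group"])
  utils::write.csv(study$truth$effects, paths["truth_effects"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
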