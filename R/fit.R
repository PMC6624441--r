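#' Fit the hierarchical LATER model
#'
#' Draws posterior samples of all group parameters (regression weights,
#' residual scales, condition deviations) and every person's accretion and
#' caution effects simultaneously, by Metropolis-within-Gibbs targeting
#' [joint_log_posterior()]. The accretion-side parameters have conjugate
#' normal full conditionals (truncated to keep composed mean latencies
#' positive under the direct form) and are Gibbs-updated; caution-side
#' parameters use adaptive random-walk Metropolis with adaptation confined
#' to burn-in.
#'
#' @param data A `later_data` object from [prepare_later_data()].
#' @param model A [later_model()] configuration.
#' @param sampler A [later_sampler()] configuration.
#' @return An object of class `"later_fit"` containing the retained draws
#'   (array: iteration x chain x parameter), the configurations, the data,
#'   and per-parameter summaries with split-chain R-hat via
#'   [summary.later_fit()].
#' @seealso [summary.later_fit()], [later_ppc()], [rhat()]
#' @export
later_fit <- function(data, model = later_model(), sampler = later_sampler()) {
  stopifnot(inherits(data, "later_data"), inherits(model, "later_model"),
            inherits(sampler, "later_sampler"))
  if (nrow(data$trials) == 0L) stop("cannot fit an empty dataset")
  free_sigma <- is.null(sampler$fix$sigma_v) || is.null(sampler$fix$sigma_theta)
  if (length(data$persons) < 2L && free_sigma &&
      is.null(sampler$fix$v) && is.null(sampler$fix$theta))
    stop("at least 2 persons are required to identify the group-level ",
         "variances; fix them (or the person effects) for reduced models")

  ss <- .suffstats(data, model$form)
  labels <- .param_labels(data, model)
  keep <- sampler$iter - sampler$warmup
  draws <- array(NA_real_, c(keep, sampler$chains, length(labels)),
                 dimnames = list(NULL, NULL, labels))
  accept <- vector("list", sampler$chains)
  for (ch in seq_len(sampler$chains)) {
    res <- .later_chain(ss, data$X, model, sampler,
                        chain_seed = sampler$seed + 1000L * ch, labels)
    draws[, ch, ] <- res$draws
    accept[[ch]] <- res$accept
  }
  if (!all(is.finite(draws)))
    stop("sampler produced non-finite draws; first offending parameter: ",
         labels[which(apply(!is.finite(draws), 3L, any))[1L]])

  structure(list(draws = draws, data = data, model = model,
                 sampler = sampler, accept = accept,
                 version = as.character(utils::packageVersion("hlater"))),
            class = "later_fit")
}

## pooled draw matrix (iterations*chains) x parameters
.pooled <- function(fit) {
  d <- fit$draws
  matrix(d, nrow = dim(d)[1L] * dim(d)[2L], ncol = dim(d)[3L],
         dimnames = list(NULL, dimnames(d)[[3L]]))
}

#' Summarize posterior draws of one parameter
#'
#' Pooled-chain posterior mean, standard deviation, median and central 95%
#' credible interval, with the split-chain [rhat()] attached.
#'
#' @param fit A `later_fit` object.
#' @param parameter Parameter name (see `dimnames(fit$draws)[[3]]`).
#' @return A one-row data frame with columns `mean`, `sd`, `q2.5`,
#'   `median`, `q97.5`, `rhat`.
#' @export
summarize_parameter <- function(fit, parameter) {
  stopifnot(inherits(fit, "later_fit"))
  labels <- dimnames(fit$draws)[[3L]]
  if (!parameter %in% labels)
    stop("unknown parameter '", parameter, "'; candidates include: ",
         paste(utils::head(labels, 8L), collapse = ", "), ", ...")
  x <- fit$draws[, , parameter]
  pooled <- as.vector(x)
  q <- unname(stats::quantile(pooled, c(0.025, 0.5, 0.975), type = 7))
  r <- if (stats::var(pooled) == 0 || nrow(as.matrix(x)) < 4L)
    NA_real_ else rhat(x)
  data.frame(parameter = parameter, mean = mean(pooled),
             sd = stats::sd(pooled), q2.5 = q[1L], median = q[2L],
             q97.5 = q[3L], rhat = r, row.names = NULL)
}

#' @export
summary.later_fit <- function(object, pars = NULL, ...) {
  labels <- dimnames(object$draws)[[3L]]
  if (is.null(pars)) pars <- labels
  bad <- setdiff(pars, labels)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  tab <- do.call(rbind, lapply(pars, summarize_parameter, fit = object))
  structure(list(table = tab,
                 n_chains = dim(object$draws)[2L],
                 n_kept = dim(object$draws)[1L],
                 form = object$model$form,
                 max_rhat = suppressWarnings(max(tab$rhat, na.rm = TRUE))),
            class = "summary.later_fit")
}

#' @export
print.summary.later_fit <- function(x, digits = 4, ...) {
  cat("Hierarchical LATER model posterior summary (", x$form,
      " form)\n", sep = "")
  cat(x$n_chains, "chains,", x$n_kept, "retained draws each\n\n")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("\nmax split-chain Rhat:", round(x$max_rhat, 4),
      if (is.finite(x$max_rhat) && x$max_rhat < 1.1) "(converged)"
      else "(NOT converged at the 1.1 criterion)", "\n")
  invisible(x)
}

#' @export
print.later_fit <- function(x, ...) {
  cat("Hierarchical LATER model fit (", x$model$form, " form)\n", sep = "")
  cat("  persons:", length(x$data$persons),
      "  trials:", nrow(x$data$trials), "\n")
  cat("  chains:", dim(x$draws)[2L], " retained draws/chain:",
      dim(x$draws)[1L], "\n")
  grp <- grep("^(beta|sigma|delta|rho)", dimnames(x$draws)[[3L]], value = TRUE)
  print(summary(x, pars = grp))
  invisible(x)
}

#' @export
coef.later_fit <- function(object,
                           which = c("group", "person", "all"), ...) {
  which <- match.arg(which)
  pooled <- .pooled(object)
  means <- colMeans(pooled)
  grp <- grepl("^(beta|sigma|delta|rho)", names(means))
  switch(which, group = means[grp], person = means[!grp], all = means)
}

## posterior-mean composed parameters per trial
.fitted_parameters <- function(object) {
  means <- colMeans(.pooled(object))
  persons <- object$data$persons
  v <- means[paste0("v[", persons, "]")]
  th <- means[paste0("theta[", persons, "]")]
  dv <- c(0, means[paste0("delta_v[", .later_condition_labels, "]")])
  dt <- c(0, means[paste0("delta_theta[", .later_condition_labels, "]")])
  idx <- match(object$data$trials$person_id, persons)
  cell <- object$data$trials$cell
  list(v_n = unname(v[idx] + dv[cell]), theta_n = unname(th[idx] + dt[cell]))
}

#' @export
fitted.later_fit <- function(object, ...) {
  par <- .fitted_parameters(object)
  expected_latency(par$v_n, par$theta_n, object$model$form)
}

#' @export
residuals.later_fit <- function(object, ...) {
  object$data$trials$rt - fitted(object)
}

#' Posterior expected latencies per person and design cell
#'
#' For each person and each of the four session/trial-type cells, computes
#' the posterior distribution of the model-implied mean latency
#' ([expected_latency()] at the composed person + condition parameters)
#' and returns its posterior mean and central 95% interval.
#'
#' @param object A `later_fit` object.
#' @param ... Unused.
#' @return A data frame with one row per person x cell.
#' @export
predict.later_fit <- function(object, ...) {
  pooled <- .pooled(object)
  persons <- object$data$persons
  out <- list()
  for (ci in 1:4) {
    dv <- if (ci == 1L) 0 else
      pooled[, paste0("delta_v[", .later_condition_labels[ci - 1L], "]")]
    dt <- if (ci == 1L) 0 else
      pooled[, paste0("delta_theta[", .later_condition_labels[ci - 1L], "]")]
    for (p in persons) {
      lat <- expected_latency(pooled[, paste0("v[", p, "]")] + dv,
                              pooled[, paste0("theta[", p, "]")] + dt,
                              object$model$form)
      q <- unname(stats::quantile(lat, c(0.025, 0.975)))
      out[[length(out) + 1L]] <- data.frame(
        person_id = p, session = .later_cells$session[ci],
        trial_type = .later_cells$trial_type[ci],
        latency = mean(lat), q2.5 = q[1L], q97.5 = q[2L])
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
plot.later_fit <- function(x, pars = NULL, ...) {
  labels <- dimnames(x$draws)[[3L]]
  if (is.null(pars))
    pars <- grep("^(delta|sigma)", labels, value = TRUE)
  pars <- intersect(pars, labels)
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                       mar = c(3, 3, 2, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old))
  for (p in pars) {
    m <- x$draws[, , p]
    graphics::matplot(m, type = "l", lty = 1, col = grDevices::hcl.colors(
      ncol(m), "Dark 3"), xlab = "retained iteration", ylab = p, main = p)
  }
  invisible(x)
}

#' Persist posterior draws as delimited text
#'
#' Long format: one row per (chain, iteration, parameter, value).
#'
#' @param fit A `later_fit` object.
#' @param path Output file path (comma-separated text).
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  labels <- dimnames(d)[[3L]]
  long <- data.frame(
    chain = rep(seq_len(dim(d)[2L]), each = dim(d)[1L], times = dim(d)[3L]),
    iteration = rep(seq_len(dim(d)[1L]), times = dim(d)[2L] * dim(d)[3L]),
    parameter = rep(labels, each = dim(d)[1L] * dim(d)[2L]),
    value = as.vector(d))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path Path to the long-format draw file.
#' @return A 3-d array (iteration x chain x parameter).
#' @export
read_draws <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "iteration", "parameter", "value") %in% names(long)))
  labels <- unique(long$parameter)
  chains <- sort(unique(long$chain))
  iters <- sort(unique(long$iteration))
  arr <- array(NA_real_, c(length(iters), length(chains), length(labels)),
               dimnames = list(NULL, NULL, labels))
  arr[cbind(match(long$iteration, iters), match(long$chain, chains),
            match(long$parameter, labels))] <- long$value
  arr
}
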