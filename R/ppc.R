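## observed person x cell trial counts of a later_data
.data_counts <- function(data) {
  P <- length(data$persons)
  idx <- match(data$trials$person_id, data$persons)
  key <- factor(idx + P * (data$trials$cell - 1L), levels = seq_len(P * 4L))
  matrix(tabulate(key, nbins = P * 4L), P, 4L)
}

## person effects and deltas of one pooled posterior draw
.draw_parameters <- function(pooled, persons, row) {
  list(effects = data.frame(
         person_id = persons,
         v = unname(pooled[row, paste0("v[", persons, "]")]),
         theta = unname(pooled[row, paste0("theta[", persons, "]")]),
         stringsAsFactors = FALSE),
       delta_v = unname(pooled[row, paste0("delta_v[",
                                           .later_condition_labels, "]")]),
       delta_theta = unname(pooled[row, paste0("delta_theta[",
                                               .later_condition_labels, "]")]))
}

.ppc_stats <- function(rt) {
  c(mean = mean(rt), sd = stats::sd(rt),
    stats::quantile(rt, c(0.1, 0.25, 0.5, 0.75, 0.9)))
}

#' Posterior predictive checks
#'
#' Generates replicate datasets from the fitted model and compares their
#' summary statistics with the observed data. Each replicate uses one
#' posterior draw of all person effects and condition deviations — draws
#' are taken equally spaced (thinned) across the pooled retained draws,
#' for reproducibility — and regenerates trials with exactly the observed
#' design shape (same persons, cells and trial counts). The seed governs
#' only the trial-level noise.
#'
#' @param fit A `later_fit` object.
#' @param n_rep Number of replicate datasets (default 100).
#' @param seed Integer seed for the trial-level noise.
#' @param window `"match"` replays the observable-window truncation the
#'   observed data were recorded under (when the data carry a finite
#'   window); `"none"` draws from the raw generative process.
#' @param keep_replicates Store the replicate latency vectors (needed for
#'   [ppc_overlay()]); default `TRUE`.
#' @return An object of class `"later_ppc"` with per-replicate summary
#'   statistics, the observed statistics, and central-95%-interval
#'   coverage flags.
#' @export
later_ppc <- function(fit, n_rep = 100L, seed = 1L,
                      window = c("match", "none"), keep_replicates = TRUE) {
  stopifnot(inherits(fit, "later_fit"))
  window <- match.arg(window)
  pooled <- .pooled(fit)
  if (n_rep < 2L) stop("n_rep must be at least 2")
  if (n_rep > nrow(pooled))
    stop("n_rep (", n_rep, ") exceeds the ", nrow(pooled),
         " retained posterior draws")
  counts <- .data_counts(fit$data)
  win <- fit$data$rt_window
  win <- if (window == "match" && all(is.finite(win))) win else NULL
  rows <- round(seq(1L, nrow(pooled), length.out = n_rep))

  set.seed(seed)
  rep_stats <- vector("list", n_rep)
  reps <- if (keep_replicates) vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    par <- .draw_parameters(pooled, fit$data$persons, rows[r])
    sim <- .simulate_cells(par$effects, par$delta_v, par$delta_theta,
                           counts, fit$model$form, window = win)
    rep_stats[[r]] <- .ppc_stats(sim$rt)
    if (keep_replicates) reps[[r]] <- sim
  }
  rep_stats <- do.call(rbind, rep_stats)
  obs_stats <- .ppc_stats(fit$data$trials$rt)
  lo <- apply(rep_stats, 2L, stats::quantile, probs = 0.025)
  hi <- apply(rep_stats, 2L, stats::quantile, probs = 0.975)
  structure(list(rep_stats = as.data.frame(rep_stats),
                 obs_stats = obs_stats,
                 covered = obs_stats >= lo & obs_stats <= hi,
                 interval = rbind(lower = lo, upper = hi),
                 n_rep = n_rep, seed = seed, window = window,
                 replicates = if (keep_replicates) reps,
                 data = fit$data, form = fit$model$form),
            class = "later_ppc")
}

#' @export
print.later_ppc <- function(x, digits = 4, ...) {
  cat("Posterior predictive check,", x$n_rep, "replicate datasets\n")
  tab <- data.frame(statistic = names(x$obs_stats),
                    observed = round(unname(x$obs_stats), digits),
                    rep_lower = round(unname(x$interval["lower", ]), digits),
                    rep_upper = round(unname(x$interval["upper", ]), digits),
                    in_central_95 = unname(x$covered))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot-ready posterior predictive overlay
#'
#' Bins the observed latencies into histogram counts and evaluates each
#' replicate's kernel density (Gaussian kernel, Silverman's
#' rule-of-thumb bandwidth) on a common latency grid, at the whole-dataset
#' level or for a single participant.
#'
#' @param result A `later_ppc` object created with
#'   `keep_replicates = TRUE`.
#' @param level `"dataset"` (all trials) or `"person"`.
#' @param person_id Person identifier, required for `level = "person"`.
#' @param bins Number of observed-histogram bins.
#' @param grid_n Number of grid points for the replicate densities.
#' @return An object of class `"later_ppc_overlay"`: a list with
#'   `observed` (bin midpoints and counts) and `replicates` (long table of
#'   replicate, latency, density).
#' @export
ppc_overlay <- function(result, level = c("dataset", "person"),
                        person_id = NULL, bins = 30L, grid_n = 128L) {
  stopifnot(inherits(result, "later_ppc"))
  level <- match.arg(level)
  if (is.null(result$replicates))
    stop("the check was run with keep_replicates = FALSE")
  obs <- result$data$trials
  if (level == "person") {
    if (is.null(person_id)) stop("person_id is required at level = 'person'")
    if (!person_id %in% result$data$persons)
      stop("unknown person '", person_id, "'")
    obs <- obs[obs$person_id == person_id, , drop = FALSE]
  }
  sel <- function(d) if (level == "person")
    d$rt[d$person_id == person_id] else d$rt
  all_rts <- c(obs$rt, unlist(lapply(result$replicates, sel)))
  ## pad the grid beyond the data range so the kernel tails are captured
  pad <- 4 * stats::bw.nrd0(sel(result$replicates[[1L]]))
  rng <- range(all_rts) + c(-pad, pad)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(obs$rt, breaks = breaks, plot = FALSE)
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  dens <- lapply(seq_along(result$replicates), function(r) {
    d <- stats::density(sel(result$replicates[[r]]), bw = "nrd0",
                        from = rng[1], to = rng[2], n = grid_n)
    data.frame(replicate = r, rt = grid, density = d$y)
  })
  structure(list(observed = data.frame(rt = h$mids, count = h$counts,
                                       density = h$density),
                 replicates = do.call(rbind, dens),
                 level = level, person_id = person_id,
                 n_trials = nrow(obs)),
            class = "later_ppc_overlay")
}

#' @export
plot.later_ppc_overlay <- function(x, ...) {
  obs <- x$observed
  w <- diff(obs$rt[1:2])
  ylim <- c(0, max(obs$density, x$replicates$density))
  graphics::plot(NULL, xlim = range(x$replicates$rt), ylim = ylim,
                 xlab = "latency (s)", ylab = "density",
                 main = if (x$level == "dataset")
                   "Posterior predictive check: all trials"
                 else paste("Posterior predictive check:", x$person_id))
  graphics::rect(obs$rt - w / 2, 0, obs$rt + w / 2, obs$density,
                 col = grDevices::adjustcolor("firebrick", 0.5),
                 border = "white")
  for (r in unique(x$replicates$replicate)) {
    d <- x$replicates[x$replicates$replicate == r, ]
    graphics::lines(d$rt, d$density,
                    col = grDevices::adjustcolor("steelblue", 0.2))
  }
  invisible(x)
}

#' @export
plot.later_ppc <- function(x, level = "dataset", person_id = NULL, ...) {
  plot(ppc_overlay(x, level = level, person_id = person_id), ...)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws `nsim` posterior predictive replicate trial tables with the
#' observed design shape, using equally spaced posterior draws (the same
#' scheme as [later_ppc()]).
#'
#' @param object A `later_fit` object.
#' @param nsim Number of replicates.
#' @param seed Integer seed for the trial-level noise.
#' @param window `"match"` or `"none"`, as in [later_ppc()].
#' @param ... Unused.
#' @return A list of `nsim` trial data frames.
#' @export
simulate.later_fit <- function(object, nsim = 1L, seed = 1L,
                               window = c("match", "none"), ...) {
  window <- match.arg(window)
  res <- later_ppc(object, n_rep = max(nsim, 2L), seed = seed,
                   window = window, keep_replicates = TRUE)
  res$replicates[seq_len(nsim)]
}
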