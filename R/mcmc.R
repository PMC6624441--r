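#' Sampler configuration
#'
#' Settings for the Markov chain Monte Carlo run: 6 chains of 2,000
#' iterations with the first 1,000 discarded as burn-in by default. All
#' randomness (initial values, proposals) flows from `seed`; identical
#' seed and configuration reproduce the draws exactly.
#'
#' @param chains Number of chains (>= 2, for convergence diagnostics).
#' @param iter Iterations per chain, burn-in included.
#' @param warmup Burn-in iterations discarded per chain (proposal scales
#'   adapt only during burn-in, so retained draws target the exact
#'   posterior).
#' @param seed Integer seed.
#' @param adapt_target Target acceptance rate for the random-walk updates.
#' @param fix Named list of parameters to hold fixed rather than sample;
#'   recognized names: `beta_v`, `beta_theta`, `sigma_v`, `sigma_theta`,
#'   `delta_v`, `delta_theta`, `rho`, `v`, `theta` (the latter two as named
#'   per-person vectors). Fixing `sigma_theta = 0` (with `beta_theta`
#'   fixed) pins every person's caution at its covariate-predicted value,
#'   which reduces the model to independent Gaussian inference on
#'   accretion — useful for closed-form validation.
#' @return An object of class `"later_sampler"`.
#' @export
later_sampler <- function(chains = 6L, iter = 2000L, warmup = 1000L,
                          seed = 1L, adapt_target = 0.44, fix = list()) {
  chains <- as.integer(chains); iter <- as.integer(iter)
  warmup <- as.integer(warmup)
  if (chains < 2L) stop("at least 2 chains are required for convergence diagnostics")
  if (warmup >= iter) stop("warmup must be smaller than iter")
  stopifnot(is.list(fix), adapt_target > 0, adapt_target < 1)
  known <- c("beta_v", "beta_theta", "sigma_v", "sigma_theta",
             "delta_v", "delta_theta", "rho", "v", "theta")
  bad <- setdiff(names(fix), known)
  if (length(bad)) stop("unknown fix entries: ", paste(bad, collapse = ", "))
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 seed = as.integer(seed), adapt_target = adapt_target,
                 fix = fix),
            class = "later_sampler")
}

#' Gelman-Rubin split-chain convergence diagnostic
#'
#' Classic (non rank-normalized) potential scale reduction factor with
#' chain splitting: each chain is halved, and the ratio of the pooled
#' variance estimate to the mean within-chain variance is returned. Values
#' near 1 indicate the chains have mixed over the same distribution; the
#' conventional failure criterion is 1.1.
#'
#' @param x A matrix of draws, iterations in rows and chains in columns.
#' @return The potential scale reduction factor; `NA` with a warning when
#'   every (split) chain has zero internal variance.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("at least 2 chains are required")
  half <- nrow(x) %/% 2L
  if (half < 2L) stop("at least 4 retained draws per chain are required")
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  w <- apply(sp, 2L, stats::var)
  W <- mean(w)
  if (W == 0) {
    warning("zero within-chain variance in all chains; rhat is undefined")
    return(NA_real_)
  }
  B_over_n <- stats::var(colMeans(sp))
  sqrt(((half - 1) / half * W + B_over_n) / W)
}

## ---- internal sampler -----------------------------------------------------

## Sufficient statistics of the Gaussian data term on the modeled scale
## w = y (direct) or w = 1/y (reciprocal): per person x cell counts, sums,
## sums of squares. The trial count makes the per-iteration cost
## independent of the number of trials.
.suffstats <- function(data, form) {
  P <- length(data$persons)
  idx <- match(data$trials$person_id, data$persons)
  cell <- data$trials$cell
  w <- if (form == "direct") data$trials$rt else 1 / data$trials$rt
  key <- factor(idx + P * (cell - 1L), levels = seq_len(P * 4L))
  N <- matrix(as.numeric(tabulate(key, nbins = P * 4L)), P, 4L)
  S1 <- matrix(vapply(split(w, key), sum, 0), P, 4L)
  S2 <- matrix(vapply(split(w * w, key), sum, 0), P, 4L)
  jac <- if (form == "reciprocal") -2 * sum(log(data$trials$rt)) else 0
  list(N = N, S1 = S1, S2 = S2, jac = jac, P = P)
}

## Per person x cell data-term log-likelihood (constants dropped handled
## by caller); cells with no trials contribute 0, invalid parameter cells
## with trials contribute -Inf.
.ll_cells <- function(ss, v, t, dv_full, dt_full, need_pos_mean) {
  P <- ss$P
  Th <- matrix(t, P, 4L) + matrix(dt_full, P, 4L, byrow = TRUE)
  Nu <- matrix(v, P, 4L) + matrix(dv_full, P, 4L, byrow = TRUE)
  has <- ss$N > 0
  ok <- Th > 0
  if (need_pos_mean) ok <- ok & Nu > 0
  L <- matrix(0, P, 4L)
  g <- has & ok
  L[g] <- ss$N[g] * log(Th[g]) -
    0.5 * (Th[g]^2 * ss$S2[g] - 2 * Th[g] * Nu[g] * ss$S1[g] +
             ss$N[g] * Nu[g]^2)
  L[has & !ok] <- -Inf
  L
}

## One chain of the Metropolis-within-Gibbs sampler. Accretion-side
## parameters (v_p, delta_v, beta_v) have conjugate truncated-normal /
## normal full conditionals given the caution side; caution-side
## parameters use adaptive random-walk Metropolis. Proposal scales adapt
## by Robbins-Monro during warmup only.
.later_chain <- function(ss, X, model, sampler, chain_seed, labels) {
  set.seed(chain_seed)
  P <- ss$P; K1 <- ncol(X)
  prior <- model$prior
  form <- model$form
  direct <- form == "direct"
  corr <- isTRUE(model$correlated_effects)
  fix <- sampler$fix
  target <- sampler$adapt_target

  b_prec <- if (prior$flat) 0 else 1 / prior$beta_scale^2
  d_prec <- if (prior$flat) 0 else 1 / prior$delta_scale^2
  b_loc <- prior$beta_location; d_loc <- prior$delta_location

  has <- ss$N > 0
  XtX <- crossprod(X)

  ## ---- initial values: per-person method-of-moments with seeded jitter
  m_w <- rowSums(ss$S1) / pmax(rowSums(ss$N), 1)
  v_w <- rowSums(ss$S2) / pmax(rowSums(ss$N), 1) - m_w^2
  sd_w <- sqrt(pmax(v_w, 1e-6))
  t_cur <- pmax(1 / sd_w, 0.3) * exp(stats::rnorm(P, 0, 0.05))
  v_cur <- pmax(m_w / sd_w, 0.1) * exp(stats::rnorm(P, 0, 0.05))
  dv <- stats::rnorm(3L, 0, 0.02)
  dt <- stats::rnorm(3L, 0, 0.02)
  bv <- c(mean(v_cur), rep(0, K1 - 1L)) + stats::rnorm(K1, 0, 0.02)
  bt <- c(mean(t_cur), rep(0, K1 - 1L)) + stats::rnorm(K1, 0, 0.02)
  sv <- max(stats::sd(v_cur), 0.05)
  if (!is.finite(sv)) sv <- 0.1
  sv <- sv * exp(stats::rnorm(1, 0, 0.1))
  st <- max(stats::sd(t_cur), 0.1)
  if (!is.finite(st)) st <- 0.2
  st <- st * exp(stats::rnorm(1, 0, 0.1))
  rho <- 0

  ## ---- apply fixed values
  upd <- list(v = TRUE, theta = TRUE, dv = TRUE, dt = TRUE, bv = TRUE,
              bt = TRUE, sv = TRUE, st = TRUE, rho = corr)
  if (!is.null(fix$beta_v)) { bv <- rep_len(as.numeric(fix$beta_v), K1); upd$bv <- FALSE }
  if (!is.null(fix$beta_theta)) { bt <- rep_len(as.numeric(fix$beta_theta), K1); upd$bt <- FALSE }
  if (!is.null(fix$delta_v)) { dv <- as.numeric(fix$delta_v); upd$dv <- FALSE }
  if (!is.null(fix$delta_theta)) { dt <- as.numeric(fix$delta_theta); upd$dt <- FALSE }
  if (!is.null(fix$sigma_v)) { sv <- as.numeric(fix$sigma_v); upd$sv <- FALSE }
  if (!is.null(fix$sigma_theta)) { st <- as.numeric(fix$sigma_theta); upd$st <- FALSE }
  if (!is.null(fix$rho)) { rho <- as.numeric(fix$rho); upd$rho <- FALSE }
  if (!is.null(fix$v)) { v_cur <- rep_len(as.numeric(fix$v), P); upd$v <- FALSE }
  if (!is.null(fix$theta)) { t_cur <- rep_len(as.numeric(fix$theta), P); upd$theta <- FALSE }
  if (sv == 0) {
    if (upd$bv) stop("fixing sigma_v at 0 requires fixing beta_v as well")
    upd$v <- FALSE
  }
  if (st == 0) {
    if (upd$bt) stop("fixing sigma_theta at 0 requires fixing beta_theta as well")
    upd$theta <- FALSE
  }

  mu_v <- drop(X %*% bv); mu_t <- drop(X %*% bt)
  if (sv == 0) v_cur <- mu_v
  if (st == 0) t_cur <- mu_t
  ## ensure a valid starting point under the positivity constraints
  dv_full <- c(0, dv); dt_full <- c(0, dt)
  t_cur <- pmax(t_cur, 1e-3 - min(dt_full))
  if (direct) v_cur <- pmax(v_cur, 1e-3 - min(dv_full))

  ## adaptive proposal log-scales
  ls_t <- rep(log(0.05), P); ls_dt <- rep(log(0.02), 3L)
  ls_sv <- log(0.2); ls_st <- log(0.2); ls_rho <- log(0.2)
  acc <- c(theta = 0, delta_theta = 0, sigma = 0)
  acc_n <- c(theta = 0, delta_theta = 0, sigma = 0)

  keep <- sampler$iter - sampler$warmup
  npar <- 2L * K1 + 2L + 6L + corr + 2L * P
  out <- matrix(NA_real_, keep, npar)

  halfnorm <- function(s, scale) {
    if (prior$flat) 0 else log(2) + stats::dnorm(s, 0, scale, log = TRUE)
  }
  re_logdens <- function(v, t) {
    ## person-effect log-density; deterministic blocks (sigma == 0)
    ## contribute a constant and are skipped
    out <- 0
    if (sv > 0 && st > 0 && rho != 0)
      return(sum(.person_effect_logdens(v, t, mu_v, mu_t, sv, st, rho)))
    if (sv > 0) out <- out + sum(stats::dnorm(v, mu_v, sv, log = TRUE))
    if (st > 0) out <- out + sum(stats::dnorm(t, mu_t, st, log = TRUE))
    out
  }

  for (it in seq_len(sampler$iter)) {
    adapting <- it <= sampler$warmup
    gam <- if (adapting) min(0.25, 1 / sqrt(it)) else 0
    dv_full <- c(0, dv); dt_full <- c(0, dt)
    Th <- matrix(t_cur, P, 4L) + matrix(dt_full, P, 4L, byrow = TRUE)
    ThS1 <- Th * ss$S1

    ## ---- accretion block: one exact joint Gibbs draw of (v, delta_v,
    ## beta_v), whose full conditional given the caution side is
    ## multivariate normal (truncated to positive composed means under
    ## the direct form; enforced by rejection, which almost never fires
    ## away from degenerate fits) ----
    if (upd$v || upd$dv || upd$bv) {
      if (corr && rho != 0 && st > 0 && sv > 0) {
        a_off <- rho * sv / st * (t_cur - mu_t)
        s2c <- sv^2 * (1 - rho^2)
      } else { a_off <- rep(0, P); s2c <- sv^2 }
      ## delta components with no data and no proper prior are
      ## unidentified; they stay at their current value outside the block
      d_free <- if (upd$dv)
        which(colSums(ss$N[, 2:4, drop = FALSE]) > 0 | d_prec > 0)
      else integer(0)
      nv <- if (upd$v) P else 0L
      nd <- length(d_free)
      nb <- if (upd$bv && sv > 0) K1 else 0L
      dim_u <- nv + nd + nb
      iv <- seq_len(nv)
      id <- nv + seq_len(nd)
      ib <- nv + nd + seq_len(nb)
      Q <- matrix(0, dim_u, dim_u)
      b <- numeric(dim_u)
      ## data term: quadratic in (v_p + delta_c)
      for (c in 1:4) {
        n_c <- ss$N[, c]
        if (!any(n_c > 0)) next
        lin_c <- ThS1[, c]
        pos <- if (c > 1L) match(c - 1L, d_free) else NA_integer_
        if (upd$v) {
          Q[cbind(iv, iv)] <- Q[cbind(iv, iv)] + n_c
          b[iv] <- b[iv] + lin_c -
            if (c > 1L && is.na(pos)) n_c * dv_full[c] else 0
          if (!is.na(pos)) {
            j <- id[pos]
            Q[iv, j] <- Q[iv, j] + n_c
            Q[j, iv] <- Q[j, iv] + n_c
          }
        }
        if (!is.na(pos)) {
          j <- id[pos]
          Q[j, j] <- Q[j, j] + sum(n_c)
          b[j] <- b[j] + sum(lin_c) -
            if (!upd$v) sum(n_c * v_cur) else 0
        }
      }
      ## person-effect prior: (v_p - x_p beta - a_p)^2 / s2c
      if (upd$v && sv > 0) {
        Q[cbind(iv, iv)] <- Q[cbind(iv, iv)] + 1 / s2c
        if (nb) {
          Q[iv, ib] <- Q[iv, ib] - X / s2c
          Q[ib, iv] <- Q[ib, iv] - t(X) / s2c
          Q[ib, ib] <- Q[ib, ib] + XtX / s2c
          b[iv] <- b[iv] + a_off / s2c
          b[ib] <- b[ib] - crossprod(X, a_off) / s2c
        } else {
          b[iv] <- b[iv] + (mu_v + a_off) / s2c
        }
      }
      if (nd) {
        Q[cbind(id, id)] <- Q[cbind(id, id)] + d_prec
        b[id] <- b[id] + d_loc * d_prec
      }
      if (nb) {
        Q[cbind(ib, ib)] <- Q[cbind(ib, ib)] + b_prec
        b[ib] <- b[ib] + b_loc * b_prec
      }
      R <- chol(Q)
      mean_u <- backsolve(R, forwardsolve(t(R), b))
      for (try in seq_len(1000L)) {
        u <- drop(mean_u + backsolve(R, stats::rnorm(dim_u)))
        v_new <- if (upd$v) u[iv] else v_cur
        dv_new <- dv
        if (nd) dv_new[d_free] <- u[id]
        if (!direct) break
        nu_new <- matrix(v_new, P, 4L) +
          matrix(c(0, dv_new), P, 4L, byrow = TRUE)
        if (all(nu_new[has] > 0)) break
        if (try == 1000L)
          stop("accretion block rejected 1000 proposals; the positivity ",
               "constraint is binding")
      }
      if (upd$v) v_cur <- v_new
      if (upd$dv) { dv <- dv_new; dv_full <- c(0, dv) }
      if (nb) { bv <- u[ib]; mu_v <- drop(X %*% bv) }
    }
    if (upd$sv) {
      ls_new <- log(sv) + exp(ls_sv) * stats::rnorm(1)
      sv_new <- exp(ls_new)
      lr <- {
        old <- re_logdens(v_cur, t_cur)
        sv_old <- sv; sv <- sv_new
        new <- re_logdens(v_cur, t_cur)
        sv <- sv_old
        new - old + halfnorm(sv_new, prior$sigma_scale) -
          halfnorm(sv, prior$sigma_scale) + ls_new - log(sv)
      }
      a <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a) sv <- sv_new
      acc["sigma"] <- acc["sigma"] + a; acc_n["sigma"] <- acc_n["sigma"] + 1
      if (adapting) ls_sv <- ls_sv + gam * (a - target)
    }

    ## ---- caution block: adaptive random-walk Metropolis; two sweeps
    ## per iteration, since these updates are the mixing bottleneck ----
    ll_rows <- rowSums(.ll_cells(ss, v_cur, t_cur, dv_full, dt_full, direct))
    for (sweep in 1:2) {
    if (upd$theta) {
      if (corr && rho != 0 && sv > 0) {
        mu_c <- mu_t + rho * st / sv * (v_cur - mu_v)
        sd_c <- st * sqrt(1 - rho^2)
      } else { mu_c <- mu_t; sd_c <- st }
      t_new <- t_cur + exp(ls_t) * stats::rnorm(P)
      ll_new <- rowSums(.ll_cells(ss, v_cur, t_new, dv_full, dt_full, direct))
      lr <- ll_new - ll_rows +
        stats::dnorm(t_new, mu_c, sd_c, log = TRUE) -
        stats::dnorm(t_cur, mu_c, sd_c, log = TRUE)
      a <- is.finite(lr) & log(stats::runif(P)) < lr
      t_cur[a] <- t_new[a]
      ll_rows[a] <- ll_new[a]
      acc["theta"] <- acc["theta"] + mean(a); acc_n["theta"] <- acc_n["theta"] + 1
      if (adapting) ls_t <- ls_t + gam * (a - target)
    }
    if (upd$dt) {
      for (j in 1:3) {
        c <- j + 1L
        if (!any(has[, c])) next
        dt_new <- dt; dt_new[j] <- dt[j] + exp(ls_dt[j]) * stats::rnorm(1)
        ll_new <- rowSums(.ll_cells(ss, v_cur, t_cur, dv_full,
                                    c(0, dt_new), direct))
        lr <- sum(ll_new) - sum(ll_rows) +
          (if (prior$flat) 0 else
            stats::dnorm(dt_new[j], d_loc, prior$delta_scale, log = TRUE) -
             stats::dnorm(dt[j], d_loc, prior$delta_scale, log = TRUE))
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) { dt <- dt_new; ll_rows <- ll_new }
        acc["delta_theta"] <- acc["delta_theta"] + a / 3
        acc_n["delta_theta"] <- acc_n["delta_theta"] + 1 / 3
        if (adapting) ls_dt[j] <- ls_dt[j] + gam * (a - target)
      }
      dt_full <- c(0, dt)
    }
    }
    if (upd$bt && st > 0) {
      if (corr && rho != 0 && sv > 0) {
        u <- t_cur - rho * st / sv * (v_cur - mu_v)
        s2 <- st^2 * (1 - rho^2)
      } else { u <- t_cur; s2 <- st^2 }
      Prec <- XtX / s2 + diag(b_prec, K1)
      R <- chol(Prec)
      mean_b <- backsolve(R, forwardsolve(t(R), crossprod(X, u) / s2 + b_loc * b_prec))
      bt <- drop(mean_b + backsolve(R, stats::rnorm(K1)))
      mu_t <- drop(X %*% bt)
    }
    if (upd$st) {
      ls_new <- log(st) + exp(ls_st) * stats::rnorm(1)
      st_new <- exp(ls_new)
      old <- re_logdens(v_cur, t_cur)
      st_old <- st; st <- st_new
      new <- re_logdens(v_cur, t_cur)
      st <- st_old
      lr <- new - old + halfnorm(st_new, prior$sigma_scale) -
        halfnorm(st, prior$sigma_scale) + ls_new - log(st)
      a <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a) st <- st_new
      if (adapting) ls_st <- ls_st + gam * (a - target)
    }
    if (upd$rho) {
      z <- atanh(rho)
      z_new <- z + exp(ls_rho) * stats::rnorm(1)
      rho_new <- tanh(z_new)
      old <- re_logdens(v_cur, t_cur)
      rho_old <- rho; rho <- rho_new
      new <- re_logdens(v_cur, t_cur)
      rho <- rho_old
      ## uniform prior on rho; Jacobian of the Fisher-z transform
      lr <- new - old + log1p(-rho_new^2) - log1p(-rho^2)
      a <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a) rho <- rho_new
      if (adapting) ls_rho <- ls_rho + gam * (a - target)
    }
    if (sv == 0) v_cur <- mu_v
    if (st == 0) t_cur <- mu_t

    if (it > sampler$warmup)
      out[it - sampler$warmup, ] <- c(bv, bt, sv, st, dv, dt,
                                      if (corr) rho, v_cur, t_cur)
  }
  colnames(out) <- labels
  list(draws = out,
       accept = ifelse(acc_n > 0, acc / acc_n, NA_real_))
}

## Parameter name registry for a data/model pair.
.param_labels <- function(data, model) {
  K <- colnames(data$X)
  c(paste0("beta_v[", K, "]"), paste0("beta_theta[", K, "]"),
    "sigma_v", "sigma_theta",
    paste0("delta_v[", .later_condition_labels, "]"),
    paste0("delta_theta[", .later_condition_labels, "]"),
    if (isTRUE(model$correlated_effects)) "rho",
    paste0("v[", data$persons, "]"),
    paste0("theta[", data$persons, "]"))
}
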