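# Exact jump-process simulation (Gillespie direct method) and Euler-Maruyama
# Langevin integration, with stationary estimators used to verify the LNA
# predictions and the designed perturbations.

# Compile the rate laws into a fast positional function of the dynamic state:
# parameters and boundary species are baked in as constants, hill() is
# expanded, and the result is byte-compiled.
make_rate_fun <- function(net, params = NULL) {
  pv <- param_values(net, params)
  dyn_ids <- net$species$id[!net$species$is_boundary]
  bnd <- net$species[net$species$is_boundary, , drop = FALSE]
  subst <- c(
    stats::setNames(lapply(seq_along(dyn_ids), function(i) bquote(x[.(i)])), dyn_ids),
    stats::setNames(as.list(bnd$initial_amount), bnd$id),
    as.list(pv)
  )
  exprs <- lapply(net$reactions, function(r) {
    do.call(substitute, list(expand_hill(r$rate), subst))
  })
  body <- as.call(c(as.name("c"), exprs))
  f <- eval(call("function", as.pairlist(alist(x = )), body), baseenv())
  compiler::cmpfun(f)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' @param net a Markov-jump [reaction_network()] with integer initial amounts.
#' @param structure optional [stoichiometric_decomposition()].
#' @param t_end simulation end time.
#' @param seed integer RNG seed (recorded in the output).
#' @param params optional parameter overrides.
#' @param max_steps safety cap on the number of reaction events.
#' @return object of class `trajectory`: `times` (event times, ending at
#'   `t_end`), `states` (matrix, one row per time, dynamic species columns),
#'   `seed`, `method = "ssa"`, and `absorbed` flag (TRUE when the total
#'   propensity hit zero before `t_end`).
#' @export
ssa_simulate <- function(net, structure = NULL, t_end, seed,
                         params = NULL, max_steps = 5e6) {
  stopifnot(net$kind == "markov-jump", t_end > 0)
  if (is.null(structure)) structure <- stoichiometric_decomposition(net)
  dyn_ids <- structure$species_ids
  x0 <- net$species$initial_amount[!net$species$is_boundary]
  if (any(x0 != round(x0))) stop("ssa requires integer initial amounts", call. = FALSE)
  ratefun <- make_rate_fun(net, params)
  N <- structure$N
  n_sp <- length(dyn_ids)
  n_rx <- ncol(N)
  set.seed(as.integer(seed))

  cap <- 65536L
  times <- numeric(cap)
  states <- matrix(0, cap, n_sp)
  x <- as.numeric(round(x0))
  t <- 0
  k <- 1L
  times[1L] <- 0
  states[1L, ] <- x
  absorbed <- FALSE

  for (step in seq_len(max_steps)) {
    a <- ratefun(x)
    if (any(a < 0) || any(!is.finite(a))) {
      stop("ssa: negative or non-finite propensity encountered", call. = FALSE)
    }
    a0 <- sum(a)
    if (a0 <= 0) { absorbed <- TRUE; break }
    t <- t + stats::rexp(1L, a0)
    if (t > t_end) break
    j <- 1L + sum(stats::runif(1L) * a0 > cumsum(a))
    if (j > n_rx) j <- n_rx
    x <- x + N[, j]
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      times <- c(times, numeric(cap / 2L))
      states <- rbind(states, matrix(0, cap / 2L, n_sp))
    }
    times[k] <- t
    states[k, ] <- x
  }

  # close the trajectory at t_end (state holds constant after the last event)
  k <- k + 1L
  if (k > cap) { times <- c(times, 0); states <- rbind(states, 0) }
  times[k] <- t_end
  states[k, ] <- x

  out <- list(times = times[seq_len(k)],
              states = `colnames<-`(states[seq_len(k), , drop = FALSE], dyn_ids),
              seed = as.integer(seed), method = "ssa", absorbed = absorbed,
              t_end = t_end)
  class(out) <- "trajectory"
  out
}

#' Euler-Maruyama integration of a Langevin network
#'
#' Drift is the deterministic rate equation `N v(x)`; noise increments are
#' Gaussian with covariance `D dt`, where `D` is the network's explicit
#' diffusion matrix over the dynamic species.
#'
#' @param net a Langevin [reaction_network()].
#' @param t_end end time.
#' @param dt time step.
#' @param seed integer RNG seed.
#' @param params optional parameter overrides.
#' @param record_every record every k-th step (default 1).
#' @return object of class `trajectory` with `method = "langevin"`.
#' @export
langevin_simulate <- function(net, t_end, dt, seed, params = NULL,
                              record_every = 1L) {
  stopifnot(net$kind == "langevin", dt > 0, t_end > dt)
  structure <- stoichiometric_decomposition(net)
  dyn_ids <- structure$species_ids
  ratefun <- make_rate_fun(net, params)
  N <- structure$N
  D <- net$diffusion[dyn_ids, dyn_ids, drop = FALSE]
  ed <- eigen((D + t(D)) / 2, symmetric = TRUE)
  B <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nrow = nrow(D))
  set.seed(as.integer(seed))

  n_steps <- ceiling(t_end / dt)
  n_rec <- floor(n_steps / record_every) + 1L
  times <- numeric(n_rec)
  states <- matrix(0, n_rec, length(dyn_ids))
  x <- net$species$initial_amount[!net$species$is_boundary]
  times[1L] <- 0
  states[1L, ] <- x
  r <- 1L
  sq <- sqrt(dt)
  for (step in seq_len(n_steps)) {
    drift <- as.numeric(N %*% ratefun(x))
    x <- x + drift * dt + as.numeric(B %*% stats::rnorm(nrow(D))) * sq
    if (any(!is.finite(x))) {
      stop(sprintf("langevin integration blew up at t = %.4g", step * dt),
           call. = FALSE)
    }
    if (step %% record_every == 0L) {
      r <- r + 1L
      times[r] <- step * dt
      states[r, ] <- x
    }
  }
  out <- list(times = times[seq_len(r)],
              states = `colnames<-`(states[seq_len(r), , drop = FALSE], dyn_ids),
              seed = as.integer(seed), method = "langevin", absorbed = FALSE,
              t_end = t_end)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d records to t = %.4g (seed %d)\n",
              x$method, length(x$times), x$t_end, x$seed))
  invisible(x)
}

#' Stationary statistics from a trajectory
#'
#' Time-weighted means and covariances over the post-burn-in segment, noise
#' levels, autocorrelations estimated by lagged products on a resampled
#' uniform grid, and batch-means standard errors.
#'
#' @param traj a `trajectory`.
#' @param burn_in_fraction fraction of `t_end` discarded as burn-in.
#' @param lag_grid optional nonnegative lags at which to estimate the
#'   normalized autocorrelation.
#' @param n_batches number of equal-time batches for standard errors.
#' @param n_grid number of uniform resampling points.
#' @return object of class `stationary_stats` with `mean`, `cov`,
#'   `noise_level`, `se_mean`, `se_noise`, and (when `lag_grid` is given)
#'   `autocorr` (list with `lags`, `A` matrix lag x species, `se`).
#' @export
stationary_statistics <- function(traj, burn_in_fraction = 0.2, lag_grid = NULL,
                                  n_batches = 32L, n_grid = 2^14) {
  t0 <- burn_in_fraction * traj$t_end
  keep <- traj$times >= t0
  if (sum(keep) < 2L) stop("trajectory shorter than burn-in", call. = FALSE)
  ids <- colnames(traj$states)

  # resample the (right-continuous) step function on a uniform grid; all
  # estimators below use this grid, which makes time weighting uniform.
  # the grid is refined so the smallest requested lag spans >= 4 grid steps.
  if (!is.null(lag_grid) && any(lag_grid > 0)) {
    dt_target <- min(lag_grid[lag_grid > 0]) / 4
    n_grid <- min(max(n_grid, ceiling((traj$t_end - t0) / dt_target)), 2^20)
  }
  tg <- seq(t0, traj$t_end, length.out = n_grid)
  idx <- findInterval(tg, traj$times)
  Y <- traj$states[idx, , drop = FALSE]

  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  Cv <- crossprod(Yc) / nrow(Y)
  dimnames(Cv) <- list(ids, ids)
  eta <- Cv / outer(mu, mu)
  eta[!is.finite(eta)] <- NA_real_

  batch <- cut(seq_len(n_grid), breaks = n_batches, labels = FALSE)
  bmeans <- apply(Y, 2, function(col) tapply(col, batch, mean))
  se_mean <- apply(bmeans, 2, stats::sd) / sqrt(n_batches)
  bnoise <- sapply(ids, function(s) {
    tapply(Y[, s], batch, function(col) stats::var(col) / mean(col)^2)
  })
  se_noise <- apply(bnoise, 2, function(col) {
    if (any(!is.finite(col))) NA_real_ else stats::sd(col) / sqrt(n_batches)
  })
  if (n_batches < 20L) {
    warning("fewer than 20 batches: standard errors reported as missing")
    se_mean[] <- NA_real_
    se_noise[] <- NA_real_
  }

  out <- list(mean = mu, cov = Cv, noise_level = eta,
              se_mean = se_mean, se_noise = se_noise,
              n_batches = n_batches, burn_in_fraction = burn_in_fraction)

  if (!is.null(lag_grid)) {
    dtg <- tg[2] - tg[1]
    ks <- pmin(round(lag_grid / dtg), n_grid - 2L)
    A <- matrix(NA_real_, length(lag_grid), length(ids),
                dimnames = list(NULL, ids))
    se_A <- A
    v0 <- apply(Y, 2, stats::var)
    for (li in seq_along(ks)) {
      k <- ks[li]
      for (s in seq_along(ids)) {
        if (!is.finite(v0[s]) || v0[s] <= 0) next  # constant: undefined, stays NA
        y <- Yc[, s]
        n <- n_grid - k
        A[li, s] <- mean(y[seq_len(n)] * y[seq_len(n) + k]) / v0[s]
        bidx <- cut(seq_len(n), breaks = n_batches, labels = FALSE)
        prods <- y[seq_len(n)] * y[seq_len(n) + k]
        bvals <- tapply(prods, bidx, mean) / v0[s]
        se_A[li, s] <- stats::sd(bvals) / sqrt(n_batches)
      }
    }
    out$autocorr <- list(lags = lag_grid, A = A, se = se_A)
  }
  class(out) <- "stationary_stats"
  out
}

#' @export
print.stationary_stats <- function(x, ...) {
  cat("<stationary_stats>\n")
  for (s in names(x$mean)) {
    cat(sprintf("  %-10s mean %9.4g (+/- %.2g)  noise %9.4g (+/- %.2g)\n",
                s, x$mean[[s]], x$se_mean[[s]],
                x$noise_level[s, s], x$se_noise[[s]]))
  }
  invisible(x)
}
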