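# Linear noise approximation engine: deterministic steady state, Jacobian and
# diffusion matrices, stationary covariance via the Lyapunov (fluctuation-
# dissipation) equation, noise levels, and lagged autocovariances.

#' Solve for the deterministic steady state
#'
#' Damped Newton iteration (with positivity-preserving line search) on the
#' independent species, falling back to relaxation by integrating the rate
#' equations when Newton stalls. Conservation totals are preserved exactly
#' because the iteration lives in the independent-species space and the full
#' state is reconstructed through the link matrix.
#'
#' @param net a [reaction_network()].
#' @param structure its [stoichiometric_decomposition()].
#' @param initial_guess optional starting amounts (full or dynamic species);
#'   defaults to the declared initial amounts.
#' @param params optional parameter values overriding the model's.
#' @param tol relative residual tolerance on the reduced balance equations.
#' @return list with `x_star` (all species, boundary included), `v_star`,
#'   and the residual norm.
#' @export
solve_steady_state <- function(net, structure, initial_guess = NULL,
                               params = NULL, tol = 1e-10) {
  pv <- param_values(net, params)
  x_full0 <- if (is.null(initial_guess)) {
    stats::setNames(net$species$initial_amount, net$species$id)
  } else {
    full_state(net, initial_guess)
  }
  dyn_ids <- structure$species_ids
  ind_ids <- structure$independent
  L <- structure$L
  N_R <- structure$N_R
  x_dyn0 <- x_full0[dyn_ids]

  lift <- function(x_ind) {
    x <- x_dyn0 + as.numeric(L %*% (x_ind - x_dyn0[ind_ids]))
    stats::setNames(x, dyn_ids)
  }
  assemble <- function(x_dyn) {
    out <- x_full0
    out[dyn_ids] <- x_dyn
    out
  }
  resid <- function(x_ind) {
    v <- evaluate_rates(net, assemble(lift(x_ind)), pv)
    as.numeric(N_R %*% v)
  }

  if (nrow(N_R) == 0L) {
    x_star <- x_full0
    v_star <- evaluate_rates(net, x_star, pv)
    return(list(x_star = x_star, v_star = v_star, residual = 0))
  }

  newton <- function(x_ind, max_iter = 100L) {
    for (it in seq_len(max_iter)) {
      x_dyn <- lift(x_ind)
      v <- evaluate_rates(net, assemble(x_dyn), pv)
      f <- as.numeric(N_R %*% v)
      scale <- max(1, sqrt(sum(v^2)))
      if (sqrt(sum(f^2)) < tol * scale) {
        return(list(x_ind = x_ind, converged = TRUE))
      }
      d <- rate_derivatives(net, assemble(x_dyn), pv, what = "dvdx")
      M <- N_R %*% d$dvdx %*% L
      step <- tryCatch(-solve(M, f), error = function(e) NULL)
      if (is.null(step)) return(list(x_ind = x_ind, converged = FALSE))
      lam <- 1
      f0 <- sum(f^2)
      repeat {
        x_new <- x_ind + lam * step
        if (all(lift(x_new) >= 0)) {
          f_new <- tryCatch(sum(resid(x_new)^2), error = function(e) Inf)
          if (f_new < f0 || f_new < (tol * scale)^2) break
        }
        lam <- lam / 2
        if (lam < 1e-10) return(list(x_ind = x_ind, converged = FALSE))
      }
      x_ind <- x_ind + lam * step
    }
    list(x_ind = x_ind, converged = sqrt(sum(resid(x_ind)^2)) < tol)
  }

  x_ind <- x_dyn0[ind_ids]
  sol <- newton(x_ind)
  if (!sol$converged) {
    # relaxation fallback: integrate the rate equations toward stationarity
    rhs <- function(t, y, parms) {
      x <- assemble(stats::setNames(pmax(y, 0), dyn_ids))
      v <- evaluate_rates(net, x, pv)
      list(as.numeric(structure$N %*% v))
    }
    y <- x_dyn0
    t_span <- 10
    for (k in 1:12) {
      out <- deSolve::ode(y = y, times = c(0, t_span), func = rhs, parms = NULL,
                          method = "lsoda")
      y <- stats::setNames(pmax(out[nrow(out), -1L], 0), dyn_ids)
      sol <- newton(y[ind_ids])
      if (sol$converged) break
      t_span <- t_span * 4
    }
    if (!sol$converged) {
      stop(sprintf("steady-state solver did not converge (residual %.3e)",
                   sqrt(sum(resid(sol$x_ind)^2))), call. = FALSE)
    }
  }

  x_dyn <- lift(sol$x_ind)
  x_star <- assemble(x_dyn)
  v_star <- evaluate_rates(net, x_star, pv)
  list(x_star = x_star, v_star = v_star,
       residual = sqrt(sum((N_R %*% v_star)^2)))
}

#' Linearize the dynamics at a steady state
#'
#' Returns the reduced Jacobian `A = N_R (dv/dx) L` and the diffusion matrix
#' `D` of the independent species: `N_R diag(v*) N_R^T` for Markov jump
#' networks, or the model's explicit diffusion specification (restricted to
#' the independent species) for Langevin networks.
#'
#' @inheritParams solve_steady_state
#' @param x_star steady-state amounts (all species).
#' @return list with matrices `A` and `D`.
#' @export
linearize <- function(net, structure, x_star, params = NULL) {
  pv <- param_values(net, params)
  d <- rate_derivatives(net, x_star, pv, what = "dvdx")
  A <- structure$N_R %*% d$dvdx %*% structure$L
  if (net$kind == "markov-jump") {
    v <- evaluate_rates(net, x_star, pv)
    D <- structure$N_R %*% diag(v, nrow = length(v)) %*% t(structure$N_R)
  } else {
    D <- net$diffusion[structure$independent, structure$independent, drop = FALSE]
  }
  dimnames(A) <- list(structure$independent, structure$independent)
  dimnames(D) <- dimnames(A)
  list(A = A, D = D)
}

assert_hurwitz <- function(A, where = "Lyapunov solve") {
  if (nrow(A) == 0L) return(invisible(TRUE))
  re <- max(Re(eigen(A, only.values = TRUE)$values))
  if (!is.finite(re) || re >= 0) {
    stop(sprintf("%s: steady state is not stable (max Re eigenvalue %.3e >= 0)",
                 where, re), call. = FALSE)
  }
  invisible(TRUE)
}

#' Solve the stationary Lyapunov equation
#'
#' Solves `A C + C A^T + D = 0` for the independent-species covariance by a
#' direct dense (Kronecker) linear solve, then lifts to all dynamic species
#' through the link matrix, `C = L C_ind L^T`. The residual is checked to
#' `1e-10 * ||D||` and negative covariance eigenvalues beyond `-1e-9` (relative)
#' are treated as errors.
#'
#' @param A reduced Jacobian (must be Hurwitz).
#' @param D reduced diffusion matrix (symmetric PSD).
#' @param structure the [stoichiometric_decomposition()] used for lifting.
#' @return covariance matrix over the dynamic species.
#' @export
solve_lyapunov <- function(A, D, structure) {
  assert_hurwitz(A)
  C_ind <- lyapunov_ind(A, D)
  nrmD <- max(norm(D, "F"), .Machine$double.eps)
  res <- norm(A %*% C_ind + C_ind %*% t(A) + D, "F")
  if (res > 1e-10 * max(1, nrmD)) {
    stop(sprintf("Lyapunov residual too large (%.3e)", res), call. = FALSE)
  }
  ev <- eigen(C_ind, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (length(ev) && min(ev) < -1e-9 * scale) {
    stop(sprintf("covariance is not positive semidefinite (min eig %.3e)", min(ev)),
         call. = FALSE)
  }
  C <- structure$L %*% C_ind %*% t(structure$L)
  C <- (C + t(C)) / 2
  dimnames(C) <- list(structure$species_ids, structure$species_ids)
  C
}

# A C + C A^T = -D  in the independent space, via vec() and a Kronecker solve.
lyapunov_ind <- function(A, D) {
  n <- nrow(A)
  if (n == 0L) return(matrix(0, 0, 0))
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  C <- matrix(solve(K, -as.numeric(D)), n, n)
  (C + t(C)) / 2
}

#' Noise levels from covariance and means
#'
#' The noise level is the covariance divided by the product of the two mean
#' values, `eta_ij = C_ij / (x_i* x_j*)` (the squared coefficient of variation
#' on the diagonal).
#'
#' @param C covariance over the dynamic species.
#' @param x_star steady-state amounts (named; only the species appearing in
#'   `C`'s dimnames are used).
#' @return matrix `eta` with the same dimnames as `C`.
#' @export
noise_levels <- function(C, x_star) {
  ids <- rownames(C)
  x <- x_star[ids]
  if (any(!is.finite(x)) || any(x <= 0)) {
    bad <- ids[!is.finite(x) | x <= 0][1L]
    stop(sprintf("noise level undefined: species '%s' has non-positive mean", bad),
         call. = FALSE)
  }
  C / outer(x, x)
}

#' Stationary autocovariance / autocorrelation curves
#'
#' Computes the lagged covariance `R(tau) = exp(A tau) C_ind`, lifted to all
#' dynamic species, and the normalized same-species autocorrelations
#' `A_ii(tau) = R_ii(tau) / C_ii`. The reference route is the matrix
#' exponential on the lag grid; `autocorrelation_ode()` integrates the
#' equivalent linear matrix ODE `dR/dtau = A R`, `R(0) = C_ind` as a
#' cross-check.
#'
#' @param A reduced Jacobian (Hurwitz).
#' @param C covariance over dynamic species (from [solve_lyapunov()]).
#' @param structure the [stoichiometric_decomposition()].
#' @param lags increasing nonnegative lag grid.
#' @return object of class `autocorr_curve`: `lags`, `R` (species x species x
#'   lag array) and `A_norm` (lag x species matrix of normalized same-species
#'   autocorrelations).
#' @export
autocorrelation <- function(A, C, structure, lags) {
  stopifnot(all(diff(lags) > 0) || length(lags) <= 1L, all(lags >= 0))
  assert_hurwitz(A, "autocorrelation")
  ind <- structure$independent
  ids <- structure$species_ids
  C_ind <- C[ind, ind, drop = FALSE]
  L <- structure$L
  n <- length(ids)
  R <- array(NA_real_, c(n, n, length(lags)), dimnames = list(ids, ids, NULL))
  for (k in seq_along(lags)) {
    Rk <- L %*% (expm_mat(A * lags[k]) %*% C_ind) %*% t(L)
    R[, , k] <- Rk
  }
  d0 <- diag(C[ids, ids, drop = FALSE])
  A_norm <- matrix(NA_real_, length(lags), n, dimnames = list(NULL, ids))
  pos <- d0 > 0
  for (k in seq_along(lags)) {
    Rk <- matrix(R[, , k], n, n)
    A_norm[k, pos] <- diag(Rk)[pos] / d0[pos]
  }
  out <- list(lags = lags, R = R, A_norm = A_norm)
  class(out) <- "autocorr_curve"
  out
}

expm_mat <- function(M) {
  if (nrow(M) == 1L) return(matrix(exp(M[1, 1]), 1, 1, dimnames = dimnames(M)))
  as.matrix(Matrix::expm(M))
}

# ODE cross-check route for the lagged covariance (independent species only).
autocorrelation_ode <- function(A, C_ind, lags) {
  n <- nrow(A)
  rhs <- function(t, y, parms) list(as.numeric(A %*% matrix(y, n, n)))
  times <- if (lags[1] == 0) lags else c(0, lags)
  out <- deSolve::ode(y = as.numeric(C_ind), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  keep <- match(lags, out[, 1L])
  lapply(keep, function(k) matrix(out[k, -1L], n, n))
}

#' Full LNA analysis pipeline
#'
#' Convenience wrapper chaining [stoichiometric_decomposition()],
#' [solve_steady_state()], [linearize()], [solve_lyapunov()],
#' [noise_levels()] and optionally [autocorrelation()].
#'
#' @param net a [reaction_network()].
#' @param lags optional lag grid for autocorrelations.
#' @param params optional parameter overrides.
#' @param structure optional precomputed decomposition.
#' @return object of class `lna_fit` with `structure`, `x_star`, `v_star`,
#'   `A`, `D`, `C`, `eta` and (when `lags` given) `curve`.
#' @export
lna_analysis <- function(net, lags = NULL, params = NULL, structure = NULL) {
  if (is.null(structure)) structure <- stoichiometric_decomposition(net)
  ss <- solve_steady_state(net, structure, params = params)
  lin <- linearize(net, structure, ss$x_star, params = params)
  assert_hurwitz(lin$A, "steady state")
  C <- solve_lyapunov(lin$A, lin$D, structure)
  eta <- noise_levels(C, ss$x_star)
  out <- list(net = net, structure = structure,
              x_star = ss$x_star, v_star = ss$v_star, residual = ss$residual,
              A = lin$A, D = lin$D, C = C, eta = eta)
  if (!is.null(lags)) out$curve <- autocorrelation(lin$A, C, structure, lags)
  class(out) <- "lna_fit"
  out
}

#' @export
print.lna_fit <- function(x, ...) {
  cat(sprintf("<lna_fit '%s'>\n", x$net$name))
  dyn <- x$structure$species_ids
  cat("  steady state:\n")
  for (id in dyn) {
    cat(sprintf("    %-10s mean %10.4g   noise level %10.4g\n",
                id, x$x_star[[id]], x$eta[id, id]))
  }
  invisible(x)
}
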