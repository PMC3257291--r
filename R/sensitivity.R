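# Control coefficients (CCs): scaled and unscaled parametric sensitivities of
# stationary means, covariances, noise levels and normalized autocorrelations.
#
# The mean sensitivities follow the classical concentration control pattern
# dx*/dp = -L (N_R J L)^{-1} N_R dv/dp. Covariance sensitivities come from
# differentiating the stationary Lyapunov equation: the perturbation dC/dp
# solves a second Lyapunov equation with inhomogeneity dA C + C dA^T + dD,
# where dA and dD carry both the explicit parameter dependence and the
# implicit dependence through the shifted steady state. Autocorrelation
# sensitivities integrate the variational equation of dR/dtau = A R.

#' Control coefficients of stationary means
#'
#' @param net a [reaction_network()].
#' @param structure its [stoichiometric_decomposition()].
#' @param steady an [lna_analysis()] fit (or any list with `x_star`).
#' @param parameters parameter ids to differentiate against (default: all).
#' @return list with `unscaled` and `scaled` (species x parameter matrices;
#'   scaled entries are `(p/x) dx/dp`, `NA` where the mean vanishes).
#' @export
mean_ccs <- function(net, structure, steady, parameters = NULL) {
  pv <- param_values(net)
  par_ids <- if (is.null(parameters)) names(pv) else parameters
  d <- rate_derivatives(net, steady$x_star, pv)
  M <- structure$N_R %*% d$dvdx %*% structure$L
  rhs <- structure$N_R %*% d$dvdp[, par_ids, drop = FALSE]
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("mean control coefficients: reduced Jacobian is singular (degenerate steady state)",
         call. = FALSE)
  })
  unscaled <- -structure$L %*% sol
  dimnames(unscaled) <- list(structure$species_ids, par_ids)
  x <- steady$x_star[structure$species_ids]
  scaled <- sweep(unscaled, 2, pv[par_ids], `*`) / ifelse(abs(x) > 0, x, NA_real_)
  list(unscaled = unscaled, scaled = scaled)
}

# dA/dx_k and dA/dp_j by central finite differences of the analytic first
# derivatives (relative step 1e-6): keeps the symbolic layer first-order only.
jacobian_partials <- function(net, structure, x_star, pv, par_ids) {
  A_at <- function(state, params) {
    d <- rate_derivatives(net, state, params, what = "dvdx")
    structure$N_R %*% d$dvdx %*% structure$L
  }
  dyn_ids <- structure$species_ids
  dA_dx <- lapply(dyn_ids, function(s) {
    h <- 1e-6 * max(abs(x_star[[s]]), 1)
    xp <- x_star; xp[[s]] <- x_star[[s]] + h
    xm <- x_star; xm[[s]] <- x_star[[s]] - h
    (A_at(xp, pv) - A_at(xm, pv)) / (2 * h)
  })
  names(dA_dx) <- dyn_ids
  dA_dp <- lapply(par_ids, function(p) {
    h <- 1e-6 * pv[[p]]
    pp <- pv; pp[[p]] <- pv[[p]] + h
    pm <- pv; pm[[p]] <- pv[[p]] - h
    (A_at(x_star, pp) - A_at(x_star, pm)) / (2 * h)
  })
  names(dA_dp) <- par_ids
  list(dA_dx = dA_dx, dA_dp = dA_dp)
}

#' Control coefficients of the stationary covariance
#'
#' Differentiates the stationary Lyapunov equation parameter by parameter and
#' solves the perturbed equation `A dC + dC A^T = -(dA C + C dA^T + dD)` in the
#' independent-species space.
#'
#' @inheritParams mean_ccs
#' @param mean the output of [mean_ccs()].
#' @return list with `unscaled` and `scaled` 3-index arrays (species, species,
#'   parameter), plus `dA` and `dC_ind` kept for downstream autocorrelation
#'   sensitivities.
#' @export
covariance_ccs <- function(net, structure, steady, mean, parameters = NULL) {
  pv <- param_values(net)
  par_ids <- colnames(mean$unscaled)
  if (!is.null(parameters)) par_ids <- parameters
  ids <- structure$species_ids
  ind <- structure$independent
  n <- length(ids)
  A <- steady$A
  C_ind <- steady$C[ind, ind, drop = FALSE]
  d <- rate_derivatives(net, steady$x_star, pv)
  v <- if (net$kind == "markov-jump") evaluate_rates(net, steady$x_star, pv) else NULL
  jp <- jacobian_partials(net, structure, steady$x_star, pv, par_ids)

  unscaled <- array(0, c(n, n, length(par_ids)), dimnames = list(ids, ids, par_ids))
  dA_list <- vector("list", length(par_ids))
  names(dA_list) <- par_ids
  dC_ind_list <- dA_list

  for (j in seq_along(par_ids)) {
    p <- par_ids[j]
    dxdp <- stats::setNames(mean$unscaled[, p], rownames(mean$unscaled))
    dA <- jp$dA_dp[[p]]
    for (s in ids) dA <- dA + jp$dA_dx[[s]] * dxdp[[s]]
    if (net$kind == "markov-jump") {
      dv <- d$dvdp[, p] + as.numeric(d$dvdx %*% dxdp)
      dD <- structure$N_R %*% diag(dv, nrow = length(dv)) %*% t(structure$N_R)
    } else {
      dD <- matrix(0, nrow(A), nrow(A))
    }
    rhs <- dA %*% C_ind + C_ind %*% t(dA) + dD
    dC_ind <- lyapunov_ind(A, rhs)
    dA_list[[p]] <- dA
    dC_ind_list[[p]] <- dC_ind
    unscaled[, , j] <- structure$L %*% dC_ind %*% t(structure$L)
  }

  Cfull <- steady$C[ids, ids, drop = FALSE]
  denom <- ifelse(abs(Cfull) > 1e-12 * max(abs(Cfull), 1), Cfull, NA_real_)
  scaled <- unscaled
  for (j in seq_along(par_ids)) {
    scaled[, , j] <- pv[[par_ids[j]]] * unscaled[, , j] / denom
  }
  list(unscaled = unscaled, scaled = scaled, dA = dA_list, dC_ind = dC_ind_list)
}

#' Control coefficients of noise levels
#'
#' Chain rule on `eta_ij = C_ij / (x_i x_j)`:
#' `d(eta)/dp = dC/dp / (x_i x_j) - eta_ij (dx_i/dp / x_i + dx_j/dp / x_j)`.
#'
#' @param steady an [lna_analysis()] fit.
#' @param mean output of [mean_ccs()].
#' @param covariance output of [covariance_ccs()].
#' @return list with `unscaled` and `scaled` arrays (species, species,
#'   parameter); scaled entries are `NA` (flagged missing) where `eta = 0`.
#' @export
noise_ccs <- function(steady, mean, covariance) {
  ids <- rownames(mean$unscaled)
  par_ids <- colnames(mean$unscaled)
  x <- steady$x_star[ids]
  if (any(x <= 0)) {
    stop(sprintf("noise control coefficients need strictly positive means ('%s')",
                 ids[x <= 0][1L]), call. = FALSE)
  }
  eta <- steady$eta[ids, ids, drop = FALSE]
  pv <- param_values(steady$net)[par_ids]
  n <- length(ids)
  unscaled <- array(0, c(n, n, length(par_ids)), dimnames = list(ids, ids, par_ids))
  scaled <- unscaled
  xx <- outer(x, x)
  for (j in seq_along(par_ids)) {
    rel <- outer(mean$unscaled[, j] / x, mean$unscaled[, j] / x, `+`)
    unscaled[, , j] <- covariance$unscaled[, , j] / xx - eta * rel
    scaled[, , j] <- pv[[j]] * unscaled[, , j] / ifelse(eta != 0, eta, NA_real_)
  }
  list(unscaled = unscaled, scaled = scaled)
}

#' Control coefficients of normalized autocorrelations
#'
#' For each parameter the lagged-covariance perturbation solves the variational
#' system `d(dR)/dtau = A dR + dA R`, `dR(0) = dC`, integrated in closed form
#' through the exponential of the block matrix `[[A, 0], [dA, A]]`. CCs of the
#' normalized same-species autocorrelation `A_ii(tau) = R_ii(tau)/C_ii` follow
#' by the quotient rule and are scaled by `p / A_ii` where `|A_ii| > 1e-6`;
#' lags where the autocorrelation is smaller than that are flagged and the
#' scaled value is left `NA` (the unscaled value is always available).
#'
#' @inheritParams mean_ccs
#' @param covariance output of [covariance_ccs()] (carries `dA`, `dC_ind`).
#' @param lags nonnegative increasing lag grid.
#' @return list with `lags`, `unscaled` and `scaled` arrays (lag, species,
#'   parameter) and a logical `flagged` array marking near-zero denominators.
#' @export
autocorr_ccs <- function(net, structure, steady, covariance, lags) {
  ind <- structure$independent
  ids <- structure$species_ids
  par_ids <- names(covariance$dA)
  pv <- param_values(net)[par_ids]
  A <- steady$A
  C_ind <- steady$C[ind, ind, drop = FALSE]
  L <- structure$L
  m <- nrow(A)
  n <- length(ids)
  d0 <- diag(steady$C[ids, ids, drop = FALSE])

  curve <- autocorrelation(A, steady$C, structure, lags)
  unscaled <- array(NA_real_, c(length(lags), n, length(par_ids)),
                    dimnames = list(NULL, ids, par_ids))
  scaled <- unscaled
  flagged <- array(FALSE, dim(unscaled), dimnames = dimnames(unscaled))

  for (j in seq_along(par_ids)) {
    p <- par_ids[j]
    dA <- covariance$dA[[p]]
    dC_ind <- covariance$dC_ind[[p]]
    dCfull <- matrix(covariance$unscaled[, , j], n, n)
    B <- rbind(cbind(A, matrix(0, m, m)), cbind(dA, A))
    Y0 <- rbind(C_ind, dC_ind)
    for (k in seq_along(lags)) {
      Y <- expm_mat(B * lags[k]) %*% Y0
      dR_ind <- Y[(m + 1):(2 * m), , drop = FALSE]
      dR <- L %*% dR_ind %*% t(L)
      Rk <- matrix(curve$R[, , k], n, n)
      for (i in seq_len(n)) {
        if (d0[i] <= 0) next
        dAn <- (dR[i, i] * d0[i] - Rk[i, i] * dCfull[i, i]) / d0[i]^2
        unscaled[k, i, j] <- dAn
        An <- curve$A_norm[k, i]
        if (is.finite(An) && abs(An) > 1e-6) {
          scaled[k, i, j] <- pv[[p]] * dAn / An
        } else {
          flagged[k, i, j] <- TRUE
        }
      }
    }
  }
  # dA/d(ln p): relative-parameter sensitivity without the 1/A_norm factor;
  # well-defined at every lag (no blow-up near zero crossings)
  logp <- unscaled
  for (j in seq_along(par_ids)) logp[, , j] <- pv[[par_ids[j]]] * unscaled[, , j]
  list(lags = lags, unscaled = unscaled, scaled = scaled, logp = logp,
       flagged = flagged, curve = curve)
}

#' Compute the full control-coefficient set
#'
#' Chains [mean_ccs()], [covariance_ccs()], [noise_ccs()] and (when `lags` is
#' given) [autocorr_ccs()] on an LNA fit.
#'
#' @param fit an [lna_analysis()] fit, or a [reaction_network()] (analyzed
#'   on the fly).
#' @param lags optional lag grid for autocorrelation CCs.
#' @param parameters parameter ids to differentiate against (default: all).
#' @return object of class `cc_set`.
#' @export
control_coefficients <- function(fit, lags = NULL, parameters = NULL) {
  if (inherits(fit, "reaction_network")) fit <- lna_analysis(fit, lags = lags)
  net <- fit$net
  str <- fit$structure
  mean <- mean_ccs(net, str, fit, parameters = parameters)
  covv <- covariance_ccs(net, str, fit, mean, parameters = parameters)
  noise <- noise_ccs(fit, mean, covv)
  out <- list(parameter_ids = colnames(mean$unscaled),
              species_ids = rownames(mean$unscaled),
              rate_parameters = intersect(net$rate_parameters, colnames(mean$unscaled)),
              mean = mean, covariance = covv, noise = noise, fit = fit)
  if (!is.null(lags)) {
    out$autocorr <- autocorr_ccs(net, str, fit, covv, lags)
  }
  class(out) <- "cc_set"
  out
}

#' @export
print.cc_set <- function(x, ...) {
  cat(sprintf("<cc_set '%s'> %d species x %d parameters\n",
              x$fit$net$name, length(x$species_ids), length(x$parameter_ids)))
  cat("scaled mean CCs:\n")
  print(round(x$mean$scaled, 4))
  cat("scaled noise CCs (diagonal):\n")
  diag_noise <- t(sapply(x$species_ids, function(s) x$noise$scaled[s, s, ]))
  colnames(diag_noise) <- x$parameter_ids
  print(round(diag_noise, 4))
  invisible(x)
}

#' Summation-theorem residuals
#'
#' Sums scaled CCs over the network's rate parameters; invariance of the
#' stationary state under a uniform rescaling of time forces these sums to
#' zero for means and noise levels.
#'
#' @param ccs a `cc_set`.
#' @return list with `mean` (per species) and `noise` (per species pair) sums.
#' @export
cc_summation <- function(ccs) {
  rp <- ccs$rate_parameters
  mean_sum <- rowSums(ccs$mean$scaled[, rp, drop = FALSE])
  noise_sum <- apply(ccs$noise$scaled[, , rp, drop = FALSE], c(1, 2), sum)
  list(mean = mean_sum, noise = noise_sum)
}

#' Finite-difference oracle for control coefficients
#'
#' Recomputes the full pipeline (steady state, Lyapunov solve, noise levels or
#' autocorrelations) at log-perturbed parameters `p (1 +/- step)` and forms
#' central differences of the scaled sensitivities. This is a brute-force
#' reference route, fully independent of the analytic CC computations.
#'
#' @param net a [reaction_network()].
#' @param structure its [stoichiometric_decomposition()].
#' @param target `"mean"`, `"noise"` or `"autocorr"`.
#' @param step relative perturbation in (0, 0.1].
#' @param lags lag grid (required for `target = "autocorr"`).
#' @param parameters parameter ids (default: all).
#' @return scaled CC array shaped like the corresponding analytic output.
#' @export
finite_difference_ccs <- function(net, structure, target = c("mean", "noise", "autocorr"),
                                  step = 1e-4, lags = NULL, parameters = NULL) {
  target <- match.arg(target)
  stopifnot(step > 0, step <= 0.1)
  pv <- param_values(net)
  par_ids <- if (is.null(parameters)) names(pv) else parameters
  if (target == "autocorr" && is.null(lags)) stop("autocorr oracle needs lags", call. = FALSE)

  observe <- function(params) {
    fit <- tryCatch(
      lna_analysis(net, lags = if (target == "autocorr") lags else NULL,
                   params = params, structure = structure),
      error = function(e) stop(sprintf("oracle: perturbed system failed (%s)",
                                       conditionMessage(e)), call. = FALSE))
    switch(target,
           mean = fit$x_star[structure$species_ids],
           noise = fit$eta,
           autocorr = fit$curve$A_norm)
  }

  base <- observe(pv)
  out <- NULL
  for (j in seq_along(par_ids)) {
    pp <- pv; pp[[par_ids[j]]] <- pv[[par_ids[j]]] * (1 + step)
    pm <- pv; pm[[par_ids[j]]] <- pv[[par_ids[j]]] * (1 - step)
    diff <- (observe(pp) - observe(pm)) / (2 * step)
    cc <- diff / ifelse(base != 0, base, NA_real_)
    if (is.null(out)) {
      out <- array(NA_real_, c(dim(as.array(cc)), length(par_ids)),
                   dimnames = c(dimnames(as.array(cc)), list(par_ids)))
    }
    if (target == "mean") out[, j] <- cc else out[, , j] <- cc
  }
  out
}
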