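# Control design: turn control coefficients into perturbation directions.
# All perturbations live in relative (log) parameter space: a direction u
# paired with scaled CCs, applied multiplicatively as p -> p (1 + lambda u).

#' Extract a control vector
#'
#' The control vector of a system variable is its vector of scaled control
#' coefficients across a chosen parameter subset; parameter perturbations
#' perpendicular to it leave the variable unchanged to first order.
#'
#' @param ccs a `cc_set` from [control_coefficients()].
#' @param variable list describing the variable: `type` one of `"mean"`,
#'   `"noise"`, `"autocorr"`; `species` a species id; for noise optionally
#'   `species2` (cross noise level); for autocorr a `lag` value.
#' @param parameter_subset ordered character vector of parameter ids
#'   (default: all parameters in `ccs`).
#' @return object of class `control_vector` with `variable`, `parameter_ids`,
#'   `components`.
#' @export
control_vector <- function(ccs, variable, parameter_subset = NULL) {
  if (is.character(variable)) variable <- list(type = variable[1], species = variable[2])
  ps <- if (is.null(parameter_subset)) ccs$parameter_ids else parameter_subset
  if (length(ps) == 0L) stop("parameter subset is empty", call. = FALSE)
  if (any(!ps %in% ccs$parameter_ids)) {
    stop(sprintf("unknown parameter '%s'", setdiff(ps, ccs$parameter_ids)[1L]),
         call. = FALSE)
  }
  sp <- variable$species
  if (is.null(sp) || !sp %in% ccs$species_ids) {
    stop(sprintf("unknown species '%s' in control variable", sp %||% "<missing>"),
         call. = FALSE)
  }
  comp <- switch(variable$type,
    mean = ccs$mean$scaled[sp, ps],
    noise = {
      sp2 <- variable$species2 %||% sp
      ccs$noise$scaled[sp, sp2, ps]
    },
    autocorr = {
      if (is.null(ccs$autocorr)) stop("cc_set has no autocorrelation CCs", call. = FALSE)
      k <- which.min(abs(ccs$autocorr$lags - variable$lag))
      ccs$autocorr$scaled[k, sp, ps]
    },
    stop(sprintf("unknown variable type '%s'", variable$type), call. = FALSE)
  )
  out <- list(variable = variable, parameter_ids = ps,
              components = stats::setNames(as.numeric(comp), ps))
  class(out) <- "control_vector"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cv_components <- function(x) {
  if (inherits(x, "control_vector")) x$components else as.numeric(x)
}

#' Orthogonal control design
#'
#' Projects the control vector of the variable to be moved onto the space
#' perpendicular to the control vector of the variable to be held fixed.
#' Perturbing along the returned unit direction changes the moved variable at
#' strength `S` per unit perturbation while leaving the fixed variable
#' unchanged to first order. The efficiency `eps = |sin(theta)|` (with `theta`
#' the angle between the two control vectors) is the fraction of the moved
#' vector living in the perpendicular space; `S = ||G_moved|| eps`. The
#' projection direction coincides with the minimum-norm Lagrange-multiplier
#' solution of the constrained problem (see [generalized_design()]).
#'
#' @param G_fixed control vector of the variable to hold fixed.
#' @param G_moved control vector of the variable to change.
#' @param sense `"reduce"` (default) to decrease the moved variable,
#'   `"increase"` to increase it.
#' @return object of class `orthogonal_design` with `direction` (unit vector),
#'   `strength_S`, `efficiency_eps`, `theta` and `possible` (FALSE when the
#'   two vectors are (anti-)parallel and orthogonal control is impossible).
#' @export
orthogonal_design <- function(G_fixed, G_moved, sense = c("reduce", "increase")) {
  sense <- match.arg(sense)
  gf <- cv_components(G_fixed)
  gm <- cv_components(G_moved)
  stopifnot(length(gf) == length(gm))
  nf <- sqrt(sum(gf^2))
  nm <- sqrt(sum(gm^2))
  if (nf == 0) stop("fixed-variable control vector has zero norm", call. = FALSE)
  uf <- gf / nf
  par_comp <- sum(gm * uf)
  proj <- gm - par_comp * uf
  npr <- sqrt(sum(proj^2))
  # angle and efficiency from the decomposition itself: atan2 keeps full
  # precision near the parallel/anti-parallel limits where acos loses half
  # the significant digits
  theta <- atan2(npr, par_comp)
  eps <- if (nm > 0) npr / nm else 0
  S <- npr
  sgn <- if (sense == "reduce") -1 else 1
  possible <- eps >= 1e-10 && npr > 0
  direction <- if (possible) sgn * proj / npr else rep(0, length(gm))
  names(direction) <- names(gm)
  out <- list(fixed_variable = if (inherits(G_fixed, "control_vector")) G_fixed$variable else NULL,
              moved_variable = if (inherits(G_moved, "control_vector")) G_moved$variable else NULL,
              parameter_ids = names(gm),
              direction = direction, strength_S = if (possible) S else 0,
              efficiency_eps = eps, theta = theta, sense = sense,
              possible = possible)
  class(out) <- "orthogonal_design"
  out
}

#' @export
print.orthogonal_design <- function(x, ...) {
  cat("<orthogonal_design>\n")
  cat(sprintf("  efficiency eps = %.6g, strength S = %.6g, theta = %.4f rad\n",
              x$efficiency_eps, x$strength_S, x$theta))
  if (!x$possible) cat("  orthogonal control impossible (control vectors are (anti-)parallel)\n")
  cat("  direction:\n")
  for (i in seq_along(x$direction)) {
    cat(sprintf("    %-12s %+.6f\n", names(x$direction)[i], x$direction[i]))
  }
  invisible(x)
}

#' Generalized minimum-norm control design
#'
#' Solves `C dp = targets` for the relative parameter perturbation `dp/p`,
#' where the rows of `C` are control vectors of the target variables and the
#' right-hand side holds the desired percentage changes. Degenerate systems
#' get the minimum-norm solution (pseudoinverse, equivalent to the Lagrange
#' multiplier construction); inconsistent systems are reported as
#' overconstrained rather than raising an error.
#'
#' @param cc_matrix numeric matrix, one row per target variable.
#' @param targets numeric vector of desired fractional changes.
#' @param feasibility_tol residual threshold (relative to `||targets||`) above
#'   which the design is declared overconstrained.
#' @return object of class `generalized_design` with `delta_p`, `residual`,
#'   `status` (`"exact"`, `"min-norm"` or `"overconstrained"`).
#' @export
generalized_design <- function(cc_matrix, targets, feasibility_tol = 1e-8) {
  cc_matrix <- rbind(cc_matrix)
  stopifnot(nrow(cc_matrix) == length(targets))
  dp <- as.numeric(MASS::ginv(cc_matrix) %*% targets)
  names(dp) <- colnames(cc_matrix)
  residual <- sqrt(sum((cc_matrix %*% dp - targets)^2))
  nt <- sqrt(sum(targets^2))
  square_nonsing <- nrow(cc_matrix) == ncol(cc_matrix) &&
    abs(det(cc_matrix)) > 1e-12 * max(abs(cc_matrix))^nrow(cc_matrix)
  status <- if (residual > feasibility_tol * max(nt, .Machine$double.eps)) {
    "overconstrained"
  } else if (square_nonsing) "exact" else "min-norm"
  out <- list(targets = targets, delta_p = dp, residual = residual, status = status)
  class(out) <- "generalized_design"
  out
}

#' @export
print.generalized_design <- function(x, ...) {
  cat(sprintf("<generalized_design> status: %s, residual %.3e\n", x$status, x$residual))
  cat("  delta_p / p:\n")
  for (i in seq_along(x$delta_p)) {
    cat(sprintf("    %-12s %+.6f\n", names(x$delta_p)[i] %||% i, x$delta_p[i]))
  }
  invisible(x)
}

#' Tolerance-relaxed orthogonal-control metrics
#'
#' When the fixed variable is allowed to change by up to `tol` per unit
#' perturbation, the perpendicular plane expands into a cone of half-angle
#' `theta_d = arcsin(min(1, tol / ||G_fixed||))` around it. The moved
#' vector's angle to the plane is `alpha = |pi/2 - theta|`; if it lies inside
#' the expanded space (`alpha <= theta_d`) the efficiency is 1, otherwise
#' `eps_tol = cos(alpha - theta_d)`. `tol = 0` reduces exactly to
#' [orthogonal_design()].
#'
#' @inheritParams orthogonal_design
#' @param tol nonnegative allowed fractional change of the fixed variable per
#'   unit perturbation.
#' @return list with `eps_tol`, `S_tol`, `theta_d`, `direction` (unit vector
#'   toward the nearest admissible perturbation, signed by `sense`).
#' @export
tolerance_adjusted_metrics <- function(G_fixed, G_moved, tol,
                                       sense = c("reduce", "increase")) {
  sense <- match.arg(sense)
  stopifnot(tol >= 0)
  gf <- cv_components(G_fixed)
  gm <- cv_components(G_moved)
  nf <- sqrt(sum(gf^2))
  nm <- sqrt(sum(gm^2))
  if (nf == 0) stop("fixed-variable control vector has zero norm", call. = FALSE)
  theta_d <- asin(min(1, tol / nf))
  base <- orthogonal_design(gf, gm, sense)
  alpha <- abs(pi / 2 - base$theta)
  uf <- gf / nf
  par_n <- sum(gm * uf)            # signed component along the fixed vector
  perp <- gm - par_n * uf
  nperp <- sqrt(sum(perp^2))

  if (nm == 0) {
    eps_tol <- 0
    direction <- rep(0, length(gm))
  } else if (alpha <= theta_d + 1e-15) {
    eps_tol <- 1
    direction <- gm / nm
  } else {
    eps_tol <- cos(alpha - theta_d)
    # rotate the moved unit vector toward the perpendicular plane by alpha - theta_d
    u_perp <- if (nperp > 1e-300 * max(1, nm)) {
      perp / nperp
    } else {
      # moved vector parallel to the fixed one: pick a deterministic
      # perpendicular basis direction
      basis <- diag(length(gm))
      k <- which.max(apply(basis - outer(uf, uf) %*% basis, 2,
                           function(col) sum(col^2)))
      w <- basis[, k] - sum(basis[, k] * uf) * uf
      w / sqrt(sum(w^2))
    }
    direction <- cos(theta_d) * u_perp + sin(theta_d) * sign(par_n + (par_n == 0)) * uf
  }
  sgn <- if (sense == "reduce") -1 else 1
  direction <- sgn * direction
  names(direction) <- names(gm)
  list(eps_tol = eps_tol, S_tol = nm * eps_tol, theta_d = theta_d,
       theta = base$theta, direction = direction, sense = sense)
}

#' Rank all two-parameter control schemes
#'
#' For every unordered parameter pair, restricts the fixed and moved control
#' vectors to that two-dimensional subspace and computes tolerance-adjusted
#' efficiency and strength; entries are sorted by efficiency then strength
#' (descending), ties broken by lexicographic parameter ids.
#'
#' @param ccs a `cc_set`.
#' @param fixed_variable,moved_variable variable descriptors as in
#'   [control_vector()].
#' @param tol constraint tolerance (0 for strict orthogonal control).
#' @param parameters parameter ids to draw pairs from (default: all).
#' @param sense `"reduce"` or `"increase"` for the moved variable.
#' @return object of class `scheme_ranking`: a data.frame with columns
#'   `parameter_1`, `parameter_2`, `efficiency_eps`, `strength_S`.
#' @export
rank_parameter_pairs <- function(ccs, fixed_variable, moved_variable, tol = 0,
                                 parameters = NULL, sense = "reduce") {
  ps <- if (is.null(parameters)) ccs$parameter_ids else parameters
  if (length(ps) < 2L) stop("need at least two parameters to rank pairs", call. = FALSE)
  gf_full <- control_vector(ccs, fixed_variable, ps)$components
  gm_full <- control_vector(ccs, moved_variable, ps)$components
  pairs <- utils::combn(sort(ps), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    pr <- pairs[, k]
    gf <- gf_full[pr]
    gm <- gm_full[pr]
    if (sqrt(sum(gf^2)) == 0) {
      # the fixed variable is insensitive to this pair: every direction is
      # admissible, so the efficiency is 1 when the moved variable responds
      # at all and 0 when it does not
      nm <- sqrt(sum(gm^2))
      data.frame(parameter_1 = pr[1], parameter_2 = pr[2],
                 efficiency_eps = as.numeric(nm > 0),
                 strength_S = nm,
                 stringsAsFactors = FALSE)
    } else {
      m <- tolerance_adjusted_metrics(gf, gm, tol, sense)
      data.frame(parameter_1 = pr[1], parameter_2 = pr[2],
                 efficiency_eps = m$eps_tol, strength_S = m$S_tol,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$efficiency_eps, -df$strength_S, df$parameter_1, df$parameter_2)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scheme_ranking", "data.frame")
  df
}

#' Iterative orthogonal noise reduction
#'
#' Repeatedly (1) recomputes the mean and noise control vectors of the target
#' species, (2) forms the orthogonal-control direction, and (3) applies the
#' multiplicative update `p_j <- p_j (1 + lambda u_j)`. This is a first-order
#' Euler march along the constraint manifold: per step the fixed mean drifts
#' by O(lambda^2) only.
#'
#' @param net a [reaction_network()].
#' @param target_species species id whose noise level is reduced.
#' @param parameter_subset parameter ids allowed to move (default: the
#'   network's rate parameters).
#' @param lambda positive step size (relative parameter change per step).
#' @param n_iter number of steps.
#' @param tol constraint tolerance passed to the per-step design (0 = strict).
#' @return object of class `iteration_trace`: data.frame with one row per
#'   recorded state (step 0 = initial) and columns for the parameters, the
#'   target mean and noise level; attributes `possible` and `status`.
#' @export
iterate_noise_reduction <- function(net, target_species, parameter_subset = NULL,
                                    lambda = 0.05, n_iter = 5, tol = 0) {
  stopifnot(lambda > 0, n_iter >= 1)
  ps <- parameter_subset %||% net$rate_parameters
  pv <- param_values(net)
  rows <- list()
  status <- "ok"
  possible <- TRUE
  for (step in 0:n_iter) {
    fit <- tryCatch(lna_analysis(net, params = pv), error = function(e) e)
    if (inherits(fit, "error")) {
      status <- sprintf("halted at step %d: %s", step, conditionMessage(fit))
      break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      step = step, t(pv[ps]),
      mean = unname(fit$x_star[[target_species]]),
      noise = unname(fit$eta[target_species, target_species]))
    if (step == n_iter) break
    ccs <- control_coefficients(fit, parameters = ps)
    gf <- control_vector(ccs, list(type = "mean", species = target_species), ps)
    gm <- control_vector(ccs, list(type = "noise", species = target_species), ps)
    if (tol > 0) {
      m <- tolerance_adjusted_metrics(gf, gm, tol, "reduce")
      u <- m$direction
      eff <- m$eps_tol
    } else {
      des <- orthogonal_design(gf, gm, "reduce")
      u <- des$direction
      eff <- des$efficiency_eps
      if (!des$possible) possible <- FALSE
    }
    if (eff < 1e-10) possible <- FALSE
    new_pv <- pv
    new_pv[ps] <- pv[ps] * (1 + lambda * u)
    if (any(new_pv <= 0)) {
      status <- sprintf("halted at step %d: parameter became non-positive", step)
      break
    }
    pv <- new_pv
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  attr(trace, "lambda") <- lambda
  attr(trace, "possible") <- possible
  attr(trace, "status") <- status
  class(trace) <- c("iteration_trace", "data.frame")
  trace
}

#' Amplitude and period control scores for noisy oscillations
#'
#' Locates the first interior trough and the following peak of the normalized
#' autocorrelation (amplitude anchors) and the steepest descending /
#' ascending flank lags around the trough (period anchors). A parameter's
#' amplitude score is `min(|CC(trough)|, |CC(peak)|)` when the two scaled CCs
#' share a sign (a same-sign pair raises both extremes in relative terms,
#' i.e. changes the oscillation amplitude), else 0; the period score is the
#' analogous opposite-sign rule at the flank lags (stretching the lag axis
#' moves the two flanks in opposite relative directions).
#'
#' @param ccs_autocorr output of [autocorr_ccs()] (or the `autocorr` element
#'   of a `cc_set`).
#' @param curve an `autocorr_curve` (defaults to the one inside
#'   `ccs_autocorr`).
#' @param species species id.
#' @return object of class `oscillation_scores`: list with anchor lags and
#'   `amplitude`, `period` ranking data.frames (descending score).
#' @export
oscillation_control_scores <- function(ccs_autocorr, curve = NULL, species) {
  if (!is.null(ccs_autocorr$autocorr)) ccs_autocorr <- ccs_autocorr$autocorr
  curve <- curve %||% ccs_autocorr$curve
  lags <- curve$lags
  an <- curve$A_norm[, species]
  n <- length(an)
  # interior local minima / maxima
  is_min <- c(FALSE, an[2:(n - 1)] < an[1:(n - 2)] & an[2:(n - 1)] < an[3:n], FALSE)
  trough <- which(is_min)[1]
  if (is.na(trough)) {
    stop(sprintf("non-oscillatory autocorrelation for species '%s' (no trough found)",
                 species), call. = FALSE)
  }
  is_max <- c(FALSE, an[2:(n - 1)] > an[1:(n - 2)] & an[2:(n - 1)] > an[3:n], FALSE)
  peak <- which(is_max & seq_len(n) > trough)[1]
  if (is.na(peak)) {
    stop(sprintf("non-oscillatory autocorrelation for species '%s' (no peak after trough)",
                 species), call. = FALSE)
  }
  slope <- diff(an) / diff(lags)
  down_range <- seq_len(trough - 1)                 # descending flank before the trough
  up_range <- seq(trough, peak - 1)                 # ascending flank trough -> peak
  flank_down <- down_range[which.min(slope[down_range])]
  flank_up <- up_range[which.max(slope[up_range])]

  par_ids <- dimnames(ccs_autocorr$scaled)[[3]]
  score_tbl <- function(arr, k1, k2, same_sign) {
    sc <- vapply(par_ids, function(p) {
      c1 <- arr[k1, species, p]
      c2 <- arr[k2, species, p]
      if (!is.finite(c1) || !is.finite(c2)) return(0)
      ok <- if (same_sign) sign(c1) == sign(c2) else sign(c1) == -sign(c2)
      if (ok && c1 != 0 && c2 != 0) min(abs(c1), abs(c2)) else 0
    }, numeric(1))
    df <- data.frame(parameter = par_ids,
                     score = as.numeric(sc),
                     cc_anchor_1 = arr[k1, species, ],
                     cc_anchor_2 = arr[k2, species, ],
                     stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$parameter), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  # amplitude: scaled (relative) CCs at trough and peak, same-sign rule — a
  # same-sign pair inflates both extremes in relative magnitude.
  # period: a pure lag-axis stretch moves the descending and ascending flanks
  # in opposite absolute directions; the sign test is done on dA/d(ln p),
  # which (unlike the scaled CC) does not change sign with A_norm itself.
  out <- list(species = species,
              trough_lag = lags[trough], peak_lag = lags[peak],
              flank_lags = c(lags[flank_down], lags[flank_up]),
              amplitude = score_tbl(ccs_autocorr$scaled, trough, peak,
                                    same_sign = TRUE),
              period = score_tbl(ccs_autocorr$logp, flank_down, flank_up,
                                 same_sign = FALSE))
  class(out) <- "oscillation_scores"
  out
}

#' @export
print.oscillation_scores <- function(x, ...) {
  cat(sprintf("<oscillation_scores> species %s: trough at %.3g, peak at %.3g\n",
              x$species, x$trough_lag, x$peak_lag))
  cat("  amplitude ranking:\n")
  print(utils::head(x$amplitude, 5))
  cat("  period ranking:\n")
  print(utils::head(x$period, 5))
  invisible(x)
}
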