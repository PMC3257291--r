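test_that("control vectors extract scaled CCs in subset order", {
  ccs <- control_coefficients(birth_death(2, 0.4))
  gm <- control_vector(ccs, list(type = "mean", species = "X"))
  expect_equal(unname(gm$components), c(1, -1), tolerance = 1e-8)
  gn <- control_vector(ccs, list(type = "noise", species = "X"))
  expect_equal(unname(gn$components), c(-1, 1), tolerance = 1e-8)
  # subspace restriction and ordering
  g1 <- control_vector(ccs, list(type = "mean", species = "X"), "k_d")
  expect_equal(unname(g1$components), -1, tolerance = 1e-8)
  g2 <- control_vector(ccs, list(type = "mean", species = "X"), c("k_d", "k_s"))
  expect_equal(names(g2$components), c("k_d", "k_s"))
  expect_error(control_vector(ccs, list(type = "mean", species = "Y")), "unknown species")
  expect_error(control_vector(ccs, list(type = "mean", species = "X"), "zz"),
               "unknown parameter")
})

test_that("orthogonal design handles the perpendicular and anti-parallel limits", {
  # already perpendicular: full efficiency, direction along -G_moved
  d <- orthogonal_design(c(1, 0), c(0, 1), "reduce")
  expect_equal(unname(d$direction), c(0, -1))
  expect_equal(d$efficiency_eps, 1)
  expect_equal(d$strength_S, 1)
  expect_true(d$possible)
  d2 <- orthogonal_design(c(1, 0), c(0, 1), "increase")
  expect_equal(unname(d2$direction), c(0, 1))

  # anti-parallel birth-death vectors: impossible, S = 0
  ccs <- control_coefficients(birth_death())
  gf <- control_vector(ccs, list(type = "mean", species = "X"))
  gm <- control_vector(ccs, list(type = "noise", species = "X"))
  db <- orthogonal_design(gf, gm)
  expect_false(db$possible)
  expect_equal(db$strength_S, 0)
  expect_lt(db$efficiency_eps, 1e-8)
})

test_that("designed directions are orthogonal to the fixed control vector", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    gf <- stats::rnorm(n)
    gm <- stats::rnorm(n)
    d <- orthogonal_design(gf, gm)
    if (!d$possible) next
    expect_lt(abs(sum(d$direction * gf)), 1e-10)
    expect_true(d$efficiency_eps >= 0 && d$efficiency_eps <= 1)
    expect_lte(d$strength_S, sqrt(sum(gm^2)) + 1e-12)
    expect_equal(d$strength_S, sqrt(sum(gm^2)) * d$efficiency_eps,
                 tolerance = 1e-10)
    expect_equal(d$efficiency_eps, abs(sin(d$theta)), tolerance = 1e-10)
  }
})

test_that("the projection direction equals the minimum-norm constrained solution", {
  # Lagrange/projection equivalence: solving (G_fixed . dp = 0,
  # G_moved . dp = target) with minimum norm must be parallel to the
  # projection of G_moved onto the perpendicular space
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    gf <- stats::rnorm(n)
    gm <- stats::rnorm(n)
    d <- orthogonal_design(gf, gm, "reduce")
    if (!d$possible) next
    g <- generalized_design(rbind(gf, gm), c(0, -0.03))
    expect_true(g$status %in% c("exact", "min-norm"))
    cosine <- sum(g$delta_p * d$direction) /
      sqrt(sum(g$delta_p^2) * sum(d$direction^2))
    expect_gt(cosine, 1 - 1e-10)
  }
})

test_that("generalized design reports exact, min-norm and overconstrained statuses", {
  # birth-death orthogonal request: hold the mean, cut the noise -> no solution
  g <- generalized_design(rbind(c(1, -1), c(-1, 1)), c(0, -0.03))
  expect_equal(g$status, "overconstrained")

  # single-row system: minimum-norm solution along the control vector
  g2 <- generalized_design(rbind(c(1, -1)), -0.10)
  expect_equal(g2$status, "min-norm")
  expect_equal(unname(g2$delta_p), c(-0.05, 0.05), tolerance = 1e-12)

  # square nonsingular system: unique exact solution
  M <- rbind(c(1, 0.2), c(-0.3, 1))
  g3 <- generalized_design(M, c(0.05, -0.01))
  expect_equal(g3$status, "exact")
  expect_equal(as.numeric(M %*% g3$delta_p), c(0.05, -0.01), tolerance = 1e-12)
  expect_lt(g3$residual, 1e-14)
})

test_that("tolerance-adjusted metrics reduce to the strict design at tol = 0", {
  set.seed(55)
  for (rep in 1:20) {
    gf <- stats::rnorm(4)
    gm <- stats::rnorm(4)
    d0 <- orthogonal_design(gf, gm, "reduce")
    m0 <- tolerance_adjusted_metrics(gf, gm, 0, "reduce")
    expect_equal(m0$eps_tol, d0$efficiency_eps, tolerance = 1e-10)
    expect_equal(m0$S_tol, d0$strength_S, tolerance = 1e-10)
    if (d0$possible) {
      expect_equal(unname(m0$direction), unname(d0$direction), tolerance = 1e-9)
    }
  }
})

test_that("tolerance geometry matches the arcsin cone rule", {
  # anti-parallel vectors, tol = ||G_fixed||/2: eps = cos(pi/2 - arcsin(1/2)) = 1/2
  gf <- c(1, -1)
  gm <- c(-2, 2)
  m <- tolerance_adjusted_metrics(gf, gm, sqrt(2) / 2, "reduce")
  expect_equal(m$eps_tol, 0.5, tolerance = 1e-12)
  expect_equal(m$theta_d, asin(0.5), tolerance = 1e-12)

  # whole space admissible once tol >= ||G_fixed||
  m2 <- tolerance_adjusted_metrics(gf, gm, 2, "reduce")
  expect_equal(m2$eps_tol, 1)
  expect_equal(m2$theta_d, pi / 2)

  # monotone non-decreasing in tol, continuous from the strict design
  set.seed(31)
  gf <- stats::rnorm(5); gm <- stats::rnorm(5)
  tols <- seq(0, 2 * sqrt(sum(gf^2)), length.out = 25)
  eps <- vapply(tols, function(tl) tolerance_adjusted_metrics(gf, gm, tl)$eps_tol,
                numeric(1))
  expect_true(all(diff(eps) >= -1e-12))
  expect_equal(eps[1], orthogonal_design(gf, gm)$efficiency_eps, tolerance = 1e-10)
  expect_equal(eps[length(eps)], 1)
})

test_that("pair rankings behave on the canonical fixtures", {
  ccs_bd <- control_coefficients(birth_death())
  rk <- rank_parameter_pairs(ccs_bd, list(type = "mean", species = "X"),
                             list(type = "noise", species = "X"))
  expect_equal(nrow(rk), 1L)
  expect_lt(rk$efficiency_eps[1], 1e-8)

  netA <- linear_pathway("A")
  ccs_A <- control_coefficients(netA, parameters = attr(netA, "control_parameters"))
  rkA <- rank_parameter_pairs(ccs_A, list(type = "mean", species = "X3"),
                              list(type = "noise", species = "X3"),
                              parameters = attr(netA, "control_parameters"))
  expect_equal(nrow(rkA), 6L)
  expect_lt(max(rkA$efficiency_eps), 1e-8)

  ccs_p <- control_coefficients(two_state_promoter())
  rkP <- rank_parameter_pairs(ccs_p, list(type = "mean", species = "protein"),
                              list(type = "noise", species = "protein"),
                              tol = 0.05)
  expect_equal(nrow(rkP), choose(6, 2))
  expect_true(all(diff(rkP$efficiency_eps) <= 1e-12))
  # the most efficient noise-control pair involves translation
  expect_true("k_tl" %in% unlist(rkP[1, c("parameter_1", "parameter_2")]))
})

test_that("iterative noise reduction lowers noise and preserves the mean", {
  net <- linear_pathway("BC")
  ps <- attr(net, "control_parameters")
  tr <- iterate_noise_reduction(net, "X3", ps, lambda = 0.05, n_iter = 5)
  expect_true(attr(tr, "possible"))
  expect_equal(attr(tr, "status"), "ok")
  expect_equal(nrow(tr), 6L)
  expect_true(all(diff(tr$noise) < 0))
  expect_lt(max(abs(tr$mean / tr$mean[1] - 1)), 1e-8)
  # parameters stay strictly positive along the trace
  expect_true(all(as.matrix(tr[, ps]) > 0))
})

test_that("per-step mean drift is second order in the step size", {
  # first-order Euler along the constraint manifold: the drift of the held
  # mean after one step scales as lambda^2 (ratio ~4 when lambda halves)
  net <- two_state_promoter()
  drift1 <- function(lambda) {
    tr <- iterate_noise_reduction(net, "protein", NULL, lambda = lambda, n_iter = 1)
    abs(tr$mean[2] - tr$mean[1]) / tr$mean[1]
  }
  d1 <- drift1(0.08)
  d2 <- drift1(0.04)
  d3 <- drift1(0.02)
  expect_gt(d1 / d2, 3.4)
  expect_lt(d1 / d2, 4.6)
  expect_gt(d2 / d3, 3.4)
  expect_lt(d2 / d3, 4.6)
})

test_that("a zero-efficiency network yields a flagged, noise-neutral trace", {
  netA <- linear_pathway("A")
  tr <- iterate_noise_reduction(netA, "X3", attr(netA, "control_parameters"),
                                lambda = 0.05, n_iter = 3)
  expect_false(attr(tr, "possible"))
  expect_equal(tr$noise, rep(tr$noise[1], nrow(tr)), tolerance = 1e-10)
})

test_that("oscillation scoring needs an oscillatory autocorrelation", {
  lags <- seq(0, 10, by = 0.5)
  ccs <- control_coefficients(birth_death(), lags = lags)
  expect_error(oscillation_control_scores(ccs, species = "X"),
               "non-oscillatory")
})

test_that("oscillation scores rank same-sign and opposite-sign anchor CCs", {
  lags <- seq(0, 60, by = 0.5)
  ccs <- control_coefficients(feedback_oscillator(), lags = lags)
  sc <- oscillation_control_scores(ccs, species = "P53")
  expect_gt(sc$peak_lag, sc$trough_lag)
  expect_true(all(sc$flank_lags >= 0))
  top_amp <- sc$amplitude[1, ]
  expect_gt(top_amp$score, 0)
  expect_equal(sign(top_amp$cc_anchor_1), sign(top_amp$cc_anchor_2))
  top_per <- sc$period[1, ]
  expect_gt(top_per$score, 0)
  expect_equal(sign(top_per$cc_anchor_1), -sign(top_per$cc_anchor_2))
  # a parameter with opposite-sign CCs at trough and peak gets amplitude 0
  mixed <- with(ccs$autocorr, {
    k1 <- which.min(abs(lags - sc$trough_lag))
    k2 <- which.min(abs(lags - sc$peak_lag))
    which(sign(scaled[k1, "P53", ]) == -sign(scaled[k2, "P53", ]))
  })
  for (p in names(mixed)) {
    expect_equal(sc$amplitude$score[sc$amplitude$parameter == p], 0)
  }
})
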