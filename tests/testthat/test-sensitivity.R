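test_that("birth-death control coefficients are (+1,-1) for the mean and (-1,+1) for noise", {
  ccs <- control_coefficients(birth_death(2, 0.4))
  expect_equal(unname(ccs$mean$scaled["X", ]), c(1, -1), tolerance = 1e-8)
  expect_equal(unname(ccs$noise$scaled["X", "X", ]), c(-1, 1), tolerance = 1e-8)
  # dC/dk_s = 1/k_d, i.e. scaled variance CC w.r.t. k_s is +1
  expect_equal(unname(ccs$covariance$scaled["X", "X", "k_s"]), 1, tolerance = 1e-8)
  expect_equal(unname(ccs$covariance$unscaled["X", "X", "k_s"]), 1 / 0.4,
               tolerance = 1e-8)
})

test_that("chain end-product mean CCs are (+1, 0, 0, -1) and noise CCs anti-parallel", {
  net <- linear_pathway("A")
  ccs <- control_coefficients(net, parameters = c("k1", "k2", "k3", "k4"))
  expect_equal(unname(ccs$mean$scaled["X3", ]), c(1, 0, 0, -1), tolerance = 1e-8)
  expect_equal(unname(ccs$noise$scaled["X3", "X3", ]), c(-1, 0, 0, 1),
               tolerance = 1e-8)
  # Poisson anti-parallelism holds for every species of the chain
  for (s in c("X1", "X2", "X3")) {
    expect_equal(ccs$noise$scaled[s, s, ], -ccs$mean$scaled[s, ],
                 tolerance = 1e-8)
  }
})

test_that("summation theorems hold over the rate parameters on every fixture", {
  for (net in list(birth_death(), two_state_promoter(), linear_pathway("A"),
                   linear_pathway("BC"), feedback_oscillator())) {
    ccs <- control_coefficients(net)
    sums <- cc_summation(ccs)
    expect_lt(max(abs(sums$mean)), 1e-6)
    if (net$kind == "markov-jump") {
      expect_lt(max(abs(sums$noise), na.rm = TRUE), 1e-6)
    } else {
      # constant additive diffusion does not scale with the rates, so a
      # uniform rate rescaling maps C -> C/alpha: the noise CCs sum to -1
      expect_lt(max(abs(sums$noise + 1), na.rm = TRUE), 1e-6)
    }
  }
})

test_that("uniform-rate-scaling invariance forces sum_p p dC/dp = 0", {
  ccs <- control_coefficients(two_state_promoter())
  pv <- stochctrl:::param_values(two_state_promoter())
  acc <- 0 * ccs$covariance$unscaled[, , 1]
  for (p in ccs$parameter_ids) acc <- acc + pv[[p]] * ccs$covariance$unscaled[, , p]
  expect_lt(max(abs(acc)), 1e-6 * max(abs(ccs$fit$C)))
})

test_that("analytic CCs agree with the finite-difference oracle", {
  for (net in list(two_state_promoter(), linear_pathway("BC"),
                   feedback_oscillator())) {
    str <- stoichiometric_decomposition(net)
    ccs <- control_coefficients(net)
    fd_mean <- finite_difference_ccs(net, str, "mean", step = 1e-4)
    expect_lt(max_rel_gap(ccs$mean$scaled, fd_mean), 1e-3)
    fd_noise <- finite_difference_ccs(net, str, "noise", step = 1e-4)
    diag_analytic <- sapply(ccs$parameter_ids, function(p) diag(ccs$noise$scaled[, , p]))
    diag_oracle <- sapply(ccs$parameter_ids, function(p) diag(fd_noise[, , p]))
    expect_lt(max_rel_gap(diag_analytic, diag_oracle, floor = 1e-4), 1e-3)
  }
})

test_that("halving the oracle step shrinks the residual difference about fourfold", {
  # Richardson: central differences carry an O(step^2) truncation error, so
  # the oracle-vs-oracle gap to a tiny-step reference must shrink ~4x
  net <- two_state_promoter()
  str <- stoichiometric_decomposition(net)
  ref <- finite_difference_ccs(net, str, "noise", step = 1e-5)
  g1 <- max(abs(finite_difference_ccs(net, str, "noise", step = 4e-2) - ref), na.rm = TRUE)
  g2 <- max(abs(finite_difference_ccs(net, str, "noise", step = 2e-2) - ref), na.rm = TRUE)
  expect_gt(g1 / g2, 3)
  expect_lt(g1 / g2, 5)
})

test_that("autocorrelation CCs match the scalar closed form and vanish at lag 0", {
  lags <- c(0, 1, 2, 5)
  ccs <- control_coefficients(birth_death(2, 0.4), lags = lags)
  # A_norm = exp(-k_d tau): scaled CC w.r.t. k_d is -k_d tau, w.r.t. k_s is 0
  expect_equal(unname(ccs$autocorr$scaled[, "X", "k_d"]), -0.4 * lags,
               tolerance = 1e-5)
  expect_lt(max(abs(ccs$autocorr$scaled[, "X", "k_s"])), 1e-5)
  expect_equal(unname(ccs$autocorr$scaled[1, "X", ]), c(0, 0), tolerance = 1e-10)
})

test_that("autocorrelation CC sums equal the log-lag derivative of the curve", {
  # scaling all rates by alpha maps tau -> alpha tau, so the scaled CCs over
  # the rate parameters must sum to tau A'(tau)/A(tau)
  lags <- c(0, 0.5, 1, 2, 3)
  net <- two_state_promoter()
  ccs <- control_coefficients(net, lags = lags)
  fit <- ccs$fit
  h <- 1e-5
  for (k in c(2, 4)) {
    up <- autocorrelation(fit$A, fit$C, fit$structure, lags[k] * (1 + h))
    dn <- autocorrelation(fit$A, fit$C, fit$structure, lags[k] * (1 - h))
    for (s in c("mRNA", "protein")) {
      dlog <- unname((up$A_norm[1, s] - dn$A_norm[1, s]) / (2 * h) /
                       ccs$autocorr$curve$A_norm[k, s])
      got <- unname(sum(ccs$autocorr$scaled[k, s, ccs$rate_parameters]))
      expect_equal(got, dlog, tolerance = 1e-6)
    }
  }
})

test_that("autocorrelation CCs agree with the finite-difference oracle", {
  lags <- c(0.5, 1, 2, 4)
  net <- two_state_promoter()
  str <- stoichiometric_decomposition(net)
  ccs <- control_coefficients(net, lags = lags)
  fd <- finite_difference_ccs(net, str, "autocorr", step = 1e-4, lags = lags)
  gap <- max_rel_gap(ccs$autocorr$scaled[, c("mRNA", "protein"), ],
                     fd[, c("mRNA", "protein"), ], floor = 1e-3)
  expect_lt(gap, 1e-3)
})

test_that("near-zero autocorrelations are flagged instead of scaled", {
  fit <- lna_analysis(feedback_oscillator())
  an_at <- function(lag) {
    autocorrelation(fit$A, fit$C, fit$structure, lag)$A_norm[1, "P53"]
  }
  # place a lag exactly on the first zero crossing of the P53 autocorrelation
  crossing <- stats::uniroot(an_at, c(1, 8), tol = 1e-12)$root
  lags <- sort(c(0.5, crossing, 20))
  ccs <- control_coefficients(fit, lags = lags)
  k0 <- which(lags == crossing)
  expect_true(all(ccs$autocorr$flagged[k0, "P53", ]))
  expect_true(all(is.na(ccs$autocorr$scaled[k0, "P53", ])))
  expect_true(all(is.finite(ccs$autocorr$unscaled[k0, "P53", ])))
  expect_false(any(ccs$autocorr$flagged[lags == 0.5, "P53", ]))
})

test_that("the oracle rejects steps outside (0, 0.1]", {
  net <- birth_death()
  str <- stoichiometric_decomposition(net)
  expect_error(finite_difference_ccs(net, str, "mean", step = 0.5))
  expect_error(finite_difference_ccs(net, str, "mean", step = 0))
})
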