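test_that("steady states match closed forms", {
  bd <- birth_death(2, 0.4)
  fit <- lna_analysis(bd)
  expect_equal(unname(fit$x_star[["X"]]), 5, tolerance = 1e-10)

  # chain: x1 = k1 E / k2, x2 = k1 E / k3, x3 = k1 E / k4
  net <- linear_pathway("A", k1 = 0.7, k2 = 1.3, k3 = 2.1, k4 = 0.9, E_level = 6)
  fit2 <- lna_analysis(net)
  expect_equal(unname(fit2$x_star[c("X1", "X2", "X3")]),
               0.7 * 6 / c(1.3, 2.1, 0.9), tolerance = 1e-9)

  # two-state promoter: active fraction times transcription/translation cascade
  tsp <- two_state_promoter(0.1, 0.9, 10, 1, 5, 0.1)
  fit3 <- lna_analysis(tsp)
  expect_equal(unname(fit3$x_star[["protein"]]),
               (0.1 / (0.1 + 0.9)) * 10 * 5 / (1 * 0.1), tolerance = 1e-9)
  # conservation preserved exactly
  expect_equal(unname(fit3$x_star[["G_off"]] + fit3$x_star[["G_on"]]), 1)
})

test_that("linearization gives the expected Jacobian and diffusion", {
  bd <- birth_death(2, 0.4)
  str <- stoichiometric_decomposition(bd)
  ss <- solve_steady_state(bd, str)
  lin <- linearize(bd, str, ss$x_star)
  expect_equal(unname(lin$A[1, 1]), -0.4)
  expect_equal(unname(lin$D[1, 1]), 2 * 2)  # k_s + k_d x* = 2 k_s

  # chain Jacobian is lower bidiagonal with -k_{i+1} on the diagonal
  net <- linear_pathway("A")
  strA <- stoichiometric_decomposition(net)
  ssA <- solve_steady_state(net, strA)
  linA <- linearize(net, strA, ssA$x_star)
  expect_equal(unname(diag(linA$A)), -c(2, 2, 1))
  expect_equal(unname(linA$A[upper.tri(linA$A)]), rep(0, 3))

  # langevin diffusion is the explicit model matrix, passed through
  ou <- ou_network(a = 1.5, D = 3)
  strO <- stoichiometric_decomposition(ou)
  linO <- linearize(ou, strO, c(X = 0))
  expect_equal(unname(linO$D[1, 1]), 3)
})

test_that("Lyapunov solve is exact on scalars and satisfies the residual bound", {
  str1 <- stoichiometric_decomposition(ou_network())
  C <- solve_lyapunov(matrix(-2), matrix(3), str1)
  expect_equal(unname(C[1, 1]), 3 / (2 * 2))

  for (net in list(birth_death(), two_state_promoter(), linear_pathway("BC"),
                   feedback_oscillator())) {
    fit <- lna_analysis(net)
    ind <- fit$structure$independent
    C_ind <- fit$C[ind, ind, drop = FALSE]
    res <- norm(fit$A %*% C_ind + C_ind %*% t(fit$A) + fit$D, "F")
    expect_lt(res, 1e-10 * max(1, norm(fit$D, "F")))
    ev <- eigen(C_ind, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9 * max(abs(ev)))
  }
})

test_that("non-Hurwitz dynamics raise a stability error", {
  str1 <- stoichiometric_decomposition(ou_network())
  expect_error(solve_lyapunov(matrix(0.5), matrix(1), str1), "not stable")
})

test_that("birth-death variance equals the mean (Poisson) and eta = 1/mean", {
  fit <- lna_analysis(birth_death(2, 0.4))
  expect_equal(unname(fit$C[1, 1]), 5, tolerance = 1e-10)
  expect_equal(unname(fit$eta[1, 1]), 1 / 5, tolerance = 1e-10)
})

test_that("open first-order chains have product-form (diagonal Poisson) covariance", {
  set.seed(401)
  for (rep in 1:20) {
    net <- random_pathway_A()
    fit <- lna_analysis(net)
    offdiag <- fit$C - diag(diag(fit$C))
    expect_lt(max(abs(offdiag)), 1e-8 * max(diag(fit$C)))
    expect_equal(unname(diag(fit$C)),
                 unname(fit$x_star[rownames(fit$C)]), tolerance = 1e-8)
  }
})

test_that("noise levels require positive means", {
  C <- matrix(1, 1, 1, dimnames = list("X", "X"))
  expect_error(noise_levels(C, c(X = 0)), "non-positive mean.*|'X'")
})

test_that("autocorrelation matches the scalar closed form and its ODE route", {
  bd <- birth_death(2, 0.4)
  fit <- lna_analysis(bd)
  lags <- seq(0, 10, by = 0.5)
  cur <- autocorrelation(fit$A, fit$C, fit$structure, lags)
  expect_equal(unname(cur$A_norm[, "X"]), exp(-0.4 * lags), tolerance = 1e-10)
  expect_equal(matrix(cur$R[, , 1], 1, 1), fit$C, ignore_attr = TRUE)

  # matrix-exponential and ODE-integration routes agree on a coupled system
  tsp <- two_state_promoter()
  fit2 <- lna_analysis(tsp)
  ind <- fit2$structure$independent
  C_ind <- fit2$C[ind, ind]
  lags2 <- c(0, 0.5, 1, 2, 5)
  cur2 <- autocorrelation(fit2$A, fit2$C, fit2$structure, lags2)
  ode <- stochctrl:::autocorrelation_ode(fit2$A, C_ind, lags2)
  L <- fit2$structure$L
  for (k in seq_along(lags2)) {
    expect_lt(max(abs(L %*% ode[[k]] %*% t(L) - cur2$R[, , k])),
              1e-8 * max(abs(C_ind)))
  }

  # normalized autocorrelations stay within [-1, 1] and decay to zero
  tau_far <- 50 / abs(max(Re(eigen(fit2$A, only.values = TRUE)$values)))
  cur3 <- autocorrelation(fit2$A, fit2$C, fit2$structure, c(0, tau_far))
  expect_lt(max(abs(cur3$R[, , 2])), 1e-6 * norm(fit2$C, "F"))
  expect_true(all(abs(cur2$A_norm) <= 1 + 1e-9))
})

test_that("uniform rate scaling leaves x*, C, eta fixed and rescales lags", {
  net <- two_state_promoter()
  fit1 <- lna_analysis(net)
  pv2 <- 2 * stochctrl:::param_values(net)
  fit2 <- lna_analysis(net, params = pv2)
  expect_equal(fit1$x_star, fit2$x_star, tolerance = 1e-9)
  expect_equal(fit1$C, fit2$C, tolerance = 1e-8)
  expect_equal(fit1$eta, fit2$eta, tolerance = 1e-8)
  lags <- c(0, 1, 2, 4)
  c1 <- autocorrelation(fit1$A, fit1$C, fit1$structure, 2 * lags)
  c2 <- autocorrelation(fit2$A, fit2$C, fit2$structure, lags)
  expect_equal(c1$A_norm, c2$A_norm, tolerance = 1e-8)
})

test_that("the damped oscillator fixture shows a negative autocorrelation trough", {
  fit <- lna_analysis(feedback_oscillator())
  lags <- seq(0, 60, by = 0.5)
  cur <- autocorrelation(fit$A, fit$C, fit$structure, lags)
  tp <- trough_peak(cur$A_norm[, "P53"], lags)
  expect_lt(tp$trough, 0)
  expect_gt(tp$peak, 0)
  expect_gt(tp$peak_lag, tp$trough_lag)
})
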