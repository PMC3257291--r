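# Shared builders used across test files.

# a 1-species Ornstein-Uhlenbeck Langevin network: dX = -a X dt + sqrt(D) dW
ou_network <- function(a = 1, D = 2, x0 = 0) {
  reaction_network(
    species = c(X = x0),
    parameters = c(a = a),
    reactions = list(list(id = "relax", stoich = c(X = -1), rate = "a * X")),
    kind = "langevin", diffusion = matrix(D, 1, 1), name = "ou"
  )
}

# random positive rate constants for the constant-enzyme pathway (variant A)
random_pathway_A <- function() {
  ks <- stats::runif(4, 0.3, 3)
  linear_pathway("A", k1 = ks[1], k2 = ks[2], k3 = ks[3], k4 = ks[4],
                 E_level = stats::runif(1, 2, 20))
}

# max relative gap between an analytic scaled-CC array and the oracle,
# ignoring entries where the reference magnitude is below `floor`
max_rel_gap <- function(analytic, oracle, floor = 1e-6) {
  ref <- pmax(abs(oracle), floor)
  max(abs(analytic - oracle) / ref, na.rm = TRUE)
}

# species x parameter matrix of same-species entries of a 3-index CC array
noise_cc_diag <- function(arr3, ids, par_ids) {
  sapply(par_ids, function(p) vapply(ids, function(s) arr3[s, s, p], numeric(1)))
}

# trough/peak of a normalized autocorrelation series
trough_peak <- function(an, lags) {
  tr <- which.min(an)
  pk <- tr + which.max(an[tr:length(an)]) - 1L
  list(trough = an[tr], peak = an[pk], trough_lag = lags[tr], peak_lag = lags[pk])
}
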