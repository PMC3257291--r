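# Programmatic model fixtures. These are the standard study systems of
# stochastic gene-expression and metabolic noise analysis: a birth-death
# process, a two-state (telegraph) promoter expression cascade, linear
# metabolic pathways with optional end-product inhibition and enzyme
# fluctuations, and a three-species negative-feedback Langevin oscillator.
# All default parameter values are this package's own documented choices.

#' Birth-death (synthesis-degradation) process
#'
#' One species synthesized at constant rate `k_s` and degraded first-order at
#' `k_d`. Its stationary law is Poisson: mean `k_s/k_d`, noise level
#' `k_d/k_s`, so the mean and noise control vectors are exactly anti-parallel
#' and orthogonal control is impossible.
#'
#' @param k_s synthesis rate (count/time).
#' @param k_d degradation rate constant (1/time).
#' @return a [reaction_network()].
#' @export
birth_death <- function(k_s = 2, k_d = 0.4) {
  reaction_network(
    species = c(X = max(1, round(k_s / k_d))),
    parameters = c(k_s = k_s, k_d = k_d),
    reactions = list(
      list(id = "synthesis", stoich = c(X = 1), rate = "k_s"),
      list(id = "degradation", stoich = c(X = -1), rate = "k_d * X")
    ),
    name = "birth_death"
  )
}

#' Two-state promoter expression cascade
#'
#' A promoter toggling between inactive (`G_off`) and active (`G_on`) states;
#' transcription proceeds only from the active state, followed by first-order
#' mRNA decay, translation and protein decay. The promoter copy number is
#' conserved (`G_off + G_on = G_total`). Default rates are per unit time;
#' molecule counts are dimensionless.
#'
#' @param k_on,k_off promoter activation / deactivation rate constants.
#' @param k_tx transcription rate constant (per active promoter).
#' @param d_m mRNA decay rate constant.
#' @param k_tl translation rate constant (per mRNA).
#' @param d_p protein decay rate constant.
#' @param G_total total promoter copy number (conserved).
#' @return a [reaction_network()].
#' @export
two_state_promoter <- function(k_on = 0.1, k_off = 0.9, k_tx = 10, d_m = 1,
                               k_tl = 5, d_p = 0.1, G_total = 1) {
  stopifnot(G_total >= 1, G_total == round(G_total))
  reaction_network(
    species = c(G_off = G_total, G_on = 0, mRNA = 0, protein = 0),
    parameters = c(k_on = k_on, k_off = k_off, k_tx = k_tx, d_m = d_m,
                   k_tl = k_tl, d_p = d_p),
    reactions = list(
      list(id = "activation", stoich = c(G_off = -1, G_on = 1), rate = "k_on * G_off"),
      list(id = "deactivation", stoich = c(G_on = -1, G_off = 1), rate = "k_off * G_on"),
      list(id = "transcription", stoich = c(mRNA = 1), rate = "k_tx * G_on"),
      list(id = "mrna_decay", stoich = c(mRNA = -1), rate = "d_m * mRNA"),
      list(id = "translation", stoich = c(protein = 1), rate = "k_tl * mRNA"),
      list(id = "protein_decay", stoich = c(protein = -1), rate = "d_p * protein")
    ),
    name = "two_state_promoter"
  )
}

#' Linear metabolic pathway fixtures
#'
#' An enzyme-catalyzed influx followed by a three-metabolite chain with
#' first-order steps: `-> X1 -> X2 -> X3 ->`. Variants:
#' \describe{
#'   \item{A}{constant (boundary) enzyme, no feedback. Open first-order
#'     mass-action network: the stationary law is product-form Poisson, so
#'     orthogonal control of any metabolite is impossible.}
#'   \item{B}{adds end-product inhibition: the influx is multiplied by a Hill
#'     repression term in `X3`.}
#'   \item{C}{replaces the fixed enzyme by a birth-death enzyme species
#'     (extrinsic noise source).}
#'   \item{BC}{both feedback and enzyme fluctuations.}
#' }
#' The conventional control-parameter subset is the four chain rate constants
#' `k1..k4` (attribute `control_parameters`); the Hill constant `K_I` and
#' coefficient `h` are shape parameters excluded from the rate-parameter set
#' used by the summation theorems.
#'
#' @param variant `"A"`, `"B"`, `"C"` or `"BC"`.
#' @param k1,k2,k3,k4 chain rate constants (influx and the three first-order
#'   steps).
#' @param E_level enzyme level (fixed for A/B, the birth-death mean for C/BC).
#' @param k_de enzyme degradation rate constant (variants C/BC; synthesis is
#'   `E_level * k_de`).
#' @param K_I,h Hill repression constant and coefficient (variants B/BC).
#' @return a [reaction_network()] with attribute `control_parameters`.
#' @export
linear_pathway <- function(variant = c("A", "B", "C", "BC"),
                           k1 = 1, k2 = 2, k3 = 2, k4 = 1,
                           E_level = 10, k_de = 0.1, K_I = 10, h = 2) {
  variant <- match.arg(variant)
  with_fb <- variant %in% c("B", "BC")
  with_enz <- variant %in% c("C", "BC")
  influx <- if (with_fb) "k1 * E * hill(X3, K_I, h)" else "k1 * E"

  species <- c(X1 = 0, X2 = 0, X3 = 0, E = E_level)
  boundary <- if (with_enz) character() else "E"
  pars <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  reactions <- list(
    list(id = "influx", stoich = c(X1 = 1), rate = influx),
    list(id = "step12", stoich = c(X1 = -1, X2 = 1), rate = "k2 * X1"),
    list(id = "step23", stoich = c(X2 = -1, X3 = 1), rate = "k3 * X2"),
    list(id = "efflux", stoich = c(X3 = -1), rate = "k4 * X3")
  )
  rate_pars <- names(pars)
  if (with_enz) {
    pars <- c(pars, k_se = E_level * k_de, k_de = k_de)
    reactions <- c(reactions, list(
      list(id = "enzyme_synthesis", stoich = c(E = 1), rate = "k_se"),
      list(id = "enzyme_decay", stoich = c(E = -1), rate = "k_de * E")
    ))
    rate_pars <- c(rate_pars, "k_se", "k_de")
  }
  if (with_fb) pars <- c(pars, K_I = K_I, h = h)

  net <- reaction_network(
    species = species, parameters = pars, reactions = reactions,
    boundary = boundary, rate_parameters = rate_pars,
    name = sprintf("linear_pathway_%s", variant)
  )
  attr(net, "control_parameters") <- c("k1", "k2", "k3", "k4")
  attr(net, "variant") <- variant
  net
}

#' Negative-feedback Langevin oscillator
#'
#' A structurally faithful three-species damage-response motif: an upstream
#' kinase `A` activates a `P53`-like species, which induces its inhibitor `M`
#' (Mdm2/Wip1-like); the inhibitor represses the kinase through a Hill term,
#' closing a negative feedback ring. The ring makes the linearized dynamics
#' underdamped (complex eigenvalues with negative real parts), so the
#' stationary autocorrelation of `P53` shows damped oscillations.
#' Fluctuations enter as additive Gaussian white noise with a constant
#' diagonal diffusion matrix. This is a synthetic stand-in with
#' package-chosen parameters, not a published model's values.
#'
#' At the defaults the steady state is `A = P53 = M = K_M` and the complex
#' eigenvalue pair has quality factor `|Im|/|Re| ~ 4.5` (clear trough below
#' zero followed by a positive peak).
#'
#' @param k_a kinase activation rate (upstream damage signal strength).
#' @param d_a kinase first-order decay rate constant.
#' @param k_p `P53` synthesis rate constant (per kinase molecule).
#' @param d_p `P53` effective first-order degradation rate constant.
#' @param k_m inhibitor synthesis rate constant (per `P53` molecule).
#' @param d_m inhibitor decay rate constant.
#' @param K_M,h Hill constant and coefficient of the inhibition of the kinase.
#' @param sigma2 diagonal diffusion intensities (count^2/time) per species.
#' @return a Langevin [reaction_network()].
#' @export
feedback_oscillator <- function(k_a = 12, d_a = 0.3, k_p = 0.3, d_p = 0.3,
                                k_m = 0.3, d_m = 0.3, K_M = 20, h = 6,
                                sigma2 = c(4, 4, 4)) {
  D <- diag(sigma2, 3)
  net <- reaction_network(
    species = c(A = 20, P53 = 20, M = 20),
    parameters = c(k_a = k_a, d_a = d_a, k_p = k_p, d_p = d_p,
                   k_m = k_m, d_m = d_m, K_M = K_M, h = h),
    reactions = list(
      list(id = "kinase_act", stoich = c(A = 1), rate = "k_a * hill(M, K_M, h)"),
      list(id = "kinase_decay", stoich = c(A = -1), rate = "d_a * A"),
      list(id = "p53_synthesis", stoich = c(P53 = 1), rate = "k_p * A"),
      list(id = "p53_decay", stoich = c(P53 = -1), rate = "d_p * P53"),
      list(id = "mdm_synthesis", stoich = c(M = 1), rate = "k_m * P53"),
      list(id = "mdm_decay", stoich = c(M = -1), rate = "d_m * M")
    ),
    kind = "langevin", diffusion = D,
    rate_parameters = c("k_a", "d_a", "k_p", "d_p", "k_m", "d_m"),
    name = "feedback_oscillator"
  )
  # the fixture contract requires damped oscillations: complex eigenvalues
  # with negative real parts at the steady state
  str <- stoichiometric_decomposition(net)
  ss <- solve_steady_state(net, str)
  lin <- linearize(net, str, ss$x_star)
  ev <- eigen(lin$A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("non-oscillatory fixture: steady state unstable", call. = FALSE)
  }
  if (all(abs(Im(ev)) < 1e-12)) {
    stop("non-oscillatory fixture: all Jacobian eigenvalues are real", call. = FALSE)
  }
  net
}

#' Build a fixture by name
#'
#' @param name one of `"birth_death"`, `"two_state_promoter"`,
#'   `"linear_pathway"`, `"feedback_oscillator"`.
#' @param variant pathway variant (linear_pathway only).
#' @param ... parameter overrides passed to the fixture constructor.
#' @return a [reaction_network()].
#' @export
fixture <- function(name, variant = "A", ...) {
  switch(name,
         birth_death = birth_death(...),
         two_state_promoter = two_state_promoter(...),
         linear_pathway = linear_pathway(variant = variant, ...),
         feedback_oscillator = feedback_oscillator(...),
         stop(sprintf("unknown fixture '%s'", name), call. = FALSE))
}
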