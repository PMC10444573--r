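#' Boltzmann steady-state activation function
#'
#' Sigmoidal voltage dependence used for all steady-state activation and
#' inactivation variables of the HN models,
#' \deqn{f_\infty(A, B, V) = \frac{1}{1 + e^{A (V + B)}}.}
#' With this sign convention the half-(in)activation voltage is \eqn{-B};
#' negative `A` gives a curve increasing with depolarisation (activation),
#' positive `A` a decreasing one (inactivation).
#'
#' @param A steepness (1/V).
#' @param B half-activation offset (V); half activation occurs at `V = -B`.
#' @param V membrane potential (V); vectorised.
#' @return value in (0, 1), same length as `V`.  Saturates without overflow
#'   at extreme arguments.
#' @examples
#' boltzmann(-150, 0.029, -0.029)  # 0.5 at half-activation
#' @export
boltzmann <- function(A, B, V) {
  1 / (1 + exp(pmin(A * (V + B), 700)))
}

#' Generic voltage-dependent time constant
#'
#' Sigmoidal time-constant profile \eqn{\tau(V) = C + D / (1 + e^{A(V+B)})}
#' shared by most gating variables of the full HN model.
#'
#' @param A steepness (1/V).
#' @param B offset (V).
#' @param C floor (s), must be >= 0.
#' @param D sigmoidal range (s); may be negative as long as the result stays
#'   positive over the physiological voltage range.
#' @param V membrane potential (V); vectorised.
#' @return time constant (s), strictly positive.
#' @export
tau_generic <- function(A, B, C, D, V) {
  stopifnot(C >= 0)
  tau <- C + D / (1 + exp(pmin(A * (V + B), 700)))
  vchk <- seq(-0.08, 0.02, by = 0.001)
  if (any(C + D / (1 + exp(pmin(A * (vchk + B), 700))) <= 0)) {
    stop("tau_generic: non-positive time constant on [-80, 20] mV")
  }
  tau
}

#' Inactivation time constant of the fast Na+ current
#'
#' The one gating time constant of the full model with its own printed
#' functional form (a cosh well plus a sigmoidal shoulder).
#'
#' @param V membrane potential (V); vectorised.
#' @return time constant (s).
#' @export
tau_hna <- function(V) {
  0.004 + 0.02 / cosh(300 * (V + 0.0027)) +
    0.006 / (1 + exp(pmin(500 * (V + 0.028), 700)))
}

#' Steady-state activation of the hyperpolarisation-activated current
#'
#' Double-exponential sigmoid used for the h-current gate:
#' \eqn{1 / (1 + 2 e^{A_1 (V+B)} + e^{A_2 (V+B)})}.
#'
#' @param V membrane potential (V); vectorised.
#' @param A1,A2 steepnesses (1/V).
#' @param B offset (V).
#' @return value in (0, 1).
#' @export
h_inf <- function(V, A1 = 180, A2 = 500, B = 0.047) {
  1 / (1 + 2 * exp(pmin(A1 * (V + B), 700)) + exp(pmin(A2 * (V + B), 700)))
}

#' Na+/K+ pump current
#'
#' Outward pump current activated sigmoidally by intracellular Na+:
#' \deqn{I_{pump} = \frac{I^{max}_{pump}}{1 + e^{([Na^+]_{ih} - [Na^+]_i)/[Na^+]_{is}}}.}
#' The pump is voltage independent; it moves 3 Na+ out per elementary net
#' charge, so the associated Na+ efflux is three times this current.
#'
#' @param nai intracellular Na+ concentration (M); vectorised.
#' @param imax maximal pump current (nA).
#' @param naih half-activation concentration (M).
#' @param nais concentration sensitivity (M), > 0.
#' @return pump current (nA), in (0, `imax`), strictly increasing in `nai`.
#' @export
pump_current <- function(nai, imax, naih = 0.012, nais = 0.0016) {
  stopifnot(nais > 0)
  imax / (1 + exp(pmin((naih - nai) / nais, 700)))
}

#' Na+ reversal potential (Nernst)
#'
#' \eqn{E_{Na} = 0.02526 \ln([Na^+]_o / [Na^+]_i)} volts, the Nernst
#' potential at the preparation's working temperature.
#'
#' @param nao extracellular Na+ concentration (M), > 0.
#' @param nai intracellular Na+ concentration (M), > 0; vectorised.
#' @param slope RT/zF in volts.
#' @return reversal potential (V).
#' @export
nernst_ena <- function(nao, nai, slope = 0.02526) {
  if (any(nao <= 0) || any(nai <= 0)) {
    stop("nernst_ena: concentrations must be positive")
  }
  slope * log(nao / nai)
}
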