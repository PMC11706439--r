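# Mechanical building blocks: double-cosine activation, time-varying
# elastance, Ohmic diode valves, and a raw right-hand-side evaluator
# exposed for oracle-style checks.

#' Double-cosine cardiac activation function
#'
#' Dimensionless activation e(t) in \[0, 1\]: a rising half-cosine on
#' \[0, tau_es), a falling half-cosine on \[tau_es, tau_ep), and zero for
#' the rest of the cycle. Continuous everywhere; e(0) = 0 and
#' e(tau_es) = 1.
#'
#' @param t_cycle time since beat onset (s); vectorised.
#' @param tau_es time of the systolic peak (s).
#' @param tau_ep end of the systolic pulse (s); requires
#'   `0 < tau_es < tau_ep`.
#' @return numeric vector of activation values.
#' @examples
#' activation(c(0, 0.15, 0.3), tau_es = 0.3, tau_ep = 0.45)
#' @export
activation <- function(t_cycle, tau_es, tau_ep) {
  if (!(tau_es > 0 && tau_ep > tau_es)) {
    stop("timing order violated: need 0 < tau_es < tau_ep")
  }
  cv_activation(as.numeric(t_cycle), tau_es, tau_ep)
}

#' Time-varying chamber elastance
#'
#' E(t) = (E_max - E_min) e(t) + E_min on the current heart period. For
#' atria the cycle time is shifted by the atrial systole onset and
#' wrapped modulo the period, so atrial systole may span the cycle
#' boundary.
#'
#' @param t_cycle time since beat onset (s); vectorised.
#' @param e_min,e_max minimal/maximal elastance (mmHg/ml).
#' @param tau heart period (s).
#' @param init_frac,s1_frac,s2_frac timing fractions of `tau`: systole
#'   onset, systolic peak, end of systole.
#' @return elastance (mmHg/ml), bounded in \[e_min, e_max\].
#' @examples
#' # left ventricle at defaults: 0.06 at onset, 2.0 at the systolic peak
#' elastance(c(0, 0.3 * 0.58), 0.06, 2.0, tau = 0.58)
#' @export
elastance <- function(t_cycle, e_min, e_max, tau,
                      init_frac = 0, s1_frac = 0.30, s2_frac = 0.45) {
  stopifnot(e_min > 0, e_max >= e_min, tau > 0)
  tc <- (as.numeric(t_cycle) - init_frac * tau) %% tau
  e <- cv_activation(tc, (s1_frac - init_frac) * tau,
                     (s2_frac - init_frac) * tau)
  (e_max - e_min) * e + e_min
}

#' Diode heart-valve flow
#'
#' Ohmic diode: flow (P_up - P_down)/r when forward biased, and the same
#' gradient across a 1000-fold larger resistance under reverse bias.
#' Both branches vanish at zero gradient, so the law is continuous.
#'
#' @param p_up,p_down upstream/downstream pressures (mmHg); vectorised
#'   with recycling.
#' @param r_val forward valve resistance (mmHg s/ml), positive.
#' @return flow (ml/s).
#' @examples
#' valve_flow(10, 5, 0.06)   # forward:  83.33 ml/s
#' valve_flow(5, 10, 0.06)   # reverse: -0.083 ml/s
#' @export
valve_flow <- function(p_up, p_down, r_val) {
  stopifnot(r_val > 0)
  cv_valve_flow(as.numeric(p_up), as.numeric(p_down), r_val)
}

#' Raw right-hand side of the assembled model
#'
#' Evaluates the time-derivatives of all states at a given instant, with
#' the lagged filtered-pressure values supplied explicitly (pathway
#' order: E_LVmax, E_RVmax, R_sys, V_unV, tau_s sympathetic, tau_v
#' vagal). Intended for verification against independent
#' differential-algebraic formulations; the integrator uses the same
#' compiled code internally.
#'
#' @param params a `cv_parameters` object.
#' @param t absolute time (s).
#' @param state numeric state vector (see [simulate_cv()] for layout).
#' @param t_b onset time of the current beat (s).
#' @param ptilde_lags numeric vector of 6 lagged filtered pressures
#'   (ignored for unregulated variants).
#' @param promotion_sigma,promotion_gain beat-promotion bump parameters.
#' @return numeric vector of state derivatives.
#' @export
cv_rhs <- function(params, t, state, t_b = 0,
                   ptilde_lags = numeric(6),
                   promotion_sigma = 1e-3, promotion_gain = 12) {
  stopifnot(inherits(params, "cv_parameters"))
  if (any(!is.finite(state))) stop("non-finite state")
  cv_rhs_raw(pack_parameters(params), .variant_code(params),
             params$regulated, t, as.numeric(state), t_b,
             as.numeric(ptilde_lags), promotion_sigma, promotion_gain)
}

#' Total blood volume tracked by the model
#'
#' Sum of all stressed compartment volumes (chamber volumes plus
#' compliance charges); for the regulated four-chamber variant the
#' unstressed-volume deviation is added, so the returned quantity is
#' conserved by the dynamics in every variant.
#'
#' @inheritParams cv_rhs
#' @return volume (ml).
#' @export
total_blood_volume <- function(params, t, state, t_b = 0) {
  stopifnot(inherits(params, "cv_parameters"))
  cv_total_volume(pack_parameters(params), .variant_code(params),
                  params$regulated, t, t_b, as.numeric(state))
}
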