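# Baroreflex pathway functions: afferent transduction, sympathetic and
# vagal efferent arcs, static effector characteristics, first-order
# effector relaxation and the Gaussian beat-promotion rate. These are
# the reference formulas; the compiled integrator carries the same
# expressions and is cross-checked against them in the tests.

#' Afferent (baroreceptor) filter rate
#'
#' First-order real-pole/real-zero filter of arterial pressure:
#' `tau_p dP~/dt = P_art + tau_z dP_art/dt - P~`. The solution P~ is the
#' control pressure fed to the afferent sigmoid.
#'
#' @param p_art arterial pressure (mmHg).
#' @param dpart_dt its time-derivative (mmHg/s), taken from the
#'   assembled right-hand side rather than numerical differencing.
#' @param p_tilde current filtered pressure (mmHg).
#' @param tau_p,tau_z pole/zero time constants (s), `tau_p > 0`.
#' @return dP~/dt (mmHg/s).
#' @export
afferent_rate <- function(p_art, dpart_dt, p_tilde,
                          tau_p = 2.076, tau_z = 6.370) {
  stopifnot(tau_p > 0)
  (p_art + tau_z * dpart_dt - p_tilde) / tau_p
}

#' Afferent spiking frequency
#'
#' Sigmoid transduction of the filtered pressure into the carotid-sinus
#' afferent frequency, bounded in (f_min, f_max) and centred on the
#' regulation set-point.
#'
#' @param p_tilde filtered control pressure (mmHg); vectorised.
#' @param p_n regulation set-point (mmHg).
#' @param f_min,f_max saturation frequencies (spikes/s).
#' @param k_a sigmoid slope parameter (mmHg).
#' @return afferent frequency (spikes/s).
#' @export
afferent_frequency <- function(p_tilde, p_n = 92, f_min = 2.52,
                               f_max = 47.78, k_a = 11.758) {
  z <- (p_tilde - p_n) / k_a
  f_min + (f_max - f_min) * stats::plogis(z)
}

#' Sympathetic efferent frequency
#'
#' Exponential decay in the afferent frequency:
#' `f_es = f_es_inf + (f_es_0 - f_es_inf) exp(-k_es f_cs)`; monotone
#' decreasing from f_es_0 toward f_es_inf.
#'
#' @param f_cs afferent frequency (spikes/s); vectorised.
#' @param f_es_inf,f_es_0 limit/zero-input frequencies (spikes/s).
#' @param k_es activity coefficient (s).
#' @return sympathetic frequency (spikes/s).
#' @export
sympathetic_frequency <- function(f_cs, f_es_inf = 2.10, f_es_0 = 16.11,
                                  k_es = 0.0675) {
  f_es_inf + (f_es_0 - f_es_inf) * exp(-k_es * f_cs)
}

#' Vagal efferent frequency
#'
#' Monotone increasing sigmoid from f_ev_0 toward f_ev_inf, centred at
#' the afferent frequency f_cs_0.
#'
#' @param f_cs afferent frequency (spikes/s); vectorised.
#' @param f_ev_0,f_ev_inf zero/limit frequencies (spikes/s).
#' @param f_cs0 centre (spikes/s).
#' @param k_ev slope parameter (spikes/s).
#' @return vagal frequency (spikes/s).
#' @export
vagal_frequency <- function(f_cs, f_ev_0 = 3.20, f_ev_inf = 6.30,
                            f_cs0 = 25, k_ev = 7.06) {
  z <- (f_cs - f_cs0) / k_ev
  f_ev_0 + (f_ev_inf - f_ev_0) * stats::plogis(z)
}

#' Sympathetic static effector characteristic
#'
#' Logarithmic drive `G log(f_es(t - D) - f_es_min + 1)` with a cutoff
#' to zero below the minimal sympathetic frequency; continuous at the
#' threshold since log(1) = 0.
#'
#' @param f_es_delayed delayed sympathetic frequency (spikes/s);
#'   vectorised.
#' @param gain effector gain G (effector units; sign carried by the
#'   gain, e.g. negative for the sympathetic heart-period arc).
#' @param f_es_min cutoff frequency (spikes/s).
#' @return static drive sigma (effector units).
#' @export
sympathetic_static <- function(f_es_delayed, gain, f_es_min = 2.66) {
  ifelse(f_es_delayed >= f_es_min,
         gain * log(f_es_delayed - f_es_min + 1), 0)
}

#' Vagal static heart-period characteristic
#'
#' Linear drive `G_tau_v f_ev(t - D)` on the heart period; the vagal arc
#' acts on heart period only.
#'
#' @param f_ev_delayed delayed vagal frequency (spikes/s); vectorised.
#' @param gain vagal gain (s^2/spikes).
#' @return static drive sigma (s).
#' @export
vagal_static <- function(f_ev_delayed, gain = 0.09) {
  gain * f_ev_delayed
}

#' First-order effector relaxation rate
#'
#' `d(delta)/dt = (sigma - delta) / tau_theta`: each effector deviation
#' relaxes toward its delayed static drive. The heart-period deviation
#' is the SUM of a sympathetic and a vagal contribution, each integrated
#' as its own state with its own gain, time constant and delay.
#'
#' @param delta current effector deviation (effector units).
#' @param sigma static drive (effector units).
#' @param tau_theta time constant (s), positive.
#' @return d(delta)/dt.
#' @export
effector_rate <- function(delta, sigma, tau_theta) {
  stopifnot(tau_theta > 0)
  (sigma - delta) / tau_theta
}

#' Beat-to-beat promotion rate
#'
#' Smooth representation of the beat-to-beat update of heart period and
#' ventricular contractility: the held value relaxes toward
#' `theta_0 + delta` under a normalised Gaussian bump of width
#' `sigma_width` centred on the beat onset, scaled by `gain` so that the
#' post-beat residual `exp(-gain)` is negligible. Away from the onset
#' (|t - t_b| > 6 sigma) the rate is numerically zero and the held value
#' is constant.
#'
#' @param held current beat-held absolute effector value.
#' @param delta current effector deviation.
#' @param theta_0 base effector value.
#' @param t current time (s).
#' @param t_b beat onset time (s).
#' @param sigma_width Gaussian width (s), positive; much smaller than
#'   the shortest transport delay.
#' @param gain dimensionless promotion amplitude.
#' @return d(held)/dt.
#' @export
beat_promotion_rate <- function(held, delta, theta_0, t, t_b,
                                sigma_width = 1e-3, gain = 12) {
  stopifnot(sigma_width > 0)
  z <- (t - t_b) / sigma_width
  bump <- gain * exp(-0.5 * z^2) / (sigma_width * sqrt(2 * pi))
  bump * (theta_0 + delta - held)
}
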