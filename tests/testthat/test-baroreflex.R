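# Baroreflex pathway: static characteristics, effector dynamics,
# beat promotion, delays, and closed-loop feedback properties.

test_that("afferent filter and sigmoid reproduce hand-computed values", {
  expect_equal(afferent_rate(92, 0, 92), 0)
  expect_equal(afferent_rate(100, 0, 92), 8 / 2.076, tolerance = 1e-12)
  expect_equal(afferent_rate(100, 0, 92), 3.854, tolerance = 1e-3)
  # midpoint and limits of the afferent sigmoid
  expect_equal(afferent_frequency(92), (2.52 + 47.78) / 2)
  expect_equal(afferent_frequency(-1e6), 2.52, tolerance = 1e-9)
  expect_equal(afferent_frequency(1e6), 47.78, tolerance = 1e-9)
  # step response: exponential relaxation at rate 1/tau_p
  f <- function(t) 100 - (100 - 92) * exp(-t / 2.076)
  # d/dt of the closed form satisfies the filter equation
  ts <- seq(0, 5, by = 0.5)
  expect_equal((100 - f(ts)) / 2.076,
               afferent_rate(100, 0, f(ts)), tolerance = 1e-12)
})

test_that("efferent arcs reproduce hand-computed values and bounds", {
  expect_equal(sympathetic_frequency(0), 16.11)
  expect_equal(sympathetic_frequency(1e9), 2.10, tolerance = 1e-9)
  expect_equal(sympathetic_frequency(25), 2.1 + 14.01 * exp(-1.6875),
               tolerance = 1e-12)
  expect_equal(sympathetic_frequency(25), 4.692, tolerance = 1e-3)
  expect_equal(vagal_frequency(25), (3.2 + 6.3) / 2)
  expect_equal(vagal_frequency(1e9), 6.3, tolerance = 1e-9)
  v0 <- vagal_frequency(0)
  expect_gt(v0, 3.2); expect_lt(v0, 4.75)
  # monotonicity over a wide afferent range
  fcs <- seq(0, 60, by = 0.25)
  expect_true(all(diff(sympathetic_frequency(fcs)) < 0))
  expect_true(all(diff(vagal_frequency(fcs)) > 0))
  # antagonism through the whole chain: higher pressure -> lower f_es,
  # higher f_ev
  pt <- seq(60, 130, by = 1)
  chain_es <- sympathetic_frequency(afferent_frequency(pt))
  chain_ev <- vagal_frequency(afferent_frequency(pt))
  expect_true(all(diff(chain_es) < 0))
  expect_true(all(diff(chain_ev) > 0))
})

test_that("static effector characteristics: cutoff, continuity, linearity", {
  expect_equal(sympathetic_static(2.0, gain = 0.695), 0)
  expect_equal(sympathetic_static(2.66, gain = 0.695), 0)
  expect_equal(sympathetic_static(4.692, gain = 0.695),
               0.695 * log(4.692 - 2.66 + 1), tolerance = 1e-12)
  expect_equal(sympathetic_static(4.692, gain = 0.695), 0.771,
               tolerance = 1e-3)
  expect_equal(vagal_static(4.75, gain = 0.09), 0.4275)
  expect_equal(vagal_static(0), 0)
  expect_equal(vagal_static(9.5), 2 * vagal_static(4.75))
})

test_that("effector relaxation is first order toward the static drive", {
  expect_equal(effector_rate(0.5, 0.5, 6), 0)
  expect_equal(effector_rate(0, 0.771, 6), 0.1285, tolerance = 1e-3)
  # closed form: delta(t) -> sigma exponentially with time constant tau
  tt <- seq(0, 30, by = 0.01)
  delta <- 0.771 * (1 - exp(-tt / 6))
  rates <- effector_rate(delta, 0.771, 6)
  expect_equal(rates, 0.771 / 6 * exp(-tt / 6), tolerance = 1e-12)
})

test_that("beat promotion drives the held value to theta_0 + delta", {
  # quadrature oracle: integrate the bump ODE across one beat with a
  # very fine independent RK4 in R
  theta0 <- 0.58; delta <- 0.3; sigma <- 1e-3; tb <- 1
  h <- 2e-5
  tt <- seq(tb - 0.05, tb + 0.05, by = h)
  held <- 0.58
  for (t in tt) {
    k1 <- beat_promotion_rate(held, delta, theta0, t, tb, sigma)
    k2 <- beat_promotion_rate(held + h / 2 * k1, delta, theta0, t + h / 2, tb, sigma)
    k3 <- beat_promotion_rate(held + h / 2 * k2, delta, theta0, t + h / 2, tb, sigma)
    k4 <- beat_promotion_rate(held + h * k3, delta, theta0, t + h, tb, sigma)
    held <- held + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(held, 0.88, tolerance = 1e-4)
  # fixed point far from the bump: rate numerically zero
  expect_equal(beat_promotion_rate(0.88, 0.3, 0.58, t = 2, t_b = 1, 1e-3), 0,
               tolerance = 1e-12)
  # zero regulation: held stays at theta_0 across beats
  expect_equal(beat_promotion_rate(0.58, 0, 0.58, t = 1, t_b = 1, 1e-3), 0)
})

test_that("zero-gain regulated model reduces to the unregulated one", {
  for (variant in c("1ch", "4ch")) {
    zero <- c(G_Emax_LV = 0, G_Rsys = 0, G_tau_s = -1e-300, G_tau_v = 0)
    if (variant == "4ch") zero <- c(zero, G_Emax_RV = 0, G_VunV = -1e-300)
    pz <- default_parameters(variant, TRUE, overrides = zero)
    pu <- default_parameters(variant, FALSE)
    h <- if (variant == "1ch") 2.5e-4 else 2e-4
    cfg <- sim_config(t_end = 10, step_size = h)
    tz <- simulate_cv(pz, cfg)
    tu <- simulate_cv(pu, cfg)
    for (col in c("P_LV", "P_art", "P_ven")) {
      expect_equal(tz[[col]], tu[[col]], tolerance = 1e-6)
    }
    out_z <- attr(tz, "outputs"); out_u <- attr(tu, "outputs")
    expect_equal(out_z[names(out_u)], out_u, tolerance = 1e-6)
  }
})

test_that("delayed statics agree with a ring-buffer reconstruction", {
  # reconstruct the R_sys effector derivative from the sampled filtered
  # pressure, lagged by D through interpolation, and compare with the
  # finite-differenced effector state from the same trajectory
  p <- default_parameters("1ch", TRUE)
  tr <- simulate_cv(p, sim_config(t_end = 30, sample_dt = 0.005))
  v <- p$values
  t_chk <- seq(5, 25, by = 0.08)
  pt_lag <- stats::approx(tr$time, tr$P_tilde, xout = t_chk - v["D_Rsys"])$y
  sigma <- sympathetic_static(
    sympathetic_frequency(afferent_frequency(pt_lag)), gain = v[["G_Rsys"]]
  )
  dR <- stats::approx(tr$time, tr$d_R_sys, xout = t_chk)$y
  rate_expected <- effector_rate(dR, sigma, v[["tau_Rsys"]])
  dR_num <- (stats::approx(tr$time, tr$d_R_sys, xout = t_chk + 0.005)$y -
             stats::approx(tr$time, tr$d_R_sys, xout = t_chk - 0.005)$y) / 0.01
  expect_lt(max(abs(dR_num - rate_expected)), 2e-3)
  # shifting the history by the delay aligns the static with the state:
  # an unlagged reconstruction must NOT fit
  sigma_nolag <- sympathetic_static(
    sympathetic_frequency(afferent_frequency(
      stats::approx(tr$time, tr$P_tilde, xout = t_chk)$y
    )), gain = v[["G_Rsys"]]
  )
  rate_wrong <- effector_rate(dR, sigma_nolag, v[["tau_Rsys"]])
  expect_gt(max(abs(dR_num - rate_wrong)), 2e-3)
})

test_that("closed-loop homeostasis damps arterial-pressure changes", {
  # +/-10% in arterial compliance: the regulated loop must show a
  # smaller relative change in mean arterial pressure
  base_r <- default_parameters("1ch", TRUE)
  base_u <- default_parameters("1ch", FALSE)
  cfg_r <- sim_config(t_end = 100, step_size = 5e-4)
  cfg_u <- sim_config(t_end = 20)
  # average over whole trailing beats to avoid partial-beat phase bias
  mean_part <- function(tr) {
    b <- attr(tr, "beat_onsets")
    w <- tr$time >= b[length(b) - 10] & tr$time <= b[length(b)]
    mean(tr$P_art[w])
  }
  rel_change <- function(params, cfg) {
    lo <- default_parameters(params$variant, params$regulated,
                             overrides = c(C_art = 1.13 * 0.9))
    hi <- default_parameters(params$variant, params$regulated,
                             overrides = c(C_art = 1.13 * 1.1))
    p0 <- mean_part(simulate_cv(params, cfg))
    abs(mean_part(simulate_cv(hi, cfg)) - mean_part(simulate_cv(lo, cfg))) / p0
  }
  expect_lt(rel_change(base_r, cfg_r), rel_change(base_u, cfg_u))
})

test_that("unstressed-volume regulation injects stressed volume", {
  # frozen-flow check through the raw RHS: adding a negative-going
  # unstressed-volume deviation rate must raise the venous-node
  # pressure derivative (volume moves into the stressed compartment)
  p <- default_parameters("4ch", TRUE)
  st <- c(rep(6, 6), 90, 0, 0, 0, 0, 0, 0, 0.58, 2.0, 1.75)
  lag_hi <- rep(95, 6)   # high pressure -> weak sympathetic drive
  lag_lo <- rep(70, 6)   # low pressure  -> strong drive, G_VunV < 0
  d_hi <- cv_rhs(p, 0.3, st, t_b = 0, ptilde_lags = lag_hi)
  d_lo <- cv_rhs(p, 0.3, st, t_b = 0, ptilde_lags = lag_lo)
  # stronger drive pushes the unstressed volume down faster...
  expect_lt(d_lo[11], d_hi[11])
  # ...and the venous pressure rises correspondingly faster
  expect_gt(d_lo[3], d_hi[3])
})
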