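# Independent oracle implementations used across the test files. These
# deliberately re-derive the formulas in plain R (or keep explicit
# volume states) so the compiled implementation is checked against an
# independent path.

# double-cosine activation, plain R
oracle_activation <- function(tc, tes, tep) {
  vapply(tc, function(t) {
    if (t < 0) 0
    else if (t < tes) 0.5 * (1 - cos(pi * t / tes))
    else if (t < tep) 0.5 * (1 + cos(pi * (t - tes) / (tep - tes)))
    else 0
  }, numeric(1))
}

# brute-force differential-algebraic form of the unregulated 1CH model:
# explicit ventricular volume state (V, P_art, P_ven), the algebraic
# constraint P_LV = E(t) V substituted on evaluation
oracle_rhs_1ch_dae <- function(t, v_state, vals, tau = vals[["tau_HR0"]]) {
  V <- v_state[1]; Part <- v_state[2]; Pven <- v_state[3]
  tc <- t %% tau
  e <- oracle_activation(tc, vals[["tau_s1v_frac"]] * tau,
                         vals[["tau_s2v_frac"]] * tau)
  E <- (vals[["E_LVmax"]] - vals[["E_LVmin"]]) * e + vals[["E_LVmin"]]
  Plv <- E * V
  q <- function(pu, pd, r) if (pu > pd) (pu - pd) / r else (pu - pd) / (1000 * r)
  Qmv <- q(Pven, Plv, vals[["r_MV"]])
  Qav <- q(Plv, Part, vals[["r_AV"]])
  Qsys <- (Part - Pven) / vals[["R_sys"]]
  c(Qmv - Qav,
    (Qav - Qsys) / vals[["C_art"]],
    (Qsys - Qmv) / vals[["C_ven"]])
}

# same for the unregulated 4CH model with explicit chamber volumes:
# state (V_LV, P_art, V_RAtot*, V_RV, P_pulA, V_LAtot*) where the merged
# atrial/venous nodes carry total stressed volume C_ven P + P / E_A
oracle_rhs_4ch_dae <- function(t, v_state, vals, tau = vals[["tau_HR0"]]) {
  tc <- t %% tau
  eV <- oracle_activation(tc, vals[["tau_s1v_frac"]] * tau,
                          vals[["tau_s2v_frac"]] * tau)
  tca <- (tc - vals[["tau_initA_frac"]] * tau) %% tau
  eA <- oracle_activation(
    tca,
    (vals[["tau_s1a_frac"]] - vals[["tau_initA_frac"]]) * tau,
    (vals[["tau_s2a_frac"]] - vals[["tau_initA_frac"]]) * tau
  )
  Elv <- (vals[["E_LVmax"]] - vals[["E_LVmin"]]) * eV + vals[["E_LVmin"]]
  Erv <- (vals[["E_RVmax"]] - vals[["E_RVmin"]]) * eV + vals[["E_RVmin"]]
  Era <- (vals[["E_RAmax"]] - vals[["E_RAmin"]]) * eA + vals[["E_RAmin"]]
  Ela <- (vals[["E_LAmax"]] - vals[["E_LAmin"]]) * eA + vals[["E_LAmin"]]
  Vlv <- v_state[1]; Part <- v_state[2]; Vra <- v_state[3]
  Vrv <- v_state[4]; Ppa <- v_state[5]; Vla <- v_state[6]
  # merged-node pressure from total stressed volume: V = C P + P / E
  Pra <- Vra / (vals[["C_ven"]] + 1 / Era)
  Pla <- Vla / (vals[["C_pulV"]] + 1 / Ela)
  Plv <- Elv * Vlv
  Prv <- Erv * Vrv
  q <- function(pu, pd, r) if (pu > pd) (pu - pd) / r else (pu - pd) / (1000 * r)
  Qmv <- q(Pla, Plv, vals[["r_MV"]]); Qav <- q(Plv, Part, vals[["r_AV"]])
  Qtv <- q(Pra, Prv, vals[["r_TV"]]); Qpv <- q(Prv, Ppa, vals[["r_PV"]])
  Qsys <- (Part - Pra) / vals[["R_sys"]]
  Qpul <- (Ppa - Pla) / vals[["R_pul"]]
  c(Qmv - Qav,
    (Qav - Qsys) / vals[["C_art"]],
    Qsys - Qtv,
    Qtv - Qpv,
    (Qpv - Qpul) / vals[["C_pulA"]],
    Qpul - Qmv)
}

# closed-form Sobol indices of the Ishigami function (a = 7, b = 0.1)
ishigami_exact <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  list(S1 = c(v1, v2, 0) / v, ST = c(v1 + v13, v2, v13) / v)
}

ishigami_fn <- function(X) {
  sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
}

# bounds helper for plain test functions
unit_bounds <- function(names, low = 0, high = 1) {
  tibble::tibble(name = names, low = low, high = high)
}
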