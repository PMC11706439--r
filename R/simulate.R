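# Closed-loop simulation: configuration, the DDE/ODE integration wrapper,
# clinical output extraction, steady-state effector summaries and the
# regulated -> unregulated equivalence protocol.

#' Simulation settings
#'
#' @param t_end horizon (s of model time); `NULL` picks a variant default
#'   chosen so the trailing window sits well inside the settled periodic
#'   regime (150 s regulated 1CH, 300 s regulated 4CH, 20 s / 40 s for the
#'   unregulated variants).
#' @param sample_dt output sampling interval (s); the trailing "final 200
#'   time points" of the comparison protocol are 200 of these samples
#'   (2 s at the default 0.01 s).
#' @param step_size integrator step (s); `NULL` picks a variant default
#'   (2.5e-4 regulated 1CH, 2e-4 4CH, 1e-3 / 2.5e-4 unregulated 1CH/4CH).
#'   Must resolve the promotion bump: at most `promotion_sigma / 2` for
#'   regulated runs.
#' @param abs_tol,rel_tol target integration accuracy; with the
#'   fixed-step integrator these are verified by step-halving rather than
#'   used for adaptive control.
#' @param steady_window number of trailing samples for steady-state
#'   statistics (default 200).
#' @param promotion_sigma width (s) of the Gaussian beat-promotion bump;
#'   much smaller than the shortest transport delay (0.2 s).
#' @param promotion_gain dimensionless promotion amplitude; the post-beat
#'   promotion residual is about `exp(-promotion_gain)`.
#' @return a `cv_sim_config` list.
#' @export
sim_config <- function(t_end = NULL, sample_dt = 0.01, step_size = NULL,
                       abs_tol = 1e-6, rel_tol = 1e-6,
                       steady_window = 200,
                       promotion_sigma = 1e-3, promotion_gain = 12) {
  stopifnot(sample_dt > 0, steady_window >= 1,
            promotion_sigma > 0, promotion_gain > 0)
  structure(
    list(t_end = t_end, sample_dt = sample_dt, step_size = step_size,
         abs_tol = abs_tol, rel_tol = rel_tol,
         steady_window = steady_window,
         promotion_sigma = promotion_sigma,
         promotion_gain = promotion_gain),
    class = "cv_sim_config"
  )
}

.default_t_end <- function(params) {
  if (params$regulated) {
    if (params$variant == "1ch") 150 else 300
  } else {
    if (params$variant == "1ch") 20 else 40
  }
}

.default_step <- function(params, config) {
  h <- if (params$regulated) {
    if (params$variant == "1ch") 2.5e-4 else 2e-4
  } else {
    if (params$variant == "1ch") 1e-3 else 2.5e-4
  }
  if (params$regulated) h <- min(h, config$promotion_sigma / 2)
  h
}

.state_names <- function(params) {
  if (params$variant == "1ch") {
    base <- c("P_LV", "P_art", "P_ven")
    reg <- c("P_tilde", "d_E_LVmax", "d_R_sys", "d_tau_s", "d_tau_v",
             "held_tau_HR", "held_E_LVmax")
  } else {
    base <- c("P_LV", "P_art", "P_ven", "P_RV", "P_pulA", "P_pulV")
    reg <- c("P_tilde", "d_E_LVmax", "d_E_RVmax", "d_R_sys", "d_V_unV",
             "d_tau_s", "d_tau_v",
             "held_tau_HR", "held_E_LVmax", "held_E_RVmax")
  }
  if (params$regulated) c(base, reg) else base
}

.traj_colnames <- function(params) {
  extra <- if (params$variant == "1ch") {
    c("V_LV", "total_volume", "Q_MV", "Q_AV", "Q_sys",
      "E_LV", "tau_HR", "R_sys_t")
  } else {
    c("V_LV", "V_RV", "total_volume", "Q_MV", "Q_AV", "Q_TV", "Q_PV",
      "Q_sys", "Q_pul", "E_LV", "tau_HR", "R_sys_t")
  }
  c("time", .state_names(params), extra)
}

.output_names <- function(variant) {
  press <- if (variant == "1ch") {
    c("P_LV", "P_art", "P_ven")
  } else {
    c("P_LV", "P_art", "P_ven", "P_RV", "P_pulA", "P_pulV")
  }
  c("CO", "tau_HR", "V_LV_max", "V_LV_min",
    as.vector(rbind(paste0(press, "_max"), paste0(press, "_min"))))
}

#' Simulate the closed-loop model
#'
#' Integrates the coupled system (a delay-differential system for
#' regulated variants; the unregulated variants reduce to an ODE with
#' periodic elastance forcing) with a fixed-step classical Runge-Kutta
#' scheme and a dense interpolated history for the lagged afferent
#' pathway. Beats are detected when the cycle time reaches the current
#' held heart period; the Gaussian promotion bump is always resolved by
#' the step-size contract.
#'
#' By default every compartment pressure starts at the mean circulatory
#' filling pressure, which fixes the conserved total blood volume;
#' `init` overrides the full state vector (see `.state_names` layout in
#' the returned attributes).
#'
#' @param params a `cv_parameters` object.
#' @param config a [sim_config()].
#' @param init optional numeric initial state.
#' @return a `cv_trajectory`: a tibble (one row per sample) with
#'   attributes `params`, `config`, `beat_onsets`, `beat_tau`,
#'   `outputs` (extrema tracked at every integration step over the last
#'   complete beat), `vol_drift` (max relative drift of the conserved
#'   volume) and `periodic` (cycle-to-cycle check).
#' @examples
#' \donttest{
#' traj <- simulate_cv(default_parameters("1ch", regulated = FALSE),
#'                     sim_config(t_end = 10))
#' extract_outputs(traj)
#' }
#' @export
simulate_cv <- function(params, config = sim_config(), init = NULL) {
  stopifnot(inherits(params, "cv_parameters"),
            inherits(config, "cv_sim_config"))
  validate_parameters(params)
  t_end <- config$t_end %||% .default_t_end(params)
  h <- config$step_size %||% .default_step(params, config)
  # the integrator sub-steps 16-fold near promotion bumps, so the outer
  # step must satisfy h/16 <= sigma/2
  if (params$regulated && h > 8 * config$promotion_sigma + 1e-12) {
    stop("step_size must be at most 8 * promotion_sigma for regulated runs")
  }
  res <- cv_integrate(
    pack_parameters(params), .variant_code(params), params$regulated,
    t_end, h, config$sample_dt,
    config$promotion_sigma, config$promotion_gain,
    init = if (is.null(init)) NULL else as.numeric(init),
    store = TRUE
  )
  if (!res$ok && is.finite(res$t_fail)) {
    stop("integration produced non-finite state at t = ",
         signif(res$t_fail, 6), " s")
  }
  traj <- tibble::as_tibble(as.data.frame(res$traj))
  names(traj) <- .traj_colnames(params)
  outputs <- stats::setNames(res$outputs, .output_names(params$variant))

  # cycle-to-cycle periodicity check on arterial pressure extrema
  periodic <- NA
  beats <- res$beats
  if (length(beats) >= 3) {
    b <- utils::tail(beats, 3)
    w1 <- traj$P_art[traj$time >= b[1] & traj$time < b[2]]
    w2 <- traj$P_art[traj$time >= b[2] & traj$time < b[3]]
    if (length(w1) > 2 && length(w2) > 2) {
      periodic <- abs(max(w2) - max(w1)) / max(abs(max(w1)), 1e-12) < 1e-3
      if (!isTRUE(periodic)) {
        warning("periodicity check failed: cycle-to-cycle max |P_art| ",
                "changed by more than 0.1%; increase t_end")
      }
    }
  }
  structure(
    traj,
    class = c("cv_trajectory", class(traj)),
    params = params, config = config,
    beat_onsets = beats, beat_tau = res$beat_tau,
    outputs = outputs, vol_drift = res$vol_drift, periodic = periodic
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the clinical output vector from a trajectory
#'
#' Computes the measurement set over the final complete cardiac cycle:
#' cardiac output (left-ventricular stroke volume divided by that
#' cycle's heart period, ml/s), heart period, max/min left-ventricular
#' volume, and max/min pressure in every compartment (10 outputs for the
#' one-chamber model, 16 for the four-chamber; atrial pressures equal
#' the adjacent venous pressures by construction).
#'
#' @param traj a `cv_trajectory`, or any data frame with a `time` column
#'   and the compartment columns, in which case `beat_onsets` must be
#'   supplied.
#' @param beat_onsets optional beat-onset times overriding the
#'   trajectory attribute (useful for synthetic traces).
#' @return a one-row `cv_outputs` tibble.
#' @export
extract_outputs <- function(traj, beat_onsets = NULL) {
  beats <- beat_onsets %||% attr(traj, "beat_onsets")
  if (is.null(beats) || length(beats) < 3) {
    stop("need at least 2 complete beats to extract outputs")
  }
  b1 <- beats[length(beats) - 1]
  b2 <- beats[length(beats)]
  win <- traj[traj$time >= b1 - 1e-9 & traj$time <= b2 + 1e-9, , drop = FALSE]
  if (nrow(win) < 3) stop("trajectory too sparse over the final beat")
  tau <- b2 - b1
  press <- intersect(
    c("P_LV", "P_art", "P_ven", "P_RV", "P_pulA", "P_pulV"), names(traj)
  )
  out <- list(CO = NA_real_, tau_HR = tau)
  if ("V_LV" %in% names(win)) {
    out$V_LV_max <- max(win$V_LV); out$V_LV_min <- min(win$V_LV)
    out$CO <- (out$V_LV_max - out$V_LV_min) / tau
  }
  for (p in press) {
    out[[paste0(p, "_max")]] <- max(win[[p]])
    out[[paste0(p, "_min")]] <- min(win[[p]])
  }
  res <- tibble::as_tibble(out)
  class(res) <- c("cv_outputs", class(res))
  res
}

#' Trailing-window means of the regulated effectors
#'
#' The mean over the final `window` output samples of each effector's
#' absolute value: held heart period, held maximal ventricular
#' elastance(s), continuous systemic resistance, and (4CH) the
#' unstressed-volume deviation. This is the quantity the
#' regulated/unregulated comparison protocol reads off a settled run.
#'
#' @param traj a regulated `cv_trajectory`.
#' @param window number of trailing samples (default from the run's
#'   config; 200 samples at 0.01 s sampling = a 2 s window).
#' @return tibble with columns `effector`, `value`.
#' @export
steady_state_effectors <- function(traj, window = NULL) {
  params <- attr(traj, "params")
  if (is.null(params) || !params$regulated) {
    stop("steady_state_effectors needs a regulated trajectory")
  }
  window <- window %||% attr(traj, "config")$steady_window
  n <- nrow(traj)
  if (window >= n) stop("window exceeds the number of samples")
  idx <- seq.int(n - window + 1, n)
  eff <- c(
    tau_HR0 = mean(traj$held_tau_HR[idx]),
    E_LVmax = mean(traj$held_E_LVmax[idx]),
    R_sys = mean(traj$R_sys_t[idx])
  )
  if (params$variant == "4ch") {
    eff <- c(eff,
             E_RVmax = mean(traj$held_E_RVmax[idx]),
             d_V_unV = mean(traj$d_V_unV[idx]))
  }
  tibble::tibble(effector = names(eff), value = unname(eff))
}

#' Derive the equivalent unregulated parameter set
#'
#' Runs the regulated model to its settled periodic state and
#' re-assigns the unregulated base parameters to the trailing-window
#' means of the effector values (heart period, maximal ventricular
#' elastances, systemic resistance). For the four-chamber model the
#' regulated unstressed-volume shift is frozen by raising the uniform
#' initial pressure so the unregulated run starts with the same total
#' stressed volume.
#'
#' @param params a regulated `cv_parameters` object.
#' @param config a [sim_config()].
#' @return list with `params` (the equivalent unregulated
#'   `cv_parameters`), `overrides` (tibble: effector, base, value) and
#'   `trajectory` (the regulated run).
#' @export
derive_unregulated_equivalent <- function(params, config = sim_config()) {
  stopifnot(inherits(params, "cv_parameters"))
  if (!params$regulated) stop("params must be a regulated variant")
  traj <- simulate_cv(params, config)
  if (isFALSE(attr(traj, "periodic"))) {
    stop("steady state not reached; increase t_end")
  }
  eff <- steady_state_effectors(traj)
  vals <- stats::setNames(eff$value, eff$effector)
  ov <- c(tau_HR0 = unname(vals["tau_HR0"]),
          E_LVmax = unname(vals["E_LVmax"]),
          R_sys = unname(vals["R_sys"]))
  if (params$variant == "4ch") {
    ov <- c(ov, E_RVmax = unname(vals["E_RVmax"]))
    # freeze the unstressed-volume shift: uniform initial pressure such
    # that the unregulated model holds the regulated stressed volume
    v <- params$values
    s <- v["C_art"] + v["C_ven"] + v["C_pulA"] + v["C_pulV"] +
      1 / v["E_LVmin"] + 1 / v["E_RVmin"] + 1 / v["E_RAmin"] + 1 / v["E_LAmin"]
    v_target <- v["P_init"] * s - vals["d_V_unV"]
    ov <- c(ov, P_init = unname(v_target / s))
  }
  uparams <- default_parameters(params$variant, regulated = FALSE)
  # carry over any non-default base values before applying the overrides
  uparams$values[] <- params$values[names(uparams$values)]
  uparams$values[names(ov)] <- ov
  validate_parameters(uparams)
  base <- params$values[names(ov)]
  list(
    params = uparams,
    overrides = tibble::tibble(
      effector = names(ov), base = unname(base), value = unname(ov)
    ),
    trajectory = traj
  )
}

#' @export
print.cv_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<cv_trajectory> %s %s | %d samples, %d beats | volume drift %.2e\n",
    toupper(p$variant), if (p$regulated) "regulated" else "unregulated",
    nrow(x), max(length(attr(x, "beat_onsets")) - 1, 0),
    attr(x, "vol_drift")
  ))
  NextMethod()
}

#' Tidy a trajectory into long format
#'
#' @param x a `cv_trajectory`.
#' @param ... unused.
#' @return tibble with columns `time`, `series`, `value`.
#' @export
tidy.cv_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "series", values_to = "value")
}

#' One-line summary of a simulation run
#'
#' @param x a `cv_trajectory`.
#' @param ... unused.
#' @return one-row tibble: variant, regulated, beats, volume drift,
#'   periodicity flag and the headline outputs.
#' @export
glance.cv_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  out <- attr(x, "outputs")
  tibble::tibble(
    variant = p$variant, regulated = p$regulated,
    n_samples = nrow(x),
    n_beats = max(length(attr(x, "beat_onsets")) - 1, 0),
    vol_drift = attr(x, "vol_drift"),
    periodic = attr(x, "periodic"),
    CO = unname(out["CO"]), tau_HR = unname(out["tau_HR"])
  )
}

#' Pressure traces plot
#'
#' @param object a `cv_trajectory`.
#' @param window optional length (s) of the trailing window to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_trajectory <- function(object, window = 5, ...) {
  press <- intersect(
    c("P_LV", "P_art", "P_ven", "P_RV", "P_pulA", "P_pulV"), names(object)
  )
  d <- tidy(object)
  d <- d[d$series %in% press, ]
  if (!is.null(window)) d <- d[d$time >= max(d$time) - window, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
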