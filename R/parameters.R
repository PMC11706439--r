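# Parameter containers for the four model variants (1CH/4CH x
# regulated/unregulated): defaults, validation, flatten/unflatten,
# perturbation bounds and YAML config round-trip.

# canonical packed order shared with the C++ core (keep in sync with
# the enum in src/baroloop.cpp)
.packed_names <- c(
  "tau_HR0", "E_LVmin", "E_LVmax", "E_RVmin", "E_RVmax",
  "E_LAmin", "E_LAmax", "E_RAmin", "E_RAmax",
  "tau_initV_frac", "tau_s1v_frac", "tau_s2v_frac",
  "tau_initA_frac", "tau_s1a_frac", "tau_s2a_frac",
  "r_MV", "r_AV", "r_TV", "r_PV",
  "C_art", "R_sys", "C_ven", "C_pulA", "R_pul", "C_pulV",
  "mcfp", "V_unV_init",
  "P_n", "f_min", "f_max", "k_a", "f_cs0",
  "tau_p", "tau_z",
  "f_es_inf", "f_es_0", "f_es_min", "k_es",
  "f_ev_0", "f_ev_inf", "k_ev",
  "G_Emax_LV", "tau_Emax_LV", "D_Emax_LV",
  "G_Emax_RV", "tau_Emax_RV", "D_Emax_RV",
  "G_Rsys", "tau_Rsys", "D_Rsys",
  "G_VunV", "tau_VunV", "D_VunV",
  "G_tau_s", "tau_tau_s", "D_tau_s",
  "G_tau_v", "tau_tau_v", "D_tau_v",
  "P_init"
)

.baro_names_1ch <- c(
  "P_n", "f_min", "f_max", "k_a", "f_cs0", "tau_p", "tau_z",
  "f_es_inf", "f_es_0", "f_es_min", "k_es",
  "f_ev_0", "f_ev_inf", "k_ev",
  "G_Emax_LV", "tau_Emax_LV", "D_Emax_LV",
  "G_Rsys", "tau_Rsys", "D_Rsys",
  "G_tau_s", "tau_tau_s", "D_tau_s",
  "G_tau_v", "tau_tau_v", "D_tau_v"
)

.baro_names_4ch <- c(
  .baro_names_1ch,
  "G_Emax_RV", "tau_Emax_RV", "D_Emax_RV",
  "G_VunV", "tau_VunV", "D_VunV"
)

.mech_names_1ch <- c(
  "tau_HR0", "E_LVmin", "E_LVmax",
  "tau_initV_frac", "tau_s1v_frac", "tau_s2v_frac",
  "r_MV", "r_AV", "C_art", "R_sys", "C_ven", "mcfp", "P_init"
)

.mech_names_4ch <- c(
  "tau_HR0", "E_LVmin", "E_LVmax", "E_RVmin", "E_RVmax",
  "E_LAmin", "E_LAmax", "E_RAmin", "E_RAmax",
  "tau_initV_frac", "tau_s1v_frac", "tau_s2v_frac",
  "tau_initA_frac", "tau_s1a_frac", "tau_s2a_frac",
  "r_MV", "r_AV", "r_TV", "r_PV",
  "C_art", "R_sys", "C_ven", "C_pulA", "R_pul", "C_pulV",
  "mcfp", "V_unV_init", "P_init"
)

.defaults_1ch <- c(
  tau_HR0 = 0.58, E_LVmin = 0.06, E_LVmax = 2.00,
  tau_initV_frac = 0.00, tau_s1v_frac = 0.30, tau_s2v_frac = 0.45,
  r_MV = 0.06, r_AV = 0.033,
  C_art = 1.13, R_sys = 1.663, C_ven = 11.00, mcfp = 8.00,
  P_init = 9.00,
  P_n = 92.000, f_min = 2.520, f_max = 47.780, k_a = 11.758, f_cs0 = 25.000,
  tau_p = 2.076, tau_z = 6.370,
  f_es_inf = 2.100, f_es_0 = 16.110, f_es_min = 2.660, k_es = 0.0675,
  f_ev_0 = 3.200, f_ev_inf = 6.300, k_ev = 7.060,
  G_Emax_LV = 0.475, tau_Emax_LV = 8.000, D_Emax_LV = 2.000,
  G_Rsys = 0.695, tau_Rsys = 6.000, D_Rsys = 2.000,
  G_tau_s = -0.130, tau_tau_s = 2.000, D_tau_s = 2.000,
  G_tau_v = 0.090, tau_tau_v = 1.500, D_tau_v = 0.200
)

.defaults_4ch <- c(
  tau_HR0 = 0.58, E_LVmin = 0.06, E_LVmax = 2.00,
  E_RVmin = 0.15, E_RVmax = 1.75,
  E_LAmin = 0.15, E_LAmax = 0.25, E_RAmin = 0.15, E_RAmax = 0.25,
  tau_initV_frac = 0.00, tau_s1v_frac = 0.30, tau_s2v_frac = 0.45,
  tau_initA_frac = 0.92, tau_s1a_frac = 0.96, tau_s2a_frac = 1.00,
  r_MV = 0.0025, r_AV = 0.0025, r_TV = 0.0025, r_PV = 0.0025,
  C_art = 1.13, R_sys = 1.663, C_ven = 20.50,
  C_pulA = 4.50, R_pul = 0.30, C_pulV = 20.50,
  mcfp = 6.00, V_unV_init = 0.00, P_init = 6.00,
  P_n = 92.000, f_min = 2.520, f_max = 47.780, k_a = 11.758, f_cs0 = 25.000,
  tau_p = 2.076, tau_z = 6.370,
  f_es_inf = 2.100, f_es_0 = 16.110, f_es_min = 2.660, k_es = 0.0675,
  f_ev_0 = 3.200, f_ev_inf = 6.300, k_ev = 7.060,
  G_Emax_LV = 0.475, tau_Emax_LV = 8.000, D_Emax_LV = 2.000,
  G_Emax_RV = 0.282, tau_Emax_RV = 8.000, D_Emax_RV = 2.000,
  G_Rsys = 0.695, tau_Rsys = 6.000, D_Rsys = 2.000,
  G_VunV = -199.000, tau_VunV = 20.000, D_VunV = 5.000,
  G_tau_s = -0.130, tau_tau_s = 2.000, D_tau_s = 2.000,
  G_tau_v = 0.090, tau_tau_v = 1.500, D_tau_v = 0.200
)

# Reconciled perturbable sets (the reference analysis reports only
# the counts 36/9/51/22). Rule: structural constants (mcfp, initial unstressed
# volume) and pinned timings (tau_initV = 0, tau_s2a = 1) are never
# perturbed; ALL timing fractions are excluded from the regulated 4CH
# set; tau_HR0 is excluded from both unregulated sets, where heart
# period is excluded from the analysis altogether.
.free_sets <- list(
  `1ch_regulated` = c(
    "tau_HR0", "E_LVmin", "E_LVmax", "tau_s1v_frac", "tau_s2v_frac",
    "r_MV", "r_AV", "C_art", "R_sys", "C_ven", .baro_names_1ch
  ),
  `1ch_unregulated` = c(
    "E_LVmin", "E_LVmax", "tau_s1v_frac", "tau_s2v_frac",
    "r_MV", "r_AV", "C_art", "R_sys", "C_ven"
  ),
  `4ch_regulated` = c(
    "tau_HR0", "E_LVmin", "E_LVmax", "E_RVmin", "E_RVmax",
    "E_LAmin", "E_LAmax", "E_RAmin", "E_RAmax",
    "r_MV", "r_AV", "r_TV", "r_PV",
    "C_art", "R_sys", "C_ven", "C_pulA", "R_pul", "C_pulV",
    .baro_names_4ch
  ),
  `4ch_unregulated` = c(
    "E_LVmin", "E_LVmax", "E_RVmin", "E_RVmax",
    "E_LAmin", "E_LAmax", "E_RAmin", "E_RAmax",
    "r_MV", "r_AV", "r_TV", "r_PV",
    "C_art", "R_sys", "C_ven", "C_pulA", "R_pul", "C_pulV",
    "tau_s1v_frac", "tau_s2v_frac", "tau_initA_frac", "tau_s1a_frac"
  )
)

.variant_key <- function(variant, regulated) {
  paste0(variant, "_", if (regulated) "regulated" else "unregulated")
}

#' Default parameter set for a model variant
#'
#' Builds the complete input-parameter vector for the closed-loop
#' lumped-parameter cardiovascular models: mechanical constants
#' (elastances, compliances, resistances, cardiac timing fractions,
#' mean circulatory filling pressure) and, for regulated variants, the
#' Ursino baroreflex constants (afferent sigmoid, sympathetic/vagal
#' efferent arcs, effector gains, time constants and transport delays).
#'
#' Cardiac timing parameters are stored as fractions of the heart
#' period, so timing stays consistent when the period is regulated.
#'
#' @param variant `"1ch"` (left ventricle + systemic Windkessel) or
#'   `"4ch"` (four chambers, systemic and pulmonary loops).
#' @param regulated logical; couple the baroreflex feedback?
#' @param overrides optional named numeric vector of parameter values to
#'   replace the defaults (names as in `tidy()` of the result).
#' @return A `cv_parameters` object: list with `variant`, `regulated`,
#'   `values` (named numeric) and `free` (the ordered perturbable
#'   parameter names; lengths 36/9/51/22 by variant).
#' @examples
#' p <- default_parameters("1ch", regulated = TRUE)
#' length(free_parameter_order(p))  # 36
#' @export
default_parameters <- function(variant = c("1ch", "4ch"), regulated = TRUE,
                               overrides = NULL) {
  variant <- match.arg(variant)
  values <- if (variant == "1ch") .defaults_1ch else .defaults_4ch
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(values))
    if (length(bad) > 0) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    }
    values[names(overrides)] <- overrides
  }
  p <- structure(
    list(
      variant = variant,
      regulated = isTRUE(regulated),
      values = values,
      free = .free_sets[[.variant_key(variant, isTRUE(regulated))]]
    ),
    class = "cv_parameters"
  )
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of compliances, resistances, elastances and time
#' constants, ordering of the cardiac timing fractions, the sign
#' conventions of the baroreflex gains, and the afferent/efferent bound
#' orderings.
#'
#' @param params a `cv_parameters` object.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cv_parameters"))
  v <- params$values
  pos <- c(
    "tau_HR0", "E_LVmin", "E_LVmax", "r_MV", "r_AV", "C_art", "R_sys",
    "C_ven", "k_a", "tau_p", "tau_z", "k_es", "k_ev", "P_init", "mcfp",
    if (params$variant == "4ch") {
      c("E_RVmin", "E_RVmax", "E_LAmin", "E_LAmax", "E_RAmin", "E_RAmax",
        "r_TV", "r_PV", "C_pulA", "R_pul", "C_pulV")
    }
  )
  bad <- pos[!(v[pos] > 0)]
  if (length(bad) > 0) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  }
  if (v["E_LVmin"] > v["E_LVmax"]) stop("E_LVmin must not exceed E_LVmax")
  tv <- v[c("tau_initV_frac", "tau_s1v_frac", "tau_s2v_frac")]
  if (!(tv[1] >= 0 && tv[1] < tv[2] && tv[2] < tv[3] && tv[3] <= 1)) {
    stop("ventricular timing fractions must satisfy 0 <= init < s1 < s2 <= 1")
  }
  if (params$variant == "4ch") {
    if (v["E_RVmin"] > v["E_RVmax"]) stop("E_RVmin must not exceed E_RVmax")
    ta <- v[c("tau_initA_frac", "tau_s1a_frac", "tau_s2a_frac")]
    ta <- ta - ta[1]            # wrap-around normalisation
    ta[ta < 0] <- ta[ta < 0] + 1
    if (!(ta[2] > 0 && ta[3] > ta[2] && ta[3] <= 1)) {
      stop("atrial timing fractions must be ordered after wrap-around")
    }
    if (!(v["V_unV_init"] >= 0)) stop("V_unV_init must be non-negative")
  }
  if (params$regulated) {
    if (!(v["f_min"] < v["f_max"])) stop("f_min must be below f_max")
    if (!(v["f_es_inf"] < v["f_es_0"])) stop("f_es_inf must be below f_es_0")
    if (!(v["f_ev_0"] < v["f_ev_inf"])) stop("f_ev_0 must be below f_ev_inf")
    taus <- grep("^tau_(Emax|Rsys|VunV|tau)", names(v), value = TRUE)
    if (any(v[taus] <= 0)) stop("effector time constants must be positive")
    delays <- grep("^D_", names(v), value = TRUE)
    if (any(v[delays] < 0)) stop("effector delays must be non-negative")
    if (v["G_tau_s"] >= 0) stop("G_tau_s carries a negative sign")
    if (params$variant == "4ch" && v["G_VunV"] >= 0) {
      stop("G_VunV carries a negative sign")
    }
  }
  invisible(params)
}

#' Ordered perturbable parameter names
#'
#' The reference analysis reports only the parameter-space dimensions (36 regulated /
#' 9 unregulated for the one-chamber model; 51 / 22 for the
#' four-chamber). This function publishes the package's reconciled
#' lists; see the methods vignette for the reconciliation rule.
#'
#' @param params a `cv_parameters` object.
#' @return character vector of parameter names.
#' @export
free_parameter_order <- function(params) {
  stopifnot(inherits(params, "cv_parameters"))
  params$free
}

#' Flatten a parameter set to its perturbable scalar vector
#'
#' @param params a `cv_parameters` object.
#' @return named numeric vector in `free_parameter_order()` order.
#' @export
flatten_parameters <- function(params) {
  stopifnot(inherits(params, "cv_parameters"))
  params$values[params$free]
}

#' Rebuild a parameter set from a flat vector
#'
#' Inverse of [flatten_parameters()]: the vector is written back into a
#' template parameter set and the result re-validated, so
#' `unflatten_parameters(template, flatten_parameters(p))` reproduces
#' `p` exactly.
#'
#' @param template a `cv_parameters` object supplying everything not in
#'   the free set.
#' @param values numeric vector whose length equals the variant's
#'   parameter dimension.
#' @return a validated `cv_parameters` object.
#' @export
unflatten_parameters <- function(template, values) {
  stopifnot(inherits(template, "cv_parameters"))
  if (length(values) != length(template$free)) {
    stop("expected ", length(template$free), " values, got ", length(values))
  }
  out <- template
  out$values[out$free] <- as.numeric(values)
  validate_parameters(out)
  out
}

#' Per-parameter perturbation intervals
#'
#' Multiplicative bounds `base * (1 -/+ fraction)` around the base state,
#' matching the reference +/-10% exploration box. Intervals for
#' negative-base parameters (the sympathetic heart-period gain and the
#' unstressed-volume gain) are ordered numerically so samplers always
#' receive `low < high`.
#'
#' @param params a `cv_parameters` object.
#' @param fraction relative half-width, in (0, 1); `0` is allowed only
#'   with `allow_degenerate = TRUE` and yields `(base, base)`.
#' @param allow_degenerate accept `fraction = 0`?
#' @return tibble with columns `name`, `base`, `low`, `high`.
#' @export
perturbation_bounds <- function(params, fraction = 0.1,
                                allow_degenerate = FALSE) {
  stopifnot(inherits(params, "cv_parameters"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (fraction == 0 && !allow_degenerate) {
    stop("fraction = 0 gives a degenerate interval; ",
         "set allow_degenerate = TRUE to permit it")
  }
  base <- flatten_parameters(params)
  a <- base * (1 - fraction)
  b <- base * (1 + fraction)
  tibble::tibble(
    name = names(base),
    base = unname(base),
    low = unname(pmin(a, b)),
    high = unname(pmax(a, b))
  )
}

#' @export
print.cv_parameters <- function(x, ...) {
  cat(sprintf(
    "<cv_parameters> %s, %s | %d perturbable parameters\n",
    toupper(x$variant), if (x$regulated) "regulated" else "unregulated",
    length(x$free)
  ))
  print(utils::head(tidy(x), 10))
  cat("# ... use tidy() for the full table\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set
#'
#' @param x a `cv_parameters` object.
#' @param ... unused.
#' @return tibble with columns `name`, `value`, `free`.
#' @export
tidy.cv_parameters <- function(x, ...) {
  tibble::tibble(
    name = names(x$values),
    value = unname(x$values),
    free = names(x$values) %in% x$free
  )
}

# ---- packed encoding for the C++ core ----

# dense numeric vector in .packed_names order; 1CH slots missing from the
# variant are filled with inert placeholders (never read by the 1CH RHS)
pack_parameters <- function(params) {
  stopifnot(inherits(params, "cv_parameters"))
  out <- stats::setNames(rep(1.0, length(.packed_names)), .packed_names)
  # placeholders that keep every formula well-defined if touched
  out[c("tau_initA_frac", "tau_s1a_frac", "tau_s2a_frac")] <- c(0.92, 0.96, 1.0)
  out["tau_initV_frac"] <- 0
  out["V_unV_init"] <- 0
  out[names(params$values)] <- params$values
  out
}

.variant_code <- function(params) if (params$variant == "1ch") 1L else 2L

# ---- YAML config round-trip ----

.config_sections <- c("model", "mechanical", "baroreflex",
                      "simulation", "sensitivity")

#' Write a model configuration file
#'
#' Serialises a parameter set (plus optional simulation and sensitivity
#' settings) to a nested YAML file with sections `model`, `mechanical`,
#' `baroreflex`, `simulation`, `sensitivity`.
#'
#' @param params a `cv_parameters` object.
#' @param path output file path.
#' @param simulation optional named list of [sim_config()] fields.
#' @param sensitivity optional named list of sensitivity settings.
#' @return `path`, invisibly.
#' @export
write_cv_config <- function(params, path, simulation = NULL,
                            sensitivity = NULL) {
  stopifnot(inherits(params, "cv_parameters"))
  mech_names <- if (params$variant == "1ch") .mech_names_1ch else .mech_names_4ch
  cfg <- list(
    model = list(variant = params$variant, regulated = params$regulated),
    mechanical = as.list(params$values[mech_names])
  )
  if (params$regulated) {
    baro_names <- if (params$variant == "1ch") .baro_names_1ch else .baro_names_4ch
    cfg$baroreflex <- as.list(params$values[baro_names])
  }
  if (!is.null(simulation)) cfg$simulation <- simulation
  if (!is.null(sensitivity)) cfg$sensitivity <- sensitivity
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a model configuration file
#'
#' Inverse of [write_cv_config()]. Unknown sections or keys are errors.
#'
#' @param path YAML file written by [write_cv_config()] (or by hand in
#'   the same schema).
#' @return list with elements `params` (a `cv_parameters`),
#'   `simulation`, `sensitivity` (the latter two possibly `NULL`).
#' @export
read_cv_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .config_sections)
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$model$variant)) stop("config is missing model: variant")
  variant <- match.arg(cfg$model$variant, c("1ch", "4ch"))
  regulated <- isTRUE(cfg$model$regulated)
  overrides <- c(unlist(cfg$mechanical), unlist(cfg$baroreflex))
  defaults <- if (variant == "1ch") .defaults_1ch else .defaults_4ch
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  }
  params <- default_parameters(variant, regulated, overrides = overrides)
  list(params = params, simulation = cfg$simulation,
       sensitivity = cfg$sensitivity)
}
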