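# Reproducible perturbed parameter sets and run manifests.

#' Generate perturbed parameter fixtures
#'
#' Draws `n` parameter sets uniformly inside the perturbation box
#' (default +/-10% around the base state), each validated. Deterministic
#' given the seed; distinct seeds give distinct draws.
#'
#' @param params a `cv_parameters` template.
#' @param n number of fixtures (0 gives an empty list).
#' @param fraction perturbation half-width.
#' @param seed integer seed.
#' @return list of `cv_parameters` objects.
#' @export
perturbed_parameter_sets <- function(params, n, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(params, "cv_parameters"), n >= 0)
  if (n == 0) return(list())
  b <- perturbation_bounds(params, fraction)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      repeat {
        v <- stats::runif(nrow(b), b$low, b$high)
        out <- try(unflatten_parameters(params, v), silent = TRUE)
        if (!inherits(out, "try-error")) return(out)
      }
    })
  })
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seed, package version,
#' wall-clock interval and produced artifact paths as JSON, one manifest
#' per artifact-producing command.
#'
#' @param path output JSON path.
#' @param command command label.
#' @param config list snapshot of the configuration used.
#' @param seed integer seed (or NA).
#' @param outputs character vector of produced file paths.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NA,
                               outputs = character(),
                               started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("baroloop")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a trajectory or sensitivity result to CSV
#'
#' Trajectories are written one row per sample with columns named by
#' state symbol; output sets as key/value pairs; Sobol and local
#' sensitivity results as long-format tables.
#'
#' @param x a `cv_trajectory`, `cv_outputs`, `cv_sobol` or `cv_lsa`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  d <- if (inherits(x, "cv_outputs")) {
    tibble::tibble(output = names(x), value = as.numeric(x[1, ]))
  } else if (inherits(x, c("cv_sobol", "cv_lsa"))) {
    tidy(x)
  } else if (inherits(x, "cv_trajectory")) {
    tibble::as_tibble(x)
  } else {
    tibble::as_tibble(x)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
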