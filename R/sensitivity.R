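# Sensitivity analysis: scaled local sensitivity matrices (central
# differences with a Richardson step-halving check) and variance-based
# Sobol analysis with the Saltelli (2010) first-order and Jansen (1999)
# total-order estimators, space-filling A/B designs, joint-row bootstrap
# confidence intervals, the convergence schedule and error summaries.

# ---- designs ----

#' Build a Sobol A/B sampling design
#'
#' Draws the two independent base matrices A and B over the perturbation
#' box. The default sampler is a seeded randomised Latin hypercube over
#' 2n dimensions (split into A and B), giving stratified space-filling
#' coverage; `"random"` gives plain Monte Carlo. The radial matrices
#' AB_i (A with column i replaced from B) are formed lazily, so a full
#' evaluation costs K (n + 2) model runs.
#'
#' @param bounds tibble with columns `name`, `low`, `high` (see
#'   [perturbation_bounds()]).
#' @param K number of base samples (powers of two recommended).
#' @param seed integer seed; the design is reproducible bit-for-bit.
#' @param sampler `"lhs"` or `"random"`.
#' @return a `cv_sobol_design`: list with matrices `A`, `B` (K x n,
#'   columns named), `bounds`, `K`, `seed`, `sampler`.
#' @export
sobol_design <- function(bounds, K, seed = 1L, sampler = c("lhs", "random")) {
  sampler <- match.arg(sampler)
  stopifnot(is.data.frame(bounds), all(c("name", "low", "high") %in% names(bounds)),
            K >= 2)
  n <- nrow(bounds)
  u <- withr::with_seed(as.integer(seed), {
    if (sampler == "lhs") lhs::randomLHS(K, 2L * n) else
      matrix(stats::runif(K * 2L * n), nrow = K)
  })
  lo <- bounds$low; hi <- bounds$high
  scale01 <- function(m) sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
  A <- scale01(u[, seq_len(n), drop = FALSE])
  B <- scale01(u[, n + seq_len(n), drop = FALSE])
  colnames(A) <- colnames(B) <- bounds$name
  structure(
    list(A = A, B = B, bounds = bounds, K = K, seed = as.integer(seed),
         sampler = sampler),
    class = "cv_sobol_design"
  )
}

#' Stack a Sobol design into its evaluation matrix
#'
#' Rows are ordered A block, B block, then the n radial AB_i blocks
#' (A with column i replaced from B), `K (n + 2)` rows in total —
#' the layout [sobol_estimate()] expects.
#'
#' @param design a `cv_sobol_design`.
#' @return numeric matrix with named columns.
#' @export
design_rows <- function(design) {
  stopifnot(inherits(design, "cv_sobol_design"))
  A <- design$A; B <- design$B
  n <- ncol(A); K <- nrow(A)
  X <- matrix(NA_real_, nrow = K * (n + 2L), ncol = n,
              dimnames = list(NULL, colnames(A)))
  X[seq_len(K), ] <- A
  X[K + seq_len(K), ] <- B
  for (i in seq_len(n)) {
    ABi <- A
    ABi[, i] <- B[, i]
    X[(i + 1L) * K + seq_len(K), ] <- ABi
  }
  X
}

# ---- estimators ----

# Saltelli 2010 first-order and Jansen 1999 total-order estimators with
# joint-row bootstrap. YA, YB: K x m; YAB: K x m x n.
sobol_estimate_core <- function(YA, YB, YAB, B_boot, seed,
                                parameter_names, output_names) {
  K <- nrow(YA); m <- ncol(YA); n <- dim(YAB)[3]
  # centre the outputs before forming the Saltelli products: the
  # estimator's expectation is unchanged by a constant shift, but the
  # Monte-Carlo variance would otherwise be inflated by (mean/sd)^2
  mu0 <- (colMeans(YA) + colMeans(YB)) / 2
  YBc <- sweep(YB, 2, mu0)
  # per-parameter product/square blocks, precomputed once
  P <- vector("list", n)   # Saltelli numerator terms, K x m
  Q <- vector("list", n)   # Jansen numerator terms, K x m
  for (i in seq_len(n)) {
    P[[i]] <- YBc * (YAB[, , i] - YA)
    Q[[i]] <- (YA - YAB[, , i])^2
  }
  est_at <- function(idx) {
    ya <- YA[idx, , drop = FALSE]; yb <- YB[idx, , drop = FALSE]
    mu <- (colMeans(ya) + colMeans(yb)) / 2
    vy <- (colMeans(ya^2) + colMeans(yb^2)) / 2 - mu^2
    vy[vy <= 0] <- NA_real_
    s1 <- matrix(NA_real_, n, m)
    st <- matrix(NA_real_, n, m)
    for (i in seq_len(n)) {
      s1[i, ] <- colMeans(P[[i]][idx, , drop = FALSE]) / vy
      st[i, ] <- colMeans(Q[[i]][idx, , drop = FALSE]) / (2 * vy)
    }
    list(s1 = s1, st = st)
  }
  point <- est_at(seq_len(K))
  ci <- NULL
  if (B_boot > 0) {
    bs1 <- array(NA_real_, c(n, m, B_boot))
    bst <- array(NA_real_, c(n, m, B_boot))
    withr::with_seed(as.integer(seed), {
      for (b in seq_len(B_boot)) {
        idx <- sample.int(K, K, replace = TRUE)
        e <- est_at(idx)
        bs1[, , b] <- e$s1
        bst[, , b] <- e$st
      }
    })
    qf <- function(a, pr) apply(a, c(1, 2), stats::quantile, probs = pr,
                                na.rm = TRUE)
    ci <- list(
      s1_lo = qf(bs1, 0.025), s1_hi = qf(bs1, 0.975),
      st_lo = qf(bst, 0.025), st_hi = qf(bst, 0.975),
      hi_lo = qf(bst - bs1, 0.025), hi_hi = qf(bst - bs1, 0.975)
    )
  }
  dimnames(point$s1) <- dimnames(point$st) <-
    list(parameter_names, output_names)
  structure(
    list(S1 = point$s1, ST = point$st, higher = point$st - point$s1,
         ci = ci, K = K, B = B_boot, seed = as.integer(seed)),
    class = "cv_sobol"
  )
}

#' Estimate Sobol indices from arranged model evaluations
#'
#' Takes the output matrix evaluated on the rows of [design_rows()] (A
#' block, B block, then the n radial AB_i blocks) and returns first-order
#' (Saltelli 2010), total-order (Jansen 1999) and higher-order (ST - S1)
#' index matrices with bootstrap 95% confidence bounds. Bootstrap
#' resampling draws rows of the (A, B, AB_i) blocks jointly, preserving
#' the estimator pairing. Negative Monte-Carlo estimates are retained;
#' clipping happens only at display time.
#'
#' @param Y numeric matrix of evaluations, `K * (n + 2)` rows, one
#'   column per model output (columns named).
#' @param design the `cv_sobol_design` used to generate the rows.
#' @param B_boot number of bootstrap resamples (0 disables CIs).
#' @param seed bootstrap seed.
#' @return a `cv_sobol` object; see [tidy.cv_sobol()].
#' @export
sobol_estimate <- function(Y, design, B_boot = 100, seed = 1L) {
  stopifnot(inherits(design, "cv_sobol_design"))
  Y <- as.matrix(Y)
  n <- ncol(design$A); K <- design$K
  if (nrow(Y) != K * (n + 2L)) {
    stop("Y must have K*(n+2) = ", K * (n + 2L), " rows")
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  m <- ncol(Y)
  const <- apply(Y, 2, function(col) {
    all(is.finite(col)) && stats::sd(col) == 0
  })
  if (any(const)) {
    warning("output(s) with zero variance flagged as undefined: ",
            paste(colnames(Y)[const], collapse = ", "))
  }
  YA <- Y[seq_len(K), , drop = FALSE]
  YB <- Y[K + seq_len(K), , drop = FALSE]
  YAB <- array(NA_real_, c(K, m, n))
  for (i in seq_len(n)) {
    YAB[, , i] <- Y[(i + 1L) * K + seq_len(K), , drop = FALSE]
  }
  res <- sobol_estimate_core(YA, YB, YAB, B_boot, seed,
                             colnames(design$A), colnames(Y))
  res$sampler <- design$sampler
  res
}

#' Sobol analysis of a plain R function
#'
#' Convenience driver for closed-form test functions and oracles:
#' builds the design, evaluates `fn` on every row, and estimates.
#'
#' @param fn function taking a numeric matrix (rows = evaluation points,
#'   named columns) and returning a numeric vector or matrix of outputs.
#' @param bounds tibble `name`/`low`/`high`.
#' @param K,B_boot,seed,sampler as in [sobol_design()] /
#'   [sobol_estimate()].
#' @return a `cv_sobol` object.
#' @export
sobol_indices_fn <- function(fn, bounds, K, B_boot = 100, seed = 1L,
                             sampler = "lhs") {
  design <- sobol_design(bounds, K, seed = seed, sampler = sampler)
  X <- design_rows(design)
  Y <- fn(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(NULL, "y"))
  sobol_estimate(Y, design, B_boot = B_boot, seed = seed)
}

# ---- model-level drivers ----

# expand free-parameter rows into packed full-parameter rows
.packed_rows <- function(params, X) {
  base <- pack_parameters(params)
  M <- matrix(rep(base, each = nrow(X)), nrow = nrow(X),
              dimnames = list(NULL, names(base)))
  M[, colnames(X)] <- X
  M
}

# rows whose timing fractions are invalidly ordered (possible when the
# atrial fractions are perturbed jointly) are flagged as failed runs
.valid_timing_rows <- function(M) {
  ok <- M[, "tau_s1v_frac"] > M[, "tau_initV_frac"] &
    M[, "tau_s2v_frac"] > M[, "tau_s1v_frac"] &
    M[, "tau_s2v_frac"] <= 1
  ok & M[, "tau_s1a_frac"] > M[, "tau_initA_frac"] &
    M[, "tau_s2a_frac"] > M[, "tau_s1a_frac"]
}

# evaluate the model's SA output vector on free-parameter rows
.evaluate_model_rows <- function(params, X, config) {
  h <- config$step_size %||% .default_step(params, config)
  t_end <- config$t_end %||% .default_t_end(params)
  M <- .packed_rows(params, X)
  ok <- .valid_timing_rows(M)
  Y <- matrix(NA_real_, nrow(M), length(.output_names(params$variant)),
              dimnames = list(NULL, .output_names(params$variant)))
  if (any(ok)) {
    Y[ok, ] <- cv_batch_outputs(
      M[ok, , drop = FALSE], .variant_code(params), params$regulated,
      t_end, h, config$promotion_sigma, config$promotion_gain
    )
  }
  # heart period is constant in unregulated runs: excluded from SA outputs
  if (!params$regulated) Y <- Y[, colnames(Y) != "tau_HR", drop = FALSE]
  Y
}

#' Global (Sobol) sensitivity analysis of a model variant
#'
#' Runs the full variance-based pipeline: the perturbation box (default
#' +/-10% around the base state of every perturbable parameter), the
#' A/B/AB_i design, `K (n + 2)` model evaluations with step-tracked
#' output extrema, and the Saltelli/Jansen estimators with joint-row
#' bootstrap confidence intervals. Heart period is excluded from the
#' outputs of unregulated variants (it is constant there).
#'
#' Runs that fail (non-finite outputs, or timing orderings broken by a
#' joint perturbation) are imputed with the base-point output and
#' logged; a failure rate above `max_fail` aborts with diagnostics.
#'
#' @param params a `cv_parameters` object.
#' @param K number of base samples.
#' @param B_boot bootstrap resamples.
#' @param seed design + bootstrap seed.
#' @param fraction perturbation half-width (default 0.10).
#' @param config a [sim_config()]; horizon and step defaults are
#'   variant-appropriate.
#' @param sampler `"lhs"` (default) or `"random"`.
#' @param max_fail maximum tolerated failed-run fraction (default 1%).
#' @return a `cv_sobol` with an extra `failed` attribute (failed row
#'   indices in the evaluation stack).
#' @export
run_gsa <- function(params, K, B_boot = 100, seed = 1L, fraction = 0.1,
                    config = sim_config(), sampler = "lhs",
                    max_fail = 0.01) {
  stopifnot(inherits(params, "cv_parameters"))
  bounds <- perturbation_bounds(params, fraction)
  design <- sobol_design(bounds, K, seed = seed, sampler = sampler)
  X <- design_rows(design)
  Y <- .evaluate_model_rows(params, X, config)
  bad <- which(!stats::complete.cases(Y))
  if (length(bad) > nrow(Y) * max_fail) {
    stop("model failure rate ", signif(length(bad) / nrow(Y), 3),
         " exceeds ", max_fail, "; first failed rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(bad) > 0) {
    base_y <- .evaluate_model_rows(params, .base_free_row(params), config)
    Y[bad, ] <- matrix(rep(base_y[1, ], length(bad)), byrow = TRUE,
                       nrow = length(bad))
    message(length(bad), " failed run(s) imputed with the base-point output")
  }
  res <- sobol_estimate(Y, design, B_boot = B_boot, seed = seed)
  res$params <- params
  res$fraction <- fraction
  attr(res, "failed") <- bad
  res
}

.base_free_row <- function(params) {
  matrix(flatten_parameters(params), nrow = 1,
         dimnames = list(NULL, params$free))
}

# ---- local sensitivity ----

#' Scaled local sensitivity matrix
#'
#' Relative (scaled) local sensitivities
#' `S_ij = (theta_i / y_j) dy_j / d theta_i` about the base state, by
#' central finite differences with relative step `step`. With
#' `richardson = TRUE` the derivative is recomputed at `step / 2` and
#' entries where the two disagree by more than 1% (relative, above a
#' small absolute floor) are flagged. Outputs that vanish at the base
#' point make the scaling undefined; those columns are flagged, not
#' dropped.
#'
#' Methods exist for `cv_parameters` (the model) and for a plain
#' function `fn(theta) -> named outputs` (closed-form harnesses).
#'
#' @param x a `cv_parameters` object or a function.
#' @param ... passed to methods.
#' @return a `cv_lsa`: list with the scaled matrix `S` (parameters x
#'   outputs), `base_outputs`, `step`, and logical matrices `flagged`
#'   (Richardson disagreement) / `undefined` (zero base output).
#' @export
local_sensitivity <- function(x, ...) UseMethod("local_sensitivity")

.lsa_assemble <- function(evaluate, theta, step, richardson, output_names) {
  n <- length(theta)
  y0 <- drop(evaluate(matrix(theta, nrow = 1,
                             dimnames = list(NULL, names(theta)))))
  m <- length(y0)
  deriv_at <- function(s) {
    X <- matrix(rep(theta, each = 2L * n), nrow = 2L * n,
                dimnames = list(NULL, names(theta)))
    for (i in seq_len(n)) {
      X[2L * i - 1L, i] <- theta[i] * (1 + s)
      X[2L * i, i] <- theta[i] * (1 - s)
    }
    Y <- evaluate(X)
    D <- matrix(NA_real_, n, m)
    for (i in seq_len(n)) {
      D[i, ] <- (Y[2L * i - 1L, ] - Y[2L * i, ]) / (2 * s * theta[i])
    }
    D
  }
  D <- deriv_at(step)
  flagged <- matrix(FALSE, n, m)
  if (richardson) {
    D2 <- deriv_at(step / 2)
    # disagreement is judged against the derivative, floored at a small
    # fraction of the output's dominant derivative so negligible entries
    # are not flagged for noise alone
    col_scale <- apply(abs(D2), 2, max)
    denom <- pmax(abs(D2), matrix(0.05 * col_scale, n, m, byrow = TRUE))
    flagged <- abs(D - D2) / denom > 0.01
    D <- D2  # the finer-step estimate is kept
  }
  undefined <- matrix(rep(abs(y0) < 1e-12, each = n), nrow = n)
  S <- D * outer(theta, ifelse(abs(y0) < 1e-12, NA_real_, 1 / y0))
  dimnames(S) <- dimnames(flagged) <- dimnames(undefined) <-
    list(names(theta), output_names)
  structure(
    list(S = S, base_outputs = y0, step = step,
         flagged = flagged, undefined = undefined),
    class = "cv_lsa"
  )
}

#' @rdname local_sensitivity
#' @param config a [sim_config()] (model method).
#' @param step relative perturbation for the central difference.
#' @param richardson verify derivatives by step halving?
#' @export
local_sensitivity.cv_parameters <- function(x, config = sim_config(),
                                            step = 1e-4, richardson = TRUE,
                                            ...) {
  theta <- flatten_parameters(x)
  out_names <- .output_names(x$variant)
  if (!x$regulated) out_names <- setdiff(out_names, "tau_HR")
  res <- .lsa_assemble(
    function(X) {
      Y <- .evaluate_model_rows(x, X, config)
      if (any(!is.finite(Y))) stop("base model run failed during LSA")
      Y
    },
    theta, step, richardson, out_names
  )
  res$params <- x
  res
}

#' @rdname local_sensitivity
#' @param theta named numeric base point (function method).
#' @export
local_sensitivity.function <- function(x, theta, step = 1e-4,
                                       richardson = TRUE, ...) {
  stopifnot(!is.null(names(theta)))
  evaluate <- function(X) {
    out <- apply(X, 1, x)
    if (is.matrix(out)) t(out) else
      matrix(out, ncol = 1, dimnames = list(NULL, "y"))
  }
  probe <- evaluate(matrix(theta, nrow = 1,
                           dimnames = list(NULL, names(theta))))
  out_names <- colnames(probe) %||% paste0("y", seq_len(ncol(probe)))
  .lsa_assemble(evaluate, theta, step, richardson, out_names)
}

# ---- convergence study and error summaries ----

#' The study's convergence sampling schedule
#'
#' K = 100..2000 by 100 with 100 bootstrap resamples, 2500..10000 by 500
#' and 15000..150000 by 5000 with 1000 resamples.
#'
#' @param max_k truncate the schedule at this sample count.
#' @return tibble with columns `K`, `B`.
#' @export
convergence_schedule <- function(max_k = 150000) {
  k <- as.integer(c(seq(100, 2000, by = 100), seq(2500, 10000, by = 500),
                    seq(15000, 150000, by = 5000)))
  b <- ifelse(k <= 2000, 100L, 1000L)
  out <- tibble::tibble(K = k, B = b)
  out[out$K <= max_k, ]
}

#' Convergence trace of selected sensitivity indices
#'
#' Re-estimates the Sobol indices over a schedule of sample counts and
#' records the selected (parameter, output) entries with their bootstrap
#' confidence bounds, so the Monte-Carlo convergence (half-widths
#' shrinking like K^-1/2) can be inspected.
#'
#' @param x a `cv_parameters` object or a function (as in
#'   [sobol_indices_fn()]).
#' @param schedule tibble `K`/`B` (see [convergence_schedule()]).
#' @param pairs tibble with columns `parameter`, `output` selecting the
#'   entries to trace (`output` is ignored for single-output functions);
#'   `NULL` keeps everything.
#' @param seed base seed; each schedule point uses `seed + K`.
#' @param ... passed to [run_gsa()] or [sobol_indices_fn()] (`bounds`
#'   is required for the function method).
#' @return a `cv_convergence` tibble: `K`, `B`, `parameter`, `output`,
#'   `order`, `index`, `ci_low`, `ci_high`.
#' @export
convergence_study <- function(x, schedule, pairs = NULL, seed = 1L, ...) {
  stopifnot(is.data.frame(schedule), all(c("K", "B") %in% names(schedule)))
  rows <- lapply(seq_len(nrow(schedule)), function(r) {
    K <- schedule$K[r]; B <- schedule$B[r]
    res <- if (inherits(x, "cv_parameters")) {
      run_gsa(x, K = K, B_boot = B, seed = seed + K, ...)
    } else {
      sobol_indices_fn(x, K = K, B_boot = B, seed = seed + K, ...)
    }
    d <- tidy(res)
    d <- d[d$order %in% c("first", "total"), ]
    if (!is.null(pairs)) {
      keep <- if ("output" %in% names(pairs)) {
        paste(d$parameter, d$output) %in% paste(pairs$parameter, pairs$output)
      } else {
        d$parameter %in% pairs$parameter
      }
      d <- d[keep, ]
    }
    d$K <- K; d$B <- B
    d
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_convergence", class(out))
  out
}

#' Aggregate bootstrap error of a Sobol result
#'
#' Mean and range of the 95% confidence-interval half-widths per index
#' order, the margin-of-error summary used to judge convergence.
#'
#' @param result a `cv_sobol` with bootstrap CIs.
#' @return tibble: `order`, `mean_error`, `min_error`, `max_error`,
#'   `n_entries`.
#' @export
error_summary <- function(result) {
  stopifnot(inherits(result, "cv_sobol"))
  if (is.null(result$ci)) stop("bootstrap was disabled; no error to summarise")
  d <- tidy(result)
  d <- d[d$order %in% c("first", "total"), ]
  d$half_width <- (d$ci_high - d$ci_low) / 2
  if (all(is.na(d$half_width))) {
    warning("all bootstrap half-widths undefined (zero-variance outputs?)")
  }
  dplyr::summarise(
    dplyr::group_by(d, .data$order),
    mean_error = mean(.data$half_width, na.rm = TRUE),
    min_error = min(.data$half_width, na.rm = TRUE),
    max_error = max(.data$half_width, na.rm = TRUE),
    n_entries = dplyr::n(),
    .groups = "drop"
  )
}

# ---- tidy/plot methods ----

#' Tidy a Sobol result
#'
#' @param x a `cv_sobol`.
#' @param ... unused.
#' @return long tibble: `parameter`, `output`, `order` (first / total /
#'   higher), `index`, `ci_low`, `ci_high`.
#' @export
tidy.cv_sobol <- function(x, ...) {
  melt <- function(M, ord, lo, hi) {
    tibble::tibble(
      parameter = rep(rownames(M), times = ncol(M)),
      output = rep(colnames(M), each = nrow(M)),
      order = ord,
      index = as.vector(M),
      ci_low = if (is.null(lo)) NA_real_ else as.vector(lo),
      ci_high = if (is.null(hi)) NA_real_ else as.vector(hi)
    )
  }
  ci <- x$ci
  dplyr::bind_rows(
    melt(x$S1, "first", ci$s1_lo, ci$s1_hi),
    melt(x$ST, "total", ci$st_lo, ci$st_hi),
    melt(x$higher, "higher", ci$hi_lo, ci$hi_hi)
  )
}

#' @export
print.cv_sobol <- function(x, ...) {
  cat(sprintf("<cv_sobol> %d parameters x %d outputs | K = %d, B = %d\n",
              nrow(x$S1), ncol(x$S1), x$K, x$B))
  cat("First-order indices (head):\n")
  print(utils::head(round(x$S1, 4), 5))
  invisible(x)
}

#' One-line summary of a Sobol result
#'
#' @param x a `cv_sobol`.
#' @param ... unused.
#' @return one-row tibble with design size and index ranges.
#' @export
glance.cv_sobol <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x$S1), n_outputs = ncol(x$S1),
    K = x$K, B = x$B, seed = x$seed,
    max_S1 = max(x$S1, na.rm = TRUE), max_ST = max(x$ST, na.rm = TRUE)
  )
}

# per-output display normalisation: |value| / column max
.heat_norm <- function(d) {
  dplyr::mutate(
    dplyr::group_by(d, .data$output, .data$order),
    display = pmax(.data$index, 0) / max(abs(.data$index), na.rm = TRUE)
  )
}

#' Sensitivity heatmap
#'
#' Parameters x outputs tile plot of the chosen index order, with each
#' output column normalised by its maximum absolute entry so values read
#' on \[0, 1\]; negative Monte-Carlo estimates are clipped at zero for
#' display only (the stored results retain them).
#'
#' @param object a `cv_sobol`.
#' @param order `"first"`, `"total"` or `"higher"`.
#' @param normalize per-output-column display normalisation?
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_sobol <- function(object, order = "first", normalize = TRUE, ...) {
  d <- tidy(object)
  d <- d[d$order == order, ]
  d <- if (normalize) dplyr::ungroup(.heat_norm(d)) else
    dplyr::mutate(d, display = .data$index)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$output, y = .data$parameter,
                                  fill = .data$display)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "magma", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste(order, "order")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tidy a local sensitivity matrix
#'
#' @param x a `cv_lsa`.
#' @param ... unused.
#' @return long tibble: `parameter`, `output`, `sensitivity`,
#'   `flagged`, `undefined`.
#' @export
tidy.cv_lsa <- function(x, ...) {
  S <- x$S
  tibble::tibble(
    parameter = rep(rownames(S), times = ncol(S)),
    output = rep(colnames(S), each = nrow(S)),
    sensitivity = as.vector(S),
    flagged = as.vector(x$flagged),
    undefined = as.vector(x$undefined)
  )
}

#' @export
print.cv_lsa <- function(x, ...) {
  cat(sprintf("<cv_lsa> %d parameters x %d outputs | step %g\n",
              nrow(x$S), ncol(x$S), x$step))
  print(utils::head(round(x$S, 4), 5))
  invisible(x)
}

#' Local sensitivity heatmap
#'
#' @param object a `cv_lsa`.
#' @param normalize per-output-column |S| normalisation to \[0, 1\]?
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_lsa <- function(object, normalize = TRUE, ...) {
  d <- tidy(object)
  if (normalize) {
    d <- dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(d, .data$output),
      display = abs(.data$sensitivity) /
        max(abs(.data$sensitivity), na.rm = TRUE)
    ))
  } else {
    d$display <- d$sensitivity
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$output, y = .data$parameter,
                                  fill = .data$display)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::labs(x = NULL, y = NULL, fill = "|S| (scaled)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
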