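# Sensitivity machinery on closed-form oracles: designs, Saltelli/Jansen
# estimators with bootstrap CIs, convergence behaviour, local matrices.

test_that("sobol designs are in-bounds, distinct and seed-deterministic", {
  b <- unit_bounds(c("a", "b"), low = c(1, -2), high = c(2, -1))
  d <- sobol_design(b, K = 4, seed = 7)
  for (M in list(d$A, d$B)) {
    expect_true(all(M[, 1] >= 1 & M[, 1] <= 2))
    expect_true(all(M[, 2] >= -2 & M[, 2] <= -1))
  }
  expect_false(identical(d$A, d$B))
  d2 <- sobol_design(b, K = 4, seed = 7)
  expect_identical(d, d2)
  d3 <- sobol_design(b, K = 4, seed = 8)
  expect_false(identical(d$A, d3$A))
  # evaluation cost is K (n + 2)
  expect_identical(nrow(design_rows(d)), 4L * (2L + 2L))
  calls <- 0
  fn <- function(X) { calls <<- calls + nrow(X); rowSums(X) }
  invisible(sobol_indices_fn(fn, b, K = 16, B_boot = 0, seed = 1))
  expect_identical(calls, 16 * (2 + 2))
})

test_that("additive linear model recovers its closed-form indices", {
  # y = x1 + 2 x2 on equal unit ranges: S1 = ST = (0.2, 0.8) exactly
  b <- unit_bounds(c("x1", "x2"))
  fn <- function(X) X[, 1] + 2 * X[, 2]
  r <- sobol_indices_fn(fn, b, K = 8192, B_boot = 200, seed = 3)
  d <- tidy(r)
  exact <- c(x1 = 0.2, x2 = 0.8)
  for (ord in c("first", "total")) {
    for (nm in c("x1", "x2")) {
      row <- d[d$parameter == nm & d$order == ord, ]
      ci_half <- (row$ci_high - row$ci_low) / 2
      expect_lt(abs(row$index - exact[nm]), 3 * ci_half + 1e-9)
    }
  }
  s1 <- r$S1[, 1]
  expect_lt(sum(s1), 1.05)
  expect_gt(sum(s1), 0.9)
})

test_that("Ishigami indices match the published closed form", {
  b <- tibble::tibble(name = c("x1", "x2", "x3"), low = -pi, high = pi)
  r <- sobol_indices_fn(ishigami_fn, b, K = 8192, B_boot = 200, seed = 5)
  ex <- ishigami_exact()
  expect_equal(unname(ex$S1), c(0.3139, 0.4424, 0), tolerance = 1e-3)
  d <- tidy(r)
  for (i in 1:3) {
    s1 <- d[d$parameter == paste0("x", i) & d$order == "first", ]
    st <- d[d$parameter == paste0("x", i) & d$order == "total", ]
    expect_lt(abs(s1$index - ex$S1[i]), 3 * (s1$ci_high - s1$ci_low) / 2 + 1e-9)
    expect_lt(abs(st$index - ex$ST[i]), 3 * (st$ci_high - st$ci_low) / 2 + 1e-9)
  }
})

test_that("pure interaction has zero first-order but full total-order", {
  b <- unit_bounds(c("x1", "x2"), low = -1, high = 1)
  fn <- function(X) X[, 1] * X[, 2]
  r <- sobol_indices_fn(fn, b, K = 8192, B_boot = 100, seed = 9)
  expect_equal(unname(r$S1[, 1]), c(0, 0), tolerance = 0.05)
  expect_equal(unname(r$ST[, 1]), c(1, 1), tolerance = 0.05)
  # total >= first within Monte-Carlo noise, and higher = ST - S1
  expect_true(all(r$ST - r$S1 > -0.02))
  expect_equal(r$higher, r$ST - r$S1)
})

test_that("bootstrap CIs shrink like K^(-1/2)", {
  b <- unit_bounds(c("x1", "x2"))
  fn <- function(X) X[, 1] + 2 * X[, 2]
  half <- function(K) {
    d <- tidy(sobol_indices_fn(fn, b, K = K, B_boot = 200, seed = 13))
    mean((d$ci_high - d$ci_low)[d$order == "first"]) / 2
  }
  h1 <- half(512); h2 <- half(8192)
  ratio <- h1 / h2
  expect_gt(ratio, 4 / 2)     # sqrt(16) = 4 within generous slack
  expect_lt(ratio, 4 * 2)
})

test_that("zero-variance outputs are flagged as undefined", {
  b <- unit_bounds(c("x1", "x2"))
  expect_warning(sobol_indices_fn(function(X) rep(1, nrow(X)), b,
                                  K = 64, B_boot = 10, seed = 1),
                 "zero variance")
})

test_that("error_summary aggregates CI half-widths per order", {
  b <- unit_bounds(c("x1", "x2"))
  r <- sobol_indices_fn(function(X) X[, 1] + 2 * X[, 2], b,
                        K = 1024, B_boot = 100, seed = 4)
  es <- error_summary(r)
  expect_identical(sort(es$order), c("first", "total"))
  d <- tidy(r)
  d1 <- d[d$order == "first", ]
  expect_equal(es$mean_error[es$order == "first"],
               mean((d1$ci_high - d1$ci_low) / 2))
  expect_true(all(es$min_error <= es$mean_error &
                    es$mean_error <= es$max_error))
  r0 <- sobol_indices_fn(function(X) X[, 1], unit_bounds("x1"),
                         K = 256, B_boot = 0, seed = 1)
  expect_error(error_summary(r0), "bootstrap")
})

test_that("convergence schedule follows the reference sampling plan", {
  s <- convergence_schedule()
  expect_identical(s$K[1:20], seq(100L, 2000L, by = 100L))
  expect_true(all(s$B[s$K <= 2000] == 100))
  expect_true(all(s$B[s$K > 2000] == 1000))
  expect_identical(nrow(convergence_schedule(max_k = 2000)), 20L)
  expect_identical(max(s$K), 150000L)
})

test_that("convergence_study traces selected entries over the schedule", {
  b <- unit_bounds(c("x1", "x2"))
  fn <- function(X) X[, 1] + 2 * X[, 2]
  sched <- tibble::tibble(K = c(256L, 1024L, 4096L), B = 100L)
  tr <- convergence_study(fn, sched, pairs = tibble::tibble(parameter = "x2"),
                          seed = 2, bounds = b)
  expect_identical(sort(unique(tr$K)), c(256L, 1024L, 4096L))
  expect_true(all(tr$parameter == "x2"))
  hw <- with(tr[tr$order == "first", ], (ci_high - ci_low) / 2)
  expect_lt(hw[3], hw[1])   # shrinking CIs along the schedule
})

test_that("scaled local sensitivity has the closed-form invariance", {
  # y = theta^2: scaled sensitivity (theta / y) dy/dtheta = 2, any theta
  fn <- function(theta) c(y = unname(theta["a"])^2)
  for (a in c(0.3, 1, 5)) {
    l <- local_sensitivity(fn, theta = c(a = a), step = 1e-4)
    expect_equal(unname(l$S["a", "y"]), 2, tolerance = 1e-6)
    expect_false(any(l$flagged))
  }
  # multi-parameter: zero-influence parameter has exactly zero entry
  fn2 <- function(theta) c(y = unname(theta["a"]) * 3)
  l2 <- local_sensitivity(fn2, theta = c(a = 2, b = 5), step = 1e-4)
  expect_equal(unname(l2$S["b", "y"]), 0)
  expect_equal(unname(l2$S["a", "y"]), 1, tolerance = 1e-8)
  # zero base output flags the scaling as undefined
  fn3 <- function(theta) c(y = unname(theta["a"]) - 2)
  l3 <- local_sensitivity(fn3, theta = c(a = 2), step = 1e-4)
  expect_true(all(is.na(l3$S)))
  expect_true(all(l3$undefined))
})

test_that("model-level GSA runs end to end on a tiny design", {
  p <- default_parameters("1ch", FALSE)
  g <- run_gsa(p, K = 8, B_boot = 10, seed = 3,
               config = sim_config(t_end = 10))
  expect_identical(dim(g$S1), c(9L, 9L))       # tau_HR excluded
  expect_false("tau_HR" %in% colnames(g$S1))
  expect_true(all(is.finite(g$S1)))
  # seed determinism through the full pipeline
  g2 <- run_gsa(p, K = 8, B_boot = 10, seed = 3,
                config = sim_config(t_end = 10))
  expect_identical(g$S1, g2$S1)
  expect_identical(g$ci, g2$ci)
})
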