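test_that("WHAM with one unbiased window is the histogram estimator", {
  th <- thermo_state(300)
  set.seed(2)
  vals <- rnorm(4000, 20, 1)
  vals <- vals[vals >= 16 & vals <= 24]    # keep inside the bin range
  s <- structure(list(window = list(index = 0L, center = 20,
                                    force_constant = 0),
                      values = vals, source_potential = NULL),
                 class = "window_sample")
  edges <- seq(16, 24, by = 0.25)
  sol <- wham(list(s), edges, th)
  h <- hist(vals, breaks = edges, plot = FALSE, right = FALSE)
  keep <- h$counts > 0
  expected <- -th$kT * log(h$counts[keep] / sum(h$counts))
  expect_equal(sol$pmf$w, expected - min(expected), tolerance = 1e-12)
  expect_true(sol$converged)
})

test_that("WHAM recovers a harmonic PMF's curvature on the window grid", {
  th <- thermo_state(300)
  harm <- potential_spec("harmonic", domain = c(15.5, 27), kappa = 0.5,
                         center = 20)
  wg <- fixture_window_grid()
  sams <- sample_windows(harm, wg,
                         sampler_config(n_steps = 8000, seed = 31,
                                        record_interval = 2), th)
  sol <- wham(sams, thermo = th)
  sel <- abs(sol$pmf$grid - 20) < 3
  fit <- lm(w ~ poly(grid, 2, raw = TRUE),
            data = data.frame(grid = sol$pmf$grid[sel], w = sol$pmf$w[sel]))
  kappa_hat <- 2 * coef(fit)[3]
  expect_lt(abs(kappa_hat - 0.5) / 0.5, 0.10)
})

test_that("WHAM flags gaps and non-convergence instead of guessing", {
  th <- thermo_state(300)
  mk <- function(center, vals) structure(
    list(window = list(index = 0L, center = center, force_constant = 10),
         values = vals, source_potential = NULL), class = "window_sample")
  set.seed(4)
  far <- list(mk(0, rnorm(500, 0, 0.2)), mk(8, rnorm(500, 8, 0.2)))
  expect_error(wham(far, seq(-1, 9, by = 0.1), th), "disconnected")
  near <- list(mk(0, rnorm(500, 0, 0.3)), mk(0.5, rnorm(500, 0.5, 0.3)))
  sol <- wham(near, seq(-1, 1.5, by = 0.1), th, max_iter = 1L)
  expect_false(sol$converged)
  expect_gt(sol$residual, 1e-7)
})

test_that("gradient integration recovers analytic PMFs", {
  # exact harmonic gradients: machine-precision quadratic
  harm <- potential_spec("harmonic", domain = c(0, 2), kappa = 4)
  st <- generate_abf_gradient_stream(harm, seq(0, 2, by = 0.01),
                                     n_samples = 10, noise_sd = 0, seed = 1)
  p <- abf_pmf(st)
  truth <- 0.5 * 4 * p$grid^2
  expect_lt(max(abs((p$w - min(truth)) - (truth - min(truth)))), 1e-4)

  # noisy double-well: RMS error < 0.1 kcal/mol
  dw <- fixture_double_well()
  st2 <- generate_abf_gradient_stream(dw, seq(16, 26.5, by = 0.1),
                                      n_samples = 10000, noise_sd = 0.5,
                                      seed = 12)
  p2 <- abf_pmf(st2)
  truth2 <- dw$energy(p2$grid)
  resid <- (p2$w - truth2) - mean(p2$w - truth2)
  expect_lt(sqrt(mean(resid^2)), 0.1)

  rev_stream <- st
  rev_stream$bin_centers <- rev(rev_stream$bin_centers)
  expect_error(abf_pmf(rev_stream), "increasing")
  low <- st; low$n[3] <- 0
  expect_error(abf_pmf(low), "fewer")
})

test_that("overlap matrix matches analytic Gaussian overlap", {
  th <- thermo_state(300)
  set.seed(6)
  sigma <- sqrt(th$kT / 10)     # 0.244 A for k = 10 at 300 K
  mk <- function(center, vals) structure(
    list(window = list(index = 0L, center = center, force_constant = 10),
         values = vals, source_potential = NULL), class = "window_sample")
  a <- mk(20.0, rnorm(40000, 20.0, sigma))
  b <- mk(20.5, rnorm(40000, 20.5, sigma))
  m <- overlap_matrix(list(a, b), seq(18, 22.5, by = 0.05))
  expect_equal(diag(m), c(1, 1))
  expect_equal(m[1, 2], m[2, 1])
  # analytic overlap of equal-width Gaussians: 2 Phi(-d/(2 sigma))
  analytic <- 2 * pnorm(-0.5 / (2 * sigma))
  expect_lt(abs(m[1, 2] - analytic), 0.02)

  ident <- overlap_matrix(list(a, a), seq(18, 22.5, by = 0.05))
  expect_equal(ident[1, 2], 1.0)
  disjoint <- overlap_matrix(list(mk(0, rnorm(1000, 0, 0.1)),
                                  mk(5, rnorm(1000, 5, 0.1))),
                             seq(-1, 6, by = 0.05))
  expect_equal(disjoint[1, 2], 0.0)
  expect_error(overlap_matrix(list(a)), "at least 2")
})

test_that("half-split uncertainty follows the max-deviation rule", {
  u <- half_split_uncertainty(mean, c(1, 2, 3, 1, 2, 3))
  expect_equal(u$uncertainty, 0)
  u2 <- half_split_uncertainty(mean, c(0, 0, 2, 2))
  expect_equal(u2$value, 1)
  expect_equal(u2$half1, 0)
  expect_equal(u2$half2, 2)
  expect_equal(u2$uncertainty, 1)
  # odd n: first half gets floor(n/2) items
  u3 <- half_split_uncertainty(length, as.list(1:5))
  expect_equal(u3$half1, 2)
  expect_equal(u3$half2, 3)
  expect_error(half_split_uncertainty(mean, 1), "at least 2")
  expect_error(
    half_split_uncertainty(function(x) stop("boom"), c(1, 2)),
    "boom")
})

test_that("acceptance reports count per neighbor pair", {
  log <- data.frame(step = rep(c(100, 200), each = 2),
                    pair_lo = c(0L, 2L, 0L, 2L), pair_hi = c(1L, 3L, 1L, 3L),
                    accepted = c(TRUE, FALSE, TRUE, TRUE))
  rep <- exchange_acceptance_report(log)
  expect_equal(rep$rate, c(1.0, 0.5))
  expect_equal(rep$attempted, c(2L, 2L))
  log2 <- data.frame(step = 1:10, pair_lo = 0L, pair_hi = 1L,
                     accepted = rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(exchange_acceptance_report(log2)$rate, 0.3)
  expect_error(exchange_acceptance_report(log[0, ]), "empty")
})

test_that("WHAM is invariant to window relabeling and duplication", {
  th <- thermo_state(300)
  flat <- potential_spec("flat", domain = c(17, 23))
  wg <- make_window_grid(18, 22, 0.5, 10)
  sams <- sample_windows(flat, wg, sampler_config(n_steps = 4000, seed = 55),
                         th)
  edges <- seq(17.4, 22.6, by = 0.1)
  base <- wham(sams, edges, th)
  perm <- wham(rev(sams), edges, th)
  expect_equal(perm$pmf$w, base$pmf$w, tolerance = 1e-6)
  # merging a duplicated window's samples changes nothing
  dup <- sams
  merged <- sams
  merged[[3]]$values <- c(sams[[3]]$values, sams[[3]]$values)
  dup <- c(sams, sams[3])
  expect_equal(wham(dup, edges, th)$pmf$w, wham(merged, edges, th)$pmf$w,
               tolerance = 1e-6)
})

test_that("WHAM and gradient integration agree on one ground truth", {
  th <- thermo_state(300)
  dw <- fixture_double_well()
  wg <- fixture_window_grid()
  sams <- sample_windows(dw, wg, sampler_config(n_steps = 12000, seed = 71,
                                                record_interval = 2), th)
  sol <- wham(sams, thermo = th)
  st <- generate_abf_gradient_stream(dw, sol$bin_edges, n_samples = 1500,
                                     noise_sd = 0.5, seed = 72)
  pa <- abf_pmf(st)
  wa <- pmf_interp(pa, sol$pmf$grid)
  resid <- (sol$pmf$w - wa) - mean(sol$pmf$w - wa)
  expect_lt(sqrt(mean(resid^2)), 0.15)
})

test_that("harmonic curvature recovery improves with sample size", {
  th <- thermo_state(300)
  harm <- potential_spec("harmonic", domain = c(15.5, 27), kappa = 0.5,
                         center = 21)
  wg <- fixture_window_grid()
  err_at <- function(n, seed) {
    sams <- sample_windows(harm, wg, sampler_config(n_steps = n, seed = seed),
                           th)
    sol <- wham(sams, thermo = th)
    sel <- abs(sol$pmf$grid - 21) < 3
    fit <- lm(w ~ poly(grid, 2, raw = TRUE),
              data = data.frame(grid = sol$pmf$grid[sel],
                                w = sol$pmf$w[sel]))
    abs(2 * coef(fit)[3] - 0.5)
  }
  sizes <- c(500, 2000, 8000)
  mean_err <- vapply(sizes, function(n)
    mean(vapply(1:5, function(s) err_at(n, 100 * s + n), 1)), 1)
  expect_true(mean_err[3] < mean_err[1])
})
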