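# Synthetic biased-sampling generators: umbrella windows, replica
# exchange between windows, and ABF-style gradient streams on analytic
# toy potentials. These provide desk-scale stand-ins for the biased MD
# the estimators were designed for; only the stationary distributions
# matter, not the dynamics.

#' Build an umbrella-sampling window grid
#'
#' Stratifies a coordinate range into equally spaced harmonic windows.
#' The canonical separation grid is 20 windows with centers from 16.5 to
#' 26.0 Angstroms at 0.5 A spacing and a spring constant of
#' 10 kcal mol^-1 A^-2.
#'
#' @param lo,hi First and last window centers (inclusive), Angstroms.
#' @param spacing Center-to-center spacing, Angstroms (> 0).
#' @param force_constant Full harmonic force constant k in the bias
#'   u(xi) = (k/2)(xi - center)^2, kcal mol^-1 A^-2.
#' @return A data frame of class `window_grid` with columns `index`
#'   (0-based, as window indices are conventionally reported), `center`
#'   and `force_constant`.
#' @examples
#' nrow(make_window_grid(16.5, 26.0, 0.5, 10))  # 20
#' @export
make_window_grid <- function(lo, hi, spacing, force_constant = 10) {
  stopifnot(is.finite(lo), is.finite(hi), is.finite(spacing))
  if (!(lo < hi)) stop("need lo < hi, got lo=", lo, " hi=", hi)
  if (spacing <= 0) stop("spacing must be positive, got ", spacing)
  if (force_constant < 0) stop("force_constant must be >= 0")
  n_steps <- (hi - lo) / spacing
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("window range [", lo, ", ", hi, "] is not commensurate with spacing ",
         spacing)
  centers <- lo + spacing * seq(0, round(n_steps))
  out <- data.frame(index = seq_along(centers) - 1L, center = centers,
                    force_constant = force_constant)
  class(out) <- c("window_grid", "data.frame")
  out
}

#' Sampler configuration
#'
#' @param scheme "metropolis" (random-walk Metropolis, step size auto-tuned
#'   to a 30--50% acceptance rate during burn-in) or "overdamped-langevin"
#'   (Euler--Maruyama discretization; carries an O(dt) discretization bias
#'   and is provided for qualitative use only).
#' @param n_steps Number of recorded samples to produce (> 0).
#' @param step_size Initial proposal step (Metropolis) or sqrt(2 D dt)
#'   (Langevin), in coordinate units. `NULL` auto-initializes to the
#'   thermal width of the tightest bias present.
#' @param seed Integer seed; identical seed and configuration give an
#'   identical sample stream.
#' @param record_interval Steps between recorded samples (thinning).
#' @param burn_in_frac Fraction of additional leading steps discarded
#'   (and, for Metropolis, used for step-size adaptation).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(scheme = c("metropolis", "overdamped-langevin"),
                           n_steps = 10000L, step_size = NULL, seed = 1L,
                           record_interval = 1L, burn_in_frac = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(n_steps > 0, record_interval >= 1, burn_in_frac >= 0,
            burn_in_frac < 1)
  structure(list(scheme = scheme, n_steps = as.integer(n_steps),
                 step_size = step_size, seed = as.integer(seed),
                 record_interval = as.integer(record_interval),
                 burn_in_frac = burn_in_frac),
            class = "sampler_config")
}

# Advance n parallel chains by one MCMC step. Positions outside the
# (extended) domain are rejected, i.e. the domain acts as hard walls.
step_chains <- function(x, energy_fun, step, beta, domain, scheme,
                        grad_fun = NULL) {
  n <- length(x)
  if (scheme == "metropolis") {
    prop <- x + stats::runif(n, -step, step)
    ok <- prop >= domain[1] & prop <= domain[2]
    dE <- ifelse(ok, energy_fun(prop) - energy_fun(x), Inf)
    acc <- log(stats::runif(n)) < -beta * dE
    x[acc] <- prop[acc]
    list(x = x, accepted = acc)
  } else {
    drift <- -0.5 * step^2 * beta * grad_fun(x)
    prop <- x + drift + step * stats::rnorm(n)
    prop <- pmin(pmax(prop, domain[1]), domain[2])
    list(x = prop, accepted = rep(TRUE, n))
  }
}

# Core driver shared by sample_biased() and run_reus(): runs one chain
# per window with optional neighbor exchanges. Returns recorded samples
# (matrix: recorded step x window) and the exchange log.
run_window_chains <- function(potential, windows, config, thermo,
                              exchange_interval = NULL,
                              alternation = c("even-first", "odd-first")) {
  alternation <- match.arg(alternation)
  n_w <- nrow(windows)
  beta <- thermo$beta
  domain <- potential$domain
  centers <- windows$center
  ks <- windows$force_constant
  energy_fun <- function(x) potential$energy(x) + 0.5 * ks * (x - centers)^2
  grad_fun <- function(x) potential$gradient(x) + ks * (x - centers)
  bias_e <- function(w, x) 0.5 * ks[w] * (x - centers[w])^2

  step0 <- config$step_size
  if (is.null(step0)) {
    kmax <- max(ks, 0)
    step0 <- if (kmax > 0) 2.4 * sqrt(1 / (beta * kmax)) else
      0.2 * diff(domain)
  }
  step <- rep(step0, n_w)

  n_record <- config$n_steps
  total_main <- n_record * config$record_interval
  n_burn <- ceiling(config$burn_in_frac * total_main)
  x <- pmin(pmax(centers, domain[1]), domain[2])
  if (all(ks == 0)) x <- rep(mean(domain), n_w)

  samples <- matrix(NA_real_, nrow = n_record, ncol = n_w)
  log_rows <- list()
  with_seed(config$seed, {
    # burn-in with per-chain step adaptation (Metropolis only)
    acc_count <- rep(0L, n_w); acc_window <- 0L
    for (i in seq_len(n_burn)) {
      st <- step_chains(x, energy_fun, step, beta, domain, config$scheme,
                        grad_fun)
      x <- st$x
      acc_count <- acc_count + st$accepted
      acc_window <- acc_window + 1L
      if (config$scheme == "metropolis" && acc_window == 50L) {
        rate <- acc_count / 50
        step <- step * ifelse(rate > 0.5, 1.25, ifelse(rate < 0.3, 0.8, 1))
        acc_count[] <- 0L; acc_window <- 0L
      }
    }
    zero_acc_check <- 0L
    rec <- 0L
    parity <- if (alternation == "even-first") 0L else 1L
    for (i in seq_len(total_main)) {
      st <- step_chains(x, energy_fun, step, beta, domain, config$scheme,
                        grad_fun)
      x <- st$x
      zero_acc_check <- if (any(st$accepted)) 0L else zero_acc_check + 1L
      if (zero_acc_check > 1000L)
        stop("zero acceptance over 1000 consecutive steps; ",
             "sampler is stuck")
      if (!is.null(exchange_interval) && i %% exchange_interval == 0L) {
        lo <- if (parity + 1L <= n_w - 1L)
          seq.int(parity + 1L, n_w - 1L, by = 2L) else integer(0)
        if (length(lo) > 0L) {
          hi <- lo + 1L
          delta <- (bias_e(lo, x[hi]) + bias_e(hi, x[lo])) -
                   (bias_e(lo, x[lo]) + bias_e(hi, x[hi]))
          acc <- log(stats::runif(length(lo))) < -beta * delta
          tmp <- x[lo][acc]; x[lo][acc] <- x[hi][acc]; x[hi][acc] <- tmp
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(step = i, pair_lo = windows$index[lo],
                       pair_hi = windows$index[hi], accepted = acc)
        }
        parity <- 1L - parity
      }
      if (i %% config$record_interval == 0L) {
        rec <- rec + 1L
        samples[rec, ] <- x
      }
    }
  })
  exchange_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), pair_lo = integer(), pair_hi = integer(),
               accepted = logical())
  list(samples = samples, exchange_log = exchange_log, step = step)
}

#' Draw biased Boltzmann samples from one umbrella window
#'
#' Samples (asymptotically) from the density proportional to
#' exp(-beta (U(xi) + (k/2)(xi - center)^2)) on the potential's domain,
#' by random-walk Metropolis or overdamped Langevin dynamics.
#' Deterministic for a fixed seed and configuration.
#'
#' @param potential A [potential_spec()].
#' @param window One row of a [make_window_grid()] (or a list with
#'   `center`, `force_constant`, optionally `index`).
#' @param config A [sampler_config()].
#' @param thermo A [thermo_state()].
#' @return A `window_sample`: list with `window`, `values` (numeric
#'   vector of length `config$n_steps`) and the generating `potential`.
#' @export
sample_biased <- function(potential, window, config = sampler_config(),
                          thermo = thermo_state()) {
  w <- data.frame(index = if (!is.null(window$index)) window$index else 0L,
                  center = window$center,
                  force_constant = window$force_constant)
  res <- run_window_chains(potential, w, config, thermo)
  structure(list(window = as.list(w), values = drop(res$samples[, 1]),
                 source_potential = potential),
            class = "window_sample")
}

#' Sample every window of an umbrella grid
#'
#' Runs one independent chain per window (no exchanges), advancing all
#' chains in lockstep; statistically equivalent to calling
#' [sample_biased()] per window but much faster for full grids.
#'
#' @inheritParams run_reus
#' @return List of `window_sample` objects, one per window.
#' @export
sample_windows <- function(potential, windows, sampler = sampler_config(),
                           thermo = thermo_state()) {
  res <- run_window_chains(potential, windows, sampler, thermo)
  lapply(seq_len(nrow(windows)), function(i) {
    structure(list(window = as.list(windows[i, ]),
                   values = res$samples[, i],
                   source_potential = potential),
              class = "window_sample")
  })
}

#' Run replica-exchange umbrella sampling on a toy potential
#'
#' One Markov chain per window, with configuration (position) swaps
#' attempted between adjacent windows every `exchange_interval` steps.
#' Attempted pairs alternate between even-indexed and odd-indexed lower
#' partners, and a swap between windows i and j is accepted with
#' probability min(1, exp(-beta * delta)) where
#' delta = [u_i(x_j) + u_j(x_i)] - [u_i(x_i) + u_j(x_j)] involves only
#' the window biases (the unbiased potential cancels).
#'
#' @param potential A [potential_spec()].
#' @param windows A [make_window_grid()] with >= 2 windows.
#' @param sampler A [sampler_config()].
#' @param thermo A [thermo_state()].
#' @param exchange_interval Steps between exchange attempts (> 0).
#' @param alternation "even-first" or "odd-first".
#' @return List with `samples` (list of `window_sample`, one per window)
#'   and `exchange_log` (data frame: step, pair_lo, pair_hi, accepted).
#' @seealso [exchange_acceptance_report()]
#' @export
run_reus <- function(potential, windows, sampler = sampler_config(),
                     thermo = thermo_state(), exchange_interval = 100L,
                     alternation = c("even-first", "odd-first")) {
  if (nrow(windows) < 2L)
    stop("replica exchange needs at least 2 windows, got ", nrow(windows))
  if (exchange_interval <= 0) stop("exchange_interval must be positive")
  alternation <- match.arg(alternation)
  res <- run_window_chains(potential, windows, sampler, thermo,
                           exchange_interval = exchange_interval,
                           alternation = alternation)
  samples <- lapply(seq_len(nrow(windows)), function(i) {
    structure(list(window = as.list(windows[i, ]),
                   values = res$samples[, i],
                   source_potential = potential),
              class = "window_sample")
  })
  list(samples = samples, exchange_log = res$exchange_log)
}

#' Generate an ABF-style per-bin gradient sample stream
#'
#' Emulates ideal adaptive-biasing-force gradient accumulation: for each
#' bin of the grid it draws `n_samples` observations of dU/dxi at the bin
#' center plus zero-mean Gaussian noise. (The extended-system dynamics
#' and the associated unbiasing step of eABF are not emulated; streams
#' are already unbiased estimates of the free-energy gradient.)
#'
#' @param potential A [potential_spec()].
#' @param grid Strictly increasing bin edges covering the region of
#'   interest within the potential domain.
#' @param n_samples Samples per bin.
#' @param noise_sd Gradient noise standard deviation,
#'   kcal mol^-1 per coordinate unit.
#' @param seed Integer seed.
#' @return An `abf_stream`: list with `bin_edges`, `bin_centers`,
#'   `samples` (n_samples x n_bins matrix), `mean`, `se` and `n`.
#' @export
generate_abf_gradient_stream <- function(potential, grid, n_samples = 1000L,
                                         noise_sd = 0, seed = 1L) {
  if (length(grid) < 2L) stop("gradient grid must have at least 2 edges")
  if (any(diff(grid) <= 0)) stop("bin edges must be strictly increasing")
  centers <- (grid[-1] + grid[-length(grid)]) / 2
  truth <- potential$gradient(centers)
  samples <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n_samples * length(centers), 0, noise_sd),
                    nrow = n_samples)
    sweep(noise, 2L, truth, "+")
  })
  structure(list(bin_edges = grid, bin_centers = centers, samples = samples,
                 mean = colMeans(samples),
                 se = apply(samples, 2L, stats::sd) / sqrt(n_samples),
                 n = rep(n_samples, length(centers))),
            class = "abf_stream")
}
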