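# Shared fixtures for the test suite. Everything is generated in code;
# no stored data files.

TH300 <- thermo_state(300)

# the double-well ground truth used across the PMF estimator tests,
# spanning the canonical 16.5-26 A umbrella grid
fixture_double_well <- function() {
  potential_spec("double-well", domain = c(15.5, 27), center = 21.25,
                 height = 2.5, half_sep = 2.25)
}

fixture_window_grid <- function() make_window_grid(16.5, 26.0, 0.5, 10)

# brute-force minimum cross-group distance (oracle for contact series)
brute_min_dist <- function(xyz, ga, gb) {
  best <- Inf
  for (i in ga) for (j in gb) {
    best <- min(best, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  best
}

# excise a subset of atoms as its own structure
subset_toy <- function(st, idx) {
  st$atoms <- st$atoms[idx, , drop = FALSE]
  st
}

# independent radial-reduction oracle for the pairwise descreening
# integral: (1/4pi) * integral of 1/s^4 over the neighbor sphere
# (radius sr, center distance r), excluding s < rho_i
oracle_descreen <- function(r, rho_i, sr, n = 20000) {
  if (r + sr <= rho_i) return(0)
  lo <- max(rho_i, abs(r - sr)); hi <- r + sr
  s <- seq(lo, hi, length.out = n)
  mu_c <- pmin(1, pmax(-1, (s^2 + r^2 - sr^2) / (2 * s * r)))
  v <- pracma::trapz(s, (1 - mu_c) / 2 / s^2)
  if (sr - r > rho_i) {
    s2 <- seq(rho_i, sr - r, length.out = n)
    v <- v + pracma::trapz(s2, 1 / s2^2)
  }
  v
}
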