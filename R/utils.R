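# Internal helpers.

# Evaluate expr with a private RNG stream; the caller's RNG state is
# untouched. All seeded generators in the package go through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic quasi-uniform directions on the unit sphere (golden
# spiral); n = 1 gives the +z pole.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Trapezoid weights for a (possibly non-uniform) grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two grid points")
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

deg2rad <- function(x) x * pi / 180
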