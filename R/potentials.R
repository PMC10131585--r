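# Analytic toy potentials: the ground truths the synthetic samplers draw
# from and the PMF estimators are judged against.

#' Construct a toy potential specification
#'
#' A `potential_spec` is an analytic (or tabulated) 1-D potential energy
#' function on a closed domain, used as a known ground truth for the
#' synthetic samplers and the PMF estimators.
#'
#' Kinds:
#' \describe{
#'   \item{harmonic}{U(x) = (kappa/2) (x - center)^2.}
#'   \item{double-well}{U(x) = h ((x - center)^2 - half_sep^2)^2 / half_sep^4,
#'     a quartic with minima at center +/- half_sep and barrier height h.}
#'   \item{tabulated}{cubic-spline interpolation through (grid, values);
#'     grid must be strictly increasing.}
#'   \item{angular-harmonic}{harmonic in an angle measured in degrees,
#'     U = (kappa/2) (x - center)^2 with kappa in kcal mol^-1 deg^-2.}
#'   \item{flat}{U(x) = 0.}
#' }
#'
#' @param kind One of "harmonic", "double-well", "tabulated",
#'   "angular-harmonic", "flat".
#' @param domain Closed interval `c(lo, hi)`; Angstroms (or degrees for
#'   angular potentials).
#' @param kappa Curvature / force constant, kcal mol^-1 per unit^2.
#' @param center Location parameter, same units as the domain.
#' @param height Barrier height for the double well, kcal mol^-1.
#' @param half_sep Half the separation between the double-well minima.
#' @param grid,values Nodes for a tabulated potential.
#' @return A `potential_spec` object with callable `energy(x)` and
#'   `gradient(x)` in kcal mol^-1 (per unit for the gradient).
#' @examples
#' dw <- potential_spec("double-well", domain = c(16, 26.5),
#'                      center = 21.25, height = 2.5, half_sep = 2.25)
#' dw$energy(21.25)   # barrier top: 2.5
#' dw$energy(19.0)    # minimum: 0
#' @export
potential_spec <- function(kind = c("harmonic", "double-well", "tabulated",
                                    "angular-harmonic", "flat"),
                           domain, kappa = 1, center = 0,
                           height = 2, half_sep = 1,
                           grid = NULL, values = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(domain) == 2L, all(is.finite(domain)), domain[1] < domain[2])
  if (kind %in% c("harmonic", "angular-harmonic")) {
    force(kappa); force(center)
    energy <- function(x) 0.5 * kappa * (x - center)^2
    gradient <- function(x) kappa * (x - center)
    params <- list(kappa = kappa, center = center)
  } else if (kind == "double-well") {
    stopifnot(height >= 0, half_sep > 0)
    energy <- function(x) height * ((x - center)^2 - half_sep^2)^2 / half_sep^4
    gradient <- function(x) 4 * height * (x - center) *
      ((x - center)^2 - half_sep^2) / half_sep^4
    params <- list(center = center, height = height, half_sep = half_sep)
  } else if (kind == "tabulated") {
    stopifnot(!is.null(grid), !is.null(values), length(grid) == length(values))
    if (any(diff(grid) <= 0)) stop("tabulated grid must be strictly increasing")
    if (any(!is.finite(values))) stop("tabulated values must be finite")
    sf <- stats::splinefun(grid, values, method = "natural")
    energy <- function(x) sf(x)
    gradient <- function(x) sf(x, deriv = 1)
    params <- list(grid = grid, values = values)
  } else { # flat
    energy <- function(x) rep(0, length(x))
    gradient <- function(x) rep(0, length(x))
    params <- list()
  }
  ev <- energy(seq(domain[1], domain[2], length.out = 101))
  if (any(!is.finite(ev))) stop("potential is not finite on its domain")
  structure(list(kind = kind, domain = domain, params = params,
                 energy = energy, gradient = gradient),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$kind, "on [", x$domain[1], ",", x$domain[2], "]\n")
  invisible(x)
}

#' Harmonic umbrella-window bias energy
#'
#' u(xi) = (k/2) (xi - center)^2 with k the full harmonic force constant
#' (some packages omit the 1/2; this package never does).
#'
#' @param window A one-row window data frame (see [make_window_grid()]) or
#'   any list with `center` and `force_constant`.
#' @param x Coordinate values.
#' @return Bias energies, kcal mol^-1.
#' @export
window_bias_energy <- function(window, x) {
  0.5 * window$force_constant * (x - window$center)^2
}
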