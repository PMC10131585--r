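# PMF estimation from biased sampling: WHAM over umbrella windows,
# integration of ABF gradient streams, window-overlap diagnostics, the
# half-split uncertainty rule, and replica-exchange bookkeeping.

#' Gridded potential of mean force
#'
#' @param grid Strictly increasing coordinate values (Angstroms or
#'   degrees).
#' @param w Free energy at each grid point, kcal mol^-1 (finite).
#' @param reference Referencing convention: "min-zero" shifts the
#'   minimum to zero, "endpoint-zero" the last point, "raw" leaves
#'   values untouched.
#' @return A `pmf_profile` object.
#' @export
pmf_profile <- function(grid, w, reference = c("min-zero", "endpoint-zero",
                                               "raw")) {
  reference <- match.arg(reference)
  stopifnot(length(grid) == length(w), length(grid) >= 2L)
  if (any(diff(grid) <= 0)) stop("PMF grid must be strictly increasing")
  if (any(!is.finite(w))) stop("PMF values must be finite")
  w <- switch(reference,
              "min-zero" = w - min(w),
              "endpoint-zero" = w - w[length(w)],
              "raw" = w)
  structure(list(grid = grid, w = w, reference = reference),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile> ", length(x$grid), " points on [",
      min(x$grid), ", ", max(x$grid), "], reference ", x$reference, "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a PMF at arbitrary points by linear interpolation
#'
#' Points outside the grid give NA (never extrapolated).
#'
#' @param pmf A [pmf_profile()].
#' @param x Coordinate values.
#' @return Interpolated free energies, kcal mol^-1.
#' @export
pmf_interp <- function(pmf, x) {
  stats::approx(pmf$grid, pmf$w, xout = x, rule = 1)$y
}

default_bin_edges <- function(samples) {
  centers <- vapply(samples, function(s) s$window$center, numeric(1))
  vals <- unlist(lapply(samples, `[[`, "values"))
  width <- if (length(centers) > 1L) min(diff(sort(centers))) / 5 else
    diff(range(vals)) / 50
  lo <- floor(min(vals) / width) * width
  hi <- ceiling(max(vals) / width) * width
  seq(lo, hi, by = width)
}

#' Weighted histogram analysis of umbrella-sampling windows
#'
#' Iterates the self-consistent WHAM equations for harmonic-bias
#' windows until the maximum change in the per-window free energies
#' falls below `tolerance` (the first window's free energy is pinned to
#' zero to fix the gauge). Replica-exchange window sets are pooled per
#' window. Bins never visited by any window are excluded from the PMF
#' support (never silently interpolated), and a gap splitting the
#' visited support into disconnected components is an error.
#'
#' @param samples List of `window_sample` objects (see
#'   [sample_biased()], [run_reus()]).
#' @param bin_edges Histogram bin edges; defaults to bins of one fifth
#'   of the window spacing spanning the sampled range.
#' @param thermo A [thermo_state()].
#' @param tolerance Convergence threshold on max |df|, kcal mol^-1.
#' @param max_iter Iteration cap; non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @return A `wham_solution`: list with `pmf` (a min-zero
#'   [pmf_profile()] on the visited bin centers), `window_free_energies`,
#'   `iterations`, `converged`, `residual`, `bin_edges`, `bin_counts`.
#' @export
wham <- function(samples, bin_edges = NULL, thermo = thermo_state(),
                 tolerance = 1e-7, max_iter = 100000L) {
  stopifnot(length(samples) >= 1L)
  if (is.null(bin_edges)) bin_edges <- default_bin_edges(samples)
  if (any(diff(bin_edges) <= 0))
    stop("bin edges must be strictly increasing")
  beta <- thermo$beta
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  n_bins <- length(centers)
  n_win <- length(samples)
  counts <- matrix(0, n_win, n_bins)
  for (wdx in seq_len(n_win)) {
    v <- samples[[wdx]]$values
    if (!length(v)) stop("window ", wdx, " has no samples")
    v <- v[v >= bin_edges[1] & v <= bin_edges[length(bin_edges)]]
    if (!length(v)) stop("window ", wdx, " has no samples inside the bins")
    h <- graphics::hist(v, breaks = bin_edges, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    counts[wdx, ] <- h$counts
  }
  visited <- colSums(counts) > 0
  if (!any(visited)) stop("no visited bins")
  # adjacent windows (by center) must share at least one visited bin,
  # otherwise the pooled support splits into disconnected components
  if (n_win > 1L) {
    ord <- order(vapply(samples, function(s) s$window$center, numeric(1)))
    for (k in seq_len(n_win - 1L)) {
      i <- ord[k]; j <- ord[k + 1L]
      if (!any(counts[i, ] > 0 & counts[j, ] > 0)) {
        stop(sprintf(paste0(
          "histogram support is disconnected: windows centered at %.4g ",
          "and %.4g share no visited bin"),
          samples[[i]]$window$center, samples[[j]]$window$center))
      }
    }
  }
  vis_idx <- which(visited)
  N_w <- rowSums(counts)
  # bias factors at visited bin centers
  u <- t(vapply(samples, function(s)
    0.5 * s$window$force_constant * (centers[visited] - s$window$center)^2,
    numeric(length(vis_idx))))
  u <- matrix(u, nrow = n_win)
  cb <- exp(-beta * u)                       # n_win x n_vis
  nb <- colSums(counts)[visited]
  f <- numeric(n_win)
  iter <- 0L
  residual <- Inf
  repeat {
    iter <- iter + 1L
    denom <- colSums(N_w * exp(beta * f) * cb)
    p <- nb / denom
    p <- p / sum(p)
    f_new <- -log(as.vector(cb %*% p)) / beta
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    f <- f_new
    if (residual <= tolerance || iter >= max_iter) break
  }
  wvals <- -log(p) / beta
  sol <- list(pmf = pmf_profile(centers[visited], wvals, "min-zero"),
              window_free_energies = f, iterations = iter,
              converged = residual <= tolerance, residual = residual,
              bin_edges = bin_edges, bin_counts = counts,
              visited = visited)
  class(sol) <- "wham_solution"
  sol
}

#' PMF by integration of an ABF gradient stream
#'
#' Averages the per-bin gradient samples and integrates them with the
#' cumulative trapezoid rule; the result is min-zero referenced.
#'
#' @param stream An `abf_stream` (see
#'   [generate_abf_gradient_stream()]) or a list with `bin_centers` and
#'   per-bin `mean` gradients and counts `n`.
#' @param min_count Minimum samples required in every bin.
#' @return A [pmf_profile()] on the bin centers.
#' @export
abf_pmf <- function(stream, min_count = 1L) {
  centers <- stream$bin_centers
  if (any(diff(centers) <= 0))
    stop("gradient grid must be strictly increasing")
  if (any(stream$n < min_count)) {
    bad <- which(stream$n < min_count)
    stop("bins with fewer than ", min_count, " samples: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  g <- stream$mean
  w <- pracma::cumtrapz(centers, g)
  pmf_profile(centers, as.vector(w), "min-zero")
}

#' Pairwise window-overlap matrix
#'
#' Entry (i, j) is the overlap coefficient sum_bins min(p_i, p_j) of
#' the two windows' normalized sample histograms: 1 for identical
#' distributions, 0 for disjoint support. Good adjacent-window overlap
#' is the standard diagnostic that an umbrella grid is exchange- and
#' WHAM-ready.
#'
#' @param samples List of `window_sample` objects (>= 2).
#' @param bin_edges Shared histogram bin edges (default as in [wham()]).
#' @return Symmetric matrix with unit diagonal.
#' @export
overlap_matrix <- function(samples, bin_edges = NULL) {
  if (length(samples) < 2L) stop("need at least 2 windows")
  if (is.null(bin_edges)) bin_edges <- default_bin_edges(samples)
  probs <- vapply(samples, function(s) {
    if (!length(s$values)) stop("empty window sample")
    v <- s$values
    v <- v[v >= bin_edges[1] & v <= bin_edges[length(bin_edges)]]
    h <- graphics::hist(v, breaks = bin_edges, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    h$counts / sum(h$counts)
  }, numeric(length(bin_edges) - 1L))
  n <- length(samples)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- sum(pmin(probs[, i], probs[, j]))
  }
  m
}

#' Half-split uncertainty of an estimator
#'
#' Applies the estimator to the full ordered data set and to its first
#' and second halves (the earlier half receiving floor(n/2) items), and
#' reports the maximum absolute difference between either half's result
#' and the full-data result as the uncertainty.
#'
#' @param estimator Function mapping a data subset to a scalar.
#' @param data Ordered samples: a vector, or a list whose elements the
#'   estimator accepts.
#' @return An `uncertainty_estimate`: list with `value`, `half1`,
#'   `half2`, `uncertainty`.
#' @export
half_split_uncertainty <- function(estimator, data) {
  n <- if (is.list(data) && !is.data.frame(data)) length(data) else
    NROW(data)
  if (n < 2L) stop("need at least 2 samples to split")
  k <- floor(n / 2)
  take <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  value <- estimator(data)
  half1 <- tryCatch(estimator(take(seq_len(k))), error = function(e)
    stop("estimator failed on first half: ", conditionMessage(e)))
  half2 <- tryCatch(estimator(take((k + 1L):n)), error = function(e)
    stop("estimator failed on second half: ", conditionMessage(e)))
  structure(list(value = value, half1 = half1, half2 = half2,
                 uncertainty = max(abs(half1 - value), abs(half2 - value))),
            class = "uncertainty_estimate")
}

#' Per-pair replica-exchange acceptance rates
#'
#' @param exchange_log Data frame from [run_reus()] with columns
#'   `pair_lo`, `pair_hi`, `accepted`.
#' @return Data frame with `pair_lo`, `pair_hi`, `attempted`,
#'   `accepted`, `rate`.
#' @export
exchange_acceptance_report <- function(exchange_log) {
  if (!nrow(exchange_log)) stop("empty exchange log")
  key <- paste(exchange_log$pair_lo, exchange_log$pair_hi)
  agg <- stats::aggregate(exchange_log$accepted,
                          by = list(key = key), FUN = function(a)
                            c(attempted = length(a), accepted = sum(a)))
  pl <- as.integer(vapply(strsplit(agg$key, " "), `[`, "", 1))
  ph <- as.integer(vapply(strsplit(agg$key, " "), `[`, "", 2))
  out <- data.frame(pair_lo = pl, pair_hi = ph,
                    attempted = agg$x[, "attempted"],
                    accepted = agg$x[, "accepted"])
  out$rate <- out$accepted / out$attempted
  out <- out[order(out$pair_lo), ]
  rownames(out) <- NULL
  out
}
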