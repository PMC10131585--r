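# The staged "geometric route" to a standard binding free energy:
# restraint application/release free energies from 1-D PMFs, the
# analytic orientational-restraint term, the separation term with its
# standard-state correction, and assembly of the nine-stage total.

#' Define a harmonic restraint on a named collective variable
#'
#' u(xi) = (k/2)(xi - center)^2 with k the full force constant.
#'
#' @param coordinate One of "rmsd", "euler_Theta", "euler_Phi",
#'   "euler_Psi", "polar_theta", "polar_phi", "distance_r".
#' @param center Restraint center, Angstroms or degrees.
#' @param force_constant kcal mol^-1 per unit^2 (>= 0). The
#'   conventional defaults are 10 for distance-like coordinates
#'   (kcal mol^-1 A^-2) and 0.1 for angles (kcal mol^-1 deg^-2).
#' @param units "angstrom" or "degree" (inferred from the coordinate if
#'   omitted).
#' @return A `restraint_def` object with an `energy(x)` evaluator.
#' @export
restraint_def <- function(coordinate = c("rmsd", "euler_Theta", "euler_Phi",
                                         "euler_Psi", "polar_theta",
                                         "polar_phi", "distance_r"),
                          center = 0, force_constant = NULL, units = NULL) {
  coordinate <- match.arg(coordinate)
  angular <- coordinate %in% c("euler_Theta", "euler_Phi", "euler_Psi",
                               "polar_theta", "polar_phi")
  if (is.null(units)) units <- if (angular) "degree" else "angstrom"
  if (is.null(force_constant)) force_constant <- if (angular) 0.1 else 10
  if (force_constant < 0) stop("force_constant must be >= 0")
  force(center)
  structure(list(coordinate = coordinate, center = center,
                 force_constant = force_constant, units = units,
                 energy = function(x) 0.5 * force_constant * (x - center)^2),
            class = "restraint_def")
}

#' One stage's free-energy result
#'
#' @param stage_id Integer 1-9 (the reversed-order staging convention:
#'   1 apply conformational, 2 apply orientational, 3 separation,
#'   4-9 release).
#' @param free_energy kcal mol^-1.
#' @param uncertainty Non-negative, kcal mol^-1.
#' @param method Free-text tag ("eABF", "REUS/WHAM", "analytic", ...).
#' @param system "ligand" or "complex" (optional metadata).
#' @param action "apply", "release" or "separation" (optional).
#' @return A `stage_result`.
#' @export
stage_result <- function(stage_id, free_energy, uncertainty = 0,
                         method = "", system = NA_character_,
                         action = NA_character_) {
  stopifnot(stage_id %in% 1:9, is.finite(free_energy), uncertainty >= 0)
  structure(list(stage_id = as.integer(stage_id),
                 free_energy = free_energy, uncertainty = uncertainty,
                 method = method, system = system, action = action),
            class = "stage_result")
}

#' Free energy of applying or releasing a harmonic restraint
#'
#' Evaluates, by trapezoid quadrature on the PMF grid,
#' `dG_apply = -(1/beta) ln( int exp(-beta (w + u)) dxi /
#' int exp(-beta w) dxi )` and `dG_release = -dG_apply` for the same
#' PMF. Angular PMFs are
#' assumed Jacobian-inclusive (the convention of colvar-based output),
#' so no extra sine factor is applied here.
#'
#' The PMF must cover essentially all of the restrained integrand: the
#' weight of the two boundary grid points must be below 1e-6 of the
#' total, otherwise the domain is too small and an error asks for an
#' extended profile.
#'
#' @param pmf A [pmf_profile()] along the restrained coordinate.
#' @param restraint A [restraint_def()].
#' @param direction "apply" or "release".
#' @param thermo A [thermo_state()].
#' @return A `stage_result` (stage_id must be attached by the caller
#'   via [stage_result()]; here the bare free energy is returned in a
#'   list with `free_energy` and `direction`).
#' @export
restraint_free_energy <- function(pmf, restraint,
                                  direction = c("apply", "release"),
                                  thermo = thermo_state()) {
  direction <- match.arg(direction)
  beta <- thermo$beta
  x <- pmf$grid
  w <- pmf$w - min(pmf$w)            # shift for numerical stability
  u <- restraint$energy(x)
  qw <- trapezoid_weights(x)
  num_int <- exp(-beta * (w + u))
  den_int <- exp(-beta * w)
  num <- sum(qw * num_int)
  boundary <- qw[1] * num_int[1] + qw[length(x)] * num_int[length(x)]
  if (restraint$force_constant > 0 && boundary > 1e-6 * num)
    stop("restrained integrand carries ", signif(boundary / num, 3),
         " of its weight at the PMF boundary; extend the profile domain")
  dg <- -log(num / sum(qw * den_int)) / beta
  if (direction == "release") dg <- -dg
  list(free_energy = dg, direction = direction)
}

#' Analytic orientational-restraint free energy
#'
#' Free energy of applying three harmonic Euler-angle restraints to a
#' freely tumbling ligand:
#' `dG = -(1/beta) ln( int sin(Theta) exp(-beta (u_Theta + u_Phi +
#' u_Psi)) dTheta dPhi dPsi / int sin(Theta) dTheta dPhi dPsi )`
#' over Theta in 0..180 deg and Phi, Psi in -180..180 deg. The
#' integrand is separable, so three adaptive 1-D quadratures suffice;
#' the result is exact up to quadrature and carries zero uncertainty.
#'
#' @param restraints List of three [restraint_def()]s covering
#'   euler_Theta, euler_Phi and euler_Psi (any order).
#' @param thermo A [thermo_state()].
#' @return A `stage_result` with stage_id 2 and uncertainty 0.
#' @export
orientational_restraint_analytic <- function(restraints,
                                             thermo = thermo_state()) {
  coords_given <- vapply(restraints, function(r) r$coordinate, character(1))
  need <- c("euler_Theta", "euler_Phi", "euler_Psi")
  if (!setequal(coords_given, need))
    stop("need exactly the three Euler-angle restraints; got: ",
         paste(coords_given, collapse = ", "))
  r <- restraints[match(need, coords_given)]
  beta <- thermo$beta
  if (all(vapply(r, function(x) x$force_constant, numeric(1)) == 0)) {
    warning("all three orientational force constants are zero")
    return(stage_result(2L, 0, 0, method = "analytic",
                        system = "ligand", action = "apply"))
  }
  int1 <- function(f, lo, hi) stats::integrate(f, lo, hi,
                                               rel.tol = 1e-10,
                                               subdivisions = 400L)$value
  num_T <- int1(function(x) sin(deg2rad(x)) * exp(-beta * r[[1]]$energy(x)),
                0, 180)
  den_T <- int1(function(x) sin(deg2rad(x)), 0, 180)
  num_P <- int1(function(x) exp(-beta * r[[2]]$energy(x)), -180, 180)
  num_S <- int1(function(x) exp(-beta * r[[3]]$energy(x)), -180, 180)
  dg <- -log((num_T / den_T) * (num_P / 360) * (num_S / 360)) / beta
  stage_result(2L, dg, 0, method = "analytic", system = "ligand",
               action = "apply")
}

#' Separation (binding) stage with standard-state correction
#'
#' Computes the stage-3 term -(1/beta) ln(S* I C0) where
#' I = int_a^r* exp(-beta (W(r) - W(r*))) dr on the PMF grid
#' (trapezoid; the integrand carries no r^2 factor) and
#' S* = r*^2 int int sin(theta) exp(-beta u_dir(theta, phi))
#' dtheta dphi in steradians (so S* = 4 pi r*^2 when unrestrained).
#' C0 is the 1 mol/L standard concentration 1/1660.539 A^-3.
#'
#' @param W A [pmf_profile()] of the separation distance r covering
#'   [a, r_star].
#' @param u_theta,u_phi [restraint_def()]s for the polar direction
#'   angles (degrees); zero force constants mean unrestrained.
#' @param r_star Unbound reference distance, A (default 26).
#' @param a Lower integration limit, A (default 16).
#' @param thermo A [thermo_state()].
#' @param C0_volume Standard-state volume per molecule, A^3.
#' @return A `stage_result` with stage_id 3.
#' @export
separation_term <- function(W,
                            u_theta = restraint_def("polar_theta",
                                                    force_constant = 0),
                            u_phi = restraint_def("polar_phi",
                                                  force_constant = 0),
                            r_star = 26, a = 16,
                            thermo = thermo_state(),
                            C0_volume = standard_state_volume()) {
  if (a >= r_star) stop("need a < r_star")
  if (min(W$grid) > a + 1e-9 || max(W$grid) < r_star - 1e-9)
    stop("separation PMF must cover [", a, ", ", r_star, "] A; it spans [",
         min(W$grid), ", ", max(W$grid), "]")
  beta <- thermo$beta
  rg <- sort(unique(c(a, W$grid[W$grid > a & W$grid < r_star], r_star)))
  wr <- pmf_interp(W, rg)
  w_star <- pmf_interp(W, r_star)
  I <- sum(trapezoid_weights(rg) * exp(-beta * (wr - w_star)))
  int1 <- function(f, lo, hi) stats::integrate(f, lo, hi, rel.tol = 1e-10,
                                               subdivisions = 400L)$value
  ang_theta <- int1(function(x) sin(deg2rad(x)) *
                      exp(-beta * u_theta$energy(x)), 0, 180)
  ang_phi <- int1(function(x) exp(-beta * u_phi$energy(x)), -180, 180)
  s_star <- r_star^2 * ang_theta * ang_phi * (pi / 180)^2
  dg <- -log(s_star * I / C0_volume) / beta
  stage_result(3L, dg, 0, method = "separation PMF",
               system = "complex", action = "separation")
}

#' Assemble the nine-stage standard binding free energy
#'
#' The total is the plain sum of the nine stage free energies; the
#' total uncertainty combines the stage uncertainties in quadrature
#' (stages treated as independent); the dissociation constant follows
#' from the total via [deltaG_to_kd()].
#'
#' @param stages List of nine [stage_result()]s (ids 1-9, each once),
#'   or a data frame with columns `stage_id` (or `stage`),
#'   `free_energy` and `uncertainty`.
#' @param thermo A [thermo_state()] for the K_D conversion.
#' @return A `georoute_result`: list with `stages` (data frame),
#'   `total`, `total_uncertainty` (kcal mol^-1) and `kd` (mol L^-1).
#' @export
assemble_standard_free_energy <- function(stages, thermo = thermo_state()) {
  if (is.data.frame(stages)) {
    if (is.null(stages$stage_id) && !is.null(stages$stage))
      stages$stage_id <- stages$stage
    df <- data.frame(stage_id = as.integer(stages$stage_id),
                     free_energy = stages$free_energy,
                     uncertainty = if (is.null(stages$uncertainty)) 0 else
                       stages$uncertainty,
                     system = if (is.null(stages$system)) NA else
                       stages$system,
                     action = if (is.null(stages$action)) NA else
                       stages$action)
  } else {
    df <- do.call(rbind, lapply(stages, function(s)
      data.frame(stage_id = s$stage_id, free_energy = s$free_energy,
                 uncertainty = s$uncertainty, system = s$system,
                 action = s$action)))
  }
  ids <- sort(df$stage_id)
  if (!identical(ids, 1:9)) {
    missing_ids <- setdiff(1:9, df$stage_id)
    dup_ids <- unique(df$stage_id[duplicated(df$stage_id)])
    stop("stages must be exactly 1-9 once each",
         if (length(missing_ids)) paste("; missing:",
                                        paste(missing_ids, collapse = ",")),
         if (length(dup_ids)) paste("; duplicated:",
                                    paste(dup_ids, collapse = ",")))
  }
  df <- df[order(df$stage_id), ]
  rownames(df) <- NULL
  total <- sum(df$free_energy)
  total_unc <- sqrt(sum(df$uncertainty^2))
  structure(list(stages = df, total = total,
                 total_uncertainty = total_unc,
                 kd = deltaG_to_kd(total, thermo),
                 temperature = thermo$temperature),
            class = "georoute_result")
}

#' @export
print.georoute_result <- function(x, digits = 2, ...) {
  cat("Geometric-route standard binding free energy\n")
  df <- x$stages
  df$free_energy <- sprintf(paste0("%+.", digits, "f"), df$free_energy)
  df$uncertainty <- sprintf(paste0("%.", digits, "f"), df$uncertainty)
  print(df, row.names = FALSE)
  cat(sprintf("Total dG0 = %+.*f +/- %.*f kcal/mol;  K_D = %.3g mol/L (%g K)\n",
              digits, x$total, digits, x$total_uncertainty, x$kd,
              x$temperature))
  invisible(x)
}
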