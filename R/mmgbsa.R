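# Single-trajectory MM-GBSA scoring: OBC generalized Born polar
# solvation, Shrake-Rupley SASA nonpolar term, and cutoff-free
# Coulomb/Lennard-Jones interaction energies, differenced between the
# complex and its excised parts.

#' Generalized Born / surface-area parameters
#'
#' Defaults follow the implicit-solvent rescoring convention: solvent
#' dielectric 78.5, surface tension 0.00542 kcal mol^-1 A^-2, probe
#' radius 1.4 A, Born-radius offset 0.09 A and OBC model II rescaling
#' coefficients (alpha 1.0, beta 0.8, gamma 4.85). No Debye-Hueckel
#' salt screening is applied (kappa = 0).
#'
#' @param solvent_dielectric,solute_dielectric Relative permittivities
#'   (>= 1).
#' @param surface_tension kcal mol^-1 A^-2 multiplying the SASA.
#' @param sasa_offset Constant added to the nonpolar term, kcal mol^-1.
#' @param probe_radius Solvent probe radius, A.
#' @param born_offset Intrinsic-radius offset, A.
#' @param coulomb_constant kcal A mol^-1 e^-2.
#' @param obc_alpha,obc_beta,obc_gamma OBC tanh-rescaling coefficients.
#' @return A `gb_params` list.
#' @export
gb_params <- function(solvent_dielectric = 78.5, solute_dielectric = 1.0,
                      surface_tension = 0.00542, sasa_offset = 0,
                      probe_radius = 1.4, born_offset = 0.09,
                      coulomb_constant = COULOMB_KCAL,
                      obc_alpha = 1.0, obc_beta = 0.8, obc_gamma = 4.85) {
  stopifnot(solvent_dielectric >= 1, solute_dielectric >= 1,
            surface_tension >= 0, probe_radius >= 0, born_offset >= 0)
  structure(list(solvent_dielectric = solvent_dielectric,
                 solute_dielectric = solute_dielectric,
                 surface_tension = surface_tension,
                 sasa_offset = sasa_offset, probe_radius = probe_radius,
                 born_offset = born_offset,
                 coulomb_constant = coulomb_constant,
                 obc_alpha = obc_alpha, obc_beta = obc_beta,
                 obc_gamma = obc_gamma),
            class = "gb_params")
}

# Pairwise HCT descreening integral: (1/4pi) x the integral of 1/s^4
# over the neighbor sphere (radius sr at distance r), excluding the
# region inside the offset-reduced radius rho_i. Vectorized over pairs.
hct_descreen <- function(r, rho_i, sr) {
  out <- numeric(length(r))
  act <- rho_i < r + sr          # neighbor not engulfed by atom i
  if (!any(act)) return(out)
  r <- r[act]; ri <- rho_i[act]; s <- sr[act]
  U <- r + s
  L <- pmax(ri, abs(r - s))
  v <- 0.5 * ((1 / L - 1 / U) +
              (r^2 - s^2) / (4 * r) * (1 / U^2 - 1 / L^2) +
              log(L / U) / (2 * r))
  inside <- r < s - ri           # atom i center engulfed by neighbor
  v[inside] <- v[inside] + (1 / ri - 1 / L)[inside]
  out[act] <- v
  out
}

#' Effective Born radii (OBC model II)
#'
#' Pairwise Hawkins-Cramer-Truhlar descreening (unscaled neighbor
#' radii) accumulated into the OBC tanh rescaling
#' 1/a_i = 1/rho_i - tanh(alpha Psi - beta Psi^2 + gamma Psi^3) / R_i,
#' with rho_i = R_i - offset and Psi = I_i rho_i. An isolated atom has
#' a_i = rho_i exactly.
#'
#' @param structure A [param_structure()] (all intrinsic GB radii must
#'   exceed the Born offset).
#' @param params A [gb_params()].
#' @return Per-atom effective Born radii, Angstroms.
#' @export
born_radii <- function(structure, params = gb_params()) {
  R <- structure$atoms$gb_radius
  if (any(R <= params$born_offset))
    stop("intrinsic GB radii must exceed the Born offset (",
         params$born_offset, " A)")
  rho <- R - params$born_offset
  n <- length(R)
  if (n == 1L) {
    I <- 0
  } else {
    xyz <- coords(structure)
    d <- as.matrix(stats::dist(xyz))
    I <- vapply(seq_len(n), function(i) {
      j <- setdiff(seq_len(n), i)
      sum(hct_descreen(d[i, j], rep(rho[i], n - 1L), rho[j]))
    }, numeric(1))
  }
  psi <- I * rho
  inv_a <- 1 / rho - tanh(params$obc_alpha * psi -
                          params$obc_beta * psi^2 +
                          params$obc_gamma * psi^3) / R
  1 / inv_a
}

#' Generalized Born polar solvation energy
#'
#' G_GB = -(1/2) k_e (1/eps_in - 1/eps_solv) sum_ij q_i q_j / f_GB with
#' f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j))); the double sum
#' includes the i = j self (Born) terms.
#'
#' @param structure A [param_structure()] with charges.
#' @param radii Effective Born radii from [born_radii()] for the same
#'   structure.
#' @param params A [gb_params()].
#' @return Energy in kcal mol^-1.
#' @export
gb_energy <- function(structure, radii = born_radii(structure, params),
                      params = gb_params()) {
  q <- structure$atoms$charge
  if (any(is.na(q))) stop("missing charges")
  if (length(radii) != length(q))
    stop("radii length does not match atom count")
  xyz <- coords(structure)
  r2 <- as.matrix(stats::dist(xyz))^2
  aa <- outer(radii, radii)
  fgb <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
  pref <- -0.5 * params$coulomb_constant *
    (1 / params$solute_dielectric - 1 / params$solvent_dielectric)
  pref * sum(outer(q, q) / fgb)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral test points on each atom's expanded
#' sphere (radius + probe); a point is accessible if outside every
#' neighbor's expanded sphere.
#'
#' @param structure A [param_structure()] (GB radii used as the atomic
#'   radii).
#' @param params A [gb_params()] (probe radius).
#' @param n_points Test points per atom (>= 32).
#' @return List with `total` (A^2) and `per_atom`.
#' @export
sasa <- function(structure, params = gb_params(), n_points = 960L) {
  if (n_points < 32L) stop("n_points must be >= 32 for a usable estimate")
  R <- structure$atoms$gb_radius + params$probe_radius
  if (any(R <= 0)) stop("radii must be positive")
  xyz <- coords(structure)
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  d <- as.matrix(stats::dist(xyz))
  per_atom <- vapply(seq_len(n), function(i) {
    nb <- which(d[i, ] < R[i] + R & seq_len(n) != i)
    frac <- if (!length(nb)) 1 else {
      p <- sweep(pts * R[i], 2L, xyz[i, ], "+")
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
               (p[, 3] - xyz[j, 3])^2
        free <- free & dj2 > R[j]^2
        if (!any(free)) break
      }
      mean(free)
    }
    4 * pi * R[i]^2 * frac
  }, numeric(1))
  list(total = sum(per_atom), per_atom = per_atom)
}

# Cross-group Coulomb and Lennard-Jones interaction energies
# (Lorentz-Berthelot combination, no cutoff).
pair_interaction <- function(structure, idx_a, idx_b, params) {
  at <- structure$atoms
  xyz <- coords(structure)
  xa <- xyz[idx_a, , drop = FALSE]; xb <- xyz[idx_b, , drop = FALSE]
  r2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  r <- sqrt(pmax(r2, 1e-12))
  e_coul <- params$coulomb_constant / params$solute_dielectric *
    sum(outer(at$charge[idx_a], at$charge[idx_b]) / r)
  eps <- sqrt(outer(at$lj_eps[idx_a], at$lj_eps[idx_b]))
  rmin <- outer(at$lj_rmin_half[idx_a], at$lj_rmin_half[idx_b], "+")
  sr6 <- (rmin / r)^6
  e_lj <- sum(eps * (sr6^2 - 2 * sr6))
  list(e_coulomb = e_coul, e_lj = e_lj)
}

subset_structure <- function(structure, idx) {
  at <- structure$atoms[idx, , drop = FALSE]
  param_structure(at, provenance = structure$provenance)
}

#' Single-frame MM-GBSA binding score
#'
#' Single-trajectory convention: receptor and ligand geometries are
#' excised unchanged from the complex frame, so intramolecular bonded
#' terms cancel exactly and the score reduces to
#' total = dE_coulomb + dE_LJ + dG_GB + dG_SASA, where the first two
#' are the inter-chain interaction energies and the last two are
#' complex-minus-parts differences. No conformational-entropy term is
#' included.
#'
#' @param complex_frame A [param_structure()] of the bound complex.
#' @param receptor_mask,ligand_mask Index vectors (or logical masks)
#'   that partition the atoms.
#' @param params A [gb_params()].
#' @return An `energy_breakdown`: list with `e_coulomb`, `e_lj`,
#'   `g_gb`, `g_sasa` and `total` (kcal mol^-1).
#' @export
mmgbsa_score <- function(complex_frame, receptor_mask, ligand_mask,
                         params = gb_params()) {
  n <- nrow(complex_frame$atoms)
  ia <- if (is.logical(receptor_mask)) which(receptor_mask) else
    as.integer(receptor_mask)
  ib <- if (is.logical(ligand_mask)) which(ligand_mask) else
    as.integer(ligand_mask)
  if (length(intersect(ia, ib)))
    stop("receptor and ligand masks overlap")
  if (length(union(ia, ib)) != n)
    stop("masks must partition the atom set (", n, " atoms)")
  inter <- pair_interaction(complex_frame, ia, ib, params)
  rec <- subset_structure(complex_frame, ia)
  lig <- subset_structure(complex_frame, ib)
  g_gb <- gb_energy(complex_frame, born_radii(complex_frame, params), params) -
    gb_energy(rec, born_radii(rec, params), params) -
    gb_energy(lig, born_radii(lig, params), params)
  g_sasa <- params$surface_tension *
    (sasa(complex_frame, params)$total - sasa(rec, params)$total -
       sasa(lig, params)$total) + params$sasa_offset
  out <- list(e_coulomb = inter$e_coulomb, e_lj = inter$e_lj,
              g_gb = g_gb, g_sasa = g_sasa,
              total = inter$e_coulomb + inter$e_lj + g_gb + g_sasa)
  class(out) <- "energy_breakdown"
  out
}

#' Screen a trajectory: bound time and per-frame MM-GBSA
#'
#' Flags frames as bound until the first frame whose stop-selection
#' displacement (RMSD from the first frame, receptor-aligned laboratory
#' frame, no self-fitting of the ligand) exceeds `rmsd_stop`; scores
#' only the bound frames; reports the per-frame energies, their mean
#' and standard error (frames treated as independent), and the bound
#' time.
#'
#' @param traj A [trajectory()] congruent with `topology`.
#' @param topology A [param_structure()].
#' @param receptor_mask,ligand_mask Atom index vectors partitioning the
#'   topology.
#' @param params A [gb_params()].
#' @param rmsd_stop Dissociation threshold in Angstroms (default 25).
#' @param stop_selection Atoms whose displacement defines dissociation;
#'   defaults to the ligand's CA atoms, or all ligand atoms when none
#'   are named CA.
#' @param align_receptor Superpose each frame onto the first by the
#'   receptor atoms before measuring displacement (the receptor defines
#'   the laboratory frame)?
#' @return A `screen_result`: list with `per_frame` (data frame of
#'   energy components for bound frames), `mean`, `sem`, `time_bound`
#'   (ns) and `bound_mask`. With zero bound frames, `time_bound` is 0
#'   and `mean`/`sem` are NA.
#' @export
screen_trajectory <- function(traj, topology, receptor_mask, ligand_mask,
                              params = gb_params(), rmsd_stop = 25.0,
                              stop_selection = NULL, align_receptor = TRUE) {
  if (traj$n_atoms != nrow(topology$atoms))
    stop("trajectory and topology atom counts differ")
  ia <- if (is.logical(receptor_mask)) which(receptor_mask) else
    as.integer(receptor_mask)
  ib <- if (is.logical(ligand_mask)) which(ligand_mask) else
    as.integer(ligand_mask)
  if (is.null(stop_selection)) {
    ca <- ib[topology$atoms$name[ib] == "CA"]
    stop_selection <- if (length(ca)) ca else ib
  }
  ref <- traj$frames[[1]]
  n_frames <- length(traj$frames)
  disp <- vapply(seq_len(n_frames), function(f) {
    fr <- traj$frames[[f]]
    if (align_receptor && length(ia) >= 3L) {
      fit <- superpose_and_rmsd(ref[ia, , drop = FALSE],
                                fr[ia, , drop = FALSE])
      fr <- t(fit$rotation %*% t(fr) + fit$translation)
    }
    superpose_and_rmsd(ref[stop_selection, , drop = FALSE],
                       fr[stop_selection, , drop = FALSE],
                       fit = FALSE)$rmsd
  }, numeric(1))
  first_out <- which(disp > rmsd_stop)[1]
  bound_mask <- if (is.na(first_out)) rep(TRUE, n_frames) else
    seq_len(n_frames) < first_out
  time_bound <- sum(bound_mask) * traj$frame_interval
  if (!any(bound_mask)) {
    return(structure(list(per_frame = NULL, mean = NA_real_, sem = NA_real_,
                          time_bound = 0, bound_mask = bound_mask,
                          displacement = disp),
                     class = "screen_result"))
  }
  per_frame <- do.call(rbind, lapply(which(bound_mask), function(f) {
    s <- topology
    s$atoms[, c("x", "y", "z")] <- traj$frames[[f]]
    e <- mmgbsa_score(s, ia, ib, params)
    data.frame(frame = f, e_coulomb = e$e_coulomb, e_lj = e$e_lj,
               g_gb = e$g_gb, g_sasa = e$g_sasa, total = e$total)
  }))
  m <- mean(per_frame$total)
  sem <- if (nrow(per_frame) > 1L)
    stats::sd(per_frame$total) / sqrt(nrow(per_frame)) else 0
  structure(list(per_frame = per_frame, mean = m, sem = sem,
                 time_bound = time_bound, bound_mask = bound_mask,
                 displacement = disp),
            class = "screen_result")
}
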