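# Seeded generators for small parameterized structures: a two-chain
# complex with a designable interface (fixture for MM-GBSA, RMSD and
# contact analyses) and a backbone-only peptide chain (fixture for
# cyclization topology).

#' Build a small two-chain complex with a designable interface
#'
#' Places the receptor's atoms on a sphere shell (chain A) and the
#' ligand's on a second shell well clear of it (chain B), then moves
#' exactly `interface_pairs` ligand atoms to within 4.4 A of distinct
#' receptor atoms, so that the complex has exactly that many
#' inter-chain atom pairs within the 5 A interface cutoff. All atoms
#' are at least 2.4 A apart. Charges are drawn randomly and shifted to
#' sum exactly to the requested net charge per chain; GB radii lie in
#' [1.2, 2.0] A. Deterministic for a fixed seed.
#'
#' @param n_receptor_atoms,n_ligand_atoms Atom counts (>= 1).
#' @param interface_pairs Exact number of inter-chain atom pairs closer
#'   than 5 A (must not exceed either atom count).
#' @param seed Integer seed.
#' @param net_charge_receptor,net_charge_ligand Integer net charge per
#'   chain (e).
#' @return A [param_structure()] with chains "A" (receptor) and "B"
#'   (ligand); each atom is its own residue so interface bookkeeping is
#'   per atom.
#' @export
build_toy_complex <- function(n_receptor_atoms, n_ligand_atoms,
                              interface_pairs = 0L, seed = 1L,
                              net_charge_receptor = 0L,
                              net_charge_ligand = 0L) {
  stopifnot(n_receptor_atoms >= 1, n_ligand_atoms >= 1, interface_pairs >= 0)
  if (interface_pairs > min(n_receptor_atoms, n_ligand_atoms))
    stop("interface_pairs (", interface_pairs,
         ") cannot exceed either chain's atom count")
  shell <- function(n, min_sep = 3.0) {
    if (n == 1L) return(matrix(0, 1, 3))
    pts <- golden_spiral_points(n)
    dmin <- min(stats::dist(pts))
    pts * (min_sep / dmin)
  }
  with_seed(seed, {
    for (attempt in 1:25) {
      rec <- shell(n_receptor_atoms)
      lig <- shell(n_ligand_atoms)
      r_rec <- if (n_receptor_atoms > 1) sqrt(sum(rec[1, ]^2)) else 0
      r_lig <- if (n_ligand_atoms > 1) sqrt(sum(lig[1, ]^2)) else 0
      offset <- r_rec + r_lig + 8
      lig <- sweep(lig, 2L, c(offset, 0, 0), "+")
      # jitter the bulk atoms slightly for irregularity
      rec <- rec + matrix(stats::runif(3 * n_receptor_atoms, -0.1, 0.1),
                          ncol = 3)
      lig <- lig + matrix(stats::runif(3 * n_ligand_atoms, -0.1, 0.1),
                          ncol = 3)
      if (interface_pairs > 0) {
        # receptor anchors: the atoms facing the ligand (+x side)
        anchors <- order(rec[, 1], decreasing = TRUE)[seq_len(interface_pairs)]
        for (m in seq_len(interface_pairs)) {
          p <- rec[anchors[m], ]
          u <- if (sqrt(sum(p^2)) > 1e-8) p / sqrt(sum(p^2)) else c(1, 0, 0)
          lig[m, ] <- p + 4.4 * u
        }
      }
      d2 <- outer(rowSums(rec^2), rowSums(lig^2), "+") - 2 * rec %*% t(lig)
      cross <- sqrt(pmax(d2, 0))
      all_xyz <- rbind(rec, lig)
      sep_ok <- n_receptor_atoms + n_ligand_atoms == 1L ||
        min(stats::dist(all_xyz)) >= 2.4
      if (sum(cross < 5) == interface_pairs && sep_ok &&
          (interface_pairs > 0 || all(cross >= 5))) break
      if (attempt == 25)
        stop("could not pack a complex with exactly ", interface_pairs,
             " interface pairs after 25 attempts")
    }
    balance <- function(n, net) {
      q <- stats::runif(n, -0.5, 0.5)
      q - mean(q) + net / n
    }
    n_tot <- n_receptor_atoms + n_ligand_atoms
    atoms <- data.frame(
      serial = seq_len(n_tot),
      name = c(sprintf("A%03d", seq_len(n_receptor_atoms)),
               sprintf("B%03d", seq_len(n_ligand_atoms))),
      resname = rep(c("REC", "LIG"), c(n_receptor_atoms, n_ligand_atoms)),
      resno = c(seq_len(n_receptor_atoms), seq_len(n_ligand_atoms)),
      chain = rep(c("A", "B"), c(n_receptor_atoms, n_ligand_atoms)),
      x = all_xyz[, 1], y = all_xyz[, 2], z = all_xyz[, 3],
      element = "C",
      charge = c(balance(n_receptor_atoms, net_charge_receptor),
                 balance(n_ligand_atoms, net_charge_ligand)),
      gb_radius = stats::runif(n_tot, 1.2, 2.0),
      lj_eps = stats::runif(n_tot, 0.05, 0.2),
      lj_rmin_half = stats::runif(n_tot, 1.3, 2.0),
      stringsAsFactors = FALSE
    )
    param_structure(atoms, provenance = sprintf(
      "synthetic toy complex (seed %d, %d interface pairs)", seed,
      interface_pairs))
  })
}

#' Build a backbone-only cyclic-peptide scaffold
#'
#' Lays the backbone N, CA and C atoms of each residue on a ring with
#' ~3.8 A CA-CA spacing: a minimal, synthetic stand-in for a
#' head-to-tail cyclizable peptide. Coordinates are idealized, not
#' energy-minimized.
#'
#' @param sequence One-letter amino-acid string (canonical 20 letters).
#' @param chain Chain identifier.
#' @return A [param_structure()] with 3 backbone atoms per residue and
#'   consecutive-residue C-N bonds (no cyclization bond; see
#'   [cyclize_head_to_tail()]).
#' @export
build_toy_peptide <- function(sequence, chain = "P") {
  aa1 <- strsplit(sequence, "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!length(aa1) || !all(aa1 %in% valid))
    stop("sequence must use the 20 canonical one-letter codes")
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")[aa1]
  n <- length(aa1)
  radius <- if (n > 2) 3.8 / (2 * sin(pi / n)) else 3.8
  ang <- 2 * pi * (seq_len(n) - 1) / n
  dang <- 2 * pi / (3 * n)
  rows <- lapply(seq_len(n), function(i) {
    data.frame(
      name = c("N", "CA", "C"), resname = unname(aa3[i]), resno = i,
      x = radius * cos(ang[i] + c(-dang, 0, dang)),
      y = radius * sin(ang[i] + c(-dang, 0, dang)),
      z = c(-0.3, 0, 0.3),
      element = c("N", "C", "C"),
      stringsAsFactors = FALSE
    )
  })
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$chain <- chain
  at$charge <- 0
  at$gb_radius <- ifelse(at$element == "N", 1.55, 1.7)
  at$lj_eps <- 0.1
  at$lj_rmin_half <- ifelse(at$element == "N", 1.85, 2.0)
  # linear backbone bonds: N-CA, CA-C within residues; C-N between
  bonds <- rbind(
    cbind(3 * (seq_len(n) - 1) + 1, 3 * (seq_len(n) - 1) + 2),
    cbind(3 * (seq_len(n) - 1) + 2, 3 * (seq_len(n) - 1) + 3),
    if (n > 1) cbind(3 * (seq_len(n - 1) - 1) + 3, 3 * seq_len(n - 1) + 1)
  )
  param_structure(at[, c("serial", "name", "resname", "resno", "chain",
                         "x", "y", "z", "element", "charge", "gb_radius",
                         "lj_eps", "lj_rmin_half")],
                  bonds,
                  provenance = sprintf("synthetic %d-residue peptide ring", n))
}
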