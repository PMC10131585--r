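# Parameterized structures: PDB-backed atom records augmented with the
# per-atom parameters (charge, GB radius, Lennard-Jones) that the
# MM-GBSA scoring needs, plus cyclization topology.

#' Construct a parameterized structure
#'
#' @param atoms Data frame with columns `serial`, `name`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z`, `element`, `charge` (e),
#'   `gb_radius` (A), `lj_eps` (kcal mol^-1), `lj_rmin_half` (A).
#' @param bonds Two-column integer matrix of atom indices (rows of
#'   `atoms`), including any cyclization bond; may be empty.
#' @param provenance Free-text origin note.
#' @return A `param_structure` object.
#' @export
param_structure <- function(atoms, bonds = NULL, provenance = "") {
  req <- c("serial", "name", "resname", "resno", "chain", "x", "y", "z",
           "element", "charge", "gb_radius", "lj_eps", "lj_rmin_half")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (chain, residue number, atom name): ",
         paste(utils::head(dups, 5), collapse = "; "))
  }
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > nrow(atoms)))
    stop("bond indices out of range")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds, provenance = provenance),
            class = "param_structure")
}

#' @export
print.param_structure <- function(x, ...) {
  cat("<param_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s), ",
      nrow(x$bonds), " explicit bond(s)\n", sep = "")
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param structure A [param_structure()].
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Read / write a per-atom parameter table
#'
#' Tab-separated with header
#' `resname atomname charge gb_radius lj_eps lj_rmin_half`, mapping
#' (residue name, atom name) to the parameters the PDB format cannot
#' carry.
#'
#' @param path File path.
#' @return Data frame with those six columns.
#' @export
read_param_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("resname", "atomname", "charge", "gb_radius", "lj_eps",
           "lj_rmin_half")
  if (!all(req %in% names(tb)))
    stop("parameter table needs columns: ", paste(req, collapse = " "))
  tb
}

#' @rdname read_param_table
#' @param table Parameter table data frame.
#' @export
write_param_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Derive the parameter table implied by a structure
#'
#' One row per distinct (resname, atom name); errors if atoms sharing a
#' key carry conflicting parameters.
#'
#' @param structure A [param_structure()].
#' @return A parameter table as in [read_param_table()].
#' @export
param_table_from_structure <- function(structure) {
  at <- structure$atoms
  tb <- unique(data.frame(resname = at$resname, atomname = at$name,
                          charge = at$charge, gb_radius = at$gb_radius,
                          lj_eps = at$lj_eps,
                          lj_rmin_half = at$lj_rmin_half))
  if (anyDuplicated(paste(tb$resname, tb$atomname)))
    stop("conflicting parameters for a (resname, atomname) key")
  rownames(tb) <- NULL
  tb
}

#' Read a parameterized structure from PDB
#'
#' ATOM/HETATM records are parsed with bio3d; the parameter table
#' supplies charge, GB radius and Lennard-Jones parameters by
#' (residue name, atom name). CONECT records (e.g. a cyclization bond)
#' are read into the bond list.
#'
#' @param path PDB file.
#' @param param_table Data frame as from [read_param_table()], or a path
#'   to one.
#' @return A [param_structure()].
#' @export
read_structure <- function(path, param_table) {
  if (is.character(param_table)) param_table <- read_param_table(param_table)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  key <- paste(a$resid, a$elety)
  pkey <- paste(param_table$resname, param_table$atomname)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no parameters for atom(s): ", paste(utils::head(bad, 8),
                                              collapse = "; "))
  }
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, resname = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    charge = param_table$charge[idx],
    gb_radius = param_table$gb_radius[idx],
    lj_eps = param_table$lj_eps[idx],
    lj_rmin_half = param_table$lj_rmin_half[idx],
    stringsAsFactors = FALSE
  )
  bonds <- read_conect_bonds(path, atoms$serial)
  param_structure(atoms, bonds, provenance = paste("read from", path))
}

read_conect_bonds <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path), value = TRUE)
  if (!length(lines)) return(NULL)
  pairs <- list()
  for (ln in lines) {
    flds <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    if (length(flds) < 2L) next
    for (j in flds[-1]) {
      i1 <- match(flds[1], serials); i2 <- match(j, serials)
      if (is.na(i1) || is.na(i2))
        stop("CONECT references unknown serial in ", basename(path))
      if (i1 < i2) pairs[[length(pairs) + 1L]] <- c(i1, i2)
    }
  }
  if (!length(pairs)) return(NULL)
  unique(do.call(rbind, pairs))
}

#' Write a parameterized structure to PDB
#'
#' ATOM records via bio3d; any bonds are emitted as CONECT records (both
#' directions, as paired structure viewers expect).
#'
#' @param structure A [param_structure()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resname, eleno = at$serial,
                   elety = at$name, chain = at$chain,
                   elesy = at$element, end = FALSE)
  lines <- readLines(path)
  if (nrow(structure$bonds)) {
    conect <- apply(structure$bonds, 1L, function(b)
      c(sprintf("CONECT%5d%5d", at$serial[b[1]], at$serial[b[2]]),
        sprintf("CONECT%5d%5d", at$serial[b[2]], at$serial[b[1]])))
    lines <- c(lines, as.vector(conect))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Add a head-to-tail cyclization bond to a peptide chain
#'
#' Joins the backbone N of the chain's first residue to the backbone C
#' of its last residue, the trans head-to-tail peptide-bond topology
#' used to cyclize designed peptides. Idempotent; never changes the
#' residue count.
#'
#' @param structure A [param_structure()].
#' @param chain Chain identifier to cyclize (>= 3 residues with backbone
#'   N and C atoms present).
#' @return The structure with exactly one added bond (or unchanged if
#'   the bond already exists).
#' @export
cyclize_head_to_tail <- function(structure, chain) {
  at <- structure$atoms
  sel <- which(at$chain == chain)
  if (!length(sel)) stop("unknown chain id: ", chain)
  resnos <- unique(at$resno[sel])
  if (length(resnos) < 3L)
    stop("head-to-tail cyclization needs >= 3 residues, chain ", chain,
         " has ", length(resnos))
  first <- min(resnos); last <- max(resnos)
  i_n <- sel[at$resno[sel] == first & at$name[sel] == "N"]
  i_c <- sel[at$resno[sel] == last & at$name[sel] == "C"]
  if (length(i_n) != 1L)
    stop("residue ", first, " of chain ", chain, " lacks a backbone N atom")
  if (length(i_c) != 1L)
    stop("residue ", last, " of chain ", chain, " lacks a backbone C atom")
  b <- structure$bonds
  if (nrow(b) && any((b[, 1] == i_n & b[, 2] == i_c) |
                     (b[, 1] == i_c & b[, 2] == i_n)))
    return(structure)
  structure$bonds <- rbind(b, c(i_n, i_c))
  structure
}

#' Optimal rigid superposition and RMSD
#'
#' Least-squares (Kabsch) rigid-body fit of `mobile` onto `reference`
#' over the selected atoms, with a guaranteed proper rotation
#' (determinant +1, never a reflection). With `fit = FALSE` the
#' coordinates are compared in the fixed laboratory frame (the
#' convention for a displacement-from-initial-positions stop criterion)
#' and the identity transform is returned.
#'
#' @param reference,mobile n x 3 coordinate matrices (congruent).
#' @param selection Optional index or logical mask of rows to use.
#' @param fit Superpose before computing RMSD?
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is x -> rotation %*% x + translation), `rmsd` (Angstrom)
#'   and `transformed` (mobile after the transform).
#' @export
superpose_and_rmsd <- function(reference, mobile, selection = NULL,
                               fit = TRUE) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)))
    stop("reference and mobile differ in size: ",
         nrow(reference), " vs ", nrow(mobile), " atoms")
  if (!is.null(selection)) {
    reference <- reference[selection, , drop = FALSE]
    mobile <- mobile[selection, , drop = FALSE]
  }
  n <- nrow(reference)
  if (!fit) {
    d2 <- rowSums((mobile - reference)^2)
    return(list(rotation = diag(3), translation = c(0, 0, 0),
                rmsd = sqrt(mean(d2)), transformed = mobile))
  }
  if (n < 3L) stop("fitting needs >= 3 atoms")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  if (qr(P)$rank < 2L) stop("fitting needs >= 3 non-collinear atoms")
  H <- crossprod(P, Q)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.vector(R %*% cm)
  moved <- t(R %*% t(mobile) + tr)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))),
       transformed = moved)
}

#' Residues at a chain-chain interface
#'
#' A residue belongs to the interface if any of its atoms lies within
#' `cutoff` of any atom of the other chain (the symmetric 5-Angstrom
#' rule used to delineate a receptor's binding site).
#'
#' @param structure A [param_structure()].
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Distance cutoff in Angstroms (default 5).
#' @return List with elements named after the two chains, each a sorted
#'   vector of interface residue numbers.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 5.0) {
  at <- structure$atoms
  ia <- which(at$chain == chain_a); ib <- which(at$chain == chain_b)
  if (!length(ia)) stop("unknown chain id: ", chain_a)
  if (!length(ib)) stop("unknown chain id: ", chain_b)
  xa <- coords(structure)[ia, , drop = FALSE]
  xb <- coords(structure)[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  close <- d2 <= cutoff^2 + 1e-12
  res_a <- sort(unique(at$resno[ia][rowSums(close) > 0]))
  res_b <- sort(unique(at$resno[ib][colSums(close) > 0]))
  out <- list(res_a, res_b)
  names(out) <- c(chain_a, chain_b)
  out
}

#' Trajectory container
#'
#' An in-memory ordered list of coordinate frames congruent with a
#' topology, written at a fixed time interval (0.2 ns per frame is the
#' screening convention).
#'
#' @param frames List of n x 3 coordinate matrices, all the same size.
#' @param frame_interval Time per frame in ns (> 0).
#' @return A `trajectory` object.
#' @export
trajectory <- function(frames, frame_interval = 0.2) {
  stopifnot(length(frames) >= 1L, frame_interval > 0)
  n <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok)) stop("all frames must be n x 3 matrices with equal atom count")
  structure(list(frames = frames, frame_interval = frame_interval,
                 n_atoms = n), class = "trajectory")
}

#' Minimum cross-group distance per frame
#'
#' For each frame, the minimum Euclidean distance over all pairs with
#' one atom in each group -- the standard contact coordinate for
#' hydrogen bonds, salt bridges and ring stacking.
#'
#' @param traj A [trajectory()].
#' @param group_a,group_b Non-empty atom index vectors.
#' @return A `contact_series`: list with `times` (ns) and `distances`
#'   (Angstrom).
#' @export
contact_distance_series <- function(traj, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("atom groups must be non-empty")
  dists <- vapply(traj$frames, function(f) {
    xa <- f[group_a, , drop = FALSE]; xb <- f[group_b, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  structure(list(times = seq_along(traj$frames) * traj$frame_interval,
                 distances = dists), class = "contact_series")
}

#' Fraction of bound frames with a contact formed
#'
#' @param series A `contact_series` from [contact_distance_series()].
#' @param threshold Contact distance threshold in Angstroms (e.g. 2.2
#'   for a salt bridge's H...O distance).
#' @param bound_mask Logical mask over frames restricting the
#'   denominator to the bound portion of the trajectory; defaults to
#'   all frames.
#' @return Fraction in [0, 1].
#' @export
contact_occupancy <- function(series, threshold,
                              bound_mask = rep(TRUE, length(series$distances))) {
  if (length(bound_mask) != length(series$distances))
    stop("bound_mask length (", length(bound_mask),
         ") must equal series length (", length(series$distances), ")")
  if (!any(bound_mask)) stop("bound_mask selects no frames")
  mean(series$distances[bound_mask] < threshold)
}
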