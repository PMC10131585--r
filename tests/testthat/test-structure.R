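test_that("PDB round trip preserves atoms, order and coordinates", {
  tc <- build_toy_complex(10, 5, 2, 3)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc, tf)
  back <- read_structure(tf, param_table_from_structure(tc))
  expect_equal(back$atoms$name, tc$atoms$name)
  expect_equal(back$atoms$chain, tc$atoms$chain)
  expect_equal(coords(back), coords(tc), tolerance = 1e-3)
  expect_equal(back$atoms$charge, tc$atoms$charge)
  # write -> read -> write -> read is stable
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(back, tf2)
  again <- read_structure(tf2, param_table_from_structure(tc))
  expect_equal(coords(again), coords(back), tolerance = 1e-9)
})

test_that("single-ATOM files parse to the stated coordinates", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00           C",
    "END"), tf)
  pt <- data.frame(resname = "ALA", atomname = "CA", charge = 0.1,
                   gb_radius = 1.7, lj_eps = 0.1, lj_rmin_half = 2.0)
  s <- read_structure(tf, pt)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])),
               c(11.104, 13.207, 2.100))
  expect_equal(s$atoms$charge, 0.1)
})

test_that("invalid structures are rejected with informative errors", {
  tc <- build_toy_complex(4, 2, 0, 1)
  dup <- tc$atoms
  dup$name[2] <- dup$name[1]; dup$resno[2] <- dup$resno[1]
  expect_error(param_structure(dup), "duplicate")
  # missing parameters are reported by atom
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc, tf)
  pt <- param_table_from_structure(tc)
  expect_error(read_structure(tf, pt[-1, ]), "no parameters")
  bad <- tc$atoms; bad$x[1] <- NaN
  expect_error(param_structure(bad), "finite")
})

test_that("head-to-tail cyclization adds exactly one idempotent bond", {
  pep <- build_toy_peptide("EIDTVLTPTGWVAKRYS")
  expect_equal(length(unique(pep$atoms$resno)), 17L)
  cyc <- cyclize_head_to_tail(pep, "P")
  expect_equal(nrow(cyc$bonds), nrow(pep$bonds) + 1L)
  expect_equal(length(unique(cyc$atoms$resno)), 17L)
  new_bond <- cyc$bonds[nrow(cyc$bonds), ]
  expect_equal(cyc$atoms$name[new_bond[1]], "N")
  expect_equal(cyc$atoms$resno[new_bond[1]], 1L)
  expect_equal(cyc$atoms$name[new_bond[2]], "C")
  expect_equal(cyc$atoms$resno[new_bond[2]], 17L)
  expect_identical(cyclize_head_to_tail(cyc, "P"), cyc)
  # cyclization bond survives a PDB round trip via CONECT
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cyc, tf)
  back <- read_structure(tf, param_table_from_structure(cyc))
  expect_true(any(back$bonds[, 1] == new_bond[1] &
                  back$bonds[, 2] == new_bond[2]))
  expect_error(cyclize_head_to_tail(build_toy_peptide("AC"), "P"),
               ">= 3 residues")
  expect_error(cyclize_head_to_tail(pep, "Z"), "unknown chain")
  # missing backbone atom is named
  noN <- pep
  noN$atoms <- noN$atoms[!(noN$atoms$resno == 1 & noN$atoms$name == "N"), ]
  expect_error(cyclize_head_to_tail(noN, "P"), "residue 1")
})

test_that("superposition recovers rigid transforms and proper rotations", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  expect_equal(superpose_and_rmsd(ref, ref)$rmsd, 0, tolerance = 1e-12)
  ax <- c(1, 2, 3) / sqrt(14); th <- pi / 2
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mob <- t(R %*% t(ref)) + rep(c(3, -2, 7), each = nrow(ref))
  fit <- superpose_and_rmsd(ref, mob)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # agreement with an independent superposition implementation
  b3 <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = as.vector(t(mob))))
  expect_equal(fit$transformed, matrix(b3, ncol = 3, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("unfitted RMSD is the plain displacement norm", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mob <- ref
  mob[1, ] <- mob[1, ] + c(2, 0, 0)
  expect_equal(superpose_and_rmsd(ref, mob, fit = FALSE)$rmsd, 1.0)
  expect_error(superpose_and_rmsd(ref, mob[1:3, ]), "size")
})

test_that("fitted RMSD never exceeds unfitted RMSD (property)", {
  for (seed in 1:8) {
    set.seed(seed)
    ref <- matrix(rnorm(24), ncol = 3)
    mob <- ref + matrix(rnorm(24, sd = seed / 4), ncol = 3) + seed
    f <- superpose_and_rmsd(ref, mob)
    u <- superpose_and_rmsd(ref, mob, fit = FALSE)
    expect_lte(f$rmsd, u$rmsd + 1e-12)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
})

test_that("interface residues match the brute-force rule", {
  tc0 <- build_toy_complex(6, 3, 0, 2)
  ir0 <- interface_residues(tc0, "A", "B", 5)
  expect_length(ir0$A, 0)
  expect_length(ir0$B, 0)

  tc <- build_toy_complex(30, 10, 4, 7)
  ir <- interface_residues(tc, "A", "B", 5)
  xyz <- coords(tc)
  at <- tc$atoms
  exp_a <- sort(unique(unlist(lapply(which(at$chain == "A"), function(i) {
    js <- which(at$chain == "B")
    if (any(sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2)) <= 5))
      at$resno[i]
  }))))
  expect_equal(ir$A, exp_a)
  # symmetry and cutoff monotonicity
  ir_swap <- interface_residues(tc, "B", "A", 5)
  expect_equal(ir_swap$B, ir$B)
  expect_equal(ir_swap$A, ir$A)
  ir_big <- interface_residues(tc, "A", "B", 8)
  expect_true(all(ir$A %in% ir_big$A))
  ir_inf <- interface_residues(tc, "A", "B", Inf)
  expect_equal(ir_inf$A, sort(unique(at$resno[at$chain == "A"])))
  expect_equal(ir_inf$B, sort(unique(at$resno[at$chain == "B"])))
  expect_error(interface_residues(tc, "A", "Q"), "unknown chain")
})

test_that("contact series and occupancy follow the minimum-distance rule", {
  set.seed(3)
  frames <- lapply(1:5, function(i) matrix(rnorm(18, sd = 3), ncol = 3))
  tr <- trajectory(frames, frame_interval = 0.2)
  ga <- 1:3; gb <- 4:6
  cs <- contact_distance_series(tr, ga, gb)
  expect_equal(cs$times, (1:5) * 0.2)
  for (f in 1:5) {
    expect_equal(cs$distances[f], brute_min_dist(frames[[f]], ga, gb))
  }
  # single-atom groups: plain interatomic distance
  cs1 <- contact_distance_series(tr, 1, 4)
  expect_equal(cs1$distances,
               vapply(frames, function(m) sqrt(sum((m[1, ] - m[4, ])^2)), 1))
  # shared atom: zero at every frame
  cs0 <- contact_distance_series(tr, 1:2, 2:3)
  expect_equal(cs0$distances, rep(0, 5))
  expect_error(contact_distance_series(tr, integer(0), gb), "non-empty")

  ser <- structure(list(times = (1:4) * 0.2,
                        distances = c(1.0, 3.0, 1.5, 2.5)),
                   class = "contact_series")
  expect_equal(contact_occupancy(ser, 2.2), 0.5)
  expect_equal(contact_occupancy(ser, 10), 1.0)
  expect_equal(contact_occupancy(ser, 0), 0.0)
  expect_equal(contact_occupancy(ser, 2.2, c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_error(contact_occupancy(ser, 2.2, c(TRUE, FALSE)), "length")
  expect_error(contact_occupancy(ser, 2.2, rep(FALSE, 4)), "no frames")
})

test_that("colvar and PMF text formats round-trip, incl. loose spacing", {
  tf <- withr::local_tempfile(fileext = ".colvar")
  steps <- seq(0, 900, by = 100)
  vals <- cbind(sin(steps / 100), cos(steps / 100))
  write_colvar(steps, vals, tf, names = c("r", "theta"))
  back <- read_colvar(tf)
  expect_equal(back$step, steps)
  expect_equal(back$r, vals[, 1], tolerance = 1e-9)
  expect_equal(back$theta, vals[, 2], tolerance = 1e-9)
  # multi-space dialect with extra comments
  tf2 <- withr::local_tempfile()
  writeLines(c("# step   r", "0    1.50", "# restart", "500      2.25"), tf2)
  b2 <- read_colvar(tf2)
  expect_equal(b2$step, c(0L, 500L))
  expect_equal(b2$r, c(1.5, 2.25))

  p <- pmf_profile(seq(16, 26, by = 0.5), (seq(16, 26, by = 0.5) - 20)^2)
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  write_pmf(p, tf3)
  pb <- read_pmf(tf3)
  expect_equal(pb$grid, p$grid)
  expect_equal(pb$w, p$w, tolerance = 1e-9)
  expect_equal(pb$reference, "min-zero")
})

test_that("window manifests and per-window colvar files feed WHAM", {
  dir <- withr::local_tempdir()
  wg <- make_window_grid(0, 2, 1, 5)
  wg$file <- file.path(dir, sprintf("win%02d.colvar", wg$index))
  for (i in seq_len(nrow(wg))) {
    write_colvar(1:50, wg$center[i] + sin(1:50 + i), wg$file[i])
  }
  mf <- file.path(dir, "windows.tsv")
  write_window_manifest(wg, mf)
  sams <- read_window_samples(mf, dir)
  expect_length(sams, 3L)
  expect_equal(sams[[2]]$window$center, 1)
  expect_equal(sams[[3]]$values, 2 + sin(1:50 + 3), tolerance = 1e-9)
})
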