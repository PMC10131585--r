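test_that("Born radii match closed forms and the descreening oracle", {
  p <- gb_params()
  one <- build_toy_complex(1, 1, 0, 1)
  one$atoms <- one$atoms[1, , drop = FALSE]
  one$atoms$gb_radius <- 1.5
  # isolated atom: no descreening, effective radius = intrinsic - offset
  expect_equal(born_radii(one, p), 1.5 - 0.09, tolerance = 1e-12)

  # two far-separated atoms: isolated values within 1e-6
  two <- build_toy_complex(1, 1, 0, 1)
  two$atoms$gb_radius <- c(1.5, 1.8)
  two$atoms[1, c("x", "y", "z")] <- c(0, 0, 0)
  two$atoms[2, c("x", "y", "z")] <- c(5000, 0, 0)
  expect_equal(born_radii(two, p), c(1.41, 1.71), tolerance = 1e-6)

  # contact pair: strictly larger radii than far apart, and equal to the
  # OBC value computed from an independent numeric descreening integral
  near <- two
  near$atoms[2, c("x", "y", "z")] <- c(2.2, 0, 0)
  a_near <- born_radii(near, p)
  expect_true(all(a_near > born_radii(two, p)))
  rho <- c(1.41, 1.71)
  for (i in 1:2) {
    I <- oracle_descreen(2.2, rho[i], rho[3 - i])
    psi <- I * rho[i]
    inv_a <- 1 / rho[i] -
      tanh(1.0 * psi - 0.8 * psi^2 + 4.85 * psi^3) / near$atoms$gb_radius[i]
    expect_equal(a_near[i], 1 / inv_a, tolerance = 1e-4)
  }
  bad <- one; bad$atoms$gb_radius <- 0.05
  expect_error(born_radii(bad, p), "offset")
})

test_that("GB energy reproduces the Born formula and its fused limit", {
  p <- gb_params()
  ion <- build_toy_complex(1, 1, 0, 1)
  ion$atoms <- ion$atoms[1, , drop = FALSE]
  ion$atoms$charge <- 1
  e <- gb_energy(ion, radii = 2.0, params = p)
  expect_equal(e, -0.5 * (1 - 1 / 78.5) * 332.0636 / 2.0, tolerance = 1e-9)
  expect_equal(e, -81.958, tolerance = 1e-4)

  neutral <- build_toy_complex(5, 3, 0, 2)
  neutral$atoms$charge <- 0
  expect_equal(gb_energy(neutral, params = p), 0)

  # r -> 0 limit: f_GB -> sqrt(a_i a_j), the fused-ion Born energy
  pair <- build_toy_complex(1, 1, 0, 1)
  pair$atoms$charge <- c(1, -1)
  pair$atoms[1, c("x", "y", "z")] <- c(0, 0, 0)
  pair$atoms[2, c("x", "y", "z")] <- c(1e-7, 0, 0)
  a <- c(1.6, 2.1)
  e2 <- gb_energy(pair, radii = a, params = p)
  kpref <- -0.5 * (1 - 1 / 78.5) * 332.0636
  fused <- kpref * (1 / 1.6 + 1 / 2.1 - 2 / sqrt(1.6 * 2.1))
  expect_equal(e2, fused, tolerance = 1e-6)
})

test_that("GB energy is invariant under rigid motions", {
  p <- gb_params()
  tc <- build_toy_complex(8, 4, 2, 6)
  e0 <- gb_energy(tc, born_radii(tc, p), p)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  rot <- tc
  rot$atoms[, c("x", "y", "z")] <- t(R %*% t(coords(tc))) + 13.7
  e1 <- gb_energy(rot, born_radii(rot, p), p)
  expect_lt(abs(e1 - e0) / abs(e0), 1e-9)
})

test_that("SASA matches sphere closed forms", {
  p <- gb_params()
  one <- build_toy_complex(1, 1, 0, 1)
  one$atoms <- one$atoms[1, , drop = FALSE]
  one$atoms$gb_radius <- 1.6
  s <- sasa(one, p, 960)
  expect_equal(s$total, 4 * pi * 3.0^2, tolerance = 0.01 * 4 * pi * 9)

  # fully separated: additivity
  two <- build_toy_complex(1, 1, 0, 1)
  two$atoms$gb_radius <- c(1.6, 1.2)
  two$atoms[2, c("x", "y", "z")] <- c(50, 0, 0)
  s2 <- sasa(two, p, 960)
  expect_equal(s2$total, 4 * pi * (3.0^2 + 2.6^2), tolerance = 1e-6)

  # overlapping equal spheres vs the spherical-cap closed form
  d <- 2.5; R <- 1.6 + 1.4
  two$atoms$gb_radius <- c(1.6, 1.6)
  two$atoms[2, c("x", "y", "z")] <- c(d, 0, 0)
  s3 <- sasa(two, p, 2000)
  h <- R - d / 2                       # buried cap height per sphere
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_equal(s3$total, analytic, tolerance = 0.02 * analytic)

  expect_error(sasa(one, p, 16), ">= 32")
  # point-set refinement changes totals by < 0.5%
  tc <- build_toy_complex(10, 5, 3, 4)
  a <- sasa(tc, p, 960)$total
  b <- sasa(tc, p, 1920)$total
  expect_lt(abs(a - b) / a, 0.005)
})

test_that("MM-GBSA score matches a term-by-term hand computation", {
  p <- gb_params()
  # two-atom complex: one atom per side, opposite unit charges, 5 A apart
  cx <- build_toy_complex(1, 1, 0, 1)
  cx$atoms$charge <- c(1, -1)
  cx$atoms$gb_radius <- c(1.7, 1.5)
  cx$atoms$lj_eps <- c(0.12, 0.2)
  cx$atoms$lj_rmin_half <- c(1.9, 1.6)
  cx$atoms[1, c("x", "y", "z")] <- c(0, 0, 0)
  cx$atoms[2, c("x", "y", "z")] <- c(5, 0, 0)
  sc <- mmgbsa_score(cx, 1, 2, p)

  # independent evaluation of the same formulas
  r <- 5
  e_coul <- 332.0636 * 1 * (-1) / r
  eps <- sqrt(0.12 * 0.2); rmin <- 1.9 + 1.6
  e_lj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  rho <- c(1.7, 1.5) - 0.09
  I1 <- oracle_descreen(r, rho[1], rho[2])
  I2 <- oracle_descreen(r, rho[2], rho[1])
  ob <- function(I, rho_i, R) {
    psi <- I * rho_i
    1 / (1 / rho_i - tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / R)
  }
  a1 <- ob(I1, rho[1], 1.7); a2 <- ob(I2, rho[2], 1.5)
  kpref <- -0.5 * (1 - 1 / 78.5) * 332.0636
  fgb <- sqrt(r^2 + a1 * a2 * exp(-r^2 / (4 * a1 * a2)))
  gb_cx <- kpref * (1 / a1 + 1 / a2 + 2 * (1 * -1) / fgb)
  gb_parts <- kpref * (1 / rho[1] + 1 / rho[2])
  g_gb <- gb_cx - gb_parts
  sas <- function(st) sasa(st, p, 960)$total
  g_sasa <- p$surface_tension *
    (sas(cx) - sas(subset_toy(cx, 1)) - sas(subset_toy(cx, 2)))
  expect_equal(sc$e_coulomb, e_coul, tolerance = 1e-9)
  expect_equal(sc$e_lj, e_lj, tolerance = 1e-9)
  expect_equal(sc$g_gb, g_gb, tolerance = 1e-4)
  expect_equal(sc$g_sasa, g_sasa, tolerance = 1e-9)
  expect_equal(sc$total, sc$e_coulomb + sc$e_lj + sc$g_gb + sc$g_sasa)

  # symmetry of the difference formula
  sc_swap <- mmgbsa_score(cx, 2, 1, p)
  expect_equal(sc_swap$total, sc$total, tolerance = 1e-12)
  expect_error(mmgbsa_score(cx, 1, 1:2, p), "overlap")
  expect_error(mmgbsa_score(cx, 1, integer(0), p), "partition")
})

test_that("a non-interacting distant ligand scores zero", {
  p <- gb_params()
  tc <- build_toy_complex(6, 3, 0, 11)
  ib <- which(tc$atoms$chain == "B")
  # strip the ligand of charge and LJ attraction, park it far away
  tc$atoms$charge[ib] <- 0
  tc$atoms$lj_eps[ib] <- 0
  tc$atoms$x[ib] <- tc$atoms$x[ib] + 500
  sc <- mmgbsa_score(tc, which(tc$atoms$chain == "A"), ib, p)
  expect_lt(abs(sc$total), 1e-6)
})

test_that("MM-GBSA total vanishes at 200 A separation", {
  p <- gb_params()
  tc <- build_toy_complex(8, 5, 0, 11)
  ib <- which(tc$atoms$chain == "B")
  tc$atoms$x[ib] <- tc$atoms$x[ib] + 200
  sc <- mmgbsa_score(tc, which(tc$atoms$chain == "A"), ib, p)
  expect_lt(abs(sc$total), 1e-3)
})

test_that("buried area is non-negative for contacting chains", {
  p <- gb_params()
  tc <- build_toy_complex(15, 8, 5, 13)
  ia <- which(tc$atoms$chain == "A"); ib <- which(tc$atoms$chain == "B")
  sc <- mmgbsa_score(tc, ia, ib, p)
  expect_lte(sc$g_sasa, 1e-9)  # gamma > 0 times non-positive delta-SASA
})

test_that("trajectory screening applies the displacement stop rule", {
  p <- gb_params()
  tc <- build_toy_complex(4, 2, 0, 21)
  ia <- which(tc$atoms$chain == "A"); ib <- which(tc$atoms$chain == "B")
  base <- coords(tc)
  # ligand drifts +6 A per frame: crosses 25 A between frames 5 and 6
  frames <- lapply(0:9, function(k) {
    m <- base
    m[ib, 1] <- m[ib, 1] + 6 * k
    m
  })
  tr <- trajectory(frames, frame_interval = 0.2)
  res <- screen_trajectory(tr, tc, ia, ib, p)
  expect_equal(sum(res$bound_mask), 5L)       # frames 1-5 (0,6,...,24 A)
  expect_equal(res$time_bound, 1.0)
  expect_equal(nrow(res$per_frame), 5L)

  # never dissociating: full duration
  tr2 <- trajectory(lapply(1:10, function(k) base), frame_interval = 0.2)
  res2 <- screen_trajectory(tr2, tc, ia, ib, p)
  expect_equal(res2$time_bound, 2.0)
  # constant geometry => constant energy => SEM 0
  expect_equal(res2$sem, 0, tolerance = 1e-9)

  # zero bound frames: flagged result, not an exception
  res4 <- screen_trajectory(tr, tc, ia, ib, p, rmsd_stop = -1)
  expect_equal(res4$time_bound, 0)
  expect_true(is.na(res4$mean))
})
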