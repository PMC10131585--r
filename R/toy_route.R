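# An analytic end-to-end fixture for the geometric route: a separable
# toy binding model whose stage PMFs all derive from one energy
# surface, so the assembled standard free energy must not depend on the
# restraint force constants (the bias must cancel across stages).

#' Analytic toy binding model for route path-consistency checks
#'
#' A separable model of a bound ligand: a deep radial well w_r(r), weak
#' harmonic site potentials on the two polar direction angles, the
#' three Euler angles and one conformational coordinate, and a bulk
#' conformational potential for the free ligand. A smooth switch turns
#' the site potentials off as the ligand leaves the well, so at the
#' unbound reference distance only the restraints act. Every quantity
#' is analytic; nothing is sampled.
#'
#' @return List of the model's potential functions and parameters:
#'   `v_theta`, `v_phi`, `v_Theta`, `v_Phi`, `v_Psi` (bare angular site
#'   potentials, degrees), `v_site`/`w_bulk` (conformational, A),
#'   `w_r` (radial well, A), `s_switch` (bound-state switch),
#'   `centers` (restraint centers) and the route geometry `r_star`,
#'   `a`.
#' @export
toy_binding_model <- function() {
  list(
    v_theta = function(x) 0.01 * (x - 60)^2,
    v_phi   = function(x) 0.01 * (x - 20)^2,
    v_Theta = function(x) 0.01 * (x - 80)^2,
    v_Phi   = function(x) 0.01 * (x + 30)^2,
    v_Psi   = function(x) 0.01 * (x - 10)^2,
    v_site  = function(x) 1.5 * (x - 1)^2,
    w_bulk  = function(x) 0.3 * (x - 4)^2,
    w_r     = function(r) -12 * exp(-((r - 17.5) / 1.0)^2),
    s_switch = function(r) ifelse(r <= 19.5, 1, ifelse(r >= 23, 0,
      0.5 * (1 + cos(pi * (r - 19.5) / 3.5)))),
    centers = list(theta = 60, phi = 20, Theta = 80, Phi = -30, Psi = 10,
                   conf = 1),
    r_star = 26, a = 16
  )
}

#' Assemble the nine geometric-route stages for the toy binding model
#'
#' Computes every stage of the route for [toy_binding_model()] with the
#' given restraint force constants: stage 1 via [restraint_free_energy()]
#' on the bulk conformational PMF, stage 2 via
#' [orientational_restraint_analytic()], stage 3 via [separation_term()]
#' on the analytically derived separation PMF (radial well, 2 kT ln r
#' geometric term and the angular/conformational occupancy factors),
#' and stages 4-9 via [restraint_free_energy()] release on the
#' Jacobian-inclusive site PMFs. Because the model is exact, the
#' assembled total must be invariant to rescaling the force constants.
#'
#' @param k_dist Distance/RMSD restraint force constant,
#'   kcal mol^-1 A^-2.
#' @param k_ang Angular restraint force constant, kcal mol^-1 deg^-2.
#' @param thermo A [thermo_state()].
#' @return A `georoute_result` (see [assemble_standard_free_energy()]).
#' @export
toy_route_stages <- function(k_dist = 10, k_ang = 0.1,
                             thermo = thermo_state()) {
  m <- toy_binding_model()
  kT <- thermo$kT; beta <- thermo$beta; deg <- pi / 180
  u_c <- restraint_def("rmsd", m$centers$conf, k_dist)
  u_t <- restraint_def("polar_theta", m$centers$theta, k_ang)
  u_p <- restraint_def("polar_phi", m$centers$phi, k_ang)
  u_T <- restraint_def("euler_Theta", m$centers$Theta, k_ang)
  u_P <- restraint_def("euler_Phi", m$centers$Phi, k_ang)
  u_S <- restraint_def("euler_Psi", m$centers$Psi, k_ang)

  xi <- seq(0, 8, by = 0.01)
  ang <- seq(0.25, 179.75, by = 0.25)
  ang2 <- seq(-180, 180, by = 0.25)

  st1 <- restraint_free_energy(pmf_profile(xi, m$w_bulk(xi), "raw"),
                               u_c, "apply", thermo)$free_energy
  st2 <- orientational_restraint_analytic(list(u_T, u_P, u_S), thermo)

  # separation PMF with occupancy factors, computed analytically
  r <- seq(m$a, m$r_star, by = 0.02)
  wt <- trapezoid_weights(ang); wt2 <- trapezoid_weights(ang2)
  wx <- trapezoid_weights(xi)
  Fd <- Fo <- Fc <- numeric(length(r))
  for (i in seq_along(r)) {
    s <- m$s_switch(r[i])
    Fd[i] <- sum(wt * sin(ang * deg) *
                   exp(-beta * (s * m$v_theta(ang) + u_t$energy(ang)))) *
      sum(wt2 * exp(-beta * (s * m$v_phi(ang2) + u_p$energy(ang2))))
    Fo[i] <- sum(wt * sin(ang * deg) *
                   exp(-beta * (s * m$v_Theta(ang) + u_T$energy(ang)))) *
      sum(wt2 * exp(-beta * (s * m$v_Phi(ang2) + u_P$energy(ang2)))) *
      sum(wt2 * exp(-beta * (s * m$v_Psi(ang2) + u_S$energy(ang2))))
    Fc[i] <- sum(wx * exp(-beta * (s * m$v_site(xi) +
                                     (1 - s) * m$w_bulk(xi) +
                                     u_c$energy(xi))))
  }
  n_r <- length(r)
  W <- m$w_r(r) - 2 * kT * log(r / m$r_star) - kT * log(Fd / Fd[n_r]) -
    kT * log(Fo / Fo[n_r]) - kT * log(Fc / Fc[n_r])
  st3 <- separation_term(pmf_profile(r, W, "raw"), u_t, u_p,
                         r_star = m$r_star, a = m$a, thermo = thermo)

  # Jacobian-inclusive site PMFs for the release stages
  jac <- -kT * log(sin(ang * deg))
  rel <- function(pmf, restr) restraint_free_energy(pmf, restr, "release",
                                                    thermo)$free_energy
  st4 <- rel(pmf_profile(ang2, m$v_phi(ang2), "raw"), u_p)
  st5 <- rel(pmf_profile(ang, m$v_theta(ang) + jac, "raw"), u_t)
  st6 <- rel(pmf_profile(ang2, m$v_Psi(ang2), "raw"), u_S)
  st7 <- rel(pmf_profile(ang2, m$v_Phi(ang2), "raw"), u_P)
  st8 <- rel(pmf_profile(ang, m$v_Theta(ang) + jac, "raw"), u_T)
  st9 <- rel(pmf_profile(xi, m$v_site(xi), "raw"), u_c)

  assemble_standard_free_energy(list(
    stage_result(1, st1, method = "PMF quadrature", system = "ligand",
                 action = "apply"),
    st2,
    st3,
    stage_result(4, st4, method = "PMF quadrature", system = "complex",
                 action = "release"),
    stage_result(5, st5, method = "PMF quadrature", system = "complex",
                 action = "release"),
    stage_result(6, st6, method = "PMF quadrature", system = "complex",
                 action = "release"),
    stage_result(7, st7, method = "PMF quadrature", system = "complex",
                 action = "release"),
    stage_result(8, st8, method = "PMF quadrature", system = "complex",
                 action = "release"),
    stage_result(9, st9, method = "PMF quadrature", system = "complex",
                 action = "release")), thermo)
}
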