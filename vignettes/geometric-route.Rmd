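---
title: "The geometric route to standard binding free energies: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The geometric route: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(georoute)
```

## The problem

Absolute binding free energies of peptide:protein complexes are hard to
converge by brute-force simulation because the bound and unbound states
differ in conformation, orientation and position all at once. The
geometric route tames this by restraining the ligand's degrees of
freedom one at a time: the free energy of *applying* conformational and
orientational restraints to the free ligand is computed first (stages
1–2), then the binding of the fully restrained ligand with its
standard-state correction (stage 3), and finally the free energies of
*releasing* the directional, orientational and conformational
restraints on the bound ligand (stages 4–9). Because the end states are
the unrestrained free species and the unrestrained complex, the sum of
all stages is the standard binding free energy, independent of the
restraint strengths — a property this package tests explicitly.

`georoute` implements the thermodynamics of that route, the PMF
estimators the stages consume, MM-GBSA screening of candidate
complexes, and the screening-table analytics of the CTLA4-binding
cyclic-peptide campaign whose staged results ship with the package
(`ctla4_stage_table()`, `ctla4_candidates()`).

## Restraint thermodynamics

For a harmonic restraint $u(\xi) = \tfrac{k}{2}(\xi - \xi_0)^2$ on a
coordinate with PMF $w(\xi)$,

$$\Delta G_{\mathrm{apply}} = -\frac{1}{\beta}\,
\ln\frac{\int e^{-\beta(w+u)}\,d\xi}{\int e^{-\beta w}\,d\xi},
\qquad \Delta G_{\mathrm{release}} = -\Delta G_{\mathrm{apply}},$$

evaluated by trapezoid quadrature on the PMF grid
(`restraint_free_energy()`). Two conventions matter and are fixed
package-wide:

* $k$ is the **full** force constant (the $\tfrac12$ is written
  explicitly); some MD packages fold the $\tfrac12$ into $k$.
* Angular PMFs supplied by users are assumed **Jacobian-inclusive**
  (i.e. $-k_BT\ln\sin\theta$ is already inside $w$), which is what
  colvar-based ABF output provides. The analytic stage-2 integral, by
  contrast, writes its $\sin\Theta$ weight explicitly because the free
  ligand's orientation is uniform.

The orientational term (stage 2) is separable in the three Euler
angles, so it is evaluated as a product of three adaptive 1-D
quadratures over $\Theta \in [0^\circ, 180^\circ]$,
$\Phi, \Psi \in [-180^\circ, 180^\circ]$
(`orientational_restraint_analytic()`); it is exact up to quadrature
and carries zero uncertainty. With the conventional angular default of
0.1 kcal mol⁻¹ deg⁻² on all three angles the term evaluates to
+6.61 kcal/mol, matching the analytic stage of the shipped table.

The separation term (stage 3) uses
$I = \int_a^{r^*} e^{-\beta(W(r) - W(r^*))}\,dr$ with **no** $r^2$
factor in the integrand: the geometric $r^{*2}$ lives entirely in
$S^* = r^{*2}\iint \sin\theta\, e^{-\beta u_{\mathrm{dir}}}\,d\theta\,
d\phi$ (in steradians, so $S^* = 4\pi r^{*2}$ unrestrained). Defaults
$r^* = 26$ Å, $a = 16$ Å follow the umbrella grid below;
$C^\circ = 1/1660.539\ \text{Å}^{-3}$ is recomputed from Avogadro's
number, not hard-coded.

Stage numbering follows the reversed (conceptual) order — apply to the
free ligand first — rather than the order of the originating plugin;
`assemble_standard_free_energy()` checks that exactly stages 1–9 are
present, sums them, combines uncertainties in quadrature (stages are
treated as independent; the shipped table's uncertainties combine to
3.458, displayed as 3.46 and reported to one decimal as 3.5), and
converts the total to a dissociation constant.

## PMF estimators

**WHAM** (`wham()`). Harmonic-window umbrella samples are pooled per
window (replica-exchange provenance is ignored, the standard practice),
histogrammed, and the self-consistent equations iterated until the
maximum change in window free energies is below 10⁻⁷ kcal/mol (gauge
fixed by pinning the first window's offset to zero; cap 10⁵
iterations, non-convergence reported via a flag, never silently).
Numerical choices:

* Bin width defaults to one fifth of the window spacing (0.1 Å on the
  production grid) — fine enough to resolve the window Gaussians
  (σ ≈ 0.24 Å at k = 10, 300 K), coarse enough to keep bins populated.
* Samples outside the bin range are dropped; bins never visited are
  excluded from the PMF support, never interpolated.
* Adjacent windows (by center) must share at least one visited bin;
  otherwise the pooled support is disconnected and `wham()` stops,
  naming the offending pair. The PMF is returned min-zero referenced.

**ABF integration** (`abf_pmf()`). Per-bin mean gradients are
integrated with the cumulative trapezoid rule. The extended-system
(eABF) dynamics and its unbiasing step are *not* emulated: the
synthetic generator produces already-unbiased gradient estimates, which
bounds what agreement between the two estimators can show about real
eABF output.

**Uncertainty** (`half_split_uncertainty()`). The estimator is applied
to the full ordered data and to its two halves (the earlier half gets
⌊n/2⌋ samples — the odd-n convention had to be fixed somewhere), and
the uncertainty is the maximum absolute deviation of either half from
the full-data value.

## Synthetic sampling: what it emulates, and what not

The generators exist so every estimator can be exercised against a
known ground truth at desk scale:

* `sample_biased()` / `sample_windows()` draw from
  $\propto e^{-\beta(U + u_w)}$ by random-walk Metropolis (step size
  auto-tuned to 30–50% acceptance during a 10% burn-in, which is
  discarded). Only the stationary distribution is faithful; dynamics,
  solvent, and multidimensional couplings of real MD are absent, so
  passing tests validate the estimators, not the sampling problem of a
  real complex. An overdamped-Langevin scheme is included for
  qualitative use; its Euler–Maruyama discretization bias is
  documented and it is not used in any test.
* `run_reus()` adds position swaps between adjacent windows every
  `exchange_interval` steps, alternating even/odd lower partners, with
  the Metropolis criterion on the bias-energy difference. Identical
  windows accept every swap; far-separated stiff windows accept none;
  per-window marginals are statistically unchanged by exchanges (all
  three properties are tested).
* `generate_abf_gradient_stream()` adds seeded Gaussian noise to the
  analytic $dU/d\xi$ at bin centers.
* `build_toy_complex()` constructs two-chain structures with an *exact*
  number of inter-chain atom pairs within 5 Å (interface geometry is
  constructed, then verified by an exhaustive distance scan), charges
  summing exactly to a stated integer per chain, and GB/LJ parameters
  in physically sensible ranges. `build_toy_peptide()` provides an
  idealized backbone ring for cyclization-topology tests; it is
  synthetic and never claims realistic geometry.

Every generator is a pure function of (configuration, seed); the
private RNG stream leaves the caller's RNG state untouched.

The double-well ground truth used in the PMF tests spans the
production umbrella grid (16.5–26.0 Å, 0.5 Å spacing,
k = 10 kcal mol⁻¹ Å⁻²) with minima near 19.0 and 23.5 Å and a
2.5 kcal/mol barrier — comparable in scale to the radial PMF of a
peptide separating from its receptor. At 5×10⁴ samples per window the
WHAM reconstruction lands well inside the 0.15 kcal/mol RMS band the
tests require (typically 0.03–0.11 depending on seed); the same grid
sizes run in seconds, which is why they are the suite's defaults.

## MM-GBSA screening

The single-trajectory convention: receptor and ligand geometries are
excised unchanged from each complex frame, so all intramolecular
bonded terms cancel in the Δ and only four terms survive —
inter-chain Coulomb and Lennard-Jones (Lorentz–Berthelot combination,
cutoff-free), the generalized-Born difference, and the
surface-area difference. No conformational entropy term is computed.

The GB flavor is OBC model II: Hawkins–Cramer–Truhlar pairwise
descreening integrals (closed form, cross-checked in the tests against
an independent radial quadrature of the $1/r^4$ kernel) accumulated
into the tanh rescaling with α = 1.0, β = 0.8, γ = 4.85 and a 0.09 Å
radius offset. Neighbor radii are used unscaled (S = 1); no
Debye–Hückel salt screening (κ = 0). Both choices are configuration
knobs in `gb_params()`. SASA is Shrake–Rupley with a deterministic
golden-spiral point set (960 points by default; refinement changes
totals by < 0.5% on the fixtures) and a 1.4 Å probe.

`screen_trajectory()` flags frames as bound until the first frame whose
stop-selection displacement exceeds 25 Å. The displacement is measured
in the receptor frame (each frame is superposed on the first by the
receptor atoms, then the ligand selection's RMSD is taken *without*
self-fitting) — the reading of a "displacement from initial positions"
criterion in which the receptor defines the laboratory frame; both
fitted and unfitted modes are exposed. Means and SEMs are computed over
bound frames only, treating frames as independent (no autocorrelation
correction — a documented limitation; at the 200 ps frame interval of
the screening convention, successive frames of a bound complex are in
fact correlated, so SEMs are optimistic).

## Screening analytics

`correlation_time_vs_energy()` reports the Pearson correlation between
bound time and MM-GBSA energy. The default selector uses the 17
designed candidates and excludes the three template entries (T0–T2);
this subset reproduces the published magnitude 0.59 and the selector is
an argument, not a hard-coded rule. The censored bound time of
peptide 16 (still bound at 2 µs) enters at its recorded value — the
printed table supports nothing more sophisticated than that, so no
survival modeling is attempted. `shortlist()` implements the two
published rules (lowest MM-GBSA energy; longest bound, censored ranking
above uncensored ties). `logo_frequencies()` treats sequences as
linear strings in a fixed register; cyclic-rotation alignment is out of
scope because the candidates share a register by construction.

## Path consistency: the end-to-end check

The deepest test the route can pass at desk scale is stiffness
invariance: assemble all nine stages for a model whose every PMF
derives from one energy surface, and verify the total does not move
when all restraint force constants double. `toy_binding_model()`
defines a separable bound state (a −12 kcal/mol radial well at 17.5 Å,
weak harmonic site potentials on the five angles and one
conformational coordinate, a distinct bulk conformational potential)
with a smooth switch that turns the site potentials off as the ligand
leaves the well — so at the unbound reference r* only the restraints
act, as the route requires. The stage-3 PMF is then computed
analytically *including* the angular/conformational occupancy factors,
and `toy_route_stages()` pushes everything through the same public
functions a real analysis would use. The assembled total moves by
~3×10⁻¹⁰ kcal/mol under doubling (tested against the 0.05 kcal/mol
band), and agrees with a brute-force evaluation of the binding
constant to within ~0.05 kcal/mol — the small residual is the
bound-state definition itself (the direct integral counts quasi-unbound
configurations between the switch and r* that the restrained route
suppresses), and it shrinks with well depth.

## Numerical choices and degenerate inputs

* Energies kcal/mol, distances Å, angles degrees, k_B = 0.0019872
  kcal mol⁻¹ K⁻¹ (the MD-package convention, so printed stage tables
  combine without unit slips); angle integrands convert to radians
  internally where steradian measure matters.
* "10 kcal mol Å⁻²" in printed umbrella specifications is read as
  10 kcal mol⁻¹ Å⁻² (a unit typo).
* `restraint_free_energy()` refuses PMFs whose domain clips the
  restrained integrand (boundary weight above 10⁻⁶ of the integral)
  rather than returning a silently truncated number.
* Trapezoid quadrature on the input grid everywhere; halving the grid
  spacing moves smooth-fixture stage values by < 10⁻⁴ kcal/mol (tested).
* Zero bound frames in screening give a flagged `NA` mean, not an
  exception; a WHAM run hitting its iteration cap reports
  `converged = FALSE` with the residual.
* Harmonic angular restraints are not periodicity-aware: a restraint
  centered near ±180° double-counts nothing only because the default
  force constants confine the integrand well inside one period. Keep
  centers away from the wrap point.

## Known limitations

* The screening MM-GBSA and bound-time values of a real campaign are
  not reproducible here — they require the original microsecond-scale
  explicit-solvent trajectories, which are outside this package's
  scope. The shipped tables are inputs, and the package's claims about
  them are arithmetic (sums, quadrature, correlation), not re-derivation.
* The analytic stage-2 value in the shipped table is likewise taken as
  input: its angular force constants and reference angles are not part
  of the shipped record, though the package's own default (0.1 kcal
  mol⁻¹ deg⁻², sinΘ-weighted) reproduces it to the printed precision.
* Per-species intramolecular nonbonded terms are not evaluated in
  MM-GBSA scores because they cancel exactly in the single-trajectory
  Δ; three-trajectory protocols would need them and are not supported.
* The Metropolis sampler is 1-D; nothing here samples coupled
  multidimensional landscapes.
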