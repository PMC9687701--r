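---
title: "Methods: nanoscale tensile mechanics of mineralized collagen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale tensile mechanics of mineralized collagen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobone)
```

## The system and the question

At the nanometre scale, bone is a composite of type I collagen molecules
(triple helices of two alpha-1 chains and one alpha-2 chain, built from
Gly-X-Y repeats of proline, hydroxyproline and glycine) bound to plate-like
hydroxyapatite crystals, Ca10(PO4)6(OH)2.  How stiff and how strong this
composite is depends on three factors this package is built to study:

* the **orientation angle** theta between the collagen fibril axis and the
  loading direction (0 degrees = longitudinal, 90 = perpendicular),
* **hydration** (tightly bound water at the interface), and
* the **mineral surface** presented to the molecule (calcium- versus
  hydroxide-terminated faces).

A fourth axis is pathological: osteogenesis imperfecta is modelled as the
substitution of glycine by bulkier residues (VAL, ARG, ASP, GLU, CYS),
and mechanical defects as explicit cracks.

The package implements the full chain: atomistic model construction,
a CHARMM-style potential with analytic forces, steered tensile molecular
dynamics with virial-stress extraction, curve reduction to ultimate
tensile strength (UTS), toughness and elastic modulus E, constitutive
polynomial and regression-surface fits, and one-way ANOVA summaries with
connecting-letter reports.  A synthetic-data module generates curve
families and modulus grids with known ground truth so the entire analysis
layer is testable by parameter recovery.

## Model construction

**Hydroxyapatite.**  The unit cell uses the standard hexagonal (P6_3/m)
basis with literature positional parameters: 44 atoms per cell (10 Ca, 6 P,
26 O, 2 H), which is the printed cell content we treat as an invariant.
The stated lattice constants are a = 9.4214 A, c = 6.8814 A, gamma = 120
degrees and b = 2a.  Crystallographically, hexagonal hydroxyapatite has
b = a; a 44-atom cell with b = 2a cannot be reconciled with a 1x2x1
supercell (which would hold 88 atoms).  We therefore take the stated cell
at face value and scale the hexagonal basis onto the b = 2a axis — the
only reading that preserves both the 44 atoms/cell count and the
44*nx*ny*nz slab count (7040 atoms at the canonical 20x2x4 replication).
The price is a structure stretched two-fold along b; none of the
acceptance-bearing quantities depend on the mineral geometry beyond the
counts and the surface termination.

The hydroxyl groups are ordered along the c-axis columns (O above H), so
peeling layers off the +Z face exposes either a calcium level or the O-H
columns.  `selectSurface()` classifies the face by the majority species in
a 0.4 A surface band — thick enough to hold one crystallographic level,
thin enough not to mix the top Ca level with the oxygen level 0.48 A
below — and peels 0.3 A levels until the requested termination appears.
Removed atoms and their net charge are logged; the re-terminated slab is
generally non-stoichiometric, which is physically expected of a polar
termination.

**Collagen.**  Chains are placed on a right-handed triple-helical
scaffold: axial rise 2.86 A per residue, 10.5 residues per superhelical
turn, C-alpha radius 2.6 A, chains phased by 120 degrees.  Residues are
united-heavy-atom templates (no apolar hydrogens; polar hydroxyl hydrogens
kept) whose local geometry approximates canonical bond lengths; models
destined for dynamics are energy-minimised first, so template strain is
not load-bearing.  The single-repeat sequences are the canonical 30-residue
alpha-1 and 29-residue alpha-2 repeats (nine or eight Pro-Hyp-Gly triplets
plus one Glu-Lys-Gly).  The default build cycles these repeats to 342 +
342 + 330 = 1014 residues in total — the total residue count is the one
checkable integer, and we read "three chains and 1014 residues" as a
total, split proportionally to repeat length.  The stated 14.9 nm molecule
length is mutually inconsistent with 1014 residues at any physical rise
(1014/3 residues x 2.86 A is about 97 nm); the builder honours the residue
count, records the computed length and diameter, and offers
`targetLength` to truncate to a length instead.

**Composites.**  The load axis is +X and the mineral surface normal +Z
throughout.  `assembleComposite()` rotates the helix in the XZ plane by
exactly theta and lowers it onto the slab until the minimum helix-slab
atom distance equals the gap (default 3 A, a typical nonbonded contact);
a clash below 1.5 A is refused.  The rotation is rigid, so intra-helix
and intra-slab geometry is bitwise preserved, and the rotated build axis
is recorded so orientation checks are exact rather than estimated.

**Hydration.**  `hydrate()` fills a shell of stated thickness around the
solute with rigid three-site waters at the bulk number density 0.0334
molecules/A^3, by dart-throwing with a 2.4 A exclusion radius against
solute atoms and other water oxygens; the accessible volume is estimated
by Monte-Carlo integration.  Placement is exactly reproducible under the
stated seed (default 42).

## The potential

The energy is the sum of an intramolecular and an intermolecular part,

$$E = E_\mathrm{INTRA} + E_\mathrm{INTER},$$

$$E_\mathrm{INTRA} = \sum k_b (r - r_0)^2 + \sum k_\theta (\theta -
\theta_0)^2 + \sum k_{UB} (r_{13} - r_{UB,0})^2 + \sum k_\phi (1 - \cos
n\phi) + \sum k_\omega (\omega - \omega_0)^2,$$

$$E_\mathrm{INTER} = \sum \frac{q_i q_j}{4\pi\varepsilon_0 r_{ij}} + \sum
\varepsilon_{ij}\left[\left(\tfrac{R_{min,ij}}{r_{ij}}\right)^{12} -
2\left(\tfrac{R_{min,ij}}{r_{ij}}\right)^{6}\right].$$

Design choices, each of which has a documented switch or is tested:

* **Torsion form.**  The torsion term is $k_\phi(1-\cos n\phi)$, matching
  the printed functional form; the conventional CHARMM
  $k_\phi(1+\cos(n\phi - \delta))$ is available via `charmmDihedral = TRUE`
  (delta = 0).
* **Urey-Bradley equilibrium.**  The 1-3 equilibrium distance is a
  separate per-angle constant, not the bond r0.
* **Exclusions.**  1-2 and 1-3 pairs are excluded, 1-4 pairs included at
  full strength; the nonbonded cutoff defaults to 12 A with potential
  shift, and there is no Ewald summation — the systems are finite,
  non-periodic clusters.
* **Units.**  kcal/mol, Angstrom, electron charges; the Coulomb constant
  332.0637 kcal A/(mol e^2) absorbs the vacuum permittivity.
  Lennard-Jones cross terms use arithmetic Rmin and geometric epsilon
  combination.
* **Parameter values.**  Only the functional form is given by the source
  material; the shipped parameter file (`inst/extdata/nanobone.prm`, a
  documented CHARMM-PRM-like dialect with BONDS/ANGLES/DIHEDRALS/
  IMPROPER/NONBONDED sections and X wildcards) is a compact
  package-authored set with CHARMM-like magnitudes: united-heavy-atom
  peptide types, formal-charge mineral types (Ca +2, P +1, phosphate O
  -1, hydroxide O -1.4 / H +0.4, leaving the 44-atom cell neutral) and
  TIP3P-like water.  No acceptance-bearing quantity depends on these
  values; what is tested about the potential is structural: forces are
  the exact negative gradient (finite-difference checks to 1e-5 relative
  on randomized micro-systems covering every term type), energies are
  invariant under rigid motions to 1e-9, terms superpose over
  non-interacting subsystems, and the breakdown identity
  E = E_INTRA + E_INTER holds exactly as summed.

Impropers are generated at trigonal sp2 centres (carbonyl, carboxylate,
guanidinium) with the centre-first CHARMM ordering and a planar target.

## Steered tensile dynamics

Pulling follows the fixed-end picture: one atom selection is frozen, the
other is tethered by stiff harmonic springs (default 10 kcal/mol/A^2) to
per-atom anchors that advance at constant speed along the pull axis.
Integration is velocity Verlet; when a temperature is requested the BAOAB
Langevin splitting is used with friction 1/ps by default.  All
stochasticity (initial Maxwell velocities, thermostat noise, water
placement) is governed by explicit seeds and trajectories are bitwise
reproducible.  The default timestep is 1 fs; 0.5 fs is used where tight
energy conservation matters, since the stiffest modes (O-H at kb = 545
kcal/mol/A^2 on a 1 amu hydrogen) have a ~9 fs period.  Energy divergence
(non-finite or |E| > 1e8 kcal/mol) aborts the run with the offending step.

**Stress.**  The virial stress is the pairwise dyadic sum
$\sigma = -(1/V)\sum_p \mathbf r_p \otimes \mathbf f_p$ (tension
positive), with multi-body terms folded in through the equivalent atomic
form $-(1/V)\sum_i \mathbf F_i \otimes \mathbf r_i$, which is
origin-independent because each term's forces sum to zero.  The kinetic
contribution is off by default.  The reference volume is the instantaneous
bounding-box cross-section times the current length; a fixed molecular
cross-section can be supplied instead.  The absolute stress scale depends
directly on this area convention (the source material never defines one),
so quantitative stress magnitudes are not an acceptance surface; trends,
orderings and the estimator's exact algebra (zero without interactions,
f*r/V for a single stretched bond, correct tensor transformation) are.

**Curves.**  Engineering strain is measured from the axis-projected
separation of the fixed- and pulled-selection centroids relative to the
first frame; stress is the pull-axis normal component of the per-frame
virial tensor, smoothed by a centred moving average (window w averages
offsets (0:(w-1)) - floor((w-1)/2); only positions where the full window
fits are kept, so a window of 1 is the identity and the ends shorten by
w - 1 samples).  Thermal jitter of the centroids can produce tiny strain
reversals; the extracted strain is clamped to be non-decreasing and the
number of clamped points recorded in the curve metadata.

## Mechanics analysis

* **UTS**: the sampled maximum of the curve, earliest strain on ties.
* **Toughness**: trapezoidal area under sigma(eps); with stress per unit
  volume this is an energy density, reported in MPa.
* **Elastic modulus**: OLS slope of stress on strain over a fit region
  defaulting to eps in [0, 0.05] (the linear region is never stated in
  the source; this is the package's choice), converted MPa -> GPa.
* **Constitutive polynomials**: least squares on the raw monomial basis,
  with the published per-condition degrees honoured verbatim (degree 5
  for hydrated 0, 6 for un-hydrated 0, 4 for hydrated 30, and so on).
  The published hydrated 20-degree leading coefficient prints as
  "-8E+0"; it is stored as -8e6, the only magnitude consistent with its
  neighbouring eps^5 term.
* **UTS prediction equation**: the orientation-only cubic is read as a
  centred polynomial — the two knots 40.83332/40.83333 (kept verbatim,
  including their discrepant fifth decimal) equal the mean of the six
  study orientations, which is the standard centred form when exponents
  are lost typographically.
* **Regression surface**: the printed 20-monomial degree-5 surface in
  (theta, eps) is stored term-by-term; `fitRegressionSurface()` refits
  the same basis by least squares and reports SSE, R^2, adjusted R^2 and
  RMSE on n - 20 denominators.
* **UTS search range**: constitutive evaluations default to eps in
  [0, 0.40], where the published curves end; the range is configurable.

**A label swap, and a non-monotonicity, both documented rather than
patched.**  Least squares on the reference modulus grid's Ca columns
reproduces the published "OH mineral surface" E-theta coefficients
(-0.0227 theta + 3.2177 un-hydrated; -0.0226 theta + 2.9231 hydrated) and
the OH columns reproduce the published "Ca" pairs; the package's
comparison tests therefore pair each published line with its numerically
matching column.  Separately, the published constitutive set does not
yield per-orientation stress maxima that decrease monotonically through
all six orientations (over [0, 0.40] the un-hydrated maxima run 83.3,
35.8, 64.5, 40.8, 49.7, 62.4 MPa), and the prediction cubic upturns
between 60 and 90 degrees.  What does hold, and what the package asserts,
is the qualitative ordering: the longitudinal (0 degree) maximum is the
global maximum and exceeds the perpendicular (90 degree) one, the modulus
grid is strictly decreasing in theta in all four condition columns,
un-hydrated moduli exceed hydrated ones cell by cell, and the mineral
surface has no significant effect.

## Statistics

`oneWayAnova()` wraps the standard between/within decomposition (F = 0,
p = 1 when all observations are identical; designs with one observation
per level are refused).  `connectingLetters()` performs pairwise Student
t tests on least-squares means with the pooled ANOVA mean square —
deliberately uncorrected, matching the LSMeans convention — and assigns
letters by the insert-and-absorb algorithm, so two levels share a letter
exactly when their pairwise difference is non-significant.  A Tukey HSD
option is provided and documented as stricter.  SDs are sample SDs
(n - 1); the published hydration summary (2.29 +/- 0.78 and 1.99 +/- 0.74
GPa) is matched by the recomputed grid means within rounding (2.284,
1.998), while the published SDs differ from the sample SDs of the twelve
printed values in the second decimal — the source's SD convention is not
stated, and we do not chase it.

## Synthetic data: what it emulates, and what it does not

The generator produces stress-strain families sigma(eps) = P(eps) +
i.i.d. N(0, sd^2) around the published constitutive polynomials, and
modulus grids E(theta) = slope*theta + intercept + N(0, sd^2) around the
published linear laws.  Noise is homoscedastic Gaussian by design — the
source says nothing about residual structure — and in particular the
generator makes no attempt to emulate the time-correlated noise of real
molecular-dynamics stress traces.  Passing recovery tests therefore shows
that the analysis layer is correct and well-calibrated for independent
noise, not that it is robust to correlated MD noise.

Two calibration choices:

* **Curve noise** defaults to the level implied by each condition's
  published R^2: for a correctly specified fit,
  R^2 ~= var(signal)/(var(signal) + sd^2), so
  sd = sd(signal) * sqrt((1-R^2)/R^2) — about 3.6 MPa for the un-hydrated
  0-degree condition (signal SD 23.2 MPa over [0, 0.40], published R^2
  0.9771).  Refitting then brackets the published R^2 by construction,
  which is exactly what the recovery tests check.
* **Grid noise** defaults to 0.15 GPa, the scale of the reference grid's
  scatter about its fitted lines; slope recovery within +/-20% succeeds
  in >= 90% of seeds at this level.

The toy composite (one-repeat helix over a 2x1x1 slab, about 700 atoms)
is the standard dynamics fixture; it is a valid composite by every
builder invariant but is far smaller than the canonical 1014-residue,
7040-atom system.

## Problem sizes and numerical tolerances used by the test suite

The suite runs on one CPU in a few minutes.  Sizes were chosen as the
smallest that exercise each property meaningfully: finite-difference
force checks on 50 randomized 6-atom micro-systems (h = 1e-5 A, 1e-5
relative); NVE conservation over 10^4 steps of the ~700-atom toy
composite at dt = 0.5 fs (drift < 1e-4 relative; dt^2 scaling verified on
a 130-atom helix fragment at two timesteps); Langevin setpoint within 15%
at dt = 0.5 fs; quasi-static dimer pulling against Hooke's law within 2%;
recovery experiments with 50-200 seeds and n = 500 curve samples.
Least-squares fits are compared against an explicit normal-equations
oracle at 1e-9 — on fitted values for degree-6 designs, whose Vandermonde
conditioning limits the oracle itself below coefficient-level 1e-9.

## Known limitations

* The forcefield parameter values are package-authored stand-ins with
  realistic magnitudes, not a validated biomolecular forcefield; absolute
  energies and stress magnitudes should not be compared against
  experiment.
* No periodic boundary conditions, no Ewald electrostatics, no CMAP, no
  polarizability; pulling is stiff-spring steered MD only (no NPT, no
  affine deformation).
* The collagen scaffold is idealised (no D-periodic packing, no
  crystallographic refinement); built diameters come out near 1.6-1.9 nm
  depending on side-chain content, slightly above the nominal 1.5 nm.
* The published raw-simulation stress maxima (125.12 / 60.03 MPa) are not
  reproducible from any printed equation and are not targets; likewise
  Figure-only curves are not digitised.

```{r example, eval = FALSE}
# a complete miniature run of the pipeline
model <- generateToyComposite()
sys <- buildSystem(model, defaultForceField())
sel <- which(sys$atoms$chain %in% c("A", "B", "C"))
xs <- sys$pos[sel, 1]
prot <- tensileProtocol(fixedSelection = sel[xs <= quantile(xs, 0.1)],
                        pulledSelection = sel[xs >= quantile(xs, 0.9)],
                        pullSpeed = 8, temperature = 100, friction = 5,
                        nSteps = 1200, saveInterval = 20, seed = 1)
traj <- runTensile(sys, protocol = prot)
curve <- extractStressStrain(traj, window = 21)
ultimateTensileStrength(curve)
elasticModulus(curve, fitRegion = c(0, 0.05))
```
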