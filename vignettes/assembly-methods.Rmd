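---
title: "Multi-component rigid-body assembly into cryo-EM maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-component rigid-body assembly into cryo-EM maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emassemble)
```

## The problem

Given a low-resolution (20--45 Å) cryo-EM density map of a macromolecular
machine and atomic (or coarse-grained) models of its subunits, the task is
to place all subunits into the map *simultaneously*: positions and
orientations of every component, respecting the point-group symmetry of the
complex and avoiding inter-subunit clashes. At these resolutions the map
carries no side-chain or secondary-structure detail, so single-subunit
fitting is ambiguous and the problem is combinatorial.

`emassemble` treats this as staged stochastic optimization, in the
sampling-then-scoring tradition of protein--protein docking: a smooth,
permissive fitting energy drives millions (desk-scale: thousands) of random
starting arrangements into the map; a sharper contour-based score then
ranks the minimized candidates; partial solutions are recombined; and a
final force-field refinement tightens the interfaces.

## The Gaussian overlap fitting energy

Every coarse-grained bead and every map voxel is modelled as an isotropic
3D Gaussian. All Gaussians share the standard deviation

$$\sigma = \frac{\text{resolution}/2}{\sqrt{3}},$$

i.e. half the nominal map resolution distributed over the three Cartesian
axes (the per-axis divisor is configurable in
`sigma_from_resolution()`). The overlap of two Gaussians is itself a
Gaussian of their center distance $D$:

$$O(D) = A_1 A_2 \left(\frac{\pi}{s_1+s_2}\right)^{3/2}
 \exp\!\left(-\frac{s_1 s_2}{s_1+s_2} D^2\right),
 \qquad s_i = \frac{1}{2\sigma_i^2},$$

verified in the tests against brute-force numerical integration of the
product of two Gaussians. The overlap of a bead with the whole map is the
sum of its pair overlaps with every voxel Gaussian, with voxel amplitudes
proportional to the (deconvolved) density values. Because distant voxels
contribute non-negligibly, the summation is never truncated; it is
precomputed once per map (`precompute_overlap_grid()`) as an exact
separable Gaussian convolution, together with its analytic gradient field.

During fitting, a bead's overlap is interpolated from the eight
surrounding stored voxels (`interpolate_overlap()`). The interpolant is
the mean of the plain trilinear combination of the corner values and the
trilinear combination of the corners' first-order expansions
$O_c + g_c\cdot(r - r_c)$; this uses exactly the stored values and
gradients, is exact for quadratic fields, reduces to plain trilinear
weighting wherever the gradient is constant, and keeps the relative
interpolation error below $10^{-3}$ at the ratio-4 voxel sizes used (the
overlap grid is stored on a subdivided lattice for this -- fourfold by
default, twofold inside the protocol stages where speed matters more
than tail accuracy). The minimization force on a bead is the *exact*
derivative of this interpolant, so analytic forces and central finite
differences of the energy agree to $10^{-4}$ -- the test suite's master
check for every energy term. The precomputed analytic gradient field is
also carried along: it is the attraction direction for beads that leave
the grid (clamped-boundary interpolation, falling back to the direction
of the map's overlap centroid where boundary deconvolution ringing
leaves the clamped gradient pointing outward), and it is validated
against finite differences of the overlap field.

### Calibration: maximum overlap and the spillover factor F

A bead inside a folded structure receives "spillover" overlap from its
neighbours, especially in the core. Each component is therefore calibrated
against itself (`calibrate_max_overlap()`): its own map is simulated at
the working resolution, deconvolved, and each bead's achieved overlap at
its native position is recorded as that bead's *maximum overlap*. In a
multi-component complex, additional intermolecular spillover arrives from
adjacent subunits; this is modelled by a single factor $F \ge 1$ that
scales the intramolecular maxima. The fitting energy penalizes two
deficiencies per bead harmonically,

$$E = \sum_b k_\mathrm{hard}\,\max(0,\,O_b^{\max}-O_b)^2
 + k_\mathrm{soft}\,\max(0,\,F\,O_b^{\max}-O_b)^2,$$

with $k_\mathrm{hard} : k_\mathrm{soft} = 100 : 1$ by default (the hard
term enforces 100% of the intramolecular maximum, the soft term the
spillover-scaled target). Reference values of $F$ for the
chaperonin system are 5.1 (cis ring, 40 Å), 1.7 (20 Å), 7.0 (full
complex, 40 Å) and 9.8 (44.8 Å experimental); all are accepted through
`emfit_config()`. For new systems, `calibrate_spillover()` automates the
reference-inspection procedure: it takes a low quantile of the per-bead
ratio of achieved to maximum overlap on the reference structure -- the
largest uniform scaling the reference still satisfies before the violation
energy rises.

The penalties are divided by the mean squared maximum overlap by default
(`normalize = TRUE`). This is pure unit conditioning -- minima and
rankings are unchanged -- but it keeps the energy of a fully deficient
bead at order $k_\mathrm{hard}$ regardless of bead weights, which the
quasi-Newton line search needs to take sensible first steps.

### Voxel atom density and the clash term

The trilinear weights already "divide" each bead among its eight
neighbouring voxels, so accumulating them
(`accumulate_voxel_density()`) measures how much atom weight occupies
each voxel. Voxels above a cap contribute $k\,(\rho-\mathrm{cap})^2$ and
push their contributing beads down the interpolated excess-density
gradient (`density_clash_energy()`). Reference caps are 18 (assembly,
40 Å), 16 (refinement), 4 (20 Å), 19 (44.8 Å) and 4.4 (23.5 Å) in
units of atoms per voxel, consistent with an average interior packing
density of about 14 for folded proteins; the synthetic benchmark
calibrates its caps from its own reference complex, which is the same
procedure used to derive those reference values.

## Gradient vector matching (GVM)

The overlap energy judges only density *values*; it is deliberately
permissive so that minimization can slide components around inside dense
regions. Contours -- where density changes sharply -- carry the
orientation information, and GVM scores them directly. For each grid the
3D Prewitt gradient is computed: the $x$ component at a voxel is the sum
over its 3×3 $(y,z)$ neighbourhood of the difference between the $x{+}1$
and $x{-}1$ planes (18 per unit step on a linear ramp of unit slope, the
tests' closed form). The experimental field $V_\mathrm{exp}$ comes from
the scoring-resolution map rescaled to the model's total weight (so map
and atom-density units are commensurate); the model field
$V_\mathrm{model}$ comes from the assembly's voxel atom density grid and
is multiplied by a systematic scale (default 1.35;
`calibrate_model_scale()` re-estimates it per system by least squares
over significant voxels). The energy sums, over voxels where
$|V_\mathrm{exp}|$ exceeds a significance threshold (default 2), the
squared per-component deviation beyond a tolerance (default 2; 20 is the
reference choice for large full-complex runs where gradients are larger
and more numerous):

$$E_\mathrm{GVM} = \sum_{v:\,|V_\mathrm{exp}|\ge\tau}\sum_{d\in\{x,y,z\}}
 \max(0,\,|V_{\mathrm{exp},d}-V_{\mathrm{model},d}| - \mathrm{tol})^2.$$

Significance is judged on the Euclidean norm by default (a per-component
alternative is exposed), the penalty constant is 1 (rankings are invariant
to it), and boundary voxels, where the Prewitt stencil is undefined, are
excluded. GVM is a *score*, never a force term: it ranks pools
(`rank_by_gvm()`), it is not minimized.

## Restraints

**Symmetry.** $C_X$ symmetry is enforced purely through harmonic
distance-equality restraints between backbone beads
(`build_cx_restraints()`), with no symmetry axis ever defined -- the
energy is invariant under global rigid transforms. Backbone beads are
arranged into pairs (bead $i$ with bead $p-i+1$); for each pair, equality
set $S_k$ holds the $X$ cyclically shifted distances
$d(A_n, B_{n+k})$, $n = 1..X$ with monomer indices modulo $X$. The
allowed shifts are $1 \le k \le \lfloor X/2\rfloor$: the inclusive upper
bound reproduces the reference three equalities $S_1,S_2,S_3$ for $X=7$
while still giving $C_2$ (used for dimers) one equality. Each distance is
restrained to its set mean with force $F = -c\,D$ on the deviation $D$,
$c = 0.005$ kcal/mol/Å; the logged energy is the integrated form
$\tfrac{1}{2}cD^2$, consistent with that force (the constant factor does
not affect rankings or minima). $D_4$ restraints implement the three
listed 2-member equalities per pair. Because the restraint count grows
linearly with the backbone bead count, sparse coarse models carry far
fewer restraints than a real protein chain; the stage configurations
accept a symmetry weight to restore protein-like ring stiffness (the
synthetic benchmark sets it to the ratio of a ~500-residue chain to its
own bead count).

**Location.** Component centers of mass can be restrained to approximate
known positions with $E = \tfrac{1}{2}k|d|^2$, $k = 0.5$ kcal/mol/Å,
forces distributed weight-proportionally over beads. Drawing each offset
coordinate uniformly from $(-5, 5)$ Å reproduces the reference mean
displacement of 4.8 Å.

**Gravity.** A weak harmonic center-of-mass attraction
(0.001 kcal/mol/Å²) between all component pairs, plus a strong harmonic
repulsion (1.0 kcal/mol/Å²) inside 0.8 times the summed radii of
gyration, keeps pre-assembly structures compact without biasing any
particular arrangement. The functional forms and constants are this
package's choices (configurable); only the qualitative design -- weak
long-range attraction, strong short-range repulsion -- is prescribed.

## The intermolecular force field

Refinement needs short-range packing forces. The bundled potential is a
soft 8-6 pair interaction per bead-kind pair,
$U(r) = \varepsilon\,[3(r_m/r)^8 - 4(r_m/r)^6]$ with $r_m$ the summed
bead radii, smooth switching between 12 and 15 Å, optional screened
Coulomb, and analytic forces. It is a deliberately generic stand-in: the
staged protocol requires the *presence* of short-range packing forces
during refinement, not any particular parameterization, and the parameter
table is loadable from a text file for users who want their own.

## Rigid-body minimization

`minimize()` runs BFGS with Armijo backtracking over 6 degrees of freedom
per unfrozen component: a translation plus an incremental axis-angle
rotation about the component's center of mass. Rotation gradients are
exact (via the left Jacobian of SO(3), so the axis-angle parameterization
has no small-angle approximation), rotation coordinates are scaled by the
component's radius of gyration to balance them against translations, and
final rotations are re-projected onto SO(3) (drift below $10^{-9}$).
Accepted-step energies are monotone non-increasing by construction and
recorded per term in the result's trace. A non-finite energy aborts with
a diagnostic naming the offending term. `orientation_only_minimize()`
freezes all translations -- the mode used to impose symmetry on
pre-positioned ring starts. Defaults: `max_iter` 500 and `tol` $10^{-6}$
(stage plans use smaller budgets, see below).

## The staged protocol

`run_protocol()` chains the stages:

1. **Starting structures** -- uniform random poses in a box
   (`random_starts()`), or ring-topology starts
   (`ring_topology_starts()`): per ring, a shared axial offset
   $Z \pm 5$ Å, a radius drawn uniformly from $35 \pm 15$ Å, a random
   phase, even spacing in the $xy$ plane and random orientations (the
   standard prescription for the three-ring chaperonin system, whose reference
   rings sit at $Z = -64.4/0.0/71.4$ Å with radii 26.6/46.0/46.8 Å).
2. **Pre-assembly** -- symmetry energy minimized with all density and
   atomic terms off; orientation-only when positions are already
   symmetric. The pool is sorted by symmetry energy and truncated.
3. **Assembly** -- overlap fitting into the *coarse* (typically 40 Å)
   map + clash + symmetry + gravity; the coarse Gaussians are long-range
   and smooth enough to pull components in from far away.
4. **Scoring** -- truncation by assembly energy, then GVM ranking against
   the *fine* map (20 Å simulated / 23.5 Å experimental in the reference
   system).
5. **Recombination** (optional, 1--2 rounds) -- for every ordered pair of
   the top parents and every swap pattern, a child takes the pattern
   blocks (e.g. one ring) from the second parent; 100 parents with two
   patterns yield exactly $100 \cdot 99 \cdot 2 = 19\,800$ children,
   which are pooled with the parents and re-ranked by GVM.
6. **Refinement** -- four sub-stage minimizations against the fine map:
   (a) fine-map term on, force field off; (b) force field at weight 0.01;
   (c) force field full, overlap terms scaled by 50 to prevent
   disintegration; (d) both at weight 1. Final GVM re-ranking.
7. **Post-refinement recombination** (when recombination is configured) --
   refined structures carry fully settled ring blocks, so one more
   recombination round over the refined pool, GVM ranking, and a brief
   re-refinement assembles complementary correct blocks that ended up in
   different parents. This mirrors the repeated
   recombination-and-rescoring applied to the experimental system, and at
   desk scale it is the step that routinely turns a pool of
   two-rings-correct candidates into a fully correct top model.

Pool sizes are configured by `stage_plan()`: the `"full"` preset keeps
the reference full scale ($10^6$ starts, $5\times10^5$ after pre-assembly,
$10^5$ scored, $10^3$ refined); the default `"desk"` preset
(2000 starts / 1000 pre-assembled / 200 scored / 32 refined, 60
recombination parents) runs the full pipeline on one CPU in about ten
minutes and is what the tests and the acceptance script use. The refined
count of 32 matches the number the reference cis-ring analysis selected
at its GVM energy gap; a narrower refinement bottleneck can collapse the
ring-block diversity that the final recombination round needs.
The reference cis-ring analysis also selected refinement candidates at a
conspicuous gap in sorted GVM energy; `select_by_energy_gap()` generalizes
this (cut at the largest relative gap, fixed-count fallback). Every stage
derives per-structure random streams deterministically from the master
seed and the structure index, so runs are exactly reproducible and
independent of execution order.

## The synthetic benchmark

`make_toy_assembly()` builds rings of identical rigid subunits with known
ground truth; `make_benchmark_case()` adds simulated maps (ratio-4
voxels), per-ring symmetry restraints, and calibrations performed on the
reference exactly as they would be on a real reference structure
(density caps, spillover factor, GVM model scale). Design choices:

* **Geometry**: an axial stack of three well-separated $C_7$ rings at
  $Z = -64.4/0.0/71.4$ Å with radii 40/46.0/46.8 Å -- one smaller and
  two large rings, so that swapped ring blocks misfit the map (the
  negative control).
* **Subunits** are curved rods of 20--24 beads (half-length 15--17 Å,
  tangential bend, small Gaussian jitter) with a monotone mass gradient
  along the rod and a radial/axial tilt in the reference pose.
  Unstructured Gaussian bead clouds often have nearly degenerate
  orientation landscapes at 20 Å, and subunits much shorter than the
  intra-ring spacing blend into a featureless torus whose subunit
  orientation no density score can recover; the rod shape with
  distinguishable ends, sized close to the ring spacing, keeps
  orientation identifiable -- which the fixture's purpose (testing
  orientation recovery) requires.
* **Bead weights** (5--10 per bead) are sized so the assembled voxel atom
  density lands in the standard protein-interior packing range (~14--18
  per 10 Å voxel). This puts the fixed GVM significance threshold and
  tolerance (2 units each) in the same regime they were calibrated for.
* **What the toy does not emulate:** real side-chain detail, conformational
  flexibility, micrograph noise (only optional voxel-wise Gaussian noise),
  non-ideal symmetry, and map artifacts. Passing the synthetic benchmark
  demonstrates the machinery -- energies, gradients, ranking, staging,
  recombination -- not performance on experimental maps.

Homo-oligomeric rings make a model rotated by $2\pi/X$ physically
identical to the reference while per-index RMSD is large;
`assembly_rmsd()` therefore accepts a list of equivalent relabelings
(all per-ring cyclic shifts, `ring_equivalences()`) and reports the
minimum. `ligand_rmsd()` measures relative placement: the receptor
component is superposed onto its reference copy and the unfitted RMSD of
the ligand component is averaged over all equivalent pairs.

## Numerical choices and degenerate inputs

* Deconvolution of maps into voxel-Gaussian amplitudes uses a Wiener
  filter with a small regularizer ($10^{-8}$) on a zero-padded copy;
  Richardson--Lucy is available. Noisy experimental maps may skip
  deconvolution entirely (`deconvolve = FALSE` in `emfit_config()`), the
  treatment used for the experimental chaperonin map.
* Downsampling joins (sums) voxels rather than averaging, so the density
  sum -- which experimental maps are rescaled against -- is conserved
  exactly; low-pass filtering conserves it up to reported edge losses.
* Resolution-to-voxel ratios other than 4 trigger a warning, not an
  error: assembly and especially GVM are tuned for that ratio.
* Superposition uses the closed-form Kabsch solution via SVD with the
  reflection resolved to $\det = +1$; collinear point sets are rejected.
* Trilinear derivatives are discontinuous across voxel faces; the
  finite-difference tests nudge probe beads off cell faces, and the
  minimizer is unaffected (it never needs second derivatives).
* Out-of-grid beads: zero overlap (hence maximal deficiency) and a pull
  along the clamped boundary gradient back into the map; they deposit no
  voxel atom density and are counted.
* Exact-duplicate children in recombination are removed by bit-identical
  pose comparison; no clustering is performed.

## Problem sizes used in tests and the acceptance script

The bundled verification uses the desk preset: a 21-component, 476-bead
toy complex, 40 Å/20 Å simulated maps, 2000 starts, 200 scored
structures, 60 recombination parents and 32 refined structures; module
tests use single rings and smaller grids. These sizes
were chosen so the full pipeline exercises every stage at interactive
cost; the `"full"` preset preserves the reference pool sizes for
full-scale reproduction.

## Known limitations

* Rigid bodies only: no flexibility, normal modes or conformational
  copies.
* A single global $F$ models intermolecular spillover; per-bead overrides
  are exposed for knowledge-driven refinement, but no automatic per-region
  estimation is provided.
* GVM is scoring-only; it is not integrated into the minimization.
* Orientation of subunits that are small relative to their ring spacing
  (e.g. a compact cap ring whose density blends into a torus) is
  genuinely underdetermined at 20 Å: the overlap energy is flat across
  such orientations and even contour scoring discriminates only weakly.
  The bundled benchmark therefore uses rings whose subunits stay
  resolvable; on real systems with such components, location restraints
  or external information play that role.
* Maps must have isotropic voxels and axis-aligned order; no CTF
  modelling, map symmetrization or FSC estimation.
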