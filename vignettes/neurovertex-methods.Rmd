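---
title: "Model and methods behind neurovertex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind neurovertex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurovertex)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and their defaults,
the numerical choices, what the synthetic machinery does and does not
emulate, and the known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The tissue model

The apical surface of a pseudostratified neuroepithelium (the lumen-facing
plane of the embryonic neural tube) is represented as a polygonal tiling of
an unwrapped torus: a flat rectangle with periodic wrap in both axes, `x`
being the dorsoventral (DV) and `y` the anterioposterior (AP) coordinate.
Periodicity avoids boundary artefacts for a tissue patch that is far from
the rostral/caudal limits; the torus radii `R = L_DV/2π` and `H = L_AP/2π`
grow over time. Every vertex is trivalent, so the Euler relation on the
torus fixes the mean polygon side count at exactly 6 — the test suite uses
this as a structural identity, not a statistical observation.

Vertex dynamics are overdamped gradient descent on the standard epithelial
energy with area elasticity, junctional line tension and perimeter
contractility (`energy()`, `vertex_forces()`), with all cells and edges
sharing uniform `K`, `Λ`, `Γ`. The pair `(Λ̄, Γ̄) = (Λ/(K A⁰^{3/2}),
Γ/(K A⁰))` locates a parameter set on the hexagonal-ground-state phase
diagram; `classify_phase_region()` implements the standard analysis
(perimeter-degenerate "soft" region, stable hexagonal solid at zero or
negative tension, tense solid at positive tension, collapsed regime where
the single-cell energy is minimised at zero size). The six built-in presets
all fall in the epithelial (solid) regions. Because the exact transition
curves are a matter of convention near the boundaries, the classification is
validated in tests only through the presets and limiting cases.

### Interkinetic nuclear movement

During the cell cycle the nucleus translocates apicobasally: basal descent
through G1, S phase basal, apical ascent through G2, mitosis apical. The
model encodes this through the target area
`A⁰(t) = (1 + g t̃) · f(ρ(t̃))`, where `t̃` is the cell's age, `g` its
growth rate (drawn per cell from a normal with mean `1/t_T` and s.d. 20% of
the mean, redrawn if non-positive), and `ρ(t̃)` the piece-wise linear
apicobasal position. The interpolant `f` must satisfy `f(0) = 1/2`,
`f(1) = 1` and rise faster near the apical surface; the package default is
`f(ρ) = (1 + ρ²)/2`, the simplest convex choice with those endpoints. It is
an explicit assumption, isolated behind the `interp` argument of
`simulation_config()` so alternatives such as `(1 + ρ³)/2` can be swapped
in without touching the engine.

Phase durations default to 55% G1, 40% S+G2 (split 1:2 between S and G2)
and 5% M of a 13 h cycle. Division requires both M phase and apical area
above a critical `A_c`; cells that reach the end of M below `A_c` wait
apically, still growing, until the area condition is met. Daughters restart
the cycle with fresh growth rates and inherit clone and domain labels.

### The division threshold `A_c`

`A_c` deserves its own paragraph because it couples the cycle to the
mechanics. In the epithelial presets the contractility and tension terms
shift the mechanical ground state of a cell noticeably *below* its target
area (for preset V, a hexagonal cell with target `A⁰` equilibrates near
`A⁰ − 0.45`). An M-phase cell with target ≈ 2 therefore realises an apical
area around 1.5–1.6. The package sets `A_c = 1.5` so that the area gate
triggers near the natural end of M under this compression; this implements
the model's stated calibration of the proliferation rate to 0.05 per hour
(equivalently a 13 h effective cycle, `λ = ln 2/t_T`), which the test suite
measures directly from division events. A larger `A_c` (e.g. 1.8) makes
cells wait well past `t_T`, stretching the effective cycle to ~17 h.

### Differentiation and extrusion

Neuronal differentiation removes cells from the apical plane. Each eligible
cell commits with a first-order hazard (rate × dt, with a warning when the
step is too coarse for that approximation); a committed cell's target area
is set to zero, it shrinks, its junctions shorten below the T1 threshold,
and T1 transitions whittle it down until a two-sided cell remains, which is
removed. In two-domain simulations a band covering 30% of the DV length is
labelled pMN after equilibration and differentiates at 0.1 per hour;
membership is a lineage label inherited by daughters, not re-evaluated
positionally, because the band is the initial condition of a cell
population, not a spatial forcing.

### Topological rules

A junction shorter than 3% of the tissue-mean junction length (strict
less-than) is eliminated; the new perpendicular junction has length
`l_new`, by default twice the elimination length so it cannot immediately
re-collapse. Sensitivity runs over `l_new` from one to fifteen times the
elimination length, and over thresholds up to 15%, left the measured T1
frequency essentially unchanged, so the default matters for robustness, not
for the reported rates. Short edges are processed one per junction per
step, ascending by length; if a transition triggers an extrusion the
remaining candidates are deferred to the next step (vertex renumbering
would otherwise invalidate them — a determinism-preserving simplification).
Division cleaves through the midpoint of an edge chosen with probability
proportional to its length and the midpoint of the opposite edge (for odd
side counts, the nearer mid-opposite candidate, ties to the lower index).

Removal of a two-sided cell deletes its two vertices and both parallel
junctions and re-stitches the two neighbours along a single junction,
subtracting `(2, 1, 3)` from `(N_v, N_c, E)`; each neighbour necessarily
loses two sides (the deletion of three junctions removes six cell-sides,
two of which belonged to the removed cell). Four-sided neighbours cascade.

### Global growth and anisotropic drag

Tissue-scale expansion is driven by the same energy: the generalised forces
`F_R = −∂E/∂R`, `F_H = −∂E/∂H` of uniform dilations are balanced by
per-cell drags, `dR/dt = F_R/(2 μ′ N_c)` and `dH/dt = F_H/(2 μ″ N_c)`, and
vertex positions are rescaled affinely after each radius update (operator
splitting within one Euler step). The exact geometric prefactor of the drag
law is a modelling convention; it is isolated in `step_scales()` and the
dilation-gradient accumulation of the kernel, and validated against the
observable it controls (the final tissue aspect ratio under
`μ′ = 0.02, μ″ = 1`). In the rapid-growth limit the AP/DV ratio tends to
`√(μ′/μ″)` and in the slow-growth limit to 1; simulated ratios must stay in
that interval, which the property tests assert.

## Simulation protocol

A run builds a brick-wall hexagonal tiling (`build_hexagonal_tissue()`;
per-row offsets are chosen so any grid, odd or even, closes periodically
without defects), assigns uniformly distributed initial cell ages — the
natural desynchronised state; synchronous ages would inject artificial
division waves that 30 h of equilibration only partly removes — and
equilibrates for 30 h of biological time under *symmetric* drag (both axes
at `μ′`). Equilibration exists to produce a disordered, isotropic steady
state; the anisotropic drag represents the embryonic constraints acting
during the tracked developmental window, so it is switched on when the
clock is reset, founders are labelled, and the pMN band (if any) is
designated. The tracked phase then runs (default 48 h) with divisions,
differentiation, T1s and global growth, logging every event with its
angles.

## Numerical choices

* **Time step.** One nondimensional time unit is 460 s; the vertex
  relaxation time at the default mechanics is of order one unit. Production
  protocols use `dt = 0.02` (≈ 5 × 10³ steps per 13 h cycle), well inside
  stability; `mechanical_params()` defaults to the much finer
  `dt = 1.017e-3` (10⁵ steps per cycle) for users who want the conservative
  discretisation. The test suite checks that halving `dt` leaves cell
  counts, mean areas and aspect ratios statistically unchanged, and the
  measured T1 frequency is insensitive between `dt = 0.02` and `0.005`.
* **Problem sizes.** Protocol runs start from 10×10 cells (15×15 for
  two-domain and uniform-differentiation runs, whose populations shrink),
  equilibrate 30 h and track 48 h, with 1–3 replicates per quantity. These
  sizes keep a full reproduction within minutes on one core while leaving
  hundreds-to-thousands of cells at measurement time.
* **Degenerate inputs.** Zero-length edges abort the force kernel (the
  topology layer must remove them first); loops with non-positive signed
  area raise errors; displacement per step beyond a quarter box aborts with
  a step-size diagnostic; a torus radius driven non-positive aborts.
* **Determinism.** A single seed drives construction, growth-rate
  sampling, differentiation, division edge choice and T1 processing order;
  identical seeds reproduce identical event logs bit-for-bit.

## The synthetic geometry fixture

`synthetic_geometry_fixture()` generates segmentation-style tables
(gamma-distributed areas, perimeter tied to area through the hexagon
isoperimetric ratio with mild lognormal scatter, integer neighbour counts
symmetric about six, elongations ≥ 1) so the screening machinery
(`ks_statistic()`, `geometry_similarity_score()`, `screen_parameters()`)
can be exercised without image data. It reproduces marginal moments, not
the spatial correlations, Lewis-law structure or domain differences of real
segmented tissue: a screen that ranks parameter sets against the fixture
demonstrates the machinery, not biological calibration. Units are carried
explicitly (µm² for the fixture, nondimensional for simulations); score
functions refuse to mix them unless the 23 µm² area scale is supplied.

## Known limitations

* The apicobasal dimension is collapsed into the target-area factor; there
  are no explicit 3D nuclear trajectories, no cell-cycle checkpoints, and
  no apoptosis.
* Vertices are strictly trivalent; rosettes are not represented.
* Tissues with sustained net cell loss (uniform differentiation faster
  than proliferation) eventually collapse into a thin tube whose DV
  circumference is one or two cell diameters. There the minimum-image mesh
  representation leaves its validity domain — cells approach half the box,
  the same bound that rules out two-row initial grids — and topological
  churn explodes. The engine stops a run once either box length falls
  below three mean cell diameters (or fewer than four cells remain), and
  rate measurements on collapsing tissues stop in the last hour during
  which both box lengths exceed four mean cell diameters; growing tissues
  never reach either guard.
* The measured T1 frequency of the default parameterisation sits well
  below the per-cell rates reported for the tissue this model family was
  built to describe, while its dependence on differentiation (higher
  turnover, more rearrangement) has the right direction and roughly the
  right ratio; sensitivity analyses over the threshold, `l_new` and `dt`
  did not close the gap, pointing at an unresolved convention (what counts
  as one T1 event) or an unprinted parameter rather than at the integration.
  Quantities that hinge on the absolute T1 rate — most visibly the clone
  AP/DV spread ratio, which needs strong intercalation to reach ~0.3 —
  inherit this bias, and the mean target area is depressed a few percent by
  the shorter effective M-phase wait; both are reported as measured.
* Late in very large runs the drag-induced area lag grows with the tissue
  radius squared, slowly depressing the division rate below its early-window
  calibration; measurements tied to a stated window (the 10 h
  proliferation-rate window) are taken where the calibration is defined.
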