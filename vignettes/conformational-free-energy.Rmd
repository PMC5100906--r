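---
title: "Collective variables and free-energy methods for helix-packing dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective variables and free-energy methods for helix-packing dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metawham)
```

## Scope and model

Nuclear-receptor ligand binding domains (LBDs) switch between an
*agonistic* conformation, with helix 12 packed against the domain core to
complete the coactivator groove, and an *antagonistic* conformation with
helix 12 displaced antiparallel to helix 11. For the progesterone-receptor
LBD the two end states are known from crystallography, but the apo-form
ensemble between them is not. `metawham` implements the quantitative
machinery used to study that ensemble:

* **geometric collective variables (CVs)** on structures and trajectory
  frames — a difference RMSD to the two end states, smooth contact numbers
  between helix pairs, an alpha-helix secondary-structure CV, helix
  crossing angles, side-chain function-group distances with close-contact
  and pi-cation criteria;
* **two free-energy engines over any scalar CV** — umbrella sampling with
  weighted-histogram (WHAM) unbiasing and bootstrap errors, and
  well-tempered metadynamics with tempered hill deposition, square-well
  wall biases, hill-sum free-energy-surface (FES) reconstruction and a
  basin-difference convergence diagnostic;
* **trajectory statistics** — RMSD/RMSF series, histogram potentials of
  mean force (PMF), block-averaged dynamic cross-correlation networks,
  GROMOS conformational clustering and dihedral PCA;
* a **toy sampling layer** (overdamped Langevin dynamics and exact
  Boltzmann samplers on analytic potentials) plus **seeded synthetic
  generators**, so every method is exercised against known answers at desk
  scale.

All-atom molecular dynamics itself is out of scope: the package analyses
structures, frames and CV time series, and verifies its estimators on
analytic truth rather than on solvated production runs.

Internal units are nm, kJ/mol, ps and K, with
`kB = 0.0083144621` kJ mol^-1 K^-1 and a default temperature of 300 K.
PDB files (Angstrom) are converted only at the I/O boundary, and author
residue numbering is used verbatim throughout (e.g. backbone 683–902 as
the stable core, C-alpha 903–932 as the mobile helix-loop-helix segment).

## The collective variables

**Difference RMSD.** A frame is superposed on each reference end state
using the core backbone, and the RMSD of the mobile segment is evaluated;
the coordinate is

$$\Delta\mathrm{RMSD} = \mathrm{RMSD}_{\mathrm{agonistic}} -
\mathrm{RMSD}_{\mathrm{antagonistic}},$$

so negative values mean agonist-like. The printed definition of the two
RMSD terms in the source protocol is internally inconsistent with every
reported landmark (the agonist-like minimum sits at −1.3 nm); this package
adopts the landmark-consistent sign above, and `delta_rmsd()` is exactly
antisymmetric under swapping the references.

**Contact numbers.** Pairwise C-alpha contacts are counted smoothly with
the rational switching function

$$f(r) = \frac{1 - (r/r_0)^8}{1 - (r/r_0)^{12}}, \qquad r_0 = 0.85\
\mathrm{nm},$$

summed over all inter-group pairs (NC1: helix 12 residues 908–922 vs
helix 3 residues 713–734; NC2: helix 12 vs helix 11 residues 882–898; the
helix 11 range is used exactly as specified even though it brushes the
895–908 loop). The singularity at `r = r0` is removable: `switching_fn()`
returns the analytic limit `n/m = 2/3` there and uses a first-order series
within `|r/r0 − 1| < 1e-6`, so the CV is continuous and differentiable
everywhere.

**Alpha-helix RMSD.** For every contiguous six-residue window the
backbone (N, CA, C, O) RMSD to an ideal alpha-helical template is pushed
through the same switching function with `r0 = 0.08` nm and summed. The
template is generated internally by `build_ideal_helix()` from ideal
internal coordinates (phi = −57°, psi = −47°, trans peptide, standard bond
lengths and angles), giving the canonical 3.6 residues/turn, 0.15 nm rise
and 0.38 nm C-alpha spacing. The exact template convention shifts the CV
smoothly; documenting one reproducible template was preferred over
depending on an external definition.

**Crossing angles and contacts.** Helix axes run from the C-alpha centre
of mass of an N-terminal residue group to that of a C-terminal group
(helix 11: 883–886 to 894–897; helix 3: 712–715 to 730–733), and the
directed angle is reported over the full 0–180° range because orientation
states up to ~80° are meaningful and must not be folded. Side-chain
interactions use function-group centroids (Arg: NE/NH1/NH2; Glu: OE1/OE2;
and so on per `function_group_table()`), a 0.5 nm close-contact cutoff,
and a pi-cation criterion of centroid distance < 0.6 nm with the
cation–normal angle inside [60°, 120°]. That angular window places the
cation near the ring *plane*, opposite to the conventional stacked
geometry; it is implemented exactly as printed in the protocol it
reproduces, and flagged here because users porting the criterion elsewhere
will usually want the complementary window.

## Umbrella sampling and WHAM

Windows restrain the CV with `E = k (x − C_i)^2` — note the absence of the
conventional 1/2 — with `k = 10` kJ/(mol nm^2) and 30 centres spaced
0.1 nm apart in the reference protocol. `interpolate_path()` supplies
ordered window seeds by linear Cartesian interpolation between the
superposed end states; it replaces normal-mode morphing deliberately,
because the umbrella machinery needs only ordered, roughly evenly spaced
seeds, and along a linear path the difference RMSD is provably monotone
with uniform spacing (the default two-state pair separates the end states
by 1.45 nm so that a 30-point path reproduces the 0.1 nm spacing).

`wham()` solves the standard self-consistent equations on bin centres.
Numerical choices, fixed for reproducibility because the source protocol
does not state them: convergence when every window free energy moves less
than `1e-8` kJ/mol, an iteration cap of `1e5` (non-convergence is an error
reporting the residual), bin width of one fifth of the window spacing, and
50 bootstrap resamples per window for per-bin standard errors (replicates
are re-anchored at their minimum; bins that empty in a resample are
dropped from that replicate rather than contributing infinities).
Adjacent windows with disjoint histograms trigger a warning and the
profile is flagged disconnected rather than silently glued. With a single
unbiased window the estimator reduces exactly to the histogram PMF, which
is tested.

## Well-tempered metadynamics

Hills of base height `w0 = 0.2` kJ/mol and width 1.0 (in CV units) are
deposited at the current CV position; each deposit is tempered by the bias
already present,

$$w = w_0\, e^{-V(s,t)/k_B \Delta T}, \qquad \Delta T = (\gamma - 1) T,$$

with bias factor `gamma = 10` and `T = 300` K, so `dT = 2700` K. The FES
estimator is `F(s) = −(gamma/(gamma−1)) V(s)`. An auxiliary CV can be
confined by a square-well wall, zero inside `[5, 10]` and
`k ((x − a)/s)^e` against the violated bound outside (`k = 300`, `e = 2`,
`s = 1`, offset 0), matching the printed substitutions (75 kJ/mol at 4.5,
300 kJ/mol at 11).

Convergence is judged as in the source protocol: the free-energy
difference between two basins, `delta_fes_series()`, evaluated from the
hills available at each checkpoint, should drift by less than 1 kJ/mol
over the final stretch of the run.

**Numerical choices.** The Langevin driver deposits every 100 integrator
steps by default; the 1 ps pace of the all-atom protocol is meaningful
only there. For 1-D runs `metad_run()` can tabulate the accumulated bias
on a dense grid (spacing 0.01 CV units) and interpolate it linearly during
integration, making the cost linear in the number of steps; the recorded
hills stay exact, and a regression test confirms the tabulated and exact
paths produce matching hills and surfaces. Empty FES bins are masked and
excluded from minima and basin sums instead of being assigned infinities.

**Toy study conditions.** The verification potential is the quartic double
well `V(x) = h((x/a)^2 − 1)^2` with `h = 6.5` kJ/mol — the barrier scale
of the reference umbrella profile. For metadynamics the wells sit at
`a = ±10` CV units: with the protocol's kernel width of 1.0, features must
be large against the kernel for the hill sum to resolve them, and ±10
mimics the contact-number axes of the reference FES where basins sit
5–25 units apart. A convolution analysis of the analytic profile puts the
intrinsic kernel-smoothing bias on the barrier at about −6% for ±10
(versus −16% at ±6), within the 10% recovery tolerance. Verification runs
use `dt = 0.05` ps, friction 1, 4.8e6 steps and 48 000 hills (~30 s on one
CPU), the length at which the basin-difference drift criterion is met with
margin across seeds; umbrella verification uses 30 exactly-sampled windows
of 10 000 samples each.

## Trajectory statistics

The histogram PMF is `−k_B T \ln(P_i/P_{max})`: the modal bin is exactly
zero and empty bins are masked. Cross-correlation uses Pearson
coefficients of C-alpha displacement vectors about block means,
`C_ij = ⟨Δr_i·Δr_j⟩ / \sqrt{⟨Δr_i^2⟩⟨Δr_j^2⟩}`, averaged over contiguous
blocks and then over repeat trajectories; defaults analyse the last 40% of
each trajectory in four blocks, the fraction-based restatement of the
reference protocol (last 40 of 100 ns in 10-ns blocks). Network edges
exclude sequence neighbours (`|i − j| <= 10`) and classify by coefficient:
anti −0.4 to −0.2, weak 0.2–0.4, moderate 0.4–0.6, strong >= 0.6. The
printed anti-correlation bin overlapped the weak bin (an upper bound of
+0.2); since the bins must be disjoint and the class is labelled
anti-correlation, the upper bound is read as −0.2. GROMOS clustering
breaks neighbour-count ties to the lowest frame index, for determinism;
representatives minimise the summed within-cluster RMSD. Dihedral PCA maps
phi/psi to (cos, sin) pairs before diagonalising, skipping terminal
residues that lack one dihedral, and summarises PC1/PC2 with a 2-D PMF.

Two estimator properties worth knowing, both verified by tests:

* rigid-body fitting removes six degrees of freedom, so the RMSF of
  isotropically jittered atoms converges to `sqrt(3)*sigma` only up to a
  factor `sqrt((3N−6)/3N)`; recovery tests use enough atoms (N >= 40) that
  this shrinkage is inside the stated 5% tolerance;
* fitting also strips any rigid-body-like collective component from a
  prescribed displacement field, so correlation-recovery comparisons
  against generator truth are made with `fit = FALSE` — the generator's
  frames already share one reference frame. The fitted variant exists for
  real trajectories, where centre-of-mass drift and tumbling are genuine
  nuisances.

## What the synthetic generators do and do not emulate

`build_two_state_pair()` reproduces the *geometry* of a two-state
conformational change (rigid shared core, mobile tail, known inter-state
RMSD); `correlated_gaussian_trajectory()` reproduces stationary Gaussian
fluctuations with exact covariance; `jittered_trajectory()` gives
uncorrelated thermal noise; the double well gives an exactly known
free-energy landscape. None of them emulate protein energetics,
sequence-specific packing, solvent, or the kinetics of barrier crossing in
an all-atom force field. Passing the recovery suite therefore demonstrates
that the *estimators* are correct and converge at their stated rates — not
that desk-scale runs can reproduce all-atom results. The crystal-structure
worked examples (contact numbers and crossing angle on the two reference
models) additionally depend on a loop-completed antagonistic model whose
modelled coordinates are not redistributable with the package; those
checks run whenever the user supplies the prepared files (see the README).

## Known limitations

* Structures with insertion codes are rejected rather than renumbered;
  gap-free prepared structures are the caller's responsibility, and
  selections fail loudly on missing residues (silently skipping atoms
  would corrupt contact numbers).
* WHAM operates on 1-D CVs; the metadynamics engine is generic in
  dimension but the grid-tabulated fast path is 1-D.
* The Boltzmann sampler requires a bounded domain and is exact only up to
  its grid resolution (4096 points by default).
* The pi-cation angular window is applied exactly as printed (see above).
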