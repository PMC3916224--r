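---
title: "Methods: the tubulin straight-bent free-energy pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tubulin straight-bent free-energy pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bendscape)
```

# The scientific problem

Unpolymerised αβ-tubulin sits in a *bent* conformation; incorporation into
the microtubule lattice requires a *straight* one.  The two extremes are
crystallographically defined: the zinc-sheet, taxol-bound heterodimer
(PDB 1JFF) is straight, and the α₁β₁ heterodimer of the T2R–colchicine
complex (PDB 1SA0) is bent, about 12° away.  Two quantitative questions
hang on the free-energy profile that connects them:

* how the population of the heterodimer distributes across the
  straight-to-bent continuum (and hence how drugs such as colchicine or
  contacts such as a lateral tubulin pair shift it), and
* what a straightening free-energy cost of order 1 kcal/mol does to the
  kinetics of microtubule nucleation.

bendscape implements the full desk-scale machinery behind both questions:
structural curvature metrics, path collective variables over morphing
paths, umbrella sampling with WHAM unbiasing and bootstrap errors
(exercised on analytic landscapes), basin thermodynamics, and a
nucleation–elongation kinetic model with a conformational penalty.

# Curvature metrics

## Intradimer rotation

The curvature of a heterodimer relative to a straight reference is read
from the H7 central helices (residues 222–244 of each subunit by default):

1. superpose the bent dimer onto the straight one using only the α-subunit
   H7 atoms;
2. fit one least-squares plane through the combined α-H7 + β-H7 atoms of
   each structure;
3. report the intersection angle of the two planes.

Because plane normals carry a sign ambiguity, angles are folded to
[0°, 90°].  The wording "fitting a plane to the α- and β-subunit H7
helices" admits a second reading — one plane per helix within a single
structure — but only the adopted reading produces exactly two planes, one
per heterodimer, so that the intersection angle is a property *of each
bent heterodimer*; the per-helix reading would measure the helix-helix
kink within one structure instead.

Each angle is measured three times — with all atoms, with backbone
N-Cα-C-O atoms, and with Cα atoms only — and reported as mean ± standard
deviation over the three variants.  Atom pairing across structures uses
author residue numbering; side-chain atoms without a partner are dropped
from the all-atom variant only.

## Intramonomer rotation and the domain-center bending angle

The intermediate-domain rotation of a single subunit (≈8° for α, ≈11–12°
for β between the extreme structures) is computed by aligning the two
structures on the subunit's N-terminal-domain Cα atoms (residues 1–205)
and extracting the residual rotation that superposes the intermediate
domains (residues 206–381); the angle is `acos((trace(R) − 1)/2)`.  The
exact alignment frame used in the original crystallographic analyses is
not published; the N-terminal domain is the natural body-fixed frame
because it is the nucleotide-binding core that moves least.

The alternative "intrinsic bending angle" used by the Voth group fits a
least-squares line through the mass centers of the N-terminal,
intermediate and C-terminal domains of each subunit and reports the
line–line angle.  On linear morph paths between synthetic straight/bent
pairs the two metrics track each other with regression slope ≈ 1 (a
property the test suite asserts to lie in [0.85, 1.15]).

## Surface area and clashes

Solvent-accessible surface area uses deterministic Shrake–Rupley
sphere-point sampling with a 1.2 Å probe.  The original analysis was done
in a renderer whose "solvent density 4" setting has no portable meaning;
it is mapped here to a documented default of 960 points per atom, with a
convergence test (doubling the density moves a 10-atom fixture by < 1%).
Buried surface area is `BSA = SASA(α) + SASA(β) − SASA(αβ)` with the same
probe and point set in all three terms, which makes BSA ≥ 0 a theorem
(per-point accessibility can only shrink when atoms are added) rather
than a numerical accident.  Heteroatoms are stripped by default.  Steric
clashes use the 75%-of-summed-van-der-Waals-radii rule on a Bondi-style
element table; crystal structures without hydrogens are handled as-is
with heavy-atom radii.

# Path collective variables

A reference path is a library of frames R₁..R_P over a fixed atom
selection.  Progress along and distance from the path are

$$s(R) = \frac{\sum_{i=1}^{P} i\, e^{-\lambda M_i(R)}}
              {\sum_{i=1}^{P} e^{-\lambda M_i(R)}},\qquad
  z(R) = -\frac{1}{\lambda}\ln \sum_{i=1}^{P} e^{-\lambda M_i(R)},$$

with $M_i$ the mean squared displacement (Å²) of the selection from frame
$i$ after optimal superposition, and 1-based frame indexing so that
$s \in [1, P]$.  Both sums are evaluated with exponent shifting so large
$\lambda M_i$ cannot overflow.  The prefactor is
$\lambda = c / \overline{\mathrm{MSD}}_{\rm succ}$, proportional to the
inverse mean squared displacement between successive frames; $c = 2.3$ is
the customary constant of the path-variable literature and is a
configuration knob, since only the proportionality is dictated by the
method.

Morphing paths are pure linear interpolations between the endpoint
structures after superposing the end onto the start (frames are therefore
exactly equidistant); the server-based energy minimisation used in the
original protocol is intentionally omitted, because the free-energy
engine here runs on analytic landscapes and the geometric path only needs
endpoint fidelity and equidistance.

# The synthetic sampling engine

Explicit-solvent molecular dynamics is replaced by overdamped Langevin
(Euler–Maruyama) dynamics directly in collective-variable space:

$$x_{t+\mathrm{d}t} = x_t - \frac{\nabla U_{\rm tot}}{\gamma}\mathrm{d}t
  + \sqrt{2 k_B T\,\mathrm{d}t/\gamma}\;\eta_t,$$

with $U_{\rm tot} = U + \tfrac12 k_s (x - s_0)^2$ (plus
$\tfrac12 k_z(y - z_0)^2$ in 2D).  All windows integrate simultaneously;
trajectories are bit-reproducible for a fixed seed; the first 25% of each
trajectory is discarded as equilibration, mirroring the convention of
keeping the last 3 ns of 4 ns windows.  Defaults preserve the production
settings that matter: 35 windows, $k_s = 10$ kcal/mol per squared CV
unit, $k_BT = 0.596$ kcal/mol (300 K).

The `tubulin_like` landscape is the package's stand-in for the real
bending profile: a narrow straight well (centre 1.5°, sd 0.6°), a broad
bent well (centre 7°, sd 2.5°, spanning roughly 4–13°), and a barrier
2 kcal/mol above the straight minimum near 3°.  It is built from two
Gaussian wells in energy space whose depths are solved numerically so
that (i) the bent-minus-straight basin free-energy gap, split at
θ = 3.5°, equals the requested `delta_g` *exactly* at 0.596 kcal/mol
(solver residual < 10⁻⁴ kcal/mol), and (ii) the barrier height is hit
exactly.  With `delta_g = 1.0` the straight basin holds ≈ 16% of the
population — the same regime as the reported ≈ 20/80 split, which
corresponds to ≈ 0.8 kcal/mol.

What the generator emulates: Boltzmann statistics under harmonic
umbrella biases, window overlap, autocorrelation, and a two-basin
landscape with realistic depths and widths.  What it does not emulate:
atomistic force-field errors, slow orthogonal degrees of freedom,
ligand-coupled conformational changes, and morph-path dependence.
Passing recovery tests therefore validate the *estimators* (WHAM,
bootstrap, basin integration), not any claim about real tubulin
energetics.

The synthetic dimer generator builds idealised two-chain structures
(backbone + Cβ H7 helices, symmetric Cα domain blobs whose mass centers
are exact by construction) and rotates the β subunit rigidly about a
documented interface axis that is parallel to both H7 helices and lies in
their common plane.  With that axis the combined H7-plane normal rotates
with the subunit, so the intradimer metric must return the constructed
angle (closed-form oracle `acos(|n·Rn|)`), and the domain-center lines
are perpendicular to the axis, so the bending-angle metric must return it
too.

# WHAM and bootstrap errors

The 1D estimator iterates the standard self-consistent equations

$$p_j \propto \frac{\sum_i h_{ij}}{\sum_i N_i e^{(f_i - w_{ij})/k_BT}},
 \qquad f_i = -k_BT \ln \sum_j p_j e^{-w_{ij}/k_BT},$$

on 1000 bins (default) spanning the sampled range inclusive, until the
largest change in any $f_i$ is below 10⁻⁶ kcal/mol; the profile is
gauged to zero at its global minimum and unvisited bins carry $W=+\infty$
(they contribute zero weight to any population integral and are excluded
from RMS comparisons).  Adjacent windows must share occupied bins;
disconnected segments are an error, not a silent artifact.  The 2D
estimator is the same iteration on an (s, z) grid with tolerance 0.001
kcal/mol — the tolerance is applied to the $f_i$ increments in kcal/mol,
resolving the ambiguity of whether it governs energies or probabilities.
`project_to_path()` slices the 2D surface at z = 0 with linear
interpolation between the bracketing z-bins and re-gauges.

Bootstrap uncertainty resamples each window's raw samples with
replacement, recomputes the WHAM profile per replicate (warm-started from
the full-data window constants), aligns every replicate to zero at the
bin containing ξ = 0, and reports the per-bin population-form (1/N_b)
standard deviation — so σ(0) = 0 exactly by construction.  Ordinary
(per-sample) resampling is correct for independent draws but
underestimates the spread of autocorrelated Langevin data roughly tenfold
(the test suite measures this against 8 independent repeats), so a
circular block-bootstrap mode is provided; a block of 2000 steps —
about twenty relaxation times at the default window stiffness — makes
the bootstrap spread match the repeat-experiment spread within a factor
of two for essentially all bins.

# Basin thermodynamics

Populations integrate `exp(−W/kT)` on the bin grid, with bins straddling
a basin edge contributing fractionally; populations over any partition of
the support therefore sum to one exactly, and `delta_g(a, b) =
−kT ln(pop_a/pop_b)` is antisymmetric and gauge-invariant by
construction.  The straight/bent boundary default is θ = 3.5°.  Extrema
are located after optional moving-average smoothing; the "barrier" label
goes to the highest point between the two deepest minima; monotone or
flat profiles yield no interior extrema.

# Nucleation–elongation kinetics

The assembly model is the classical two-step ladder
`X_j + X_1 ⇌ X_{j+1}` with a single diffusion-limited on-rate
$k_f = 10^6$ /M/s, weak nucleation-phase affinity ($K_d$ = 1 mM) up to
the nucleus size N = 4, strong elongation affinity ($K_d$ = 1 µM)
beyond, 10 µM total heterodimer and a 500-s horizon.  Species are
truncated at L = 8N with a closed last compartment (early-stage
nucleation is the target; the fold-change results move < 2% when L is
doubled).  The straightening penalty ε raises nucleation-phase
*dissociation* rates by `exp(m·ε/kT)`, keeping the on-rate
diffusion-limited; penalising dissociation is thermodynamically
equivalent to destabilising the straightened intermediate.

Two conventions were genuinely open: how many nucleation steps pay the
penalty, and what "time to assemble a nucleus" means.  Numerically, all
horizon- and truncation-robust readouts collapse onto two values at
ε = 1 kcal/mol: ≈ exp(ε/kT) ≈ 5.4 when the penalty is paid once (at
dimerisation), and ≈ exp(3ε/kT) ≈ 145 when every nucleation step pays
(quasi-steady pre-nucleus concentrations multiply).  Plateau-fraction
criteria evaluated inside a finite window interpolate between these but
depend strongly on the horizon and the truncation cap — within the 500-s
window these systems are still deep in their lag phase, so a "plateau" is
not defined — and were rejected for that reason.  The frozen package
convention is therefore: `penalty_mode = "first_step_only"` (the
conformational cost is paid once, when two straightened subunits commit
to the lattice-compatible dimer geometry) and nucleation time read as the
first crossing of a fixed 1e-10 M nucleated-species concentration, deep
in the lag phase, where the fold change is horizon- and
truncation-insensitive and reduces to the Boltzmann factor of the total
penalty paid.  Under this convention a 1 kcal/mol penalty delays
nucleation 5.4-fold; severalfold-to-an-order-of-magnitude delays from a
~1 k_BT penalty are exactly the regime this model family supports.

Integration uses a stiff-capable solver (lsoda) from a monomer-only
initial condition; mass conservation is asserted to 10⁻⁹ M along the
whole trajectory.

# Numerical choices and problem sizes

* Langevin step dt = 0.002 (reduced units), friction 1: about 45 steps
  per relaxation time in a k = 10 window, keeping the Euler–Maruyama
  stationary-variance bias near 1%.
* Pipeline-recovery experiments run 35 windows × 200 000 steps (150 000
  retained), 1000 WHAM bins, 50 block-bootstrap replicates — about one
  minute on one core; the harmonic-window check draws 21 × 20 000
  analytic samples so its only error is Monte Carlo.
* Extremum positions on stochastic profiles are read at the
  umbrella-window spacing (35 bins over the sampled range): locating a
  minimum of a broad basin finer than the window spacing is not
  statistically meaningful at these sample sizes.
* The tubulin-like well-depth solver alternates two 1D root solves eight
  times; construction residuals are < 10⁻⁴ kcal/mol on the basin gap and
  barrier.
* Zero-angle assertions use 10⁻⁴ degrees: `acos` near 1 amplifies
  floating-point rounding, so exact zero is not representable.
* PDB serialisation prints 0.001 Å; on ideal 23-residue helices this
  quantisation shifts plane-normal angles coherently by ≈ 10⁻³ degrees,
  which bounds how exactly a write/read round trip can reproduce an
  angle.

# Known limitations

* The geometry operations are validated against constructed-rotation and
  brute-force oracles, not against the deposited tubulin structures: the
  coordinate files are not redistributable inside the package and are not
  fetched at test time.  The real-structure comparison test runs whenever
  the files are placed under `inst/extdata/pdb`.
* Linear morphs are not energy minimised; intermediate frames can contain
  sterically strained geometry (the clash detector will happily report
  it).
* The kinetic model is deterministic (ODE); stochastic nucleation noise,
  lattice geometry, GTP hydrolysis and dynamic instability are out of
  scope.
* Secondary-structure-restricted selections (e.g. "167 Cα atoms of the
  intermediate-domain secondary structural elements") require an external
  assignment; selections here are residue-interval based and
  configurable.
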