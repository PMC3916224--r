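# bendscape

Free-energy and geometry analysis of the tubulin straight–bent
conformational equilibrium.

αβ-tubulin heterodimers are bent in solution and straight in the
microtubule lattice; the two extremes are separated by a ~12° intradimer
rotation (straight zinc-sheet structure 1JFF vs the bent T2R–colchicine
heterodimer 1SA0). bendscape is a desk-scale R pipeline for the
computational machinery used to study that equilibrium and its kinetic
consequences, aimed at structural biophysicists who want the estimators
without a cluster:

* **Structure geometry** — intradimer rotation from least-squares planes
  through the H7 helices after α-H7 superposition (three atom-selection
  variants, mean ± sd), intramonomer intermediate-domain rotations,
  domain-center-of-mass bending angles, Shrake–Rupley solvent-accessible
  and buried surface area (`BSA = SASA_α + SASA_β − SASA_αβ`), and
  75%-van-der-Waals steric clash detection. PDB/mmCIF input via bio3d.
* **Path collective variables** — linear morph paths between endpoint
  structures and the progress/distance variables
  `s(R) = Σ i·e^(−λMᵢ) / Σ e^(−λMᵢ)`,
  `z(R) = −(1/λ)·ln Σ e^(−λMᵢ)` with `λ ∝ 1/⟨MSD⟩` between successive
  frames.
* **Umbrella sampling on analytic landscapes** — an overdamped-Langevin
  sampler in CV space with harmonic window biases, including a
  `tubulin_like` two-basin landscape with an exactly controlled basin
  free-energy gap.
* **WHAM** — 1D and 2D self-consistent unbiasing, projection of a 2D
  surface onto the path at z = 0, and bootstrap uncertainty (ordinary or
  block) with profiles aligned so σ(ξ = 0) = 0.
* **Thermodynamics and kinetics** — basin populations and ΔG from PMF
  profiles, extremum/barrier location, and a two-step
  nucleation–elongation ODE model of microtubule assembly with a
  conformational straightening penalty.

## Worked example

Recover the bent/straight thermodynamics of a synthetic bending landscape
with a 1 kcal/mol basin gap, then ask what that gap does to nucleation
kinetics:

```r
library(bendscape)

pot     <- make_toy_landscape("tubulin_like", delta_g = 1.0)
windows <- generate_window_set(pot$bounds[1, ], count = 35, k_s = 10)
run     <- sample_umbrella(pot, windows, n_steps = 200000, dt = 0.002, seed = 1)
pmf     <- bootstrap_uncertainty(run, n_boot = 50, seed = 2, block_length = 2000)
pmf
#> pmf_profile: 1000 bins on [-3, 16.1], max W 3.62 kcal/mol, bootstrap sigma attached
#>   converged in 3411 iterations (residual 1e-06)

straight <- c(min(pmf$xi), 3.5); bent <- c(3.5, max(pmf$xi))
basin_population(pmf, straight)        # 0.152
basin_population(pmf, bent)            # 0.848
delta_g(pmf, bent, straight)           # -1.03 kcal/mol

locate_extrema(wham_1d(run, n_bins = 35))
#>      type        xi         W
#> 2     min  1.636804 0.8085576
#> 4     min  6.555732 0.0000000
#> 6 barrier  3.276446 2.4631420
```

The umbrella windows were unbiased into a profile whose straight basin
(θ < 3.5°) holds 15% of the population, whose bent basin holds 85%
(ΔG = −1.03 kcal/mol, recovering the constructed 1.0 within the bootstrap
uncertainty), with minima near 1.6° and 6.6° and the barrier near 3.3° —
the two-basin shape the landscape was built with.

```r
fc <- fold_change(build_model(N = 4, epsilon = 1,
                              penalty_mode = "first_step_only"),
                  build_model(N = 4, epsilon = 0))
fc$fold
#> 5.374058
```

A 1 kcal/mol straightening penalty applied at the nucleating dimerisation
step delays assembly of a 4-species nucleus 5.4-fold (the penalty
convention and nucleation-time criterion are documented in the methods
vignette, `vignettes/tubulin-bending-pmf.Rmd`).

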