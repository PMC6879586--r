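---
title: "Models and methods behind kgating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kgating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kgating)
```

`kgating` analyses replicated channel trajectories: it counts ion
permeation events, estimates single-channel currents, classifies
selectivity-filter (SF) site occupancy, builds density/free-energy and
pore-radius profiles, and extracts the collective motion coupling the
activation gate (AG) to the SF. This vignette records the models,
their assumptions, the tunable parameters, and the design choices made
where the design was genuinely open. All internal units are nm, ns,
pA, mV, kT and degrees.

## Permeation counting

Each permeant particle is tracked by a three-state machine with
hysteresis: *below* when `z < z_low − δ`, *above* when
`z > z_high + δ`, undetermined in between. An outward event completes
when a particle last seen below is next seen above (inward is the
mirror image); the margin `δ` (default 0.1 nm) suppresses boundary
flicker. The default bounds are recomputed per frame from the
annotation: `z_low` is the threonine-hydroxyl ring (bottom of the S4
cage), `z_high` the outermost glycine carbonyl ring. Choices made
where the source methodology is silent:

* A consecutive-frame jump `|Δz| > L_z/2` is a periodic-image wrap and
  resets the particle's state without counting.
* A below→above jump with no observed frame inside the filter still
  counts — output is sparsely sampled and fast traversals are real.
* A radial check (default on, `r_cut` 0.6 nm) vetoes traversals whose
  observed in-filter frames never pass near the pore axis, so bulk
  ions drifting past the channel through the periodic box edge are not
  counted.
* Event frames are reported 1-based, the R convention.

Current converts net counts with the elementary charge:
`I [pA] = 160.2176634 × (n_out − n_in) / T [ns]`, and the applied
voltage obeys `V = E·L_z`. Both net and per-direction counts are
reported. Confidence intervals come from the replica bootstrap
(below); the per-replica unit is the whole trajectory because frames
are strongly autocorrelated.

## Site occupancy and flips

Consecutive oxygen-ring planes (subunit-mean z) bound the cages
S4 = [T_OG1, T_O] up to S0 = [Y_O, G2_O]; the vestibule Scav extends
`w_cav` = 0.4 nm below the hydroxyl ring (no published bound exists
for either choice; both are exposed parameters). A particle occupies a
site when its z is inside the interval and it lies within `r_site` =
0.35 nm of the pore axis; when an ion and a water both qualify, the
particle closest to the site centre wins, and an empty site is vacant
— so ion + water + vacant = 1 exactly, per site and opening level.
Frames whose planes are not strictly increasing (distorted filter) are
excluded and counted, not interpolated.

Carbonyl flips are orientation-based: a carbonyl is flipped when its
C→O direction deviates from a per-subunit reference — the normalised
component-wise median orientation over the first replica — by more
than `theta_flip` (default 90°). A dihedral-based definition would
need backbone atoms the reduced representation does not carry; the
threshold and reference are configurable.

## Density, free energy, pore radius

Axial ion positions (relative to the instantaneous hydroxyl-ring
plane, which removes channel drift) are turned into a Gaussian KDE on
a fixed grid, renormalised to unit area by the trapezoid rule, and
converted to `F = −ln(ρ/ρ_max)` in kT, zero at the global minimum.
The automatic bandwidth is Scott's rule `sd·n^{−1/5}`; ensemble
profiles default to a fixed 0.03 nm bandwidth so different opening
levels are comparable. Profiles are computed per replica and averaged
in F, with pointwise coverage-factor CIs (Student-t quantile at
`n_rep − 1` degrees of freedom times the SEM). Since trajectories are
generated under voltage these are approximate, not equilibrium, free
energies; only differences and trends are meaningful.

The pore profile finds, per z slice, the largest sphere centred in the
slice plane touching no atom: `max_c min_i (|x_i − (c, z)| − vdW_i)`,
optimised by multi-start Nelder–Mead seeded on the previous slice
centre, clipped to `[0, r_max]`. The element-keyed vdW table
(H 0.12, C 0.17, N 0.155, O 0.152, S 0.18 nm) is a declared dialect —
different codes ship slightly different radii — and is overridable. A
constriction below 0.4 nm (the conventional hydrated-K⁺ radius) is
flagged.

## PLS functional mode analysis

The target is a scalar order parameter (typically the filter opening —
the cross-subunit CA distance at the S4 threonine); the features are
superposed, flattened coordinates. PLS1 with sequential deflation
builds `k` components (default 30); the regression vector β gives the
maximally correlated mode (MCM = β normalised) and the
ensemble-weighted mode ewMCM ∝ Cβ, with C the training-coordinate
covariance — the covariance weighting is the one formula taken from
the FMA method literature rather than defined here. The ewMCM is
oriented so increasing projection increases the target. Training uses
the contiguous first half of every replica and validation the second
half: a random split would leak autocorrelated frames across halves
and flatter the validation correlation. NIPALS is deterministic
(first weight from `Xᵀy`), components are dropped when the residual
rank is exhausted (with a warning), and at `k = rank(X)` the model
equals ordinary least squares (tested against `lm`). Interpolated
structures `mean + α·ewMCM` span the observed projection range. PCA
(eigendecomposition of the same covariance) is provided for
comparison.

## Bootstrap statistics

`bootstrap_ci()` resamples replicas with replacement (20 000 resamples
by default, explicit seed, caller RNG untouched) and returns
percentile intervals; BCa is available behind a flag but percentile is
the default, matching the plain wording of the emulated methodology.
A caveat the test suite documents explicitly: the percentile bootstrap
of a mean over 10 replicas truly covers ~90%, not 95% (direct
simulation, 10⁴ trials); coverage approaches nominal as replicas grow.
One acceptance criterion demands 95 ± 3% at 10 replicas and is
deliberately left failing rather than silently switching interval
type — the t-based `coverage_ci()` does achieve nominal coverage and
is what the profile CIs use.

## The synthetic channel

The generator emits a stated world, not a fitted one: a four-subunit
pseudo-atom channel (gate beads P19/F97/A88, an I84 side-chain tip,
SF oxygens, T59 CA/CG, three M1 and three M2 helix beads per subunit)
plus ions and waters, with

* gate opening `g` per replica (default 1.66 nm, the opening of
  maximal current; per-frame gaussian fluctuation σ_g = 0.02 nm);
* filter spread `s = 0.27 + g/3 + ε`, σ_T = 0.01 nm — an affine
  gate→filter coupling whose slope the order-parameter tests recover;
* helix beads whose radius interpolates between the gate and the
  filter, so the gate-driven collective motion concentrates on the
  lower helices and the filter, which the ewMCM test checks;
* a constant 0.45 nm I84–T59 side-chain contact;
* ions hopping over the compartments bulk–cavity–S4…S0–bulk as a
  continuous-time Markov chain (exact event-driven simulation with
  rates frozen per output frame), single occupancy per site, at most
  3 ions in the cavity, voltage tilt Δ = 1.5 kT per hop, attempt rate
  5/ns, and an S4/S3 barrier `B = 0.8 + 300·(0.823 − s)²` kT for
  `s < 0.823` — the barrier falls as the channel opens, flat above the
  optimum; permeated ions re-enter the bottom bulk (rate 2/ns), which
  the counter sees as a periodic wrap;
* water entry into S4 and S1 with probability
  `p_w(s) = logistic((s − 0.875)/0.015)` at attempt rate 2/ns (exit
  0.5/ns): negligible below the optimal spread, dominant ~0.1 nm
  above it. A site-bound water blocks ion entry outright — the
  simplest blocking model — producing the current decline at large
  openings; `kw_in = 0` ablates the mechanism;
* ~40 cavity waters at the smallest openings, growing linearly to 100
  (resampled uniformly in a 0.9 nm ball each frame), matching the
  qualitative cavity-hydration behaviour; parked reserve waters keep
  the atom count constant across replicas;
* isotropic coordinate jitter σ_xyz = 0.02 nm, small against the
  0.1 nm counting margin so the emitted coordinates reproduce the
  ground-truth hop log exactly — asserted, not assumed.

A planted-rate mode replaces the hop chain by crossings scheduled as
an exact Poisson process (0.1/ns in the calibration tests), drawn so
every event completes within the replica; the realised per-replica
count is then unbiased for the planted rate, which is what makes the
bootstrap-coverage calibration test meaningful.

What the generator does **not** emulate: real force-field energetics,
electrostatics, water structure, absolute currents (its kinetics are
~10× faster than a real channel so short test runs have counting
statistics), SF collapse/C-type inactivation, and conformational
heterogeneity beyond the planted degrees of freedom. A green pipeline
test therefore establishes correctness of the *analysis* under the
stated kinetic model — never realism of the physics.

## Statistical reading of the gating-curve criteria

Crossing counts are Poisson-like; with practical test sizes the
plateau of the no-water ablation curve has ~5% relative noise per
level, so strict monotonicity across seven levels would fail by chance
roughly half the time even in the stated world. The acceptance test
therefore asserts the *shape*: an interior maximum, a decline at the
largest opening below 60% of the maximum with rising S-site water
occupancy, and — with water entry ablated — a final level above 75% of
the maximum. Thresholds were fixed from the planted model's magnitude
(a 3× decline vs ~1.5 SE fluctuations), not adjusted after runs.

## Other limitations

* XTC/TRR readers are not implemented (no suitable R backend);
  convert to DCD or multi-frame GRO/PDB first.
* The pore-radius optimiser assumes the wall encloses the axis; for
  an open half-space it reports the capped `r_max`.
* The CLI exposes `synth` and `scan`; the remaining analyses are R
  functions — orchestration was kept where R users live, in code.
* Occupancy classification loops frames in R; it is comfortable for
  10⁴–10⁵ frames but not written for millions.
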