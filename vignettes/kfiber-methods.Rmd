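---
title: "Models and methods behind kfiber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kfiber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kfiber` models the self-organization of kinetochore-fibers in metaphase
spindles. This vignette records the models, the assumptions behind them,
the numerical choices, and the places where the design was genuinely open.
It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The director field and its assumptions

Spindle microtubules align with their neighbours. Coarse-grained, the mean
local orientation is a headless unit field (a nematic director,
`n ≡ −n`). With no hydrodynamic flow and a single elastic constant, the
steady state minimises the Frank elastic energy, so the director angle is
harmonic: `∇²n = 0`. The domain is an ellipse (semi-axes `a`, `b`, in
micrometres) with

* tangential anchoring on the boundary — MTs lie along the spindle edge;
* two disk-shaped `+1` aster defects of finite radius with radial
  anchoring — the poles. Finite disks, not point singularities, both
  because that is how aster cores behave on a grid and because the core
  radius is a physically meaningful fit parameter. The field at the exact
  defect center is undefined and masked.

The solution contains no material parameters: geometry fixes everything.
A consequence worth noting is topological frustration: a tangentially
anchored disk admits total defect charge `+1`, while two `+1` asters carry
`+2`. The compensating negative winding concentrates in thin wall regions
between each defect core and the nearby boundary vertex; this is a real
property of the model, not an artifact, and it is why streamlines seeded
within roughly one core radius of the rim ride the rim toward the vertex
instead of the pole (`seed_streamlines()` excludes that band by default).

### Numerics

The solver works on a regular grid (default 0.1 µm). Boundary cells get
the ellipse tangent angle, defect-core cells the radial angle, re-imposed
every iteration. Two phases:

1. *Vector phase.* Relax the doubled-angle vector `(cos 2θ, sin 2θ)` by
   neighbour averaging with renormalisation, starting from a superposition
   of the two aster fields. The superposition start matters: it seeds the
   correct winding around each core. Started from a uniform angle, the
   relaxation can park in metastable states containing spurious ±½ defect
   pairs or π-walls, which are invisible to nematic residuals.
2. *Angle phase.* Checkerboard successive over-relaxation directly on the
   wrapped angle, `θ ← θ + ω/4 Σ wrap_π(θ_nb − θ)`. Its fixed point
   satisfies the discrete Laplace equation to the requested tolerance
   (default residual ≤ 1e−6 rad); the vector phase's fixed point alone
   would leave an O(Δθ³) angle residual and could not reach it.

Streamlines are integrated with a fixed-step midpoint scheme (default step
= half the grid spacing), the headless sign resolved each step toward the
target pole, with bilinear interpolation of `(cos 2θ, sin 2θ)`. Arc length
`s` is 0 at the pole center; inside the defect core the field is radial,
so the last stretch is the straight distance. Trajectories that graze the
ellipse rim by less than a step are projected back inside (rim-hugging is
legitimate under tangential anchoring); larger excursions are an error.

## Flux balance

At steady state, minus-end gain, transport and loss balance along each
streamline:

`j(s) + v(s) dn/ds + n(s) dv/ds − r n(s) = 0`.

Conventions: `s` increases from pole (0) to kinetochore (`s_kin`); minus
ends move toward decreasing `s` at speed `v ≥ 0`; `r` is the detachment
rate (default 0.4 min⁻¹, the inverse of the measured KMT lifetime in the
spindle bulk). The equation is integrated in conservative form,
`d(nv)/ds = r n − j`, with zero minus-end flux through the pole, giving
`v(s) = ∫₀^s (r n − j) ds' / n(s)`. This is equivalent to imposing the
kinetochore-end boundary condition that the flux there equals the
nucleation rate, because total recruitment balances total detachment at
steady state; integrating the cumulative form avoids differentiating a
noisy `n(s)`. Masked where `n ≈ 0`.

Recruitment models:

* **Nucleate at kinetochore:** `j = 0` in the bulk; new KMTs appear at
  `s_kin` with zero length. With flat bulk `n` this forces `dv/ds = r`.
* **Capture from spindle:** `j(s) ∝ n_nonKMT(s) · P_reach(s)` where
  `P_reach = exp(−(s_kin − s)/λ)` is an exponential survival in the
  length a non-KMT must grow to reach the kinetochore. The length
  constant `λ` is exposed as a parameter (default ∞, i.e. every non-KMT
  reachable) because the detailed growth/catastrophe model behind it is
  not reproduced here; `λ → 0` recovers the nucleate model. The shape is
  normalised so bulk recruitment balances the captured share of total
  detachment. When the non-KMT density matches the KMT density, capture
  recruitment exactly cancels detachment and `v ≡ 0`.
* **Hybrid(f):** fraction `f` captured, `1 − f` nucleated.

The treadmilling profile encodes a chipper-feeder pole: minus-end
depolymerases act only at `s ≤ s_p` (default 1.5 µm). There
`v_tread = max(0, v(s_p) − v(s))` and the tubulin speed
`v_tub = v + v_tread` is constant and equal to `v(s_p)` throughout the
pole region, continuous at `s_p`.

## Stochastic KMT lifecycle

Per time step (explicit Euler, default `dt = 0.01` min, which is well
below both `1/r` and the advection stability scale since `v` is smooth
and slow): Poisson births at each kinetochore; initial minus-end position
`s_kin` (nucleate) or drawn from the normalised `j(s)` truncated to the
kinetochore's streamline (capture); advection `ds = −v(s) dt`; removal at
a detachment time drawn exponentially at birth. Minus ends reaching the
pole pin there while tubulin continues to treadmill through them. KMTs
never switch streamlines — the model treats the streamline as the KMT's
track for its whole life. Burn-in defaults to `3/r` before any snapshot;
pooled snapshots are spaced far enough apart (`2/r` by default, more in
tests) that shared survivors are rare. Detachment times of KMTs still
alive at the end of a run are right-censored and therefore not recorded;
tests of exponentiality exclude births near the end of the run for the
same reason.

## Photoconversion

**Simulation.** After burn-in (default 5 min), tubulin under an
activation line drawn perpendicular to the spindle axis is marked, with
in-plane profile `1/(1 + (d/γ)²)^p` across the line. The generalised
Cauchy exponent `p` is configurable (default 1) because only the family,
not the exact form, is pinned down; the half-width defaults to
`γ = 1.0 µm`, anchored to the measured activation width (σ = 1.0 µm).
Marks on a KMT whose minus end sits at `s` advect at that KMT's tubulin
speed `v_tub(s)`; they are destroyed when they treadmill past the minus
end or when their KMT detaches. Frames are rendered by binning mark
weights into pixels (default 0.1 µm); an optional immobile non-KMT pool
decays at its own fast rate (default 1/0.26 min⁻¹, off by default so the
marked signal isolates KMT behaviour).

Two properties of the marked line are worth keeping in mind when
interpreting extracted speeds:

* the line is a *mixture*: every KMT crossing the activation position
  contributes marks moving at its own `v_tub`, so the extracted line
  speed is a minus-end-density-weighted average (about half of
  `dv/ds = r` in the bulk for the nucleate model), not the local
  minus-end speed;
* a decelerating speed field compresses the line as it advects
  (`dv/ds > 0`), which partially offsets the intensity decay from
  detachment when peak *height* is used as the turnover readout. The
  closure tests therefore check height-decay fidelity against the
  realised marked-tubulin decay, and check rate recovery in a shear-free
  configuration.

**Analysis.** Per frame: the spindle axis is the line through the two
pole markers; intensity is averaged across a band (default ±15 px) and
indexed by axial distance from the pole at pixel resolution (an optional
tighter radial band restricts to the straight central section). Candidate
peaks are local maxima above a noise floor (median + 3× a first-difference
robust noise estimate — robust both to broad marked structure and to
zero-padding outside the spindle); the candidate nearest the
previous-frame center is fit with a 3-parameter Gaussian on the central
5 pixels (window exposed for other pixel sizes). Peak height is corrected
by subtracting an opposite-side Gaussian fit (background) and dividing by
a bleaching calibration normalised to 1 at activation. Speed is the OLS
slope of center versus time (poleward positive, ≥ 5 frames); turnover is
a dual-exponential fit with `k_fast = ρ k_slow, ρ ≥ 2` for
identifiability, initialised from a log-linear tail fit, with a
single-exponential fallback when the dual model is singular. Fits at
parameter bounds or with < 10 points are flagged.

## Model comparison

Hybrid predictions come either from the flux solution (deterministic
mark-weighted mean of `v_tub` below the activation position) or from the
full stochastic simulation plus the analysis chain. The posterior over
the captured fraction uses an independent Gaussian likelihood per
position bin with the bin's standard error (optionally inflated by Monte
Carlo prediction noise) and a uniform prior on a grid (default step
0.05). Bin means with SEMs — rather than pooled per-cell likelihoods —
is the implemented reading of the comparison. The calibration test uses
a per-bin SEM of 0.05 µm/min, representative of ~10 cells per bin with
per-cell speed scatter of ~0.15 µm/min.

## The synthetic-data generator

`generate_spindle()` emulates an EM reconstruction: a HeLa-like geometry
(ellipse 5.5 × 3 µm, poles 9 µm apart, core radius 0.5 µm), kinetochores
near the metaphase plate, KMT minus-end positions drawn from a Gaussian
pole peak (center 1 µm, σ 0.5 µm, roughly half the mass) plus a flat bulk
term, microtubules laid along streamlines with von Mises angular noise
applied in the doubled-angle representation (respecting the headless
symmetry; concentration κ = 4 targets a planar order parameter
`I₁(κ)/I₀(κ) ≈ 0.86`), and non-KMTs with exponential lengths (mean
2.0 µm) walked along the director. `generate_movie()` emulates a
photoconversion acquisition: an advecting, dual-exponentially decaying
line (slow fraction 0.26, lifetimes 2.8 min and 0.26 min — the two-photon
measurement values), bleaching (0.1 min⁻¹), a spindle-shaped
autofluorescence background, camera dark level, Gaussian noise, 5 s
frames for 2.5 min at 0.1 µm/px. `generate_orientation_map()` adds
wrapped Gaussian noise to a solved field with a binary density-proxy
weight.

What the generator does *not* emulate: point-spread blurring and
shot-noise statistics, MT curvature noise correlated along a fiber,
reconstruction tracing errors, pole-marker localisation error, and
out-of-focus background. Passing closed-loop tests therefore demonstrates
the correctness and calibration of the algorithms under the stated noise
models, not performance on raw microscope data.

### The order-parameter convention

The printed uniaxial form `S = ⟨(3cos²(θ−⟨θ⟩) − 1)/2⟩` is the default
estimator; it is 1 for aligned and 0 for 3D-isotropic angle sets but 1/4
for planar-isotropic ones. The planar estimator `⟨cos 2(θ−⟨θ⟩)⟩` (0 for
planar-isotropic) is also exposed, and is the natural ground-truth scale
for the planar synthetic generator. Both are available because the
convention used on projected angles is ambiguous; pick per use.

## Problem sizes and tolerances

Tests and the acceptance script run at desk scale: director grids of
60–120 cells per side (radial-case accuracy is measured at 0.05 µm
spacing, where the discrete solution is within 10⁻³ rad of the analytic
field); flux-balance grids of 400–1500 points; simulator runs of ~500
KMTs for ~30 lifetimes pooling ≥ 10⁴ minus ends; 200 synthetic movies for
turnover recovery; 5 replicate photoconversion simulations per activation
position; 200 replicates for posterior calibration. These sizes give
Monte-Carlo errors comfortably below the asserted tolerances while
keeping the whole suite at a few minutes per file.

## Known limitations

* Metaphase steady state only: no prometaphase assembly or anaphase.
* One elastic constant, no flows, fixed defect positions; no
  time-dependent nematodynamics.
* The capture model's reach probability is a single-parameter exponential
  stand-in for a full growth/catastrophe calculation.
* Peak-mode tracking on a strongly sheared speed field underestimates the
  position dependence of line speeds (the mixture effect above); the
  package reports what the procedure yields rather than correcting it.
* File formats are the package's own documented text formats plus TIFF;
  proprietary microscope or Amira formats are out of scope.
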