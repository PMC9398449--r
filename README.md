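# kfiber

Quantitative machinery for studying how kinetochore-fibers self-organize in
metaphase mitotic spindles.

During metaphase, every chromosome is held by a bundle of kinetochore
microtubules (KMTs) whose plus ends are embedded in the kinetochore while
their minus ends reach back toward a spindle pole. Electron-tomography
reconstructions of human spindles show that only about half of KMT minus
ends actually reach the pole; the rest end in the spindle bulk. `kfiber`
implements the modelling and analysis chain needed to explain that
distribution from KMT dynamics:

1. **Nematic director field.** MTs align locally, so at steady state (in
   the one-elastic-constant active-liquid-crystal approximation) the
   director angle solves the Laplace equation, `∇²n = 0`, in the spindle:
   an ellipse with tangential boundary anchoring and two radially anchored
   `+1` aster defects at the poles. The solution depends only on geometry.
   KMT trajectories follow streamlines of this field; `s` denotes arc
   length from the pole along a streamline.
2. **Flux balance.** At steady state the KMT minus-end density `n(s)`,
   minus-end speed `v(s)`, bulk recruitment rate `j(s)` and detachment
   rate `r` obey `j + v dn/ds + n dv/ds − r n = 0`. Given a measured
   `n(s)` and a recruitment model — nucleate-at-kinetochore (`j = 0` in
   the bulk), capture-from-spindle (`j ∝` non-KMT minus-end density ×
   reach probability), or a hybrid — the speed profile `v(s)` follows by
   integration. With flat `n` and pure nucleation, `dv/ds = r`.
3. **Stochastic KMT lifecycle.** Poisson recruitment at kinetochores,
   minus-end advection at `v(s)`, minus-end depolymerization (tubulin
   treadmilling at `v_tread = max(0, v(s_p) − v(s))` inside the pole
   region `s ≤ s_p`), and exponential detachment at rate `r`.
4. **Photoconversion.** Both directions: simulate marking a line of
   tubulin and follow it through the spindle, and analyse movies (real or
   simulated) by line-profile extraction, Gaussian peak tracking, bleach
   correction, dual-exponential turnover fitting
   (`A_s e^{−k_s t} + A_f e^{−k_f t}`) and linear speed fitting.
5. **Model comparison.** A Bayesian posterior (uniform prior, independent
   Gaussian likelihood per position bin) over the fraction of KMTs
   captured from the spindle versus nucleated at kinetochores.

A synthetic-data generator produces spindle reconstructions, orientation
maps and photoconversion movies with known ground truth, so every analysis
stage is testable end to end without any external data.

## Worked example

Solve the director field for a HeLa-like spindle, derive the nucleate-model
speed profile from a minus-end density, and simulate + analyse a
photoconversion experiment:

```r
library(kfiber)
set.seed(1)

geom  <- spindle_geometry(a = 5.5, b = 3,
                          defects = rbind(c(-4.5, 0), c(4.5, 0)),
                          defect_radius = 0.5)
field <- solve_director(geom, spacing = 0.1, tol = 1e-6)
field
#> Nematic director field
#>   grid: 113 x 63 cells, spacing 0.1 um
#>   interior cells: 4772 bulk, 248 boundary, 152 defect
#>   converged in 200 sweeps, interior residual 9.86e-07 rad

sls  <- Filter(function(s) s$pole == 1, seed_streamlines(field, 0.5))
kins <- data.frame(streamline = seq_along(sls),
                   s_kin = sapply(sls, function(s) max(s$s)), rate = 8)

# minus-end density: Gaussian pole peak (~1 um from the pole) + flat bulk
prof  <- minus_end_density(s_minus = c(abs(rnorm(250, 1, 0.45)),
                                       runif(250, 0, 4.5)),
                           s_kin = rep(4.6, 500))
speed <- solve_speed(prof, recruitment_nucleate(), r = 0.4, s_kin = 4.6)
speed
#> Minus-end speed profile (nucleate recruitment, r = 0.4 /min)
#>   domain: s in [0, 4.6] um; pole region s <= 1.5 um
#>   v at mid-spindle: 2.35 um/min; v_tub in pole region: 0.659 um/min

sim <- simulate_photoconversion(speed, sls, kins, activation_s = 3,
                                seed = 1)
ana <- analyze_movie(sim$movie)
ana$speed
#> Line speed: 0.7 +/- 0.0245 um/min poleward (n = 31 frames)
#>   initial position: 2.93 um from the pole
```

The fitted line speed (~0.7 µm/min for a line drawn 3 µm from the pole) is
the average motion of the marked tubulin: a mixture over all KMTs crossing
the activation line, each moving at its own tubulin speed `v_tub`. Under
capture-from-spindle recruitment the same pipeline yields speeds
indistinguishable from zero — the qualitative signature that distinguishes
the two recruitment models.

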