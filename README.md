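# insitu2d

In situ two-dimensional (2D) receptor–ligand binding kinetics from the
micropipette adhesion frequency assay, with companion single-cell and
statistical analyses.

The package exists for studies of how membrane context changes a
receptor's ligand binding — the motivating case being an inhibitory IgG
receptor (FcγRIIB) whose disease-associated transmembrane variant (I232T)
tilts toward the plasma membrane and loses binding. It is aimed at
biophysicists running adhesion-frequency experiments and at analysts who
need the downstream statistics of such a study reproducible:

* **2D kinetics** — the probabilistic adhesion model
  `Pa(tc) = 1 − exp{−mr·ml·AcKa·(1 − exp(−koff·tc))}`, fit by
  binomial-weighted nonlinear least squares (or binomial ML) for the
  effective 2D affinity `AcKa` (µm⁴) and off-rate `koff` (s⁻¹), with the
  effective on-rate `Ackon = AcKa × koff`, bootstrap standard errors over
  cell pairs, a detection-limit (ND) path, and fold-change comparisons
  between fits.
* **Stochastic oracle** — an exact immigration–death (Gillespie) bond
  simulator whose `P(≥1 bond)` reproduces the closed form; both modes back
  a seeded generator of whole synthetic experiments.
* **De-quenching FRET** — per-cell efficiency `E = (DQ − Q)/DQ`, group
  summaries (mean, SEM, median) and Welch/Mann–Whitney comparisons.
* **Recessive-model genetics** — parser and validator for published
  `"TT+TC (%)/CC (%)"` count rows, crude odds ratios with Woolf 95% CIs,
  Pearson chi-square, and batch analysis of subphenotype tables.
* **Trajectory geometry** — per-frame membrane-protein descriptors
  (membrane plane fit, TM helix tilt, ectodomain inclination,
  domain–bilayer distance, backbone-segment span, φ/ψ dihedrals, atom-pair
  distances) on multi-model PDB or coordinate-CSV trajectories, plus an
  analytic toy-trajectory builder with known geometry.

See `vignettes/insitu2d-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate an adhesion-frequency experiment at a published parameter set
(`AcKa = 3.03e−7` µm⁴, `koff = 7.75` s⁻¹, both densities 1500 µm⁻², six
contact times × 4 cell pairs × 50 cycles) and refit it:

```r
library(insitu2d)
dens  <- density_pair(mr = 1500, ml = 1500)
truth <- kinetic_params(AcKa = 3.03e-7, koff = 7.75)
cur   <- simulate_adhesion_cycles(truth, dens, seed = 11)
fit   <- fit_adhesion(cur, n_boot = 500, seed = 1)
summary(fit)
#> Adhesion-frequency kinetic fit (wls)
#>   AcKa  = 3.032e-07 um^4 (SE 1.8e-08)
#>   koff  = 6.197 s^-1 (SE 1.2)
#>   Ackon = 1.879e-06 um^4 s^-1 (SE 3.1e-07)
#>   converged: TRUE
#>
#> Per-contact-time fit:
#>   tc n_cycles n_adhesions    Pa fitted   residual
#>  0.1      200          47 0.235 0.2703 -0.0352883
#>  0.2      200          88 0.440 0.3841  0.0559052
#>  0.5      200          94 0.470 0.4787 -0.0086902
#>  1.0      200         100 0.500 0.4938  0.0062133
#>  2.0      200          96 0.480 0.4945 -0.0144875
#>  5.0      200          99 0.495 0.4945  0.0005111
```

The fitted affinity lands on the generating value within its bootstrap SE
(`3.03e-7 ± 0.18e-7` µm⁴); the off-rate is the harder parameter at this
design (here `6.2 ± 1.2` s⁻¹ against a generating 7.75). `plot(fit)` draws
the observed and fitted `Pa` versus contact-time curve, and
`compare_fits(a, b)` reports fold changes between two conditions.

The companion analyses, on synthetic or published inputs:

```r
hi <- simulate_fret_cells(0.40, n_cells = 20, noise_cv = 0.10, group = "232T", seed = 2)
lo <- simulate_fret_cells(0.20, n_cells = 20, noise_cv = 0.10, group = "232I", seed = 1)
cmp <- compare_fret_groups(hi, lo)
#> FRET group 232T: n = 20, mean E = 0.399 (SEM 0.016), median E = 0.410
#> FRET group 232I: n = 20, mean E = 0.202 (SEM 0.015), median E = 0.208
#> fold = 1.98, p = 5.72e-11       (Welch t-test)

crude_odds_ratio(recessive_table(50, 661, 26, 662))
#> Recessive-model association: OR = 1.926 (95% CI 1.185-3.131), chi2 = 7.204, p = 0.007276

traj <- build_toy_trajectory(tilt_deg = 40, incl_deg = 40, d_c1 = 30, span_s218_p221 = 11)
fr <- traj[traj$frame == 1, ]
pl <- membrane_plane(fr, atom = "P")
helix_tilt_angle(fr, pl, "222-248")   # 40.0 deg — and likewise for
                                      # inclination (40.0), C1 height (30.0 A),
                                      # 218-221 span (11.0 A)
```

A two-fold FRET efficiency contrast (≈20% vs ≈40%) with `p < 0.001`, a
crude recessive odds ratio of 1.926 (the published cohort counts), and a
toy trajectory whose geometry the descriptor suite recovers exactly.

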