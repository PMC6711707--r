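---
title: "Models and methods in insitu2d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in insitu2d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insitu2d)
```

`insitu2d` analyses single-cell measurements of membrane receptor function,
built around one estimator — the nonlinear fit of two-dimensional (2D)
receptor–ligand binding kinetics from micropipette adhesion-frequency data —
with three companion analyses (de-quenching FRET efficiency, recessive-model
case–control association, and membrane-protein trajectory geometry) and
seeded synthetic generators for every input. This vignette explains the
models, the assumptions behind them, the numerical choices, and what the
synthetic data do and do not establish about real experiments.

## The probabilistic adhesion model

In the adhesion frequency assay, two apposed cells — one bearing the
receptor at surface density $m_r$, one bearing the ligand at density $m_l$
(both in molecules per µm², calibrated externally and supplied as inputs) —
are brought into contact repeatedly for a preset contact time $t_c$, and
each contact–retraction cycle scores 0/1 for adhesion. Bonds form at a
constant rate proportional to $m_r m_l A_c k_{on}$ and dissociate
independently at rate $k_{off}$ (an immigration–death process). Starting
from zero bonds, the bond count at time $t_c$ is Poisson with mean

$$\langle n \rangle(t_c) = m_r m_l A_c K_a \left(1 - e^{-k_{off} t_c}\right),$$

so the probability of at least one bond — the adhesion probability — is

$$P_a(t_c) = 1 - \exp\!\left\{-m_r m_l A_c K_a \left(1 - e^{-k_{off} t_c}\right)\right\}.$$

Two parameters are estimable: the effective 2D affinity $A_cK_a$ (µm⁴ —
contact area × affinity; the two factors are never separately identifiable,
so the package never reports them apart) and the off-rate $k_{off}$ (s⁻¹).
The effective on-rate is derived exactly as
$A_ck_{on} = A_cK_a \times k_{off}$ (µm⁴ s⁻¹). `mean_bond_number()`,
`adhesion_probability()` and `derive_on_rate()` implement these closed
forms; `simulate_bond_count()` is an exact Gillespie simulation of the same
immigration–death process and serves as an independent stochastic oracle —
its empirical $P(n \ge 1)$ must (and in the tests does) match the closed
form within Monte-Carlo error.

## Fitting

`fit_adhesion()` pools cycles per contact time into observed frequencies
$\hat P_a(t_c)$ and minimises a binomial-weighted least-squares objective

$$\sum_j w_j\left(\hat P_{a,j} - P_a(t_{c,j};\theta)\right)^2,
  \qquad w_j = \frac{n_j}{\max\{\hat P_{a,j}(1-\hat P_{a,j}),\, 1/(4n_j)\}},$$

where $n_j$ is the pooled cycle count at $t_{c,j}$. The floor on the
Bernoulli variance term only engages at observed frequencies of exactly 0
or 1 and keeps weights finite. A binomial maximum-likelihood objective is
available via `method = "mle"`; the two agree well within the bootstrap
standard errors on synthetic data, and a test enforces this.

Numerical choices:

* **Log-parameter space.** Optimisation is over
  $(\log A_cK_a, \log k_{off})$, which enforces positivity and makes the
  objective much better conditioned across the seven orders of magnitude
  separating the two parameters.
* **Deterministic multi-start.** Starts combine a plateau inversion for
  $A_cK_a$ (from the largest observed frequency, clipped away from 0 and 1)
  with $k_{off} \in \{0.1, 1, 10\}$ s⁻¹, each polished by Nelder–Mead then
  BFGS; the best objective value wins. No randomness enters the fit itself.
* **Detection limit.** A curve with no adhesion in any cycle takes the
  not-detectable (ND) path: no numeric parameters are reported.
  `detection_limit_check()` also flags fitted affinities below a
  configurable threshold (default $10^{-8}$ µm⁴, the conventional
  sensitivity floor of the assay).
* **Background.** No nonspecific-adhesion correction is applied by default;
  `background = TRUE` adds a constant nonspecific mean bond count as a
  third fitted log-parameter.

Standard errors come from `bootstrap_errors()`: cell pairs are resampled
with replacement *within* each contact time — the cell pair is the
experimental replication unit — and the fit is repeated (default 1000
resamples; at least 100). At the standard 4-pairs × 50-cycles design the
bootstrap distribution of $k_{off}$ is right-skewed — occasional resamples
leave the short-contact-time points uninformative, and the refit runs to
the edge of the (physically bounded) search box — so the reported SD can
substantially exceed the central 68% spread; $A_cK_a$ is far better
behaved (relative SE typically 2–15%). `compare_fits()` turns two fits into fold changes
with normal-approximation z-tests on the log scale, using the delta-method
conversion $\mathrm{se}(\log x) \approx \mathrm{se}(x)/x$.

## The synthetic experiment generator

`simulate_adhesion_cycles()` emulates the assay at its published design:
contact times 0.1, 0.2, 0.5, 1, 2 and 5 s (the published schedule is
"0.1 … 2 s or longer"; 5 s is past the plateau for off-rates near 8 s⁻¹
and pins the plateau well), 4 cell pairs per contact time, 50 cycles per
pair, and densities around 1500 µm⁻² for both molecules. `closed_form`
mode draws cycles as independent Bernoulli trials at the model $P_a$;
`gillespie` mode simulates every cycle's bond process explicitly. The two
modes agree within binomial error, which is one of the package's core
property tests: it demonstrates the closed form and its stochastic reading
are the same model.

The generator abstracts a cycle to "bond present at $t_c$ or not" — it does
not model impingement force, retraction speed, or cycle-to-cycle memory.
Passing parameter-recovery tests on these data therefore shows the
estimator inverts its own model at realistic noise levels; it does not rule
out real-data complications such as density drift across pairs, multi-bond
species or nonspecific adhesion. At this design (6 × 4 × 50 = 1200 cycles
per experiment), the mean fitted $A_cK_a$ over 25 replicates lands within a
few percent of the generating value, and the mean $k_{off}$ within
roughly 5–10% (it carries a small upward finite-sample bias, well inside
the 20% acceptance band used in the tests).

## De-quenching FRET

Acceptor photobleaching FRET measures the donor intensity before (`Q`,
quenched) and after (`DQ`, de-quenched) destroying the acceptor; the
per-cell efficiency is $E = (DQ - Q)/DQ$ (`fret_efficiency()`), invariant
under joint rescaling of both intensities. Background subtraction is
assumed done upstream; an optional per-cell background column is subtracted
from both intensities when supplied. Cells with $Q \ge DQ$ (photobleach
failure) yield $E \le 0$ and are *flagged, not dropped* — exclusion is an
explicit choice (`drop_nonpositive = TRUE`).

Group comparison (`compare_fret_groups()`) defaults to Welch's *t*-test on
per-cell efficiencies — the common choice for ~20-cell FRET comparisons
with unequal variances — with a Mann–Whitney option; degenerate tiny groups
fall back to the rank test with a warning. Because it is unstated in
practice whether group values are means or medians, summaries report both.

`simulate_fret_cells()` draws `DQ` around a base intensity with
multiplicative lognormal noise (intensities are positive and
gain-dominated) and `Q = DQ (1 - E_{true})` with independent noise of the
same coefficient of variation (default 10%). The lognormal factors are
parameterised to have mean exactly one, so the mean computed efficiency is
an unbiased estimate of the generating efficiency — verified to <1% bias at
1000 cells.

## Recessive-model case–control statistics

The genetics module works on 2×2 tables contrasting homozygous minor-allele
carriers (CC) against all others (TT+TC). `parse_genotype_row()` reads the
published row dialect `"A+B (p1)/C (p2)"` and *validates* it: recomputed
percentages must round (half-up, one decimal — the display convention of
such tables) to the printed ones, so transcription errors fail loudly.
`crude_odds_ratio()` reports the cross-product OR with the Woolf
(log-normal) 95% CI, applying the Haldane–Anscombe +0.5 correction to all
cells (flagged) when any cell is zero — several subphenotype strata are
small, so failing outright would be unhelpful. `pearson_chi2()` computes
$\sum (O-E)^2/E$ with the 1-df chi-square p-value (no continuity correction
by default); a unit test cross-checks it against `chisq.test()`.

These are deliberately *crude* statistics. Published ORs for such cohorts
are typically logistic-regression estimates adjusted for age and sex;
individual-level covariates are not available from printed count tables, so
adjusted estimation is out of scope and the package documents that crude
ORs can differ (e.g. a printed adjusted 2.739 versus a crude 2.00 for the
early-onset stratum). `simulate_genotype_cohort()` generates cohorts under
the recessive odds model
$p_{case} = qOR/(1 + q(OR-1))$; across 1000 replicates at study-scale sizes
the mean crude OR is within 5% of the generating OR and the Woolf CI covers
it at 93–97%.

## Trajectory geometry descriptors

The geometry module computes per-frame descriptors of a membrane-protein
trajectory (multi-model PDB via `read_pdb_trajectory()`, or a plain
coordinate CSV):

* **Membrane plane** — least-squares plane (SVD) through user-selected
  anchor atoms, typically lipid phosphate markers, per frame; or a fixed
  plane for pre-aligned/toy data. The normal points toward +z by default
  (the lab convention of membrane-builder frames). Because that convention
  is not rotation-invariant, `orient_ref` accepts a frame-intrinsic
  reference point (e.g. the ectodomain linker centroid) toward which the
  normal is oriented; with it, all signed descriptors are invariant under
  arbitrary rigid transforms to 1e-6, which is property-tested over 100
  random rotations/translations.
* **Helix tilt** (`helix_tilt_angle()`) — angle between the helix axis and
  the membrane plane in [0°, 90°]. The axis is the first principal axis
  (SVD) of the helix Cα coordinates, oriented N→C; the principal axis is
  the standard estimator, exact on ideal straight helices.
* **Ectodomain inclination** (`ectodomain_inclination()`) — signed angle in
  [−90°, 90°] between the plane and the vector joining the Cα centroid of
  the TM N-terminal residues (222–224) to that of the inter-domain linker
  (130–132); negative points into the bilayer. Cα-only centroids by
  default, all-atom behind `atom = NULL` (the operational choice is
  unstated in practice; Cα is the less mass-biased default). Histograms of
  magnitudes are the usual presentation.
* **Domain–membrane distance** (`domain_membrane_distance()`) — signed
  normal projection from the anchor centroid to the domain centre of mass;
  masses are inferred from the atom name's element letter, with a flagged
  unit-mass fallback for unknown elements.
* **Backbone-segment span** (`segment_normal_length()`) — absolute normal
  separation of two residues' backbone-atom (N, CA, C, O) centroids, e.g.
  the 218–221 stalk segment.
* **Dihedrals** (`backbone_dihedrals()`, `dihedral_angle()`) — standard
  IUPAC φ/ψ, signed in (−180°, 180°].
* **Atom-pair distance** (`atom_pair_distance()`) — nearest-candidate
  Euclidean distance with a hydrogen-bond call at a configurable cutoff
  (default 3.5 Å).
* **Distributions** (`probability_distribution()`) — normalised histograms
  with edges aligned to multiples of the bin width (defaults used in
  examples: 2° for angles, 0.5 Å for distances) and the modal bin reported.

`build_toy_trajectory()` constructs frames with *known* geometry — a
phosphate grid at z = 0, a straight TM pseudo-helix at a requested tilt,
linker/domain markers realising a requested inclination and height, and a
218/221 backbone pair at a requested span — optionally with per-atom
Gaussian jitter. Jitter-free constructions are recovered by the descriptors
to 1e-6, and jittered ones fluctuate around the construction values; that
round-trip, not any reproduction of real simulation ensembles (original
trajectories of this kind are generally not deposited), is what the tests
establish. Frame-range/stride windowing of a production trajectory is left
to generic subsetting of the trajectory table.

## Problem sizes and determinism

Every stochastic routine takes an explicit integer seed and is bitwise
reproducible given it. The default test and acceptance workloads were
chosen as the smallest sizes at which the statistical checks are sharp:
25 replicate experiments per kinetic condition (the replicate-mean
comparisons), 2000 cycles for closed-form/Gillespie equivalence, 10,000
draws for the Poisson marginal check, 1000 cohorts for OR calibration and
CI coverage, 200 jittered frames and 100 random rigid transforms for the
geometry properties. All run in seconds on one CPU.

## Known limitations

* Single bond species, constant formation rate: no multi-bond mixtures,
  catch bonds, or force-dependent off-rates, and no bond-lifetime
  (force-clamp) analysis.
* Densities are trusted inputs; no calibration-bead processing.
* FRET is analysed at per-cell intensity level: no image processing,
  bleed-through correction, or Förster-distance modelling.
* Genetics: recessive model only — no allelic/genotypic trend models,
  Hardy–Weinberg testing, covariate adjustment, or multiplicity correction
  across subphenotypes.
* Geometry: descriptors only — no trajectory alignment/RMSD machinery, no
  lipid-order or membrane-thickness analysis.
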