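---
title: "Models and methods behind the lungwater toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the lungwater toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lungwater)
```

This vignette is the package's own account of the science it implements:
the signal physics that makes proton-density lung imaging quantitative,
the digital phantoms and forward model used to exercise it, the
reconstruction and motion-rejection machinery, and the statistical layer
for ordered cohorts. It also records the design decisions that were
genuinely open, and what the synthetic experiments do and do not show
about real data.

## 1. The spoiled gradient-echo signal model

A UTE lung-water sequence excites repeatedly with a constant small flip
angle $\alpha$ and repetition time $TR$, reading out each excitation at
echo times $TE_e$ starting near zero. Under ideal spoiling (all transverse
magnetization destroyed before the next pulse) the steady-state signal is

$$S = PD \cdot \sin\alpha \,\frac{1 - E_1}{1 - E_1\cos\alpha}\,
      e^{-TE/T_2^*}, \qquad E_1 = e^{-TR/T_1}.$$

`spgr_signal()` evaluates this closed form; `bloch_simulate()` iterates the
underlying longitudinal recursion
$M_z^{(n+1)} = PD + (M_z^{(n)}\cos\alpha - PD)E_1$ and serves as the
independent numerical check (the test suite requires agreement to a
relative tolerance of $10^{-3}$ across a grid of $\alpha$, $TR$, $T_1$).
The simulator flags non-convergence when the last two repetitions differ
by more than $10^{-6}$ relative; the practical warm-up guidance is at
least $5\,T_1/TR$ excitations, and more like $15\,T_1/TR$ when the
$10^{-6}$ criterion itself must be met.

As $\alpha \to 0$, $S/\sin\alpha \to PD\,e^{-TE/T_2^*}$ independently of
$T_1$: this is why a 5° flip angle makes the lung signal approximately
proportional to water content even though $T_1$ varies with it. Fat is
modelled as a second pool (fixed $T_1 = 300$ ms, $T_2^* = 30$ ms) that is
perfectly suppressed when fat saturation is on; RF-spoiling phase cycling,
slice profiles and off-resonance are out of scope.

**Sequence defaults** (all configurable): flip 5°, $TR$ 5 ms, echoes at
0.1 / 1.2 / 2.3 ms. The flip angle is the sequence's stated operating
point; the timing values are representative multiecho-UTE numbers chosen
once and used throughout.

**Lung tissue model.** `lung_tissue_model(w)` sets $PD = w$ and
interpolates the relaxation *rates* linearly in $w$ between a
dry-parenchyma anchor ($T_1 = 1100$ ms, $T_2^* = 0.5$ ms, applied at
$w = 0$) and a free-water anchor ($T_1 = 3000$ ms, $T_2^* = 50$ ms at
$w = 1$). Rate interpolation is the fast-exchange mixing rule, and pinning
the anchors at the interval endpoints keeps the rule simple: the midpoint
rate is exactly the mean of the anchor rates. Only the *conclusion* that
the low-flip-angle signal is near-linear in $w$ is asserted by tests —
the anchors themselves are order-of-magnitude literature values.

## 2. Digital phantoms

**Sponge** (`make_sponge`). A Gaussian-smoothed periodic random field is
thresholded by rank so that exactly a `fill_fraction` of pixels become
water-filled pores ($w = 1$) and the rest matrix ($w = 0$). A fill sweep
at a *fixed seed* reuses one pore texture with nested thresholds — the
digital analog of progressively doping a single physical sponge — which is
what makes the mean water content, and hence the reconstructed ROI signal,
track the fill fraction closely. Defaults: 128² grid over a 160 mm field
of view, pore correlation length 4 px.

**Thorax slice** (`make_thorax`). An axial slice at the level of the
pulmonary arteries built from analytic ellipses: chest wall
(170×120 mm on a 400 mm FOV), two lungs (48×88 mm at ±90 mm), heart
(40×35 mm), and optionally a pleural effusion (28×22 mm) placed
posterior-basally *inside* the right lung — effusions accompany the most
severe phenotype and are included in the lung ROI by default. Ellipses
give two things: exact containment relationships (each region lies inside
its parent), and exact closed-form Fourier transforms, so the acquisition
model can be tested at oracle level. The geometry is identical across
water fractions; only the lung tissue parameters change.

**Motion** (`motion_model`, `displace`). Rigid in-plane translation only:
a sinusoidal superior–inferior breathing term (amplitude in mm, period in
s) plus, with probability `jitter_burst_probability` per sampling event, a
jitter burst — a random direction and a random magnitude up to
`jitter_amplitude_mm`. Jitter is a deterministic function of
`(seed, time)`, so any timestamp can be revisited reproducibly. The
canonical exercise condition used by the motion tests is bursts of up to
15 mm with probability 0.2 per spoke: pedaling-scale bulk displacement.
At millimeter-scale amplitudes spoke rejection has nothing to win —
discarding a spoke then costs about as much information as the corruption
itself — so the artifact-suppression contract is exercised in the
strong-corruption regime where it is meaningful.

## 3. Golden-angle radial acquisition

`golden_angle_trajectory()` advances center-out spokes by the golden angle
$\Delta = \pi(\sqrt 5 - 1)/2$ rad $= 111.2461°$, the constant conventional
in golden-angle radial MRI, accumulated over the full $2\pi$ since
radial-out spokes are half-lines. Any golden-ratio rotation shares the
relevant property — near-uniform angular coverage for every spoke count
(for 377 spokes the largest angular gap is within a factor 1.9 of the mean
gap) — and the increment is a single constant should a different
convention be preferred.

`sample_kspace()` computes, for each spoke, echo and sample, the continuous
Fourier transform of the signal-weighted phantom: by summed ellipse
transforms $ab\,J_1(2\pi\rho)/\rho$ (with amplitude differences along the
containment tree) for thorax-type phantoms, and by a discrete Fourier
evaluation on the sponge's fine grid — kept at least 2× finer than the
reconstruction grid so forward and inverse models never share a
discretization. Motion enters as the exact phase ramp
$e^{-2\pi i\,\mathbf k\cdot\mathbf d(t)}$ of the spoke-time displacement;
complex white Gaussian noise is seeded and reproducible.

## 4. Reconstruction and motion rejection

`grid_reconstruct()` approximates the conjugate-phase sum
$f(\mathbf r) = \sum_j w_j F_j e^{+2\pi i \mathbf k_j\cdot\mathbf r}$ by
Kaiser-Bessel gridding (width 4 cells, Beatty shape parameter) onto a
2× oversampled grid, inverse FFT, deapodization by the FFT of the sampled
kernel, and central cropping. Density weights $w_j$ are polar area
elements: sample $j$ on a spoke gets $r_j\,\Delta k\,2\pi/n_{spokes}$,
the shared center sample the central disk area split across spokes, and
the outermost sample a half-width cell. An iterative Pipe-Menon mode is
available; it converges to the same weights up to normalization and to
near-constant weights on uniformly dense sampling. On ≤ 32² problems the
gridded image agrees with the explicit conjugate-phase oracle to a
normalized RMS difference well below the 0.05 test bound, and a fully
sampled disk's interior amplitude is recovered within 5%.

**Spoke-consistency filter.** Rigid in-plane motion leaves every k-space
*magnitude* unchanged — translation is a pure phase ramp — so consistency
must be judged on complex values. Each spoke's low-frequency profile
($|k| \le k_{max}/4$) is predicted by linear interpolation in angle
between flanking spokes; because golden-angle neighbors in *angle* are far
apart in *time*, a motion burst corrupts a spoke but not its reference.
The deviation is normalized by the product of the two angular offsets
(making the clean-spoke error, which is second-order in spacing,
homogeneous), minimized over several flanking pairs, and re-scored up to
three times with already-flagged spokes excluded, so a corrupted neighbor
cannot indict a clean spoke. Spokes scoring more than
`motion_filter_threshold` (default 3) median-absolute-deviations above the
median are rejected; if every spoke is rejected the filter errors and asks
for a higher threshold rather than returning an empty reconstruction.
After rejection, density compensation is recomputed with gap-aware
azimuthal cells over the surviving angles — without this, the holes left
by rejected spokes cost more than the rejected corruption. Reconstruction
at 2× oversampling with central cropping additionally keeps residual
streak energy of discarded spokes preferentially outside the cropped
anatomy. A static noise-free acquisition rejects nothing, and an infinite
threshold reproduces the unfiltered reconstruction exactly.

**Multiecho combination.** `first_echo` uses the echo-1 magnitude;
`te0_extrapolation` fits $\log S$ against $TE$ per pixel and extrapolates
to $TE = 0$ — exact for noise-free mono-exponential decay — falling back
per pixel to the first echo when any echo magnitude is within $10^{-6}$ of
zero relative to the image peak (the fallback mask is reported).

## 5. Quantitation

The default ROI statistic is the **sum** over the lung mask: the study's
arbitrary-unit scale (changes of hundreds of AU against baselines near
$10^4$) is that of integrated, not averaged, ROI signal; `mean` and
`median` are available. Rest and stress ROIs are contoured independently,
mirroring the manual workflow, and no coregistration is applied. The
change quantities satisfy their defining identities exactly
($\Delta = S_{stress} - S_{rest}$, $\Delta\% = 100\,\Delta/S_{rest}$; a
zero rest signal is an error, not an `Inf`). Bland-Altman limits are
$\mathrm{bias} \pm 1.96\,SD$ of the paired differences with the $n-1$
denominator. The look-up table maps the display window linearly onto
0…255 with round-half-to-even (the exact midpoint maps to 128).

The end-to-end sponge experiment (`phantom_linearity_experiment`)
generates, acquires, reconstructs and measures ≥ 5 fill fractions with a
centered disk ROI of radius 0.4 × FOV — large enough that the local pore
statistics are representative of the enforced global fill. The acceptance
suite runs 8 fractions spanning 0.05–0.5 with 200 spokes on a 64² grid.

## 6. Cardiac metrics

Volume–time curves (≥ 10 phases, one cardiac cycle) are smoothed with a
Savitzky-Golay local quadratic over 5 phases and differentiated by central
differences; the peak filling rate is the maximum of $dV/dt$ on the limb
from the global volume minimum (end systole) to the end of the cycle,
which includes diastasis. A monotone curve has no filling limb and errors.
Normalization `per_edv` divides by the curve maximum, giving EDV/s. The
smoothing window is the shortest that usefully suppresses noise at 30–40
phases; with cosine test curves at 30 phases and 1 mL noise the 20-seed
mean recovers the analytic peak within 10%, which is how the Monte-Carlo
checks are framed. Chamber summaries (EDV, ESV, SV, EF, SV/ESV) are exact
identities of the curve extrema; reserve metrics are stress-minus-rest
deltas of matched chambers.

The PCr/ATP operation applies the blood correction first — subtracting
`blood_coefficient` times the 2,3-DPG amplitude from ATP, since DPG is a
pure blood signal — then the partial-saturation factors. Both are
configuration with identity defaults: the literature values they take in
practice live in the references of the originating studies, not in this
code, and a corrected ATP amplitude ≤ 0 is an error naming the blood
correction as the cause.

## 7. Cohort statistics

Groups are ordered control < T2D < HFpEF < amyloid throughout; large
Jonckheere-Terpstra $J$ means the metric *increases* along that ordering,
and ties count ½. The exact method enumerates the full multinomial
permutation null (total $n \le 12$); the permutation method uses seeded
label resampling (≥ 10⁴ by default); the normal approximation uses the
tie-corrected mean and variance. The permutation test's type-I error at
nominal 0.05 is verified to lie in [0.03, 0.07] over 1000 null
simulations.

The signed-rank test drops zero differences (standard convention, count
reported), computes the exact null by convolution over doubled ranks — so
ties are handled exactly — for $n \le 20$, and a tie- and
continuity-corrected normal approximation beyond. With fewer than 5
non-zero differences the statistic is returned but the p-value refused.
Kruskal-Wallis omnibus testing delegates to `stats::kruskal.test`; Dunn
post hoc z statistics are computed from rank means with tie correction and
Holm-adjusted by default (the adjustment is configurable since no method
is canonical here). Identical values across all groups short-circuit to
$H = 0$, $p = 1$ rather than a 0/0.

**Mediation** follows the product-of-coefficients scheme: path $a$ from
$m \sim x$, path $b$ and the direct effect from $y \sim x + m$, indirect
effect $ab$, with a case-resampling bootstrap (≥ 1000 resamples; 5000 is
the reference analysis size) and a **bias-corrected** (BC, not BCa)
percentile interval — matching the stated interval type; the acceleration
constant is omitted. Variables enter raw, not standardized. One mediator
is tested per call; the three moderator analyses of the reference study
are three calls. Regressions inside the bootstrap use `.lm.fit` for speed;
singular designs error at fit time, and a resample that degenerates is
dropped (the effective resample count is reported).

**Synthetic cohorts** (`synthesize_cohort`) draw each group × metric from
a normal with the target median and IQR/1.349 scale, evaluated on
stratified uniforms so the sample median is pinned near its target (well
within a quarter of the group scale at $n \ge 50$) while still varying
across seeds. Default group sizes are the reference design's 11/9/14/9.
The PCr/ATP and lung-water targets are the reference group medians and
IQRs; E/e′ interpolates plausibly between the reference extremes (9.5 and
12.5 for the middle groups), and the exercise-reserve deltas are graded
plausible values (ΔRVEF +4/+2/0/−3 points, ΔRA −3/+2/+8/+14 mL) chosen
once for testing. Metrics are drawn independently *within* groups: between-metric
correlation arises only through the shared severity gradient, which is
sufficient for trend and mediation testing but weaker than the
within-group physiology of real patients.

## 8. What the synthetic experiments show — and don't

Passing tests establish that the implementation is faithful to its models:
the signal code matches Bloch dynamics, the sampling code matches analytic
transforms, gridding matches direct reconstruction, the exact tests match
brute-force enumeration, and the estimators recover the parameters of data
generated *by the package's own generators*. They do not establish
performance on real lungs: the phantoms are 2D, piecewise-constant and
rigidly moving; there is one uniform coil, no $B_0$ inhomogeneity, no
flow, no deformation; and the cohort generator has no confounding
structure. The clinical group medians, correlations and mediation
coefficients of the motivating study derive from patient data and are not
reproducible here; what is reproduced is the *machinery* — including the
sponge-linearity figure of merit and the PCr/ATP deficit arithmetic — under
stated, seeded conditions.

## 9. Problem sizes

The test and acceptance suites run, on one CPU, with: 128² phantom
rasters, 64² reconstructions (32² for oracle comparisons), 200 spokes × 65
samples × 3 echoes, 8-point fill sweeps, 10-seed motion experiments,
1000-simulation size checks, 200-repetition coverage checks with 1000
bootstrap resamples each, and 20-seed filling-rate recovery — sizes chosen
so every claim is exercised end to end while the whole suite stays
comfortably interactive.
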