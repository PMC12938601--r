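---
title: "Independent event-related brain dynamics for motor-imagery EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Independent event-related brain dynamics for motor-imagery EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor-imagery brain-computer interfaces (MI-BCIs) ask a user to imagine
moving the left or the right hand and decode which from EEG. A majority of
users reach accuracies that exceed chance but are too low for reliable
control, and many of those show an *asymmetric* profile: usable EEG
modulation for one hand only. `erdica` characterizes individual users
neurophysiologically rather than through classifier accuracy. It isolates,
per user and task class, the independent components (ICs) carrying
contralateral event-related desynchronization (ERD) and ipsilateral
event-related synchronization (ERS), quantifies them (ERD%, relative
mu/beta power, significant-region area and latency), scores inter-class
separability on the Riemannian manifold of trial covariances (ClassDis),
and stratifies users into four proficiency groups: `good`, `LgoodRpoor`,
`LpoorRgood`, `poor`.

## Pipeline and models

### Preprocessing

A 30-channel subset over frontal, central and parietal scalp is band-pass
filtered to 8–30 Hz with a zero-phase Hamming-windowed sinc FIR filter.
The transition bandwidth is 25% of each band edge, the order follows the
Hamming design rule (≈ 3.3/Δf normalized) rounded up to even, and the
symmetric kernel is applied in a single forward pass with group-delay
compensation — not forward-backward filtering, so the documented impulse
response is exactly the designed kernel. Epochs span [−1, 4) s around the
task prompt (prompt at sample 0, half-open window); [−1, 0) s is the
reference interval.

Four rejection criteria run in order, and the first that fires is logged
per trial: (1) absolute amplitude above ±25 µV on any channel; (2) linear
trend — per-channel OLS line with drift above 50 µV per epoch *and* R²
above 0.3 (the conjunction is the standard reading of the two numbers);
(3) improbability/abnormal distribution — per-trial per-channel mean log
empirical density (joint log-probability) and excess kurtosis, z-scored
across trials, thresholded at 5 SD both per channel and pooled over
channels; (4) abnormal spectrum — per-epoch Welch spectrum deviating more
than ±25 dB from the across-trial mean anywhere in 8–30 Hz. Stages 3–4
compute their reference statistics over the trials surviving earlier
stages, which is what makes rejection idempotent in practice. Note a
structural consequence of the ordering: a drift large enough to fire the
trend rule necessarily exceeds the ±25 µV amplitude rule first, so on
band-passed data the trend stage acts as a safety net rather than the
primary screen. The amplitude rule is applied to the band-passed signal,
as the pipeline order implies.

### Per-class Infomax ICA

Each task class (left-hand, right-hand imagery) is decomposed separately.
We use natural-gradient Infomax with the logistic nonlinearity, PCA
sphering to full rank (30 in → 30 out), randomized block updates (block
512, initial rate 0.1), learning-rate annealing by the angle between
successive updates (factor 0.9 beyond 60°) plus geometric late-phase
cooling (0.96 per pass after pass 100), a divergence guard that halves
the rate and restarts, and a convergence tolerance of 1e-6 on the
per-weight RMS change with a 200-pass budget (the pipeline
configuration uses 150 passes, where isolation quality on the synthetic
cohorts has saturated). The inner loop is compiled (RcppArmadillo);
block order comes from R's RNG, so results are reproducible under the
forked seeds. Extended (sub-Gaussian) Infomax is off:
band-passed oscillatory EEG sources are super-Gaussian. Scale and sign
indeterminacy are fixed by unit-norm topographies with a positive largest
weight; components are ordered by mean projected variance. A fixed seed
forked per (subject, task) from the configuration seed makes cohorts
reproducible. The same four rejection criteria are then applied to the IC
activations — screened in sensor-referred units (each activation scaled
by its largest topography weight, the biggest contribution any electrode
sees) so the microvolt amplitude threshold keeps its meaning for
unit-norm-topography components; a trial rejected in any component is
removed everywhere.

Components are screened twice before profiling: topographies dominated by
one electrode (max |w| / Σ|w| > 0.6) are discarded as non-neural, and an
equivalent current dipole is fitted to each remaining topography with
components above 15% residual variance discarded.

### Dipole fitting in a concentric-sphere model

The head model is four concentric shells (brain/CSF/skull/scalp, radii
71/72/79/85 mm, conductivities 0.33/1.0/0.0042/0.33 S/m) with an
idealized spherical 10-10 montage. The forward solution is assembled per
spherical-harmonic degree: within each shell the radial potential is
`A r^n + B r^-(n+1)`, the dipole contributes the free-space singular term
in the innermost shell, and continuity of potential and radial current at
the interfaces plus zero current outflow at the scalp yield a small
linear system per degree, solved numerically with radii normalized to the
scalp radius for conditioning. The angular part uses the multipole
expansion of the dipole potential written without associated-Legendre
sign conventions (the tangential term multiplies `m·(ê − cosγ p̂)` by
`P_n'(cosγ)`), and the test suite verifies the series against the exact
free-space dipole potential and the homogeneous-sphere closed form.
Dipole fitting minimizes residual variance over position only (the moment
is solved linearly at each candidate): a coarse pass over a cached 12-mm
grid followed by Nelder-Mead refinement. Since the selection rules only
need hemisphere and coarse region membership, region tests use an
editable table of axis-aligned boxes per Brodmann-area group (shipped as
`inst/extdata/motor_atlas.csv`); no published atlas is imitated, and
users needing template-accurate membership should supply their own table.
Midline boxes (SMA, anterior cingulate) match either hemisphere.

### Spectral parameterization

Each IC's trial-averaged Welch spectrum (2-s Hamming segments, 50%
overlap, 0.5 Hz resolution) is modeled in log10 power as an aperiodic
part `b − log10(k + f^χ)` plus Gaussian peaks `a·exp(−(f−c)²/2w²)`. The
knee is fixed at `k = 0` by default: over a 3–40 Hz (or in-pipeline
8–30 Hz) range the knee is rarely identifiable. The aperiodic part is
fitted robustly — an initial fit, then a refit restricted to the lower
envelope (points within the 2.5th percentile of the positive flattened
residuals) — then peaks are extracted iteratively from the flattened
spectrum (largest residual first, half-height width initialization),
jointly refined by bounded L-BFGS-B, the aperiodic part refitted on the
peak-subtracted spectrum, and the peaks refined once more. Peaks need
`a ≥ 0.1` log-units and `0.5 ≤ w ≤ 6` Hz; this keeps noise wiggles from
becoming "relative power". The *dominant peak* in 8–30 Hz defines
relative mu/beta power (`a`, in log10 power above the aperiodic fit),
center frequency, and two-sided width `2w`; amplitude ties prefer the
lower center frequency (mu over beta). Inside the pipeline the fit range
is the filter passband (8–30 Hz): fitting a wider range on band-limited
data would turn the filter skirts into a spurious giant "peak".

### Time-frequency maps, ERD/ERS%, and significance

IC activations are decomposed with a 3-cycle complex Morlet wavelet
(Gaussian envelope, σ_t = n_cycles/2πf) at 8–30 Hz in 1 Hz steps via FFT
convolution; per-trial power is averaged into resels of 1 Hz × 25 ms.
Samples where the wavelet support (±3.5 σ_t) overruns the epoch are
invalid per frequency and excluded from baselines and regions. The
percent-change map is `(P − R)/R × 100` with `R` the per-frequency mean
baseline power. The scalar ERD%/ERS% is the percent change of the *band
power* (power averaged over the band first, then referenced to its
baseline) averaged over [0, 4) s, restricted to columns where every band
row is valid — averaging per-frequency ratios instead would let
low-power leakage rows dominate, and a time-varying valid-row composition
would bias even a pure tone. The scalar is a plain, unrectified mean: the
selected contralateral IC yields a negative value (ERD%), the ipsilateral
IC a positive one (ERS%).

Significance: per resel, a pseudo-T contrasts per-trial power against the
trial's mean baseline power (paired mean difference over its standard
error). The null distribution is built per frequency by random sampling
within the reference interval — each resample draws, per trial, a
pseudo test value from the baseline resels and a pseudo baseline as the
mean of a with-replacement resample of the trial's 100-ms baseline blocks
(blocks respect the autocorrelation the wavelet imposes). Two-sided
p-values (add-one rule) are Benjamini-Hochberg corrected across all valid
resels and masked at q ≤ 0.05. The add-one rule floors p at 1/(R+1),
which interacts with BH: at the function default of R = 200 resamples
on a 25-ms grid (~4600 resels) the smallest detectable region is ~460
resels, so isolated effects cannot survive and only extended ones can.
The pipeline therefore runs the selection stage at 500 resamples on a
1 Hz × 100 ms grid (~1075 resels, minimum region ~43), a deliberately
more sensitive operating point for contralateral ERD; both knobs are
configuration fields. Small true ERS patches are still often (correctly
per the procedure) not significant, matching the empirical rarity of
significant ERS. Significant resels are grouped by
4-connectivity (time and frequency neighbors, no diagonals); each
region's sign comes from its mean percent change, its area is the resel
count, its latency the earliest member time.

### Selection rules

For each task class, the contralateral-ERD IC is chosen by: (1) dipole in
a contralateral motor-imagery-related region; (2) among survivors, the
top three by relative mu/beta power (ICs without an in-band peak carry
−∞ and rank last, but remain selectable by the fallback so a candidate
always exists); (3) of those, the largest significant-ERD region area;
if none has significant ERD, the highest relative power. The
ipsilateral-ERS IC: (1) dipole ipsilateral; (2) a prominent in-band peak
— a hard gate, operationalized as the dominant peak's presence under the
acceptance thresholds above; (3) largest significant-ERS area, falling
back to highest relative power. Ties: equal relative power → lower center
frequency; equal area → larger |mean change|; then lower IC index. An
optional relaxation (`relax_rule2`, off by default) falls back to all
Rule-1 survivors when the peak gate empties the candidate set. Both
rankings use the in-band dominant peak (not the whole-spectrum maximum).
The expensive significance maps are computed lazily, only for the
components the rules can actually consult.

### ClassDis

Per-trial sample covariances of the 30 preprocessed channels over
[0, 4) s (sensor space — the separability score describes the EEG
patterns a decoder would see, not the selected ICs), shrunk by 0.05
toward the scaled identity for guaranteed positive definiteness. With
`δ_R` the affine-invariant Riemannian distance (Frobenius norm of
`logm(P^-1/2 Q P^-1/2)`) and `P̄` the Fréchet mean (iterated
tangent-space averaging), ClassDis = δ_R(P̄_A, P̄_B) / ½(σ_A + σ_B),
where σ is the mean Riemannian distance of a class's trial covariances
to its mean — the "mean absolute deviation" realized in the same metric
as the numerator, keeping the ratio dimensionless. Degenerate cases:
identical classes → 0; zero dispersion with separated means → +Inf with
a warning.

### Features, regression, stratification

The eight features are ERD%, ERS%, relative ERD power and relative ERS
power for each imagery side, taken from the four selected ICs; a selected
IC without an in-band peak contributes relative power 0 and is flagged.
ClassDis is regressed on the eight features by OLS (coefficient t tests,
overall F, adjusted R², standardized β from z-scored variables), with
10-fold cross-validation (seeded fold assignment; MAE/RMSE pooled over
all held-out predictions). Stratification clusters each hand separately:
k-means (k = 2, 20 restarts, fixed seed) on the z-scored triplet {ERD%,
relative ERS power, ClassDis} for that hand — z-scoring because the
features are on incommensurate scales — labeling the higher-mean-ClassDis
cluster `good`; the two per-hand labels combine into the four groups.
Group statistics per headline feature: Levene's test (α 0.05,
median-centered) gates classic one-way ANOVA with Tukey-Kramer post hocs
(unequal-n studentized range) versus Welch's ANOVA with Games-Howell post
hocs (Welch-Satterthwaite degrees of freedom); both post hocs are
computed from their textbook formulas and the Tukey-Kramer path is
cross-checked against `stats::TukeyHSD` in the test suite. No
multiple-testing correction is applied across the four features (flagged
here deliberately). Paired within-group t tests compare left- versus
right-hand ERD% and relative ERS power.

## The synthetic-data generator

The generator is the package's test bed: it plants known structure that
every downstream stage must recover. Each subject is a continuous
30-channel record at 160 Hz of interleaved left/right imagery trials
(4.2 s imagery, 4.2 s rest; 45 per hand by default, matching three
15-trial runs). Each hemisphere hosts two mu patches: a lower-mu
(≈11 Hz) ERD patch whose output drops by `erd_depth` during
contralateral-hand imagery (full-period envelope with 0.1-s cosine
ramps), and an upper-mu (≈12 Hz) ERS patch, ~20 mm posterior, whose
output rises by `ers_gain` over a random 1–2 s sub-interval per
ipsilateral-hand trial — emulating the observation that ERS rarely
persists through the task period. The posterior offset matters: nearly
coincident dipoles have nearly collinear mixing columns, which makes
the two mu sources unidentifiable for ICA no matter how independent
their time courses are. Oscillations are amplitude-modulated narrowband
noise (2.5 Hz bandwidth, lognormal burst envelope, sigma 0.45 with
≈0.15 s coherence): realistic mu burstiness, and the strongly
super-Gaussian marginals Infomax separation quality depends on. Each
patch also emits its own 1/f broadband floor, modulated by the same
task envelope, so a component's fitted peak height above its own
aperiodic floor directly encodes the patch's oscillation-to-background
ratio; ERD patches are broader-spectrum (floor scale 4.5) than the
cleaner upper-mu ERS patches (0.8). Eight further aperiodic background
sources realize 1/f spectra (random phases on the target amplitude
spectrum) at non-motor grid locations; all sources mix through the
analytic forward solution with unit-norm columns, plus white sensor
noise (0.4 µV — low enough that genuine mu bursts respect the ±25 µV
rejection bound) and occasional in-band artifact bursts (rate 0.1 —
roughly the per-stage rejection rate reported for the real dataset).

Oscillation amplitudes are coupled to proficiency: ERD sources at
`2.6·(0.6 + 0.8·depth)` µV and ERS sources at `4.2·(0.1 + 1.5·gain)` µV.
The coupling encodes the empirical pattern that proficient users carry
prominent upper-mu peaks while weak synchronizers lack them; it is also
what makes the planted group structure recoverable through the selection
rules, because the ipsilateral rule's power fallback must find a tall
ERS peak exactly on the sides where proficiency is planted, and a
suppressed lower-mu peak everywhere else. The four group profiles are:
`good` (depth 0.5 / gain 0.6 both hands), `LgoodRpoor` (0.5/0.6 left
hand, 0.1/0.08 right), `LpoorRgood` mirrored, `poor` (0.08/0.05).
Cohorts jitter depths and gains ±15% and the aperiodic exponent ±0.2
under per-subject seeds forked from the cohort seed; the lower-mu
center is jittered ±0.4 Hz and the upper-mu center placed 1.0–1.6 Hz
above it, keeping the two rhythms spectrally distinct in every subject
(letting them collide makes the two patches unresolvable).

What the generator does *not* emulate: realistic BEM/MRI head geometry,
eye-blink or EMG artifact physics (artifacts are in-band bursts only),
non-stationary background, volume-conducted bilateral sources, or
electrode noise correlations. Passing tests therefore demonstrate that
the pipeline's logic and numerics recover planted structure through a
linear instantaneous forward model — not that it is robust to every
failure mode of real recordings.

## Numerical choices and degenerate inputs

* FIR: even order, integer group delay; FFT convolution.
* Morlet edge handling: per-frequency invalid margins; baselines, scalar
  windows and region membership all exclude invalid resels.
* Pseudo-T: add-one p-values; standard errors floored at machine epsilon;
  at least 2 trials enforced, fewer than 10 warned.
* Spectral fit: bounded parameters (w within limits, c within range);
  peaks fitted but out of bounds are dropped at the end; fit failures in
  profiling yield `peak_present = FALSE` with relative power −∞ rather
  than dropping the component.
* Riemannian operations go through symmetric eigendecompositions; the
  Fréchet iteration starts at the arithmetic mean and reports
  convergence; ClassDis treats dispersion below 1e-10 (relative) as zero.
* k-means degenerate input (all features identical) warns and assigns a
  single cluster; ptukey NaNs (zero within-group variance) propagate as
  NA p-values rather than failing.
* EDF: 16-bit with per-channel symmetric physical ranges; data are padded
  to whole-second records; events ride an EDF+ annotations channel.

## Problem sizes in the test suite

The acceptance-level tests use: 100 synthetic spectra for parameter
recovery; 200 null maps (20 trials each) for the type-I check and 20
planted-ERD runs (40 trials) for power, both at the erdmap defaults
(200 resamples, 25-ms resels); 1000 random masks against the flood-fill
oracle; 20 source-space positions for dipole self-consistency; 1000
replicates for the ANOVA/Welch null; and a 40-subject cohort at the
generator's default 45 trials per hand for end-to-end recovery. These
sizes are the package's choice of a thorough-but-routine regression
suite; the generator's scientific defaults (45 trials per hand etc.) are
unchanged by them.

## Known limitations

* The spherical head model and box atlas give coarse localization only;
  reported coordinates are model coordinates, not template MNI.
* The pseudo-T null is one concrete instantiation of reference-interval
  resampling; other choices (cluster-mass permutation, parametric tails)
  would alter sensitivity, particularly for small ERS patches.
* Relative power depends on the IC's internal signal-to-background
  ratio, which ICA quality modulates; between-subject comparisons assume
  comparable decomposition quality.
* The regression is explanatory, not predictive; with eight correlated
  features its individual coefficients are interpretable only
  directionally.
* Group statistics apply no correction across features.
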