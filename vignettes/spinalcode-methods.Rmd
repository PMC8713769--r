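---
title: "Models and methods behind spinalcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinalcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalcode)
```

`spinalcode` quantifies how well a spinal sensorimotor circuit represents a
mechanical stimulus, stage by stage, and how chronic oxaliplatin
neurotoxicity (cOIN) degrades that representation. This vignette documents
the models, the tunable parameters, and the design decisions in one place —
including what the synthetic-data generator does and does not emulate, which
bounds what a passing test suite can claim about real recordings.

## Stimuli and the passive muscle

Stretch commands are displacements (mm) from resting muscle length L_o on a
uniform clock (default 10 kHz, a config knob). Ramp-hold-release rises at a
constant velocity, holds, and releases at the same velocity — the release
rate is assumed symmetric with the rise because only the rise velocity is a
controlled protocol parameter. Vibration is a sinusoid of amplitude half the
peak-to-peak excursion; requests under 10 samples per cycle are rejected.
A baseline-offset parameter models increased background muscle length.

The nonreflexive muscle's restoring force is modelled as

$$F(t) = k\,x(t) + c\,[\dot x * g](t), \qquad
  g(t) = \sum_i \frac{f_i}{\tau_i} e^{-t/\tau_i},\ \sum_i f_i = 1,$$

a linear elastic term plus a viscous branch whose stress relaxes through a
unit-area two-exponential kernel (defaults $k = 5$ au/mm, $c = 0.2$ au per
mm/s, $\tau = 0.05, 0.5$ s with weights 0.7/0.3). This is the simplest
passive model that reproduces the characteristic force trace: a ramp
overshoot that grows with stretch velocity and a static plateau equal to
$k \times$ amplitude. Hill-type active mechanics and fusimotor drive are
deliberately out of scope. Each exponential is implemented as a recursive
first-order filter, so the simulation is O(n) and exactly reproducible.

Analysis windows are anchored at the stretch command onset: a 150 ms
*dynamic* window followed by a 1 s *static* window, disjoint by
construction.

## The synthetic-data generator

The generator defines the study conditions; it is parameterized once and
not tuned per analysis. Firing of a sensory neuron follows a rate model on
the encoded variable $e(t)$ (muscle length for Ia/I_un/II, simulated force
for Ib, skin-probe force for cutaneous classes):

$$r(t) = g_d \,[\dot e(t)]_+ \;+\; g_s\,[e(t) - \theta]_+\,
         e^{-(t - t_\mathrm{hold})/\tau_a},$$

gated to zero while $e(t) < \theta$ (the detection threshold) and after the
class's static cessation time (measured from hold onset), with the first
stretch of a repeated sequence scaled by a history-dependence factor
(default 1.5 — the magnitude of first-trial facilitation is not an anchored
value). Spikes are drawn by time rescaling with gamma-distributed rescaled
intervals (shape $1/\mathrm{CV}^2$), so the interspike CV is a direct knob;
the default CV of 0.1 matches near-regular sensory firing and CV = 0 makes
tests exactly deterministic. A spike is emitted at each threshold-gate
opening, which makes the measured detection threshold equal the generator's
at zero noise — the identity the parameter-recovery tests rely on.
Vibration is handled per cycle: one candidate spike per cycle at the peak
phase, kept with the class's entrainment probability (1.0 for Ia in both
treatments — vibration encoding is preserved under cOIN, the premise of the
central-deficit test).

Anchored phenotype values (printed empirical group means: RAI and SAII
thresholds in grams, SAI/SAII sustain times, synaptic detection counts,
attenuation folds, gait undershoot) are tabulated with their anchors in
`phenotype_provenance()`. Everything else — gains, adaptation constants,
the skin compliance of 12.5 g/mm that maps the 2 mm indentation onto the
printed gram thresholds, the cOIN muscle-threshold fold of 3 (midpoint of
the reported two- to fivefold range) — is a documented model choice.
The generator emulates *qualitative class phenotypes and anchored effect
sizes*, not the full parameter distributions of real neurons; passing
round-trip tests therefore demonstrates that the analysis code measures
what the generator injects, not that it would reproduce any particular
laboratory's numbers.

Motoneuron synaptic potentials are the population rate drive convolved with
a unit-area double-exponential EPSP kernel (rise 5 ms, decay 50 ms, gain
0.05 mV/pps), with the cOIN phenotype expressed as fold division of the
dynamic-window drive (4.5×) and of everything after it (35×), an extra
onset delay (200 ms), and — for vibration — a response pattern drawn from
{absent, decaying, present}. Attenuation is applied to the drive before
convolution; because the kernel decay is short relative to the window
separation, extracted feature ratios still recover the folds within a few
percent. Traces are averaged over 15–20 noisy trials, mirroring the
recording protocol; conductance-based neuron models are out of scope.

The gait generator emits wide-format pose exports (x, y, confidence per
keypoint per frame) at 100 Hz with 0.01 cm keypoint noise — chosen together
so that stance detection (vertical speed below 5 cm/s over at least 3
frames on 3-frame-smoothed height) is physically meaningful rather than
noise-dominated. Hindfoot steps target the prior ipsilateral forefoot rung
with the replacement probability; misses undershoot by a truncated
normal (1.72 ± 0.61 cm by default, the anchored initial-error
distribution).

## Encoding metrics

Instantaneous rate is $1/(t_i - t_{i-1})$ assigned to the later spike. The
battery holds exactly 31 parameters in three clusters — threshold (4),
dynamic (13), static (14); see `encoding_parameter_clusters()`. The cluster
structure and count are the fixed constraints; the individual identities
are this package's documented definitions, each with formula and units in
the help pages. Detection threshold is the encoded variable at the first
post-onset spike minus its pre-onset baseline; silent neurons yield `NA`
flags that propagate through trial averaging (pairwise exclusion) and into
PCA standardization (mean imputation with a count report) rather than
poisoning downstream statistics. Profiles default to 4-trial averages.

## Population codes and the latent space

Each member train is smoothed with a Gaussian kernel (default SD 20 ms — a
choice, not a protocol constant: wide enough to suppress single-spike
granularity, narrow enough to resolve the 150 ms dynamic phase; it is a
config knob exercised in tests). The ensemble mean and across-neuron SEM
are reported on a 1 kHz grid, and a stated composition (10 Ia + 5 I_un +
14 Ib + 11 II) is enforced, not assumed. Scaling divides by the mean-rate
maximum over the ramp-hold-release reference epoch; values elsewhere may
exceed 1 only if their raw rate exceeds that maximum, and such excursions
are flagged.

PCA uses the correlation matrix because the 31 parameters mix mm, pps and
seconds. Loadings are reported as parameter–PC correlations; signs are
fixed by forcing the largest-magnitude loading positive on each PC, making
the decomposition deterministic. Group ellipses use the χ²₂ 0.95 quantile
on the group's 2-D score covariance — a standard reconstruction, since the
exact elliptical-fitting algorithm behind published figures is unstated.
Shift vectors are cOIN centroid minus control centroid per class. The
latent space accepts any label subset, so muscle and cutaneous classes can
be pooled or analysed separately.

## Circuit accuracy

`vaf()` regresses the reference on the signal (free gain and offset) and
reports $100\,(1 - SS_{res}/SS_{tot})$, equal to $100\,r^2$ and invariant
to affine transforms of either series. A bounded lag search (default
≤ 300 ms, positive lag = signal delayed relative to its reference) is
included because cOIN onset delays reach hundreds of milliseconds; without
it, delay and attenuation would be conflated, so the best lag is reported
as its own defect measure. R² is computed over the stimulus epoch only
(onset to 1 s after release). Stages compound multiplicatively with integer
rounding for the report and the raw product retained. The peripheral stage
is population rate vs muscle force; the central stage is synaptic trace vs
population rate — the regression direction is fixed here as downstream
representing upstream. Only the compounding arithmetic and the
control > cOIN ordering are validated quantitatively; the simulated stage
values themselves characterize the generator.

## Detection inference

The Beta-binomial model is exact: Beta(a, b) prior, binomial likelihood,
Beta(a+k, b+n−k) posterior. The reported prior is Beta(5, 1), encoding the
expectation that most motoneurons show detectable vibration-evoked
potentials; Beta(1, 1) is available by argument. HDIs are found by
minimizing interval width on the quantile scale with `optimize()`, so they
are deterministic and their mass is exact to 1e−6 (verified by CDF
differences). Integer-percent reports *truncate* rather than round — the
one convention under which the posterior means 0.375 and 0.9231 read 37%
and 92% — and whether published proportions were means, medians or sampler
estimates is unknowable from the printed values, so this convention is a
documented reconstruction. Group significance is 95%-HDI non-overlap with
strict inequality (touching endpoints are not significant).

The hierarchical regression models used for published group comparisons are
replaced by a conjugate Normal–Inverse-Gamma group-mean model
(`group_mean_model()`): prior mean = pooled mean with 0.01 pseudo-
observations, variance prior centred on (2.5 × pooled SD)² with half a
degree of freedom; the marginal posterior of each group mean is a scaled
Student-t whose HDI is equal-tailed by symmetry. The decision rule — HDI
non-overlap — is the inferential output that matters, and the closed form
keeps it exactly testable; no MCMC, partial pooling, or out-of-sample model
validation is attempted.

## Kinematics

Frames are excluded when any keypoint's confidence falls below 0.8 or any
keypoint moves faster than 150 cm/s (both protocol constants); both rules
are evaluated against the original frame set, so their order is immaterial
and the exclusion report partitions the dropped frames. Hit and replacement
tolerances default to 0.5 cm — the published criteria are not stated, so
both are explicit arguments surfaced in every report. Direction of travel
is inferred from the forefoot x trend; errors are signed so that negative
means short of the target. Analysis keeps only the *initial* hindfoot
placement per forefoot target, excluding corrective follow-ups. Joint
angles are interior angles at knee (hip–knee–ankle) and ankle
(knee–ankle–toe); the hip angle is measured against the horizontal travel
direction because no trunk keypoint is tracked.

## Numerical choices and problem sizes

Degenerate inputs have defined behaviour throughout: fewer than two spikes
give an empty rate series, silent windows give zero rates and `NA`
latencies, constant references make R² an explicit error, a zero reference
maximum makes scaling an explicit error, and two stances separated by a
sub-threshold lift merge into one. All generators draw from one seeded
stream per call; identical seed and configuration give byte-identical
output, which the suite asserts.

The shipped tests and the pipeline default to sizes that characterize the
method without excess: 20 neurons per class for parameter recovery, 20
seeded replicates for the accuracy ordering, 40-neuron ensembles at 10 kHz
simulation / 1 kHz rate grids, 10⁴-point Monte Carlo for ellipse coverage,
and ≥ 500 steps for kinematic rate recovery. These sizes are stated here as
the package's own calibration choices.

## Known limitations

- The 31-parameter battery matches the published count and cluster
  structure, not the (unavailable) published parameter identities.
- Simulated stage accuracies and PCA variance fractions describe the
  generator, not any real dataset; only their contrasts and arithmetic are
  claims.
- The generator omits biophysics: no conductance dynamics, no axonal
  conduction, no fusimotor or reflexive muscle force, no pose-estimation
  artefacts beyond Gaussian noise and confidence dropout.
- The skin compliance converting indentation to grams is a single linear
  constant; real skin is nonlinear.
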