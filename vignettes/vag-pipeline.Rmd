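---
title: "The vagdx vibroarthrography pipeline: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vagdx vibroarthrography pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vagdx)
```

This vignette is the package's own account of the science it implements: the
signal model behind the synthetic cohort, the decomposition and feature
mathematics, the selection and classification machinery, the numerical
choices that had to be made where the methodology leaves freedom, and the
limits of what the test suite can establish.

# The diagnostic problem

Damaged articular cartilage changes the vibroacoustic signature of a moving
knee: lesions of increasing ICRS grade (0 = intact, 4 = full-thickness)
produce more frequent and more energetic transient "clicks" superimposed on
the frictional rubbing noise. The pipeline classifies a recording as healthy
control (HC) or osteoarthritis (OA, any grade 1-4 collapsed to one class)
from twelve time-domain measures of the cleaned acoustic signal plus three
demographic covariates (age, sex, BMI), in three protocol variants: I = open
kinetic chain (seated knee extension), II = closed chain (sit-to-stand),
III = both chains with each recording a separate case and a chain-indicator
input.

# The synthetic cohort

The clinical recordings that motivated this pipeline are not publicly
deposited, so the package ships a first-class simulator whose role is to
emulate the acquisition geometry and the statistical structure that every
downstream stage assumes — not cartilage tribology.

**Acquisition geometry** (fixed by the reference protocol): acoustic channel
at 1400 Hz with 10-bit quantization; encoder at 10 Hz, hard-stopped to
[0, 90] degrees; ten 90-0-90 degree cycles of about 2 s each (per-cycle
duration jitter ±10%); about 1 s of idle rest on both sides of the movement
so that cycle cutting has something to remove.

**Signal model.** Each recording sums, in units of the background-noise
standard deviation:

* band-limited Gaussian background (10-600 Hz, unit sd) — the sensor and
  tissue noise bed;
* a friction term (amplitude 0.8) whose band-limited noise is enveloped by
  the absolute angular velocity of the knee; the closed chain loads flexion
  and extension equally, the open chain weights extension 3:1 — a stated,
  qualitative stand-in for load asymmetry between the two regimes;
* transient bursts: per cycle, a Poisson number of exponentially damped
  sinusoids (carrier uniform in 50-400 Hz, inside the 10 Hz-2 kHz sensor
  band; decay constant 10-30 ms). Rates per grade 0-4 are 0.2/1/2/4/6 per
  cycle and amplitudes 0.5/2/4/6/8. Healthy joints click occasionally and
  softly; established lesions (grade >= 2) produce impulses standing well
  above the noise bed. The amplitudes matter: impulse-sensitive moments
  (kurtosis, M6A, M8A) respond to bursts only when the burst peaks clearly
  exceed the background — transients at or below ~1.5 sd are statistically
  invisible after normalization, which would contradict the
  strong-separation regime the cohort is designed to provide;
* sensor drift: integrated white noise low-passed below 0.5 Hz, scaled to
  sd 1.5 — deliberately generated so that the EMD residual genuinely
  captures it and detrending has something real to remove;
* optional 50 Hz mains hum (amplitude 0.1);
* 10-bit ADC: clipping at ±12 units and rounding onto 1024 integer levels.

**Demographics** are drawn per group from normal distributions matching the
reference cohort (HC: age 24.10 ± 5.56 y, height 1.71 ± 0.09 m, weight
65.16 ± 15.10 kg, 9/33 male; OA: 56.15 ± 12.99 y, 1.69 ± 0.09 m,
89.08 ± 14.30 kg, 15/34 male); BMI is derived. Sex affects no acoustic
parameter — it is carried purely as a covariate. OA grades are sampled
uniformly from `grade_levels`, default 2:4, emulating a surgical cohort
dominated by established lesions; set `grade_levels = 1:4` for a milder mix.
Controls contribute both knees (`knees_per_hc = 2`, so variant I has
33×2 + 34 = 100 cases), patients the operated knee only.

Everything is deterministic given the configuration: the cohort seed fans
out to per-recording seeds by a fixed counter, and each EEMD trial uses
`seed + trial`.

# Preprocessing

**Cycle cutting.** A full cycle is a descent of the encoder angle from the
upper hard stop (>= 85°) to the lower stop (<= 5°) and back. Each threshold
crossing is refined to its local angle peak, which places boundaries within
one encoder period (0.1 s) of the true turning points; a plain threshold
crossing alone carries a ~0.15 s inward bias because the 85° level is
reached well after the turn. A flat trace yields zero cycles and a warning.

**EMD.** One sifting step interpolates the local maxima and minima with
natural cubic splines to get envelopes `e_up`, `e_dow`, forms their mean
`m1 = (e_up + e_dow)/2`, and subtracts it: `d1 = x − m1` (so `h1 = x − d1`
is what remains for the next component). Numerical choices, each the
conventional remedy where the methodology is silent:

* *envelope ends:* the outermost two extrema are mirror-reflected about each
  end before spline fitting, suppressing end swings;
* *stopping rule:* sifting stops when the Cauchy criterion
  `SD = Σ(d_prev − d_cur)² / Σ d_prev² < 0.2` **and** the candidate passes
  the IMF admissibility condition (|#extrema − #zero-crossings| <= 1), with
  a hard cap of 20 sifts per IMF. A cap of 10 is the older convention, but
  about 2% of random-signal IMFs then still violate admissibility — a
  condition this package asserts on every returned IMF — while at 20 none
  do and typical IMFs converge in 3-6 sifts anyway;
* *IMF count cap:* `floor(log2(n))`, the conventional bound;
* decomposition ends when the remainder has fewer than two maxima or two
  minima; that remainder is the residual trend `r(t)`. The telescoping
  identity `Σ IMFs + r = x` holds to machine precision and is tested at
  1e-9 relative.

**EEMD.** Plain EMD mixes modes on transient-rich signals; the ensemble
variant decomposes `n_trials` noise-assisted copies `y_k = x + w_k`
(Gaussian, sd = 0.2·sd(x), the 0.2 read as relative — the common convention)
and averages aligned IMFs, padding shorter decompositions with zero IMFs.
One independent realization per trial (no paired ±noise pairs). The added
noise averages out as 1/sqrt(n_trials), which the tests check at ensemble
sizes 1/16/100. Ensemble means need not themselves satisfy the IMF
conditions — only plain-EMD components are held to them.

**Detrending and normalization.** The residual (which, by construction of
the generator's drift, is dominated by sensor drift) is subtracted, and the
signal is rescaled to [0, 1]. EEMD runs once per recording on the
idle-trimmed motion region — longer signals stabilize the decomposition —
and the cycle boundaries are applied to the cleaned signal afterwards.

# The twelve measures

Features are computed per recording on the concatenation of its cleaned
cycles (a per-cycle mode would average measures over cycles; the default
matches one-case-per-recording bookkeeping). Conventions are deliberately
mixed, following the standard definitions in vibroacoustic condition
monitoring: the variance uses 1/(N−1); kurtosis, M6A, and M8A use biased
(1/N) central moments in both numerator and denominator. The shape factor is
RMS over the rectified mean; on a [0, 1]-normalized signal the rectified
mean equals the mean, so SF = RMS/MV as well. Ratio measures with vanishing
denominators raise an error (condition class `vagdx_undefined_feature`)
rather than returning sentinels — on normalized real signals they are
unreachable, so reaching one signals an upstream bug.

One structural consequence of normalizing each recording to [0, 1] before
per-recording features: PV and PPV are then identically 1 and carry no
information; the diagnostic burden falls on the scale-invariant measures
(CF, IF, SF, KUR, M6A, M8A) and on MV/SA/RMS/VAR, which respond to how much
of the amplitude range the background occupies once a large burst has set
the maximum. (Under the per-cycle mode PV and PPV vary across cycles and
become informative again.)

# NCA feature selection

Selection runs over the 12 signal measures only; age, sex, and BMI are
always passed to the classifiers. Features are standardized (training folds
only) before weighting because the distance mixes units. The weighted
distance is `D_w(x_i, x_j) = Σ_l w_l² |x_il − x_jl|` — an L1 distance with
squared weights — and the kernel `κ(z) = exp(−z/σ)` with σ = 1 after
standardization (the alternative reading `exp(−zσ)` is a pure
reparameterization σ → 1/σ). Leave-one-out soft-neighbor probabilities
`p_ij` (rows summing to one, `p_ii = 0`) give per-point correct
classification probabilities `p_i`, and the objective
`F(w) = Σ p_i − λ Σ w_l²` is maximized by gradient ascent with backtracking
line search (all-ones start, at most 400 iterations, relative tolerance
1e-6), so the objective never decreases along accepted steps. The gradient
is derived analytically from the objective —
`∂F/∂w_l = (2 w_l/σ) Σ_i [ p_i Σ_k p_ik |x_il−x_kl| − Σ_j y_ij p_ij |x_il−x_jl| ] − 2λ w_l`
— and is verified against central finite differences at 1e-5 relative in the
tests. For numerical stability each row of the distance matrix is shifted by
its smallest off-diagonal entry before the kernel; the softmax normalization
cancels the shift exactly.

λ is chosen by 5-fold cross-validation (validation loss = 1 − mean `p_i` of
held-out points scored against the training folds) over 13 log-spaced values
in [1e-4, 100]/N. The upper end matters: on realistic cohorts the CV loss is
still decreasing at λ = 1/N, and a grid capped there returns a boundary
solution rather than an optimum. Features are retained when
`w_l² >= 0.05 · max w²`; all defaults are arguments.

# Networks

Inputs (selected measures + age, sex, BMI, + chain indicator in variant III)
are standardized with training-set statistics. The stratified 70/15/15
split uses largest-remainder per-class quotas, so the global sizes are exact
(e.g. 70/15/15 at N = 100).

**MLP:** one hidden layer; hidden activations linear / logistic / tanh /
exponential / Gaussian; outputs softmax (with the cross-entropy error) or
linear/exponential (with the sum-of-squares error). Training is BFGS
(`stats::optim`) on the analytic backpropagated gradient, run in short
segments up to the iteration cap with the best-validation-loss iterate
retained. Initialization is uniform in ±sqrt(6/(fan_in+fan_out)), seeded.

**RBF:** k-means centers on the standardized training inputs (the training
points themselves at full capacity), per-center Gaussian widths equal to the
mean distance to the two nearest fellow centers, and a softmax output layer
fit by BFGS on the cross-entropy — a convex problem.

Both fits carry a small L2 penalty on the connection weights (`decay =
0.01`, biases exempt). This is not cosmetic: when the hidden features
separate the training classes — the typical situation here — the
unpenalized cross-entropy has *no finite optimum*; weights grow until the
iteration cap and the network extrapolates with arbitrary confidence far
from the training data. The penalty makes the optimum finite and the
probabilities meaningful.

`model_search()` trains a documented grid (hidden sizes for both families;
logistic and tanh hidden units for the MLP) and ranks candidates by
validation accuracy alone — test-set performance plays no part in model
selection; ties keep grid order. Iteration counts in the leaderboard's
"BFGS k" names are caps actually consumed, not convergence claims.

# Evaluation

OA is the positive class. From the confusion counts: accuracy (%),
sensitivity = recall, specificity, precision, F1 (harmonic mean), and MCC.
Because published summaries of such pipelines sometimes swap the
sensitivity/precision orientation, the report carries the class-swapped pair
too; F1 and MCC are orientation-stable and anchor the worked-example tests.
ROC curves sweep the unique scores (anchored at (0,0) and (1,1)); AUC is
trapezoidal and equals the pairwise concordance probability (tested against
that independent oracle); the reported operating threshold maximizes
Youden's J = sensitivity + specificity − 1, ties broken toward the larger
threshold — a documented choice, since "ROC threshold" has no unique
definition. Zero-denominator metrics are flagged `NA` and listed, never
silently zeroed.

The package also embeds the reference clinical study's printed per-class
confusion counts for its six headline networks
(`reference_confusion_counts()`); every derived percentage, F1 and MCC in
that study's summary tables follows from them through `confusion_metrics()`,
which ties the evaluation code bit-for-bit to published numbers.

# Problem sizes used in the tests and the acceptance script

The worked-example, decomposition, feature-oracle, and NCA checks run on
small fixtures (two-tone signals of 0.5-2 s, 60-300-sample random signals,
a 60-point recovery dataset). The end-to-end demonstration uses the full
default cohort (33 HC + 34 OA, variant I, 100 cases at full length and
rate) with a 4-trial EEMD ensemble — at that ensemble size the residual
(the only decomposition output the pipeline consumes) is already stable,
and a 100-recording cohort decomposes in a few minutes on one core; the
100-trial default remains appropriate for single-recording analyses. The
label-permutation null retrains on label-shuffled data and is evaluated on
the one-knee-per-subject case subset (33 + 34), where the null distribution
of plain accuracy is centred at chance; with both control knees the 66:34
case mix lets a majority-class predictor score ~66% under the null, which
tests nothing. Five permutations are averaged to tame the small-sample
variance of a single draw.

# What passing tests do and do not show

The generator reproduces the acquisition geometry, the morphology of
burst-type transients, drift, hum, and quantization — enough to exercise
every pipeline stage and to verify recovery of known structure (injected
burst statistics, drift removal, grade-monotone energy, separable classes).
It does **not** simulate cartilage physics, realistic joint spectra,
sensor-skin coupling, or inter-session variability, and its class
separation is by construction stronger than in clinical populations of
early-grade lesions. Passing the end-to-end criterion therefore shows the
pipeline is correct and information-preserving, not that the headline
accuracies would transfer to real patients; conversely the published
accuracies quoted by `reference_metrics()` are reproduced from printed
counts, not recomputed from (unavailable) raw recordings.

Known limitations: per-recording normalization degenerates PV/PPV (see
above); EEMD ensemble means are averaged per index with zero-padding
alignment, the simplest of several alignment conventions; the 15-case test
sets implied by a 70/15/15 split of 100 cases make single-split accuracy a
coarse statistic (one borderline case costs 6.7 points — the reference
study's own per-network testing accuracies ranged from 85.7% to 100% for
the same reason); and the cohort occasionally samples demographically
atypical subjects (a 1-in-67 old-ish control or young patient) whose cases
are genuinely ambiguous given overlapping acoustics — a realistic feature,
not a bug, but one that caps fixed-split test accuracy below 100% on some
seeds.
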