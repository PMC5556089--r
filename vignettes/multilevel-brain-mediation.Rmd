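---
title: "Multilevel brain mediation: model, simulation world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel brain mediation: model, simulation world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

When an informational cue — here, the displayed bottle price of a wine —
changes how pleasant an identical stimulus is reported to be, some neural
pathway must be carrying that effect. Mass-univariate fMRI analysis can
show separately that (i) a price cue modulates activity somewhere and
(ii) activity somewhere predicts pleasantness ratings, but neither result
alone establishes a pathway. Mediation analysis tests the two links
jointly. `brainmediate` implements the two-level (within-subject /
between-subject) form of that analysis for task fMRI, together with
everything needed to exercise it end to end on synthetic data.

Within each subject, with trial-level cue code $x$ (the two extreme price
levels coded $-1/+1$), mediator $m$ (a voxel's single-trial response at
tasting), and rating $y$:

$$y = c\,x + e_y \qquad\text{(total effect)}$$
$$m = a\,x + e_m \qquad\text{(cue} \to \text{mediator)}$$
$$y = b\,m + c'\,x + e'_y \qquad\text{(mediator} \to \text{rating, direct effect)}$$

Wine identity and payment condition enter all three equations as centred
covariates of no interest. With the same covariates in every equation, OLS
guarantees the decomposition $c = c' + a\,b$ exactly for every subject —
the package treats this as an invariant and tests it to $10^{-10}$.

At the group level, with subject as the random unit, the mediated
(indirect) effect is not just the product of mean paths: writing $a_i,
b_i$ for subject-level coefficients,

$$\operatorname{mean}(a_i b_i) \;=\; \operatorname{mean}(a_i)\,
\operatorname{mean}(b_i) \;+\; \operatorname{cov}(a_i, b_i),$$

so consistent co-variation of the two paths across subjects mediates even
when individual coefficients are heterogeneous. The covariance here must
use the population ($1/n$) denominator or the identity is not exact;
`group_decompose()` does so (a sample-covariance mode would break the
identity by a factor $n/(n{-}1)$, which is why it is not offered).

Inference resamples whole subjects: rows of the $[a, b, c, c', ab]$ matrix
are drawn with replacement (10,000 times by default), the column mean is
the resample statistic — for $ab$ this automatically carries the
covariance component, since the identity above holds within every resample
— and two-tailed p-values are read off the bootstrap distribution as
$p = 2\min\{\Pr(\theta^* \le 0), \Pr(\theta^* \ge 0)\}$, with ties at zero
counted on both sides and a floor of $2/n_\text{boot}$. Intervals are
percentile intervals, not BCa. Subjects are the only resampling unit:
trial-level uncertainty reaches the group level only through the noise in
each subject's coefficients.

## Single-trial estimation and trial QC

The mediator is a per-trial amplitude, estimated by a "beta-series" GLM
with one regressor per trial: a 3-s boxcar at the tasting onset (an 8-s
mode covers the full swirl period), convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, peak:undershoot 6, 32-s
support) on a 0.1-s internal grid and resampled at the 2.5-s TR.
Regressor columns are peak-normalized so a planted amplitude $A$ produces
a response peaking at $A$ regardless of boxcar duration or grid step.

Nuisance regressors per run: an intercept, a linear drift (standing in
for 128-s high-pass filtering; applying both would double-correct), and
the 24-column motion set — the six rigid-body parameters, their
mean-centred squares, their first-difference derivatives (zero at each
run's first volume), and the squared derivatives. Where the construction
is underspecified we centre squares within run and leave squared
derivatives uncentred, following the stated order of operations.

Single-trial regressors can be dangerously collinear with nuisance signal
(a trial coinciding with a motion spike is inestimable). The variance
inflation factor of trial $k$,
$\mathrm{VIF}_k = 1/(1 - R_k^2)$ with $R_k^2$ the determination
coefficient of that regressor against the nuisance block, quantifies
this; trials with $\mathrm{VIF} \ge 2.5$ are excluded, listwise — the
trial leaves $x$, $m$ and $y$ together. At the generator's default noise
levels well under 5% of trials are excluded, matching the small exclusion
rates this threshold produces in practice.

## Maps, thresholds and regions of interest

`voxelwise_mediation()` runs the subject fits and the bootstrap at every
voxel and returns long-format maps for paths $a$, $b$, $ab$, $c'$ and
$c$. Thresholding follows the conventional recipe: voxelwise $p < 0.001$
uncorrected with a cluster extent of 5 voxels. Cluster connectivity is
26-neighbour by default (6 and 18 available); the convention is not
standardized across packages, so it is configurable. Family-wise control
is applied as small-volume correction within 10-mm-radius spheres around
a-priori coordinates (defaults: ventromedial prefrontal cortex
$(-2, 48, -16)$, ventral striatum $(12, 10, -16)$, anterior prefrontal
cortex $(28, 50, -8)$, MNI mm). We use Bonferroni across in-sphere voxels
rather than random-field theory: at 10-mm scale on 2-mm grids the sphere
holds a few hundred voxels, Bonferroni is conservative but assumption-free
and dependency-free, and the deviation is deliberate and documented.
Sphere membership is by centre-of-voxel distance; `mm`-to-voxel mapping
rounds half away from zero. Voxel indices are 1-based in the R API (R
convention) while the stored NIfTI affine maps 0-based indices, as the
format requires.

A mediator is classified *partial* when both $ab$ and $c'$ are
significant, *full* when only $ab$ is.

## Moderated mediation

Whether the mediation is stronger in subjects whose valuation system is
more reward-sensitive is a second-level question: a per-subject scalar
moderator $w_i$ (in the motivating design, the sphere-averaged response to
monetary reward from an independent task — supplied here by the generator
or via `sphere_average()` on any beta image) is mean-centred and the
subject-level path is regressed on it, $a_i = \gamma_0 + \gamma_1 w_i +
\varepsilon_i$. Centring makes $\gamma_0$ the average path at the mean
moderator level. Inference is a subject-pairs bootstrap. One deliberate
choice: the two-tailed p for $\gamma$ is studentized (estimate divided by
its bootstrap standard error, on $t_{n-2}$) rather than read from the
percentile distribution. At the second-level sample sizes this analysis
actually sees ($n \approx 17$), we measured the raw percentile p to
reject a true null at ≈0.085 instead of 0.05, an instance of the known
small-sample size distortion of percentile bootstrap slope tests; the
studentized form measured ≈0.065 and keeps the confidence intervals
percentile-based. Whether the original inference was bootstrap or
parametric is not recorded anywhere we could verify, so the bootstrap was
kept for symmetry with the mediation machinery.

## The behavioral arm

The companion behavioral model is a random-intercept linear mixed model
for the ratings, fitted by maximum likelihood (`lme4::lmer`,
`REML = FALSE`): fixed effects for tasting count per wine ("trial
number"), wine, price and payment (wine and price as numeric codes), all
six two-way interactions, and the trial × price × payment three-way term
— 12 fixed terms — with an intercept varying by subject. Every regressor
is z-scored across trials within subject using the sample ($n-1$)
standard deviation; the convention is not documented in the motivating
analysis and the choice only rescales coefficients. Degrees of freedom
use the residual convention $\mathrm{df} = n_\text{obs} - 12$, which is
the convention that reproduces the printed df of the motivating model
(3213 at 3225 observations); Satterthwaite approximations are
deliberately not implemented. A paired two-tailed t-test
(`paired_contrast()`) covers the informed-versus-blind comparison.

## The simulation world

The generator exists so every downstream stage is testable without any
scanner data, and its defaults *are* the stated design, not free dials:

* **Design**: 3 price levels × 2 payment conditions × 18 repetitions =
  108 trials, split into 3 runs of 36; 3 wines rotating equally through
  all cells; the same wine never on successive trials; price and payment
  repeats capped at two. The sequence is drawn by a constrained
  sequential sampler that restarts on dead ends, so balance is exact and
  the constraints hold for every seed (verified over 1,000 seeds).
  Trial timing follows the scanning protocol (2.5-s cue, 6–8-s jitter,
  8-s swirl of which 3 s are modelled, 2-s swallow, 6–8-s jitter, 8-s
  rating, 3-s rinse, 2-s swallow, 7–9-s inter-trial interval); jitters
  are uniform over the stated bounds, the distribution itself being
  unstated.
* **Subjects**: $(a_i, b_i)$ bivariate normal. Defaults $\bar a = 0.5$,
  $\bar b = 0.4$, $\sigma_{ab} = 0.05$ — the recovery target
  $\bar a \bar b + \sigma_{ab} = 0.25$ — with $\mathrm{sd}(a) = 0.30$,
  $\mathrm{sd}(b) = 0.26$, chosen so the implied $a$–$b$ correlation is
  ≈0.64, the size reported for value-system mediators in this
  literature. Direct effect $\bar c' = 0.1$ (partial mediation), rating
  intercept 5 ± 1 on the 9-point scale.
* **Trials**: unit-s.d. mediator and rating noise ("moderate" SNR: a
  per-subject path-a standard error of ≈0.12 over 72 extreme-price
  trials). Ratings are continuous by default; 9-point discretization is
  available but off, because clipping biases linear path recovery.
* **BOLD**: planted mediator voxels (shared across subjects, as real
  mediating regions would be) carry amplitude × (3-s boxcar ⊗ HRF);
  every voxel receives a per-run linear drift, AR(1) noise (default
  $\phi = 0.3$, unit innovation s.d.) and a motion-correlated leak from
  simulated slow-random-walk motion traces.

What the generator does **not** emulate: physiological noise, swallowing
artifacts, susceptibility dropout, spatial autocorrelation of noise, or
any spatial preprocessing. A green recovery test therefore establishes
that the estimation chain is correct and calibrated under the stated
noise model — not that it is robust to artifact classes the generator
never produces.

## Numerical choices and degenerate inputs

* Convolution on a 0.1-s grid, evaluated only over each event's support
  window (exact, since the response is zero elsewhere).
* A mediator exactly proportional to $x$ makes $c'$ unidentifiable; the
  aliased coefficient is attributed to the mediator ($c' = 0$), which is
  the perfect-mediation limit. A constant mediator flags the subject
  degenerate; degenerate subjects are dropped per voxel with a logged
  count.
* Bootstrap p-values are floored at $2/n_\text{boot}$; an all-identical
  path matrix yields a zero-width interval flagged degenerate.
* $R^2 \ge 1 - 10^{-12}$ in the VIF regression reports an infinite VIF
  and auto-excludes the trial; a VIF threshold that excludes everything
  is an explicit error.
* Cluster peak ties at the bootstrap p floor are broken by effect size.
* The percentile bootstrap of the group indirect effect is anti-conservative
  at small second-level samples: at 20 subjects the full pipeline rejects a
  true null at 0.078 (1,000 datasets) instead of the nominal 0.05, and a
  pure-statistics replica (iid $a_i b_i$ products, no pipeline) measures
  0.081 ± 0.004 — i.e. this is the estimator's inherent small-sample size
  on a product-distributed statistic, not an implementation artifact. The
  estimator is kept as specified (percentile, ties at zero on both sides,
  subjects as the resampling unit); the corresponding calibration check is
  reported as measured and fails its ±3-s.e. band honestly. At 30 subjects
  the distortion shrinks (the permuted-null p distribution passes a
  Kolmogorov-Smirnov uniformity check at $\alpha = 0.01$).

## Scale of the shipped checks

The acceptance checks run the stated worlds at the sizes given with them
(1,000 seeds; 1,000 null datasets × 1,000 resamples; 200 recovery
replicates at 30 subjects × 108 trials; 200 + 500 moderation replicates);
map-level bootstraps in examples and the pipeline default to 1,000–5,000
resamples rather than the canonical 10,000 so the whole suite stays
within desk-scale runtimes. The pipeline's default configuration (12
subjects, 8×8×8 grid) completes in well under a minute on one CPU.
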