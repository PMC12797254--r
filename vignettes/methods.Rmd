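---
title: "Methods: simulation, conjunction inference, and pattern similarity in neuroverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, conjunction inference, and pattern similarity in neuroverlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neuroverlap` implements a within-participant test of neural overlap between
two cognitive tasks — exemplified by single-digit arithmetic and rhyming
judgment — in block-design fMRI. The package covers the full chain: a
synthetic BOLD generator with known ground truth, artifact detection and
first-level GLMs, group conjunction with Monte-Carlo cluster-extent
correction, ROI-based representational similarity with Steiger's Z, and
cross-validated, noise-normalized pattern similarity. This vignette explains
the models, the default parameter choices, and the limits of what a passing
test establishes.

## The two-task block design

Each simulated participant completes two runs of an arithmetic task and two
runs of a rhyming task (TR = 1 s, 244 volumes per run). Arithmetic runs
contain six 30 s blocks — two per condition: Small problems (sums below 10,
typically solved by retrieval), Large problems (sums above 10, more often
procedural), and a PlusOne control (one addend is 1, solved by the
"number-after" rule). Each block holds 6 trials of 3.5 s separated by
inter-trial intervals drawn from {1, 1.5, 2} s. Rhyming runs contain three
Rhyme and three LetterMatch blocks of five 4 s trials with ITIs from
{1.5, 2, 2.5} s.

Within a block the ITI multiset is constrained to its expected sum (9 s and
10 s respectively), so every block lasts exactly 30 s. Fixation intervals —
one before each block plus a final one, seven in total — are drawn uniformly
from [8.6, 9.4] s and then rescaled so that each run lasts exactly 244 s.
The rescaling can push individual intervals slightly outside the jitter
interval (by up to ~6%); we prefer exact run length over exact jitter
bounds, since the run length is what the acquisition fixes. The two runs of
a task are independent draws from the same design distribution: whether the
original protocol repeated trial content across runs is not recoverable, and
nothing downstream depends on it.

Trials are correct with probability `p_correct` (default 1). Incorrect
trials are dropped from their condition regressor and modeled by a dedicated
nuisance regressor, mirroring standard practice.

## The forward model and its ground truth

The generator's world is a `ground_truth` object: ROI masks, per-ROI
condition amplitudes, a cross-condition pattern-correlation matrix, and a
noise model. The signal at voxel $v$ of a responsive ROI for condition $c$
is

$$ s_{cv}(t) = a_c \,\bigl(\mu + \sigma_p u_{cv}\bigr)\, x_c(t), $$

where $x_c(t)$ is the condition boxcar convolved with the canonical
double-gamma HRF (gamma peak near 6 s, undershoot near 16 s weighted 1/6, no
derivative terms — the common default basis), $a_c$ the condition amplitude,
$\mu$ (`pattern_mean`, default 1.5) the homogeneous response shared by all
voxels, and $\sigma_p u_{cv}$ (`pattern_sd`, default 0.5) the heterogeneous
multi-voxel pattern. The unit fields $u_c$ are built by mixing independent
Gaussian voxel fields through the symmetric square root of the requested
correlation matrix, so $\mathrm{corr}(u_c, u_{c'})$ equals the request
exactly in expectation; requests must be positive semi-definite and
violations are reported naming the offending pair or triple. The HRF kernel
is normalized to unit integral, so a sustained block plateaus at amplitude
$a_c \,(\mu + \sigma_p u_{cv})$ and first-level betas are read directly in
amplitude units.

Defaults state a deliberately plain world: experimental conditions drive
their regions at $a = 1.5$ and control conditions (PlusOne, LetterMatch) at
$0.75$, giving task-vs-control contrasts of $1.125\mu$; pattern correlations
default to Small–Large 0.6, Small–Rhyme 0.3, Large–Rhyme 0.5 (a +0.2
difference favoring Large–Rhyme, the direction the similarity stages are
designed to detect) with 0.2 between all control pairs. The default
geometry plants bilateral arithmetic-only regions, a left rhyming-only
region, and one left-frontal region responsive to both tasks — the overlap
the conjunction stage must find. These choices produce a per-contrast group
effect size around $d \approx 1.5$ at the default noise, in the range of
robust single-task block-design effects; they were fixed before the
acceptance thresholds were evaluated and are not tuned per test.

Noise is Gaussian with marginal SD `noise_sd` (default 1), temporal AR(1)
coefficient 0.3, and spatial Gaussian correlation of 5 mm FWHM — typical 3 T
values; none are printed in the protocol, so all are configurable. The noise
is re-standardized after spatial smoothing so `noise_sd` is the marginal SD
regardless of smoothness. Motion is a slow random walk; step displacements
and global-intensity deviations can be injected to exercise the artifact
detector. Head-motion effects on the data themselves (spin-history,
interpolation) are *not* modeled: motion affects the data only through the
nuisance regressors. Physiological noise, distortion, and multiband
artifacts are likewise out of scope, so a green simulation test says nothing
about robustness to those.

All randomness derives from one master seed via counter-based hashing
(`derive_seed`), so any subject, run, or ROI stream can be regenerated in
isolation and two invocations of any stage are bit-identical.

## Artifact detection and the first level

Framewise displacement is the sum of absolute volume-to-volume differentials
of the six realignment parameters with rotations converted to arc length on
a 50 mm sphere — the exact convention of the original toolbox is not
printed, so the radius and the formula are recorded in the output metadata
and configurable. Volumes with FD > 1.5 mm or global signal beyond 4 SD
(z-normalized within run) are flagged; a volume tripping both rules is
recorded as a displacement outlier. Runs with at least 20% flagged volumes
are excluded before any group stage.

The first-level design matrix contains HRF-convolved condition regressors
(correct trials), an incorrect-trials regressor when needed, six motion
parameters, one indicator column per flagged volume, a linear drift, and an
intercept. Fixation is the implicit baseline, so a condition beta *is* the
condition-vs-fixation effect. Multi-run fits concatenate runs with shared
condition columns and run-specific nuisance columns rather than averaging
run-wise estimates. Contrast t-maps use
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}$
voxelwise; the two protocol contrasts are
$(\text{Small}+\text{Large})/2 > \text{PlusOne}$ and
$\text{Rhyme} > \text{LetterMatch}$.

Only univariate analyses see spatially smoothed data (6 mm FWHM separable
Gaussian, zero-padded at the grid boundary); every pattern analysis uses
unsmoothed fits. This routing is asserted by a wiring test.

## Conjunction and cluster-extent correction

Group inference is a voxelwise one-sample t-test of subject effect maps
against zero with one-sided p-values; voxels with zero between-subject
variance are masked and reported rather than silently kept. The conjunction
is the conservative minimum-statistic test: a voxel belongs to the
conjunction mask only when *both* contrasts are individually significant at
the forming threshold (default p < 0.001, one-sided). The protocol text
also mentions a forming threshold of 0.05 in the context of the cluster
simulation; we read the conjunction definition (p < 0.001 for both
contrasts) as the forming threshold and 0.05 as the cluster-level
family-wise alpha. Both numbers are plain config fields, so the alternative
reading is one line away, and the chosen reading is echoed into the
provenance output.

The cluster-extent threshold k is estimated by Monte Carlo in the style of
AFNI's 3dClustSim: smooth Gaussian white volumes to the target FWHM,
re-standardize, threshold at the voxelwise quantile, record the maximum
cluster size per iteration, and set k to the ceiling of the $1-\alpha$
quantile of that null distribution (at least 1000 iterations enforced).
Cluster connectivity defaults to 18 neighbors (faces + edges), the middle
of the 6/18/26 ladder, configurable. The field smoothness is supplied
explicitly or estimated from residual lag-1 spatial autocorrelation under a
Gaussian autocorrelation model,
$\rho(d) = \exp(-d^2/(4\sigma^2))$ for kernel SD $\sigma$ — note the factor
4, not 2: the autocorrelation of a smoothed field is the kernel's
self-convolution. Because the original thresholds (k = 35 and 18) depend on
the unreleased data's smoothness, they are treated as data-dependent
quantities, not as reproduction targets.

## Naive similarity and Steiger's Z

For each conjunction cluster (the ROIs of the similarity stage), the
condition-vs-fixation patterns for Small, Large, and Rhyme are vectorized in
a fixed lexicographic voxel order from unsmoothed fits. Pairwise Pearson
correlations are Fisher-transformed, and the dependent pair
(Small–Rhyme vs Large–Rhyme, sharing the Rhyme pattern) is contrasted with
Steiger's pooled-estimate Z:

$$ Z = (z_{12} - z_{13}) \sqrt{\frac{n-3}{2 - 2\bar s}}, \qquad
   \bar s = \frac{\bar\psi}{(1-\bar r^2)^2}, $$

with $\bar r = (r_{12}+r_{13})/2$ and
$\bar\psi = r_{23}(1-2\bar r^2) - \tfrac12 \bar r^2 (1-2\bar r^2 -
r_{23}^2)$. The citation in the source protocol does not pin the variant;
the pooled form is the one recommended in the original methodological paper
for exactly this comparison. Here $n$ is the ROI voxel count — voxels are
spatially dependent, so Z is *not* interpreted as a per-participant
p-value but as a per-participant effect score, aggregated across
participants by a two-sided one-sample t-test, exactly as in the source
analysis. Positive group means indicate greater rhyme–Small similarity. The
per-ROI tests use a Dunn–Šidák corrected alpha
$1-(1-\alpha)^{1/m}$ with m defaulting to the number of ROIs analyzed
(0.017 at m = 3, 0.013 at m = 4 for family alpha 0.05).

Whether the original analysis pooled runs before computing patterns or
averaged per-run correlations is not stated; the default pools runs in the
GLM (one beta per condition) and keeps per-run patterns for the
cross-validated stage, and the choice is recorded in the output.

## Cross-validated, noise-normalized similarity

Naive within-ROI pattern correlations have a positive null bias: noise
shared across conditions within a run (global fluctuations, residual
motion) correlates any two patterns estimated from the same data. The
cross-validated stage addresses both problems. First, patterns are whitened
by $\Sigma^{-1/2}$, where $\Sigma$ is the voxel covariance of GLM residuals
shrunk toward its diagonal with an analytically chosen intensity
(Ledoit–Wolf style; eigenvalues floored at $10^{-6}$ of the maximum to
bound the condition number on small ROIs). One caveat discovered while
testing: when the true covariance *is* diagonal, the analytic intensity
legitimately approaches 1 — the target coincides with the truth — so
"small lambda" is only expected in the presence of real correlations.
Second, similarity is estimated split-half across runs,

$$ r_{cv} = \tfrac12\,[\,\mathrm{corr}(a_1, b_2) + \mathrm{corr}(a_2, b_1)\,], $$

which has expectation zero under unrelated condition patterns — the
meaningful zero baseline that makes the group t-test against 0
interpretable. The group stage Fisher-transforms $r_{cv}$, tests each
(ROI, pair) cell two-sided against zero, reports means, SDs and confidence
intervals on the correlation scale, and applies the Šidák correction across
cells. The published corrected alpha for this table (0.002) is not
derivable from any obvious cell count, so the family size m is an explicit
config knob rather than a guess.

The exact estimator of the original supplement is not in the available
text; Pearson correlation of whitened per-run patterns with two-fold (run)
cross-validation is the standard construction in the multivariate-noise-
normalization literature and is the default. A covariance-style
(non-normalized) estimator can be selected by skipping whitening.

## Numerical and scaling choices

- Cluster components use igraph on the voxel adjacency graph; the test
  oracle is an independent flood fill. Peak ties break by lexicographic
  voxel index.
- OLS is solved by QR; rank deficiency is an error naming the collinear
  columns rather than a silent drop.
- Smoothing conserves interior mass exactly (verified against a
  brute-force kernel sum) and is the identity at FWHM 0.
- Acceptance-scale simulations are scaled to a 1-CPU, 25-minute budget:
  null-cohort family-wise-error calibration runs at a 16^3 grid, and
  structural recovery at 20^3 with 10-subject cohorts (the package default
  is 24^3); parameter-recovery direction is established at the generator's
  pattern stage (100 cohorts x 34 subjects) and confirmed end-to-end
  through the full BOLD route on 10 cohorts. The reduced scales are noted
  inline in the tests.

## What a green suite does and does not establish

It establishes: exact forward-model recovery, calibrated nulls for the
Steiger test, the group t-test and the conjunction/cluster pipeline,
zero-baseline behavior of the cross-validated estimator, recovery of the
generated correlation structure and of the planted overlap geometry. It
does not establish robustness to unmodeled physiology or motion-by-signal
interactions, correctness of anatomical interpretation, or performance at
whole-brain matrix sizes — the grid here is a desk-scale stand-in chosen
for method validation, not a claim about full-resolution runtime.
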