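---
title: "Linking striatal D2/3 receptor availability to load-dependent cortical connectivity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking striatal D2/3 receptor availability to load-dependent cortical connectivity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Working memory performance depends both on striatal dopamine D2/3
receptor signalling and on how cortical networks reorganise under
cognitive load. `dopaconn` re-implements, as a tested and reusable
pipeline, an analysis that ties the three measurements together in the
same subjects:

1. **PET**: striatal D2/3 receptor availability, quantified as the
   non-displaceable binding potential BP~ND~ from regional time-activity
   curves with the simplified reference tissue model (SRTM).
2. **fMRI**: functional connectivity of 97 cortical parcels during an
   n-back task (0/1/2-back blocks), summarised per subject as the
   per-edge regression slope of Fisher-z connectivity on load,
   `zFC = w0 + w1 * load`, averaged within the default mode network
   (DMN), the task-positive network (TPN) and between them.
3. **Behaviour**: a penalized reaction time (pRT) in which incorrect or
   omitted responses are replaced by a fixed multiple (2.5-4) of the
   subject- and condition-specific mean correct RT, and the robustness
   `-dpRT` (negated OLS slope of pRT on load).

The headline claims being modelled: DMN connectivity falls with load
(group-mean `w1 < 0`), the size of that fall correlates with caudate
BP~ND~ (Spearman), and the BP~ND~-performance relationship is mediated
by the connectivity change (linear mediation, BCa bootstrap).

Because no subject-level data are released for the original study, the
package ships a synthetic-cohort generator that plants the full causal
structure with known ground truth, so every stage of the pipeline is
verifiable end to end.

## Pipeline stages and their models

### Network detection

Condition-wise connectivity matrices (0-back, negative edges set to
zero) are partitioned by maximising modularity

Q = (1/v) * sum_ij ( w_ij - gamma * s_i * s_j / v ) * delta(M_i, M_j)

with the greedy two-phase Louvain algorithm (local moving with
best-gain moves over a seeded-random node order, then aggregation),
`gamma = 1`. Robustness comes from consensus clustering: `n_iter`
seeded runs are combined into an agreement matrix, entries below 50%
agreement are zeroed, and the agreement matrix is re-clustered until
all runs of a round agree. Subject-level consensus partitions are
averaged into a group agreement matrix and the same procedure applied
again. Communities are labelled DMN or TPN by maximal Sorensen-Dice
overlap with the a-priori parcel labels; the number of communities is
never forced to two.

Numerical conventions: ties in the local-moving gain keep the current
community (so moves happen only on strict improvement and every sweep
is monotone in Q); a partition whose Q falls below the trivial
single-community partition is replaced by it; the agreement threshold
comparison is strict (`< 0.5` is zeroed); re-clustering of agreement
matrices always uses `gamma = 1` on the agreement weights directly.

### Connectivity estimation

Block windows are shifted forward by `lag_volumes` (default 2 volumes =
4 s at TR 2 s) before samples are extracted, to compensate haemodynamic
delay; condition-wise estimates concatenate all blocks of a condition
(60 volumes per load under the default design), while the
within-subject analysis estimates each 10-volume block separately.
Pearson correlations are clamped to `1 - 1e-12` in magnitude before the
`atanh` transform, so numerically perfect correlations stay finite
(about z = 13.8). Negative edges are retained everywhere except
community detection. Load is coded 0/1/2 (not centred), so `w0` is the
fitted 0-back connectivity.

### PET quantification

The SRTM operational form is

C_T(t) = R1 * C_R(t) + (k2 - R1 * k2a) * (C_R conv exp(-k2a t)),
k2a = k2 / (1 + BP_ND).

Fitting uses the basis-function method: 100 log-spaced `k2a` values in
[0.001, 1] /min, a weighted linear solve per basis (weights
proportional to frame duration), selection of the minimal weighted
residual and a local 1-D refinement of `k2a`. The convolution runs on a
1-s grid with an exact-exponential recursion. When only framed
reference activities are available they are upsampled by linear
interpolation of frame midpoints; this costs about 1% systematic error
in BP~ND~ on the default 31-frame schedule, which is why noise-free
round-trip tests use the finely sampled reference.

### Inference

* Spearman correlations use average ranks; the CI is the Fisher
  transform of rho with variance `1.06/(n-3)` (the literature's
  standard approximation; the emulated study does not name its CI
  method), p from the t approximation on n-2 df.
* Dependent overlapping correlations are compared with the
  Meng-Rosenthal-Rubin z statistic, including the f/h adjustment and a
  CI for the Fisher-scale difference.
* The repeated-measures ANOVA is the classical one-way
  sums-of-squares decomposition with df (k-1, (k-1)(n-1)); sphericity
  is assumed without correction, matching how the emulated analysis
  reports F.
* Mediation is linear (`mediator ~ treatment`;
  `outcome ~ treatment + mediator`), ACME = a*b, ADE = c', total =
  a*b + c' per bootstrap draw. Intervals are BCa over case resampling:
  bias correction z0 from the proportion of bootstrap estimates below
  the point estimate, acceleration from the jackknife; the p-value is
  the smallest alpha at which the BCa interval excludes zero (inverted
  analytically from the bootstrap mass below zero). The default
  `n_boot` in tests is 999; the emulated analysis used 10,000.
* No multiple-testing correction is applied anywhere, matching the
  emulated analysis (uncorrected two-tailed p at 0.05); this is a
  faithful re-implementation choice, not a statistical recommendation.

## The synthetic world

The generator's defaults are the stated study design: 51 subjects, 97
nodes (42 DMN / 55 task-positive), 275 volumes at TR 2 s, 18 blocks of
20 s (six per load) with 10 s rest, 10 trials per block, 31-frame PET
schedule. Where the design leaves values open, the following choices
were made once and are documented here:

* **Planted connectivity.** Each volume is drawn from a zero-mean
  multivariate normal whose within-network correlation at load L is
  `tanh(atanh(base) + base_z + slope * (L - 1))`; rest volumes use the
  load-0 structure, expressed with a 2-volume haemodynamic delay that
  the analysis-side lag shift exactly compensates. Planting on the
  Fisher-z scale makes the per-edge regression slope `w1` recover
  `slope` exactly in expectation. Centring the slope on the
  session-mean load (exactly 1 with six blocks per load) has two
  consequences that the uncentred form cannot deliver simultaneously:
  whole-session connectivity is independent of the slope (so the
  whole-session control analysis is null, as in the emulated study),
  and low-load correlations stay away from the equicorrelation
  positive-definiteness wall (a 42-node block with uniform correlation
  r is only positive definite for `r > -1/41`).
* **Slope heterogeneity** `sd_dmn_slope = 0.12` (mean -0.1). The
  design's 60 volumes per condition put an irreducible ~0.03 sampling
  noise on a subject's network-mean `w1`; only if true between-subject
  spread dominates that noise can a correlation planted on the latent
  slope survive into the measured `w1` essentially unattenuated, which
  is what the reported correlation (measured on estimated `w1`)
  requires. The implied ~20% of subjects with positive DMN slopes is
  consistent with the modest group t statistic the emulated study
  reports.
* **Baseline connectivity** 0.4 within DMN, 0.3 within TPN, 0.05
  between networks, with a subject-level baseline trait of s.d. 0.1 on
  the z scale, independent of BP~ND~.
* **Receptor coupling.** Caudate BP~ND~ ~ Normal(2.0, 0.4) truncated
  at zero; a Gaussian copula couples it to the DMN slope with latent
  Pearson `2*sin(pi*rho_s/6)`, hitting the Spearman target
  `rho_bp_slope = 0.45` exactly in population because both margins are
  monotone in their latent normals. Putamen and accumbens are
  correlated with the caudate (0.6/0.5) but conditionally independent
  of the slope; SN/VTA is independent (the negative control);
  whole-striatum BP~ND~ is the volume-weighted mean (0.38/0.48/0.14).
* **Behaviour.** Targets occur on 30% of trials (the task description
  gives no rate); errors split evenly between wrong-key and omission;
  error probability rises with load and falls with ability; the RT
  load slope equals the negated ability, where ability is
  `behav_slope_coupling * dmn_slope + direct_bp_behaviour * bp +
  Normal(0, 0.02)` - the pure mediated path under the defaults.
* **PET curves.** The reference input is a biexponential shaped to
  peak near 5 min (arbitrary rate constants, not study values); frame
  noise is Gaussian with variance proportional to 1/frame-duration,
  the conventional PET approximation; per-region R1 ~ N(0.9, 0.05) and
  k2 ~ N(0.35, 0.03)/min.

### What the generator does not emulate

No haemodynamic response convolution (the pipeline starts from
denoised residual series, and condition covariance switches with a
simple 2-volume delay), no voxel space, no physiological noise or
motion, no scanner drift, and uniform within-block correlations rather
than realistic heterogeneous edge structure. Two consequences matter
for interpretation. First, the equicorrelation geometry cannot
represent strongly negative mean within-network correlations, so the
full between-subject spread implied by the emulated study's group t
statistic (which would need slope s.d. about 0.3) is not plantable;
the chosen 0.12 is the compromise that keeps the planted world valid.
Second, a green end-to-end test establishes that the pipeline recovers
the planted linear-Gaussian structure at the stated design size - not
that the method would behave identically on real BOLD data with
heavy-tailed noise, spatially structured artefacts, or non-linear
load effects.

## Degenerate inputs and edge policies

A subject-by-load cell with zero correct trials is an explicit pRT
error (no silent default); the block-wise pRT instead penalizes against
the subject-by-condition baseline, which is always defined. d' adjusts
perfect rates to `1 - 1/(2n)` and zero rates to `1/(2n)` with n the
whole-task count of targets or non-targets (a per-load variant is
available). Constant node signals abort connectivity with the node
named. Non-positive-definite planted covariances are repaired with the
nearest positive-definite correlation matrix and logged as warnings;
failure after repair aborts generation. Consensus clustering that fails
to converge within `max_rounds` (default 50) reports the round
agreement rather than looping forever.

## Seeds and determinism

Every stochastic stage takes an explicit seed; a master seed fans out
to named sub-seeds (latents, schedule, per-subject trials/BOLD/TACs,
per-iteration Louvain runs, bootstrap) through a deterministic integer
map kept below 2^31. All RNG use is wrapped so the caller's RNG state
is never disturbed. Identical configuration and seed produce
byte-identical cohort directories.

## Known limitations

* The Spearman CI variance `1.06/(n-3)` and the BCa p-value convention
  are reasonable standards but cannot be verified against the emulated
  study's unstated choices.
* The d' metric is insensitive to processing speed and omissions by
  construction; the package reports it alongside pRT without claiming
  equivalence.
* Whole-striatum BP~ND~ uses fixed volume weights rather than
  subject-specific anatomy.
* The CLI wrapper is a convenience; the package functions are the
  supported interface.
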