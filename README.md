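# dopaconn

Striatal dopamine D2/3 receptor availability and working-memory
load-dependent cortical network connectivity: a tested, reusable
re-implementation of a multimodal PET/fMRI analysis pipeline, together
with a seeded synthetic-cohort generator that plants the full effect
structure so every stage can be verified against known ground truth.

The package is for researchers who want to study, extend, or stress-test
this class of analysis — working-memory n-back fMRI connectivity
combined with PET receptor quantification — without access to the
original subject-level data.

## What it computes

For each subject the pipeline estimates three quantities and the
statistical links between them:

* **Load-dependent connectivity.** Functional connectivity between
  cortical parcels is the Fisher z-transformed Pearson correlation of
  BOLD time courses, estimated per n-back condition. Each edge gets a
  linear model `zFC = w0 + w1 · load`; the mean `w1` over within-DMN,
  within-TPN and between-network edges summarises task-induced
  reorganisation. DMN/TPN membership is found by modularity
  maximisation, `Q = (1/v) Σ_ij (w_ij − γ s_i s_j / v) δ(M_i, M_j)`,
  via seeded Louvain clustering with subject- and group-level consensus
  (1000-run agreement matrices, <50% entries zeroed, re-clustered until
  unanimous), labelled by Dice overlap with a-priori parcel labels.
* **Receptor availability.** Regional PET time-activity curves are fit
  with the simplified reference tissue model,
  `C_T = R1·C_R + (k2 − R1·k2a)·(C_R ⊗ e^(−k2a t))`, `k2a = k2/(1+BP_ND)`,
  by the basis-function method; BP_ND = k2/k2a − 1.
* **Behaviour.** Penalized reaction time (incorrect/omitted trials
  replaced by `ratio ×` the subject- and condition-specific mean correct
  RT, ratio 2.5–4), its negated load slope `−ΔpRT` ("robustness"), and
  d′ = Z(hit) − Z(false alarm) with 1/(2n) adjustment of perfect rates.
* **Inference.** Spearman correlations with Fisher-z CIs, Meng's test
  for dependent overlapping correlations, one-sample/paired t-tests,
  repeated-measures ANOVA, block-wise within-subject regression, and
  linear mediation (ACME = a·b) with BCa bootstrap intervals.

## Worked example

Simulate the default synthetic cohort (51 subjects, 97 nodes, 275
volumes, planted DMN slope −0.1 coupled to a latent caudate BP_ND with
Spearman 0.45, pure mediated path to behaviour) and run the analysis:

```r
library(dopaconn)

cfg    <- cohort_config(seed = 1)
cohort <- simulate_cohort(cfg)
report <- run_analysis(cohort, detection = "apriori", n_boot = 999, seed = 2)
print(report)
#> Analysis report
#>   subjects: 51, analysis seed 2, config 8ea85050
#>   group w1: DMN -0.1165 (t = -5.99, p = 2.25e-07), TPN 0.0465 (t = 10.68, p = 1.69e-14)
#>   rho(caudate BP, dmn w1) = 0.376 (p = 0.0066)
#>   rho(dmn w1, -dpRT(2.5)) = 0.915 (p = 5.23e-21)
#>   caudate ACME = 0.1750 [0.0571, 0.3426], p = 0.00858
```

Reading the output: DMN connectivity decreases with working-memory load
(negative group-mean `w1`) while TPN connectivity increases; subjects
with higher caudate BP_ND show smaller DMN decreases (positive Spearman
rho); smaller DMN decreases predict more robust performance; and the
BP_ND → performance path runs through the connectivity change (positive,
significant average causal mediation effect). This reproduces the sign
pattern of the planted ground truth. `write_report(report, "report")`
serialises the full statistics table to JSON and markdown;
`detection = "consensus"` replaces the a-priori labels with the full
consensus-clustering network detection.

A command-line wrapper with `simulate` / `analyze` / `report`
subcommands is installed at `inst/scripts/dopaconn-pipeline.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — it simulates the default cohort from the given seed, executes
the complete analysis (behaviour, connectivity, load regression, SRTM
fits, correlations and mediation), prints the report, and writes the
results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
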