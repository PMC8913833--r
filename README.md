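# metabnet

Graph-theoretic analysis of **dynamic metabolic covariance networks** from
longitudinal in vivo ¹H-MRS metabolite concentrations.

Neurochemical profiling by MRS yields, per animal and time point, a vector
of metabolite concentrations (with CRLB uncertainties, as produced by
LCModel). Across the animals of a group, concentrations of functionally
coupled metabolites co-vary; treating metabolites as nodes and strong
absolute Spearman rank correlations |ρ| as edges turns each (group, time
point) into a *metabolic network* whose organisation — and whose disruption
by an intervention such as acute stress — can be quantified. metabnet is
written for MRS/systems-neurochemistry researchers who have longitudinal
concentration tables from two groups and want the complete pipeline:
quality control, network construction, small-world statistics and
permutation-based group inference.

## The statistics at the core

For a binary network obtained by thresholding the |ρ| matrix (sweep
0.41–0.49, step 0.01):

- **Global efficiency** `E_global = mean over pairs of 1/d(i,j)` (1/∞ = 0),
  **local efficiency** of node *i* = `E_global` of the subgraph induced by
  *i*'s neighbours.
- **Small-worldness** against 1000 degree-matched Maslov–Sneppen rewirings:
  `γ = E_global / E_global^rand`, `λ = mean E_local / E_local^rand`,
  `σ = λ / γ`, small-world iff `σ > 1`.
- **Backbone network**: pairs connected consistently over the T time points,
  by a one-tailed sign test at α = 0.025 (null: |ρ| = 0, each time point a
  fair coin; `p = P(Bin(T, ½) ≥ k)`), weighted by the minimum |ρ| over time.
- **Group tests**: trapezoidal AUC of σ (or a metabolite's E_local) over the
  threshold sweep; whole-subject permutation (1000×, group sizes preserved)
  with the 95th-percentile critical-value rule and FDR-adjusted two-sided
  permutation p-values.

A Gaussian-copula cohort simulator with prescribed per-time-point Spearman
templates (2 × 11 subjects × 8 time points × 11 metabolites by default)
provides ground-truth data for validation and power exploration.

## Worked example

```r
library(metabnet)

# a synthetic two-group cohort with the default control/stress design
tab <- generate_cohort(cohort_config(seed = 7))

# CRLB quality filter (strict < 35% bound)
qc <- filter_by_crlb(tab, crlb_threshold = 35)
qc$report

# control-group network at time point 1, threshold 0.41
m   <- spearman_matrix(qc$table, "control", time_point = 1)
net <- binarize(m, 0.41)
net
small_worldness(net, n_random = 200, seed = 3)
```

```
CRLB quality report (threshold 35%)
  retained metabolites:  Ala, Cr, PCr, GABA, Glu, Gln, PCh, GSH, Ins, NAA, Tau
  excluded metabolites:  0
  excluded subjects:     0
Binary metabolic network (control, time point 1) at threshold 0.41: 27 edges
Small-worldness: sigma = 1.111 (gamma = 0.994, lambda = 1.105; 200 random networks)
  criterion sigma > 1: met
```

The control network is small-world (σ = 1.11 > 1): its designed Cr–PCr–Gln,
Glu–NAA–Tau and GABA–GSH–Ins clusters make it more locally clustered than
its degree-matched rewirings (λ = 1.105) at essentially unchanged global
integration (γ = 0.994). A group comparison of creatine's local-efficiency
AUC at a disrupted time point:

```r
cmp <- permutation_test(tab, metric_elocal_auc(3, "Cr"), n_perm = 200, seed = 11)
cmp
```

```
Permutation comparison (control - stress), n_perm = 200
  AUC: control = 0.0800, stress = 0.0000; diff = 0.0800
  95% critical value = 0.0776 -> reject; two-sided p = 0.0846
```

Creatine keeps local efficiency 0.0800 (AUC units: efficiency × threshold
width) in the control group and loses all of it under stress; the observed
difference exceeds the permutation critical value, so the one-tailed 5%
percentile rule rejects the no-difference null. The full pipeline — QC,
per-time-point sweeps, backbones, all comparisons with FDR — is one call:

```r
report <- run_full_analysis(analysis_config(
  input = cohort_config(seed = 7), n_random = 200, n_perm = 200,
  seed = 7, output_dir = "results"))
```

A thin CLI wrapper (`inst/scripts/metabnet.R`) exposes `simulate`, `qc` and
`run` subcommands for shell use.

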