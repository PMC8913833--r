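---
title: "Dynamic metabolic covariance networks from longitudinal MRS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic metabolic covariance networks from longitudinal MRS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The model

In vivo proton MRS yields, per animal and acquisition, a vector of
metabolite concentrations with per-estimate CRLB uncertainties (the shape of
LCModel output). metabnet treats the *covariation of concentrations across
subjects* as a network: nodes are metabolites, and an edge connects two
metabolites whose concentrations co-vary across the animals of one group at
one time point. Because concentration data at small n are non-normal, the
association measure is Spearman's rank correlation; because only the
presence of a coupling matters (not its direction), the absolute value
|&rho;| is used, and the matrix is binarized over a sweep of thresholds
(default 0.41–0.49 in steps of 0.01) rather than at one arbitrary cutoff.

Three layers of analysis sit on top of the binary networks:

* **Small-worldness.** For a network A, global efficiency is
  E<sub>global</sub>(A) = mean over node pairs of 1/d(i,j) (with 1/&infin; = 0),
  and a node's local efficiency is the global efficiency of the subgraph
  induced by its neighbours. Against the mean efficiencies of (by default)
  1000 degree-matched random networks — Maslov–Sneppen double-edge-swap
  rewirings that preserve every node's degree —
  &gamma; = E<sub>global</sub>/E<sup>rand</sup><sub>global</sub>,
  &lambda; = mean E<sub>local</sub>/E<sup>rand</sup><sub>local</sub>, and
  &sigma; = &lambda;/&gamma;. The network is called small-world when
  &sigma; &gt; 1: more locally clustered than chance at comparable global
  integration. The efficiency formulation (rather than characteristic path
  length) is used because thresholded 11-node networks are routinely
  disconnected, and efficiency handles infinite distances gracefully.

* **Backbone.** A connection is part of the *backbone* if it is present
  consistently across the T time points: a one-tailed sign test per pair,
  with the null "no connection" making each time point a fair coin, admits a
  pair when the binomial tail P(X &ge; k), X ~ Bin(T, ½), falls below
  &alpha; = 0.025. At T = 8 this effectively requires presence at all eight
  time points (P(X &ge; 8) = 1/256 &lt; 0.025 &lt; P(X &ge; 7) = 9/256). The
  backbone's edge weight is the minimum |&rho;| across time (the most
  conservative reading of "consistently present"; the median is available),
  so the backbone matrix can be thresholded and swept like any other.

* **Group comparison.** Metrics are summarised over the threshold sweep by
  their trapezoidal AUC (exact for the piecewise-linear 9-point curves).
  Group differences in an AUC are tested by permutation: whole subjects —
  each animal's complete longitudinal record — are reallocated between the
  groups at the original 11/11 sizes, both AUCs recomputed, and the observed
  difference compared against the 95th percentile of the permutation null
  (the printed type-I level of 0.05). A two-sided permutation p-value
  (1 + #{|null| &ge; |obs|})/(n<sub>perm</sub> + 1) is reported alongside;
  the critical-value decision is the headline rule. p-values are adjusted by
  Benjamini–Hochberg FDR within families: small-worldness comparisons across
  time points form one family, local-efficiency comparisons across
  metabolite × time point another, backbone comparisons a third.

## Quality control

Estimates are trusted only when CRLB &lt; 35% (strict inequality; an
estimate at exactly 35% fails). Filtering proceeds in two steps: subjects
whose spectra produce a failing estimate for any *core-panel* metabolite at
any time point are excluded first (a failure on a normally reliable
metabolite indicates a bad spectrum), then metabolites failing anywhere in
the remaining data are dropped from the panel. The core panel defaults to
the classic 11 hippocampal metabolites (Ala, Cr, PCr, GABA, Glu, Gln, PCh,
GSH, Ins, NAA, Tau); extended basis-set metabolites are judged only by the
second step. The two-step order is what lets an extended 17-metabolite
input table reduce to 11 metabolites while also excluding whole animals.

## What the synthetic cohorts emulate

No real cohort ships with the package; the generator produces tables with
the study's shape — 2 groups × 11 subjects × 8 time points × 11 metabolites
— and a *designed* rank-correlation structure:

* **Copula construction.** Per (group, time point), subject vectors are
  drawn from a Gaussian copula whose latent correlation is the target
  Spearman matrix mapped through r = 2 sin(&pi;&rho;<sub>s</sub>/6), then
  pushed through log-normal marginals (means near literature hippocampal
  concentrations in mM, CV 0.15 — the scale of across-animal biological
  variability). Rank correlations are invariant to the monotone marginal
  transform, so the data hit the Spearman targets asymptotically while
  staying strictly positive. Targets that are not quite positive
  semi-definite are repaired by eigenvalue clipping; a repair that moves any
  entry by more than 0.05 is an error rather than a silent change of design.

* **Control group.** Three node-disjoint equicorrelated triangles at
  Spearman 0.9 — Cr–PCr–Gln (the energy-buffer cluster), Glu–NAA–Tau, and
  GABA–GSH–Ins — with Ala and PCh unconnected. Disjoint cliques are
  positive-definite at any strength below 1, and the triangles give the
  thresholded networks the local clustering that makes &sigma; &gt; 1 across
  the whole sweep. Inter-cluster correlations are zero by design; at n = 11
  the sampling noise of Spearman correlations (null SD &asymp; 0.32) still
  adds roughly 4–18 spurious edges per network, which is the realistic
  regime the analysis must tolerate.

* **Stress group.** The Cr–PCr and Cr–Gln targets are removed at *every*
  time point, so the backbone Cr cluster can never form and creatine's
  local efficiency collapses. At the disrupted time points (default 2, 3
  and 5), all designed structure is dissolved except a Glu-centred open
  wedge: Glu–Gln at +0.66 and Glu–NAA at −0.66 with Gln–NAA held at zero —
  the emergent, unclustered Glu connectivity of the acute-stress phenotype.
  The sign alternation matters: two strong same-sign correlations force
  their shared third side positive (for two arms at Spearman s with a zero
  closing side, positive-definiteness requires roughly s &le; 0.66, and
  only mixed signs achieve it), so a signed wedge is how an *open* triangle
  is realisable at all. Full independence elsewhere is deliberate: at
  n = 11, any designed triangle-free scaffold (chains, cycles) *raises*
  small-worldness, because lattice-like structure lowers &gamma; faster
  than &lambda; — the ring-lattice effect. Independence is the maximally
  de-clustered background a rank-correlation generator can produce, and
  the disrupted networks then fail &sigma; &gt; 1 as often as sampling
  noise permits.

* **CRLB model.** A constant per-metabolite baseline (5%) plus explicitly
  injected failures for QC tests. CRLB values do not feed back into the
  concentration noise; no such coupling is part of the model.

What passing tests on these cohorts show is that the *machinery* recovers a
designed covariance phenotype at the study's sample size; they cannot show
that real hippocampal metabolism has that phenotype. Real data differ in at
least: within-subject temporal autocorrelation (the generator draws time
points independently), non-log-normal marginals, CRLB–concentration
coupling, and correlated quantification errors between overlapping
resonances (e.g. Glu/Gln).

## Numerical and design choices

* **Binarization** is strict (`>`): an entry exactly at the threshold is no
  edge. With continuous data the event has probability zero.
* **Zero-variance metabolites** (possible with injected constant channels)
  produce undefined correlations; entries are set to 0 with a warning
  rather than failing the run.
* **Sign-test modes.** With continuous data |&rho;| is almost never exactly
  0, so with the raw-|&rho;| reading eligibility at T = 8 effectively means
  "nonzero at all eight time points". The strict mode — a time point counts
  only when |&rho;| exceeds the lowest analysis threshold — is the variant
  under which the test's nominal level is meaningfully exercised, and is
  what the calibration study uses.
* **Rewiring** rejects swaps that would create self-loops or multi-edges,
  with a retry budget of 100 attempts per target swap (10 swaps per edge by
  default); saturated graphs come back unchanged. Ensemble connectedness is
  *not* enforced — efficiency metrics handle disconnection, and enforcing it
  would bias the null.
* **Degenerate ensembles.** On very sparse networks every rewiring can be
  triangle-free, making &lambda; 0/0. `small_worldness()` errors by default;
  the sweep and permutation machinery use the limiting convention:
  &sigma; = 0 when the real network also has no local structure, and
  &lambda; capped at n<sub>random</sub> + 1 when only the ensemble is flat
  (a finite ensemble resolves the ratio only up to its size). One empty
  cell therefore cannot abort a comparison, and an edgeless network has
  &sigma; = 0.
* **Seeding.** One master seed; every stochastic stage (each cohort block,
  each ensemble, each permutation) derives its own stream from a stage
  label, so adding a stage never shifts another stage's draws, and whole
  reports are bit-reproducible.
* **Problem sizes.** The package defaults mirror the full design (1000
  random networks, 1000 permutations). The validation suite runs scaled
  versions chosen as the smallest sizes that still measure each property:
  calibration of the percentile rule uses 200 cohorts × 200 permutations
  with a 10-network ensemble inside the metric (the rule's level rests on
  exchangeability of observed and permuted evaluations, not on the
  Monte-Carlo precision of &sigma;), design recovery uses 200-network
  ensembles over 20 cohorts, and the sign-test level uses 500 replicates.

## Known limitations

* With 11 subjects, the permutation null of the &sigma;-AUC is extremely
  dispersed (&sigma; of a resampled 11-node correlation network ranges from
  0 to above 5), so the power of the small-worldness comparison at the
  designed effect size is modest; the designed direction (control above
  stress at disrupted time points) is recovered far more reliably than a
  significant p-value. The creatine local-efficiency contrast is the
  sharper designed effect.
* Empirical correlation networks are intrinsically somewhat clustered
  (shared-subject rank noise creates transitive edge blocks), so even
  fully independent metabolites yield &sigma; &gt; 1 in about two-thirds of
  thresholded networks. "Losing small-worldness" at a disrupted time point
  is therefore a stochastic event by nature, not a deterministic one — in
  data as in simulation.
* The backbone of a disrupted group is typically very sparse; its
  small-worldness is then dominated by the degenerate-ensemble convention.
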