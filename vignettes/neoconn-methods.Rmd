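---
title: "Methods: neonatal connectome analysis with neoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal connectome analysis with neoconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoconn)
```

`neoconn` analyses cohorts of weighted undirected structural connectomes —
per-subject matrices whose nodes are parcellation regions (93 by default) and
whose edge weights summarize white-matter connectivity, in
SIFT2-streamline-weight units — together with clinical covariates and toddler
behaviour outcomes. This vignette explains the models and procedures, the
parameters that matter, the synthetic data the package generates for itself,
and the numerical and design choices made where the methodology left room.

The pipeline starts at the matrix level: tractography, parcellation and
weight construction are upstream and out of scope.

## Data model and conventions

A connectome is a square symmetric nonnegative matrix with zero diagonal and
unique node identifiers. On input, asymmetries up to a relative tolerance of
1e-8 are averaged away (they arise from numeric round trips); anything larger
is an error rather than a silent repair, because large asymmetry usually
means a transposed or corrupt file. Files are CSV or TSV, with an optional
header row of node identifiers; when a node table is supplied, headered files
are reordered to its node order and headerless files are assumed already
ordered. Missing numeric cells in the cohort table become `NA`, never zero,
and every analysis applies listwise deletion over the variables it actually
uses, so each analysis has its own n.

## Graph metrics and cost correction

Density, nodal strength and degree, global efficiency, and nodal/local
efficiency are defined in the standard way for weighted networks. Two
conventions needed fixing:

* **Path lengths.** Shortest paths use edge length `1/w` — the reciprocal
  transform used by the common brain-connectivity toolboxes — so stronger
  connections are shorter. Efficiencies are means of inverse path lengths
  with `1/Inf = 0` for disconnected pairs.
* **Nodal efficiency.** We implement the per-node *local* efficiency: the
  efficiency of the subgraph induced by a node's neighbours, computed on the
  original weights among those neighbours (paths may not detour through the
  hub node itself), zero for nodes with fewer than two neighbours. An
  alternative reading — inverse closeness of the node — exists in the
  literature; we follow the neighbourhood-subgraph definition because it is
  the segregation measure whose average over nodes is the network's local
  efficiency.

Raw densities differ between subjects and confound every metric, so each
network is reduced to a series of fixed densities (0.05 to 0.50 in 0.01
steps, 46 values) by proportional thresholding — keeping the
`k = round(d · N(N−1)/2)` strongest edges, weights retained — and each
feature is averaged across the grid ("cost correction"). Numerical choices:
`k` rounds half away from zero; ties between equal weights break by
lexicographic node-pair order so results are deterministic; a network already
at or below a target density is left unchanged; degree is counted on the
binarized support of the surviving edges while strength and efficiencies use
the surviving weights.

## Core–periphery decomposition

Nodes are partitioned into a core and a periphery by maximizing

    q = (W_cc + W_cp − W_pp) / W_total = 1 − 2 W_pp / W_total

where `W_cc`, `W_cp`, `W_pp` are the total weights on core–core, core–
periphery and periphery–periphery edges. The ideal discrete core–periphery
pattern — any weight inside the periphery is penalized — scores 1 exactly
when the core covers every positive edge. That makes the maximum a plateau:
demoting a core node costs nothing while it has no weight into the periphery.
The search is an adapted Kernighan–Lin procedure: from a random labeling,
sweeps in which every node is moved at most once (the best single-label move
is applied even when momentarily worsening, moved nodes are locked, and the
sweep reverts to its best prefix) run until no sweep improves; the best of
100 random restarts is kept. Determinism on the plateau is imposed by a
two-part tie-break: after convergence the core is shrunk deterministically
(highest-index core nodes whose demotion leaves `q` unchanged are demoted),
and restarts with equal quality are compared by lexicographically smallest
core set. On planted structures where the periphery attaches only to the
core — the configuration the quality function idealizes — this recovers the
planted partition exactly, and the test suite verifies agreement with
exhaustive enumeration up to 12 nodes. On dense noisy networks the
vertex-cover character of the optimum inflates the core; for reproducing a
published partition the package therefore also accepts an externally
supplied node table with `partition_label`, which is how the bundled
frontal-limbic worked example is typed. Group-level partitions can be
computed from the element-wise mean connectome (default) or by per-subject
partition majority vote; edge types follow from the endpoint labels (core,
feeder, peripheral).

## Network-based statistics

For each edge present in at least 90% of subjects (configurable; a mask
prevents regressions on mostly-absent edges), edge weight is regressed on an
intercept, the nuisance covariates and the behaviour predictor; the
predictor's t statistic has `n − p` degrees of freedom. Zero-residual
(perfect) fits are capped at a sentinel of 1e6; zero-variance edges report
t = 0; covariates constant over the retained subjects are absorbed by the
intercept and dropped.

Edges whose t exceeds the primary threshold (default 3.1) in the contrast
direction (default negative: reduced connectivity with higher symptom
scores) form a graph whose connected components are the candidate
subnetworks. Family-wise error over components is controlled on *extent*
(edge count): the null distribution of the maximum component extent is built
by Freedman–Lane permutation — fit the nuisance-only model, permute its
residuals, re-add the fitted nuisance signal, refit the full model — which is
the accepted scheme for GLM permutation with nuisance covariates. The
p-value `(1 + #{null ≥ observed}) / (1 + B)` includes the observed statistic
(add-one), so p is never zero and the test is valid at finite B. Defaults:
10,000 permutations, critical p 0.025 (two behavioural outcomes tested).
Because results depend on the primary threshold, a sensitivity sweep repeats
the test at t = 2.5–3.5 in 0.1 steps using a common permutation stream, so
rows of the sweep differ only by threshold and not by Monte-Carlo noise.

## Behaviour scores and the association layer

Raw internalizing/externalizing scores are counts; all analyses use their
standardized residuals after OLS on corrected age at follow-up (sample mean
0, SD 1 over fitted subjects; an exact fit is flagged and residuals reported
as 0). Partial Spearman correlation is computed as rank transform (average
ranks for ties, appropriate for integer scores), OLS residualization of the
ranked variables on the ranked covariates, and Pearson correlation of the
residuals, with the t approximation on `n − 2 − k` degrees of freedom; an
exact permutation p-value is available for small samples (recommended below
n = 15). With no covariates this reduces exactly to plain Spearman
correlation. Benjamini–Hochberg FDR is applied within explicit families —
all nodes × metrics per outcome for nodal tests, all clinical-variable tests
per outcome for the clinical family — because pooling choices change the
adjusted values and so must be stated configuration, not an accident of call
order. T-score banding (normal < 60, borderline 60–63, clinical > 63) and
the brain-injury grading rules (WMI by focus count and size with severity
precedence; overall rating moderate/severe iff WMI is moderate/severe or a
cerebellar haemorrhage exceeds 2 mm) are total, vectorized functions.
Raw-score-to-T-score conversion uses proprietary norm tables and is out of
scope; T-scores are inputs.

## The synthetic cohort generator

No cohort of this kind can be shipped, so the package generates its own.
The generator emulates what the analysis *assumes* about the data:

* **Topology.** Edge presence is a stochastic block model over a planted
  34-core / 59-periphery split (93 nodes): core–core densest, then feeder,
  then periphery–periphery (presence ratios 1.5 : 1 : 0.75, scaled so the
  expected overall density is 0.6). Positive weights are log-normal with
  block-specific log-means (4.0 / 3.2 / 2.8) and common log-SD 0.5 — heavy
  tailed, like summed SIFT2 streamline weights, with the core carrying the
  heaviest connections.
* **Covariates.** Gestational age ~ N(38.6, 0.5) weeks; scan age adds a
  small positive lag; sex balanced; moderate/severe brain injury with
  probability 6/43; cognitive composite ~ N(93.6, 10.2); deprivation index
  log-normal (median ≈ 18.7); follow-up age ~ N(22.1, 0.35) months.
* **Outcomes.** Internalizing and externalizing raw scores are
  negative-binomial counts (means 7.5 and 13, sizes 2 and 4 — medians and
  spreads in the range seen in toddler CHD cohorts) whose log-mean has a
  mild corrected-age trend, so the age-residualization stage has real signal
  to remove.
* **Planted effect.** Each designated effect edge's weight is shifted by
  `beta × z` (z the cohort-standardized behaviour score) plus N(0, 2) noise
  and floored at zero, keeping the association linear in the sense the
  edgewise GLM tests. Effect edges are always present in every subject so
  the planted subnetwork cannot be removed by the presence mask — the
  planted-recovery scenarios test the statistics, not the mask.

Default cohort size is 43 subjects. The whole cohort is a pure function of
the configuration including its seed; null ensembles derive and record
per-cohort seeds so any single cohort is regenerable in isolation.

Choosing the log-SD deserves a note. The planted effect is additive on the
weight scale, so its detectability is governed by the ratio of `beta` to the
within-edge across-subject weight SD, while the zero floor bites when `beta`
is comparable to the weight median. At log-SD 0.5 a `beta` of −30 on
core–core edges is about 0.9 within-edge SDs — a strong effect that rarely
reaches the floor — which makes planted-recovery a well-posed question. At
substantially larger log-SDs no additive `beta` is simultaneously strong and
floor-safe. Log-SD 0.5 (≈ 53% coefficient of variation) is within the range
reported for repeated-measure variability of tractography edge weights.

What the generator does *not* emulate: spatial embedding and
distance-dependent connectivity, between-subject correlation structure in
topology (each subject's presence pattern is drawn independently),
measurement artefacts such as motion, and any dependence of covariates on
connectivity. Passing tests therefore show the statistics behave correctly
under the model's assumptions — calibrated type-I error, power against
planted linear effects — not that real neonatal data meet those assumptions.

## Pipeline and reproducibility

The pipeline (YAML config, or the `inst/cli/neoconn.R` wrapper) runs: data
(load or simulate) → cost-corrected metrics → core–periphery partition and
edge typing → partial Spearman associations with FDR (global and nodal, per
outcome) → NBS with sensitivity sweep. One master seed deterministically
derives per-stage seeds (simulation, partition restarts, permutation
streams), so stages can be re-run in isolation and a full re-run with the
same config is byte-identical in every result table; timestamps are confined
to the run log. Failure of one outcome's analysis is recorded in the report
and does not abort the others.

For routine testing the permutation count and density grid are scaled down
in the test configurations (e.g. 40–500 permutations, coarse grids, 14–40
subjects); the analysis defaults remain 10,000 permutations and the 46-step
grid. The calibration suite uses 200 null cohorts of 40 subjects with 500
permutations each and 50 planted-effect replicates — sizes at which the
Monte-Carlo standard errors quoted with each check are small enough to be
informative while the whole suite stays desk-scale.

## Known limitations

* The core–periphery quality's optimum is a plateau (see above); on dense
  networks the partition is only meaningful together with its tie-break, and
  group partitions of dense synthetic cohorts tend toward large cores.
* Partial Spearman p-values rely on the t approximation except when the
  permutation option is chosen; for n below ~15 the approximation is rough.
* The edgewise GLM assumes homoscedastic Gaussian errors per edge; SIFT2
  weights are heavy tailed, which the permutation layer absorbs for FWE
  control but which still affects per-edge t magnitudes.
* The NBS edge-inclusion mask and the exact permutation scheme of published
  toolboxes vary by version; both are explicit, configurable choices here
  (90% presence; Freedman–Lane).
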