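---
title: "Multilayer subject-similarity networks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer subject-similarity networks: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Heterogeneous, multifactorial diseases — Alzheimer's disease being the
motivating case — are measured through several weakly coupled windows at
once: regional brain volumes from structural MRI, amyloid burden from PET,
CSF analytes, cognitive test batteries, and genetic risk. Single-modality
clustering uses one window at a time; naive feature concatenation lets the
largest or noisiest modality dominate. `multinet` instead represents each
modality as one *layer* of a multilayer network whose nodes are subjects,
and looks for communities of subjects that are supported jointly, but not
necessarily identically, across layers.

# Model

## Similarity layers

Within a modality, the edge weight between subjects $i$ and $j$ is the
Pearson correlation of their preprocessed feature vectors. Preprocessing
runs, per modality and in this order:

1. **Mean centering** of every feature.
2. **Covariate residualization** by OLS with intercept: age, sex and total
   intracranial volume for MRI and PET; age and sex for CSF and cognition;
   sex only for genetics. All covariate sets are overridable.
3. **Normalization**: min–max scaling of each feature to $[0,1]$ for all
   modalities except genetics, which is z-scored (allele counts and
   polygenic scores have no natural maximum). A literal
   divide-by-the-maximum mode (`max_divide`) is also available; it cannot
   map already-centered (signed) data into $[0,1]$, which is why the
   default honors the scaling intent with min–max instead.

Because step 3 is not idempotent, tables carry a `preprocessed` flag and the
chain refuses to run twice; similarity construction refuses unflagged
tables, since correlating features of mixed provenance is only meaningful
after per-feature normalization.

## Multilayer modularity

With per-layer adjacency $A_{ijl}$, per-layer Newman–Girvan null
$M_{ijl} = k_{il} k_{jl} / 2m_l$, per-layer resolution $\gamma_l$, and a
uniform coupling $\omega$ linking each subject's copies across all layer
pairs (categorical coupling; modalities are unordered — an ordinal chain is
available as an option), the quality of an assignment $g_{il}$ of node-layers
to communities is

$$Q = \frac{1}{2\mu}\sum_{ijlr}\Big\{(A_{ijl}-\gamma_l M_{ijl})\,\delta_{lr}
      + \delta_{ij}\,\omega\Big\}\,\delta(g_{il},g_{jr}),$$

where $2\mu$ counts all intra-layer strengths plus every coupling edge from
both endpoints. The coupling term carries no null model, following the
multislice formulation this quality function comes from. The implementation
evaluates $Q$ through the supra-modularity matrix $B$ (diagonal blocks
$A_l - \gamma_l M_l$, coupling entries on off-diagonal block diagonals); a
test pins the supra-matrix form against a literal quadruple-sum oracle to
$10^{-12}$ on random signed instances.

## Optimization

`genlouvain()` maximizes $Q$ by generalized Louvain: greedy single
node-layer moves in a randomly shuffled visit order (including the option of
*isolating* a node into an empty community, which matters on signed
matrices), aggregation of communities into super-nodes, repetition on the
aggregated matrix, and an outer iteration that restarts the multi-level run
from its own flattened partition until the $Q$ gain drops below `tol`
(default $10^{-10}$). Ties in the move gain keep the current community,
otherwise the lowest community id wins. Several restarts (default 20) are
run and the best partition kept. All randomness is drawn under one integer
seed through an isolated RNG scope, so results are reproducible and the
caller's RNG state is untouched.

The number of communities is emergent from $Q$; it is never fixed in
advance. With $L = 1$ and $\omega = 0$ the quality function reduces exactly
to single-layer Newman–Girvan modularity — the monolayer analysis is this
special case, and a test cross-checks it against igraph's independent
implementation.

**Known limitation.** Greedy modularity search cannot escape every local
optimum. On small signed instances we verified one case whose global
optimum (found by exhaustive enumeration over all set partitions) is
unreachable: the greedy result is a strict local optimum under all single
moves, isolations and merges, for every restart. The test suite therefore
asserts that the optimizer never exceeds the exhaustive optimum and attains
it on essentially all small instances (50/50 seeded trials at $\le 8$
node-layers in the acceptance suite).

Another structural fact worth knowing: a *phase-1 sweep alone*, from
singletons, stalls on strongly coupled layers. On the 6-subject/2-layer
planted toy with $\omega = 1$, every node-layer first merges with its
cross-layer copy (coupling gain 1 beats the within-block gain 2/3), after
which no single-node move is positive; the aggregation level then merges
the pairs and recovers the planted blocks. This is why `genlouvain()`, not
`louvain_sweep()`, is the user-facing optimizer.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` ($\gamma_l$) | 1 | per-layer resolution; larger favors more, smaller communities |
| `omega` ($\omega$) | 1 | interlayer coupling; 0 decouples layers, large values force layer-consistent membership |
| `restarts` | 20 | randomized restarts of the optimizer |
| `tol` | 1e-10 | convergence tolerance on $Q$ |
| `sanitize_mode` | `shift_rescale` (pipeline) | mapping of signed correlations before the null model |
| `amyloid_cutoff` | 1.11 | SUVR positivity threshold; the boundary counts as positive |

$\gamma_l = 1,\ \omega = 1$ are the neutral defaults of the multislice
framework; both are exposed in `run_config()` for sweeps.

**Why the pipeline default sanitize mode is `shift_rescale`.** The
modularity core accepts signed weights directly, and `sanitize_layer()`'s
own default is `keep_signed`. But the Newman–Girvan null divides by the
total layer weight $2m_l$, and for correlation layers with balanced
positive/negative structure $2m_l$ can sit arbitrarily close to zero,
making $M = kk^\top/2m$ ill-conditioned (and flipping its sign with the
sign of $2m$). The affine map $w \mapsto (w+1)/2$ preserves the ordering of
similarities, keeps the layer dense and nonnegative, and makes the
configuration null well-behaved; it is therefore the default *for the
pipeline*, chosen on these mathematical grounds. `keep_signed` and
`clip_negative` remain one switch away.

**Boundary rule.** Amyloid positivity is `SUVR >= cutoff`: positivity at
threshold is the common reading of an SUVR cutoff; the rule is explicit and
configurable (`inclusive = FALSE` for a strict threshold).

# Evaluation

Communities are cross-tabulated against diagnosis (early/late MCI collapsed
to MCI in the main table, kept in an auxiliary one). The community with the
largest AD share is labeled AD-dominant, the largest CN share CN-dominant,
the rest intermediate; sensitivity is the percentage of AD subjects in the
AD-dominant community and specificity the percentage of CN subjects in the
CN-dominant one. MCI subjects enter neither metric; with more than two
communities, intermediate communities count as misses for both, so the
metrics stay 2x2-comparable. Confidence intervals are exact Clopper–Pearson
from beta quantiles — chosen because, on the reference contingency the
package reproduces (123/135 and 123/150 at the 95% level), the exact method
matches the published bounds where Wilson's approximation does not; a test
checks the implementation against direct binomial-tail root finding.

Feature-level group contrasts use two-sided Mann–Whitney U tests with
$U = \min(U_a, U_b)$ (midranks for ties), scaled by the maximum $U$ of the
call for interpretability, with Bonferroni (family = features in the call)
or Benjamini–Hochberg correction at 0.05.

Longitudinal behavior is summarized by transition categories (stable CN,
CN→MCI, CN→AD, stable MCI, MCI→AD converters, MCI→CN reverters, stable AD);
per category the package reports each community's share. Empty categories
report empty counts, never a division by zero.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the physics of any scanner:

- A latent subtype $z_i$ (2 by default, mirroring a CN-like/AD-like split;
  3 mirrors amyloid-stratified analyses) shifts an `affected_fraction`
  (default one half) of each modality's features by `delta` noise-SD units
  — with *alternating signs* across affected features, because real
  biomarker panels move in both directions (CSF amyloid falls while tau
  rises). The alternation is what keeps few-feature layers (3 CSF analytes,
  3 genetics features) informative: subject-pair correlations over 3 values
  are near $\pm 1$, and the sign pattern, not the magnitude, carries the
  subtype.
- Each subject expresses the subtype in a given layer with probability
  `rho` (layer consistency); below 1, layers carry complementary rather
  than redundant signal, which is the regime where interlayer coupling
  should pay off — and measurably does (the acceptance suite compares
  multilayer and best-monolayer recovery at `rho = 0.6`).
- Age, sex and ICV confounds enter every feature linearly with per-feature
  loadings, so they survive into subject-pair correlations unless
  residualized away.
- Genetics contributes an allele-count-like discrete feature (binomial with
  subtype-dependent frequency) plus two continuous polygenic-score-like
  features; at least 3 features are enforced so the layer's correlations
  are not fully degenerate.
- Diagnoses derive from the subtype with flip rate `epsilon` (recorded in
  the truth table, so mismatch behavior is testable: flipped subjects
  should land with their latent subtype, not their label), a severity
  score splits MCI into early/late at the median, and final diagnoses
  simulate conversion, reversion and dropout. Amyloid SUVRs are drawn
  around the 1.11 boundary (CN-like mean 1.00, AD-like mean 1.35, SD 0.10).

What the generator does *not* emulate: spatial covariance among brain
regions, scanner/site effects, non-linear covariate action, longitudinal
measurement series. Passing the recovery tests therefore demonstrates that
the pipeline recovers planted block structure under covariate confounds and
label noise — not that it would recover any particular clinical cohort's
subtypes.

## Problem sizes used in the tests

The recovery experiments run cohorts of $n = 200$ subjects, 5 layers
(feature counts 90/68/3/6/3), $\delta = 1$, $\varepsilon = 0.1$, 20
optimizer restarts, over 10 generator seeds — at $\rho = 0.9$ for absolute
recovery (median adjusted Rand index against the planted subtypes
$\ge 0.8$) and $\rho = 0.6$ for the multilayer-vs-monolayer comparison.
Oracle checks use exhaustive enumeration up to 8 node-layers (4140 set
partitions) and literal quadruple sums up to $n = 6,\ L = 3$. These sizes
exercise every code path at full statistical fidelity while keeping the
default suite quick to run.

# Numerical choices and degenerate inputs

- Residualization uses QR (`qr.resid`); rank-deficient covariate designs
  are an error naming the collinear columns, not a silent drop.
- Constant feature columns: centering and z-scoring warn and yield zeros;
  min–max scaling warns and yields 0.5.
- A subject with a zero-variance feature vector has no defined correlation
  with anyone; the layer builder errors naming the subject.
- A layer whose total weight is exactly zero has no configuration null;
  `newman_girvan_null()` errors rather than dividing by zero.
- Community ids are consecutive integers `1..K` (R convention) relabeled by
  first appearance; all reported quantities are invariant to relabeling
  (tested).
- Consensus per subject is the majority community across layers, ties
  resolved toward the earliest layer in assembly order; a flag records
  whether any subject was split at all.

# Reading the outputs

`run_pipeline()` writes `partition.csv` (one row per subject x layer, plus
the consensus label), `contingency.csv` (counts and within-diagnosis
percentages for baseline and final diagnosis), and `metrics.json`
(modularity, community count, sensitivity/specificity with exact CIs for
both denominators, transition shares). Baseline-denominator metrics use the
baseline diagnosis with early/late MCI collapsed; final-denominator metrics
drop subjects lost to follow-up and report how many.
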