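# multinet

Multilayer subject-similarity networks for multimodal disease subtyping.

## The problem

Heterogeneous disorders such as Alzheimer's disease (AD) are measured
through several modalities at once — regional brain volumes (structural
MRI), amyloid burden (PET SUVRs), CSF analytes, cognitive batteries, and
genetic risk — yet most analyses cluster one modality at a time or
concatenate features and let the largest table dominate. `multinet` builds
one *subject similarity network per modality* (nodes = subjects, edge
weights = pairwise correlations of preprocessed feature vectors), ties the
layers into a single multilayer network, and finds communities of subjects
supported jointly across modalities. It is aimed at researchers clustering
multimodal cohort data who want one model instead of five parallel ones.

## The model

Per layer $l$, adjacency $A_{ijl}$ comes from subject-pair correlations and
the Newman–Girvan null is $M_{ijl} = k_{il} k_{jl} / 2m_l$. Subject copies
across layers are tied by a uniform coupling $\omega$ (all layer pairs).
Communities maximize the multislice modularity

$$Q = \frac{1}{2\mu}\sum_{ijlr}\left\{\left(A_{ijl}-\gamma_l M_{ijl}\right)\delta_{lr}
     + \delta_{ij}\,\omega\right\}\delta(g_{il},g_{jr})$$

via an iterative generalized Louvain optimizer (greedy moves + aggregation
+ outer iteration, multiple seeded restarts; the community count is
emergent, never fixed). $\gamma_l$ is the per-layer resolution (default 1),
$\omega$ the interlayer coupling (default 1); $L=1,\ \omega=0$ reduces
exactly to single-layer Newman–Girvan modularity.

Communities are then evaluated against diagnosis: contingency tables,
AD-/CN-dominant labeling, sensitivity/specificity with exact
Clopper–Pearson 95% CIs, amyloid stratification at SUVR 1.11, longitudinal
transition breakdowns (MCI→AD converters, MCI→CN reverters, ...), and
scaled Mann–Whitney U feature maps with Bonferroni/FDR correction.

A synthetic multimodal cohort generator with planted subtypes, covariate
confounds, diagnosis label noise and longitudinal transitions drives the
test suite end to end — no data download is required anywhere.

## Worked example

```r
library(multinet)

# a synthetic 120-subject cohort: 5 modalities, 2 planted subtypes,
# 1-SD effect on half the features, 10% diagnosis label noise
cohort <- generate_cohort(synthetic_config(n_subjects = 120, seed = 42))

cfg <- run_config(restarts = 10, seed = 42)   # gamma = 1, omega = 1
res  <- run_pipeline(cfg, cohort, quiet = TRUE)
print(res)
#> <multilayer_partition> 2 communities over 120 subjects x 5 layers, Q = 0.158350 (some subjects split across layers)
#> community labels: 1=CN-dominant, 2=AD-dominant
#> final diagnosis: sensitivity 86.9%, specificity 88.1%

recovery_score(res$partition$consensus, cohort$truth$subtype)
#> [1] 0.8387097

res$contingency_final$counts
#>   CN MCI AD
#> 1 37  11  8
#> 2  5   3 53
```

The optimizer found two communities; community 2 holds 53 of the 61
subjects whose final diagnosis is AD (sensitivity 86.9%) and community 1
holds 37 of the 42 cognitively normal subjects (specificity 88.1%). The
adjusted Rand index of 0.84 says the consensus communities recover the
planted latent subtypes almost perfectly up to the configured label noise.
`run_pipeline(..., out_dir = "out/")` additionally writes `partition.csv`,
`contingency.csv` and `metrics.json`.

A thin command-line front end is included at `inst/cli/multinet.R`
(`run`, `simulate`, `evaluate` subcommands over YAML configs mirroring
`run_config()` / `synthetic_config()` field-for-field).

See `vignettes/multilayer-subtyping.Rmd` for the full account of the model,
preprocessing, parameter defaults, and the design decisions.

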