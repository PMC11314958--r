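# connectolesion

Graph-theoretic analysis of structural brain connectomes in case-control
neuropathology cohorts, built around virtual-lesion resilience.

## The problem

Diffusion tractography summarizes a brain's white-matter wiring as a
symmetric matrix $W$ of streamline-weighted connection strengths between
$n$ parcellated grey-matter regions (here $n = 225$). In neurodegenerative
disease — the motivating application is postmortem Parkinson disease (PD)
versus control cohorts — two questions arise per region: has its *topology*
changed (centrality, clustering), and how *resilient* is the whole network
to its failure? This package implements that analysis end to end:

1. **Graph construction** — per-subject proportional thresholding (keep the
   top 20% strongest connections, $k = \mathrm{round}(0.20 \cdot
   n(n-1)/2)$) and binarization.
2. **Topology** — global efficiency
   $GE = \frac{1}{n(n-1)}\sum_{i \ne j} d_{ij}^{-1}$, nodal clustering
   $cc_i = 2t_i/(k_i(k_i-1))$, and eigenvector centrality (unit-norm
   leading eigenvector of the adjacency matrix), implemented from first
   principles and oracle-verified.
3. **Virtual lesioning** — for each region of interest,
   $\Delta GE = GE_{\mathrm{lesion}} - GE$ after deleting that single node;
   values near zero mean the network tolerates the failure.
4. **Rank-based inference** — group contrasts by Jaeckel's rank-dispersion
   regression with Wilcoxon scores (age, sex, postmortem delay as
   covariates), Cohen's *d* on raw values, exact one-sample signed-rank
   deviation tests, partial Spearman correlations with covariates,
   Mann-Whitney/Fisher demographics tests, and Benjamini-Hochberg FDR
   within explicit families.
5. **Synthetic cohorts** — a fully seeded generator (15 controls + 19 PD,
   modular geometric 225-node connectomes, Braak-stage-scaled reliance on
   the dorsal anterior insula node, stage-coupled regional pathology) so
   the whole pipeline is testable without restricted clinical data.

See `vignettes/network-resilience-methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(connectolesion)

cfg     <- cohortConfig(seed = 42)      # the default synthetic study design
cohort  <- simulateCohort(cfg)          # subjects, pathology, 34 connectomes
results <- runPipeline(cohort)          # metrics + all statistics

gt <- results$groupTests
gt[!gt$outliers_excluded & gt$region %in% c("dai", "phg") &
   gt$metric %in% c("ec", "dge"),
   c("metric", "region", "estimate", "d", "p", "p_fdr")]
#>  metric region  estimate      d        p    p_fdr
#>      ec    dai  3.95e-02  4.841 1.37e-11 1.10e-10
#>      ec    phg -5.90e-03 -0.691 9.21e-04 3.69e-03
#>     dge    dai -1.38e-03 -3.375 4.89e-07 3.91e-06
#>     dge    phg  7.28e-05  0.157 2.24e-01 3.59e-01
```

The generator's injected effect concentrates connection mass on the dorsal
anterior insula (`dai`) in proportion to Braak alpha-synuclein stage, so the
PD network relies on that node: its removal costs the cases more global
efficiency (`dge` row: adjusted difference −1.4 × 10⁻³, *d* = −3.4,
surviving the 8-region FDR family), and its eigenvector centrality is
correspondingly higher in cases. Regions without an injected effect (e.g.
parahippocampal `dge`) stay null.

```r
st <- results$stagingCorrelations
st[st$family == "staging", c("variable", "r_s", "p", "p_fdr")]
#>    variable    r_s        p    p_fdr
#>  braak_asyn -0.796 8.49e-08 2.55e-07
#>   braak_nft -0.422 1.80e-02 2.70e-02
#>        thal -0.167 3.70e-01 3.70e-01
```

Insula ΔGE falls with Braak alpha-synuclein stage (partial Spearman with
age/sex/postmortem-delay covariates, FDR across the 3 staging systems) —
the stage-coupled mechanism the generator injects; the weaker Braak-NFT
correlation is carried by the stage correlation between the two systems.

`writeReport(results, "out/")` writes the per-subject metrics both wide
(`metrics.csv`: one row per subject, one column per measure) and tidy long
(`metrics_long.csv`: subject_id, metric, region, value), plus
`group_tests.csv`, `deviation_tests.csv`, `correlations.csv`,
`results.json` and a Markdown report. A thin command-line front end ships in `inst/scripts/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","connectolesion",package="connectolesion"))')" \
    all --config cfg.yaml --out results/
```

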