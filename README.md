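# pathsem

Pathway perturbation analysis for two-group gene expression studies via
observed-variable structural equation modeling (SEM).

## The problem and who this is for

Case/control expression studies usually stop at a list of differentially
expressed genes (DEGs). But phenotypes arise from perturbed *pathways*:
sets of genes wired together by activation and inhibition. `pathsem` is
for researchers who want to go from an expression matrix and a set of
curated pathway graphs to quantitative, testable statements about *which
regulatory links change between groups*:

1. **DEG detection** by Significance Analysis of Microarrays (SAM):
   modified t-statistics `d_i = r_i / (s_i + s0)` with a permutation null
   and an adjustable Δ threshold trading off FDR against sensitivity.
2. **Pathway ranking** by combining over-representation evidence (the
   hypergeometric tail `pNDE`) with topological perturbation accumulation
   (`pPERT` from the propagation model `PF = ΔE + M·PF`, where
   `M[i,j] = sign(j→i)/outdeg(j)`), into the global `pG = c − c·ln c`,
   `c = pNDE·pPERT`.
3. **Module extraction**: all shortest paths between DEGs on the pathway
   graph, optional merging of non-DEG nodes into protein superfamilies,
   and edge pruning by Fisher-z partial-correlation tests.
4. **SEM fitting**: the module becomes a linear structural model
   `y = By + ζ`, `ζ ~ N(0, Ψ)`, with implied covariance
   `Σ(θ) = (I−B)⁻¹ Ψ (I−B)⁻ᵀ` fitted by maximum likelihood
   (χ² = N·F_ML, RMSEA, SRMR, CFI, AIC, BIC), refined iteratively via
   modification indices.
5. **Group comparison**: a base model, a node-effects model (binary group
   variable directed into every node), and a two-group edge-effects model,
   compared by likelihood-ratio tests; per-edge differences
   `d_est = β̂¹ − β̂⁰` with Wald intervals; Brown's method for combining
   dependent p-values.

Everything runs offline: a simulation module generates expression data
from known structural models so the full pipeline is testable end-to-end.

## Worked example

A bundled scenario embeds a five-gene chain `A→B→C→D→E` (one path
coefficient differing between groups: 0.25 vs 0.75 on `C ~ B`) in 2,000
background genes, 40 of them mean-shifted; 150 samples per group.

```r
library(pathsem)
sc  <- end_to_end_scenario("perturbed-chain", seed = 7)
sam <- sam_deg(sc$matrix, sc$labels, delta = 0.95, n_perm = 100, seed = 7)
sam
#> SAM result: 2005 genes, delta = 0.95, s0 = 0.1077
#>   cutoffs [-Inf, 3.183], called = 45, FDR = 0

tab <- rank_pathways(sc$pathways, sam, sc$matrix, n_boot = 2000, seed = 7)
head(tab[, c("pathway","k","m","pNDE","tA","pPERT","pG","pG_fdr")], 3)
#>    pathway k m     pNDE    tA  pPERT       pG   pG_fdr
#> 1   chain5 5 5 4.55e-09 11.29 0.0015 1.82e-10 3.82e-09
#> 7   null06 5 1 1.07e-01  5.42 0.3888 1.74e-01 1.00e+00
#> 11  null10 5 1 1.07e-01  1.31 0.4433 1.93e-01 1.00e+00
```

All five chain genes are called DE (45 calls ≈ 5 chain genes + 40
spike-ins), and the perturbed chain ranks first by `pG`. Fit the module
SEM and compare groups:

```r
module <- extract_perturbation_module(annotate_degs(sc$pathways[[1]],
                                                    sam$deg_ids))
model  <- build_sem_model(module)
set    <- fit_group_models(model, sc$matrix, sc$labels)
set$comparison
#>     model npar chisq df   pvalue   cfi  aic  bic  rmsea   srmr
#>  fit_base    9  27.0  6 0.000143 0.972 3532 3566 0.1081 0.0612
#>  fit_node   14  16.7  7 0.019687 0.990 3753 3805 0.0678 0.0296
#>  fit_edge   18  21.7 12 0.041547 0.976 3301 3367 0.0518 0.0657

edge_effects(set)$table
#>  lhs op rhs   d_est   d_se    d_z d_lower d_upper
#>    B  ~   A  0.0650 0.0929  0.699  -0.117   0.247
#>    C  ~   B  0.3423 0.0843  4.063   0.177   0.507
#>    D  ~   C  0.0982 0.1028  0.955  -0.103   0.300
#>    E  ~   D -0.0367 0.0962 -0.381  -0.225   0.152
edge_effects(set)$verdict
#> [1] "edge invariance rejected"   # LRT p = 0.00277
```

Only the truly perturbed edge `C ~ B` has a significant group difference
(`d_z = 4.06`); its estimate is attenuated below the generating 0.5
because the scenario's group-to-node mean shifts inflate the pooled
variances used for standardization (see the methods vignette).

## Command-line interface

`inst/cli/pathsem.R` exposes the workflow as commands `deg`, `enrich`,
`module`, `fit`, `groups`, `simulate`, configured by YAML plus flag
overrides; results are written as TSV with fixed headers, logs go to
stderr:

```sh
Rscript inst/cli/pathsem.R simulate --scenario perturbed-chain --seed 7 --out demo
Rscript inst/cli/pathsem.R deg --expression demo/expression.tsv \
    --labels demo/labels.tsv --delta 0.95 --seed 7 --out demo/run
```

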