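# pbinet

Paired biomarker scoring and metabolite ratio networks for
longitudinal metabolomics.

`pbinet` is for analysts working with paired concentration data — the
same subjects measured at a baseline and at one or more follow-up
timepoints, e.g. a targeted MS/MS panel (amino acids, acylcarnitines,
lactate, in µmol/L) sampled at rest and at peak workload of a bicycle
stress test. It answers two questions:

1. *Which analytes respond?* Each metabolite is ranked by the **paired
   Biomarker Identifier (pBI)**, a signed score of within-subject
   change:

   pBI = λ · DA\* · |Δ<sub>change</sub> / CV| · sign(Δ<sub>change</sub>),  
   Δ<sub>change</sub> = Δ if Δ ≥ 1, −1/Δ otherwise,

   where Δ is the median per-subject fold change
   (follow-up / baseline), DA\* ∈ [0, 1] the fraction of subjects
   changing in the dominant direction, CV the coefficient of variation
   of the fold changes capped at 1, and λ = 100. Scores with
   |pBI| > 73 (strict) are **strong predictors**; the sign reports the
   direction of change.

2. *Which analyte pairs interact?* For every metabolite pair the
   absolute log2 concentration ratio |log2(m<sub>i</sub>/m<sub>j</sub>)|
   is scored through time with the same statistic, and pairs with
   |s<sub>ij</sub>| > τ become edges of an undirected network
   (τ = 73 by default, selectable by cross-validated KNN accuracy on
   simulated data). Hubs of the per-timepoint ("kinetic") networks
   corroborate the univariate ranking.

A synthetic cohort generator (Normal(10, 1) null backbone, planted
responder metabolites with recorded ground truth) supports validation
and calibration throughout; a command-line interface and
GraphML/SIF/edge-list exports (Cytoscape-compatible) tie the steps into
a usable tool.

## Worked example

```r
library(pbinet)

ds <- generate_stress_cohort(seed = 1)   # 30 subjects x 60 metabolites,
                                         # 5 planted up-responders
tab <- rank_metabolites(ds, "tmax")
head(tab[, c("metabolite", "score", "delta_change", "da_star", "cv",
             "predictor_class")], 6)
#>   metabolite  score delta_change da_star     cv predictor_class
#> 1        M34 1163.2        3.502  0.9667 0.2910          strong
#> 2        M15 1097.9        3.881  0.9667 0.3417          strong
#> 3        M55  949.4        2.922  0.9333 0.2873          strong
#> 4        M52  776.5        2.401  0.9333 0.2886          strong
#> 5        M58 -733.9       -1.076  0.7667 0.1124          strong
#> 6        M42 -713.7       -1.084  0.7000 0.1063          strong
```

The four top-ranked metabolites (M34, M15, M55, M52) are planted
responders; their median fold changes (Δ<sub>change</sub> 2.4–3.9) are
directionally consistent in ≥ 93% of subjects (DA\*), with fold-change
CVs around 0.3. M58 illustrates the score's signal-to-noise character:
its median change is small (−1.08, an 8% decrease) but unusually
uniform (CV 0.11), which a practitioner should read together with the
effect-size column, not from the score alone.

```r
net <- infer_network(ratio_score_matrix(ds, "tmax"), tau = 73, tab)
net
#> pbinet network (t0 vs tmax, tau = 73): 60 vertices, 888 edges
hubs(net, 5)
#>   metabolite degree
#> 1        M15     59
#> 2        M32     59
#> 3        M34     59
#> 4        M52     59
#> 5        M55     59
ds$truth$planted$metabolite
#> [1] "M32" "M52" "M55" "M34" "M15"
```

All five planted responders — including M32, the weakest (fold 2) —
are recovered as the maximal-degree hubs: each connects to all 59
other metabolites, because its ratio to any stable partner shifts
consistently. Export with `write_graphml(net, "net.graphml")`,
`write_sif()` or `write_edgelist()` for Cytoscape.

Threshold calibration and the shell interface:

```r
ev <- select_tau(ds, "tmax")   # 40-step grid, KNN CV accuracy per tau
plot(ev)
```

```sh
Rscript inst/scripts/pbinet simulate --seed 1 --out sim
Rscript inst/scripts/pbinet score --input sim/cohort.tsv --timepoint tmax --out scores
Rscript inst/scripts/pbinet network --input sim/cohort.tsv --tau 73 \
    --format graphml,sif,edgelist --out net
```

Every run writes a `manifest.yaml` (resolved configuration, input
hashes, seed, warnings); identical inputs reproduce identical output
bytes.

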