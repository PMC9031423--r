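# soilNDEP

Quantifies how faithfully **air-dried soil archives** preserve the *source
of variation* in soil microbial community structure, for microbial
ecologists deciding whether archived (rather than fresh) soils can answer a
spatial question.

## The statistic

For every pair of sampling plots *i* and each treatment (fresh or
air-dried), technical rarefaction replicates of the two OTU count vectors
feed a one-factor PERMANOVA on Bray–Curtis dissimilarities; its R² is the
**explanation proportion** EP — the fraction of community variation
attributable to the sampling location. Matching the two treatments per pair
gives the **normalised difference explanation proportion**

```
NDEP_i = (EP_fresh_i − EP_air-dried_i) / EP_fresh_i
```

NDEP ≈ 0 means the archive preserves the variation source; positive NDEP is
fidelity loss. Downstream, NDEP is related to the spatial distance
(haversine, km) and the min–max Euclidean environmental difference between
the plots: Spearman correlations, Jenks natural-breaks scale classes,
two-set variation partitioning, exhaustive best-subset regression of NDEP
on per-variable environmental differences (with relative-effect
percentages), and paired differential abundance of prevalent OTUs
(signed-rank, Bonferroni). A synthetic-data generator emulates the study
design — 19 plots at 4 sites spanning ~500–2500 km, paired fresh/air-dried
tables with a planted, directionally consistent drying response — so the
whole pipeline is testable without sequence data.

## Worked example

```r
library(soilNDEP)

# one synthetic world under the default study design: 19 plots, 4 sites
ds <- generate_dataset(synthetic_config(seed = 20260924))
res <- run_pipeline(ds$table, ds$frame,
                    pipeline_config(rarefy_depth = 4000,
                                    replicate_depth = 2000, seed = 20260924))

res$ep_test
#> Paired signed-rank: V = 13064, p = 1.28e-18 (normal_approx), effect size r = 0.674, n = 171
#>   medians (IQR): 0.9667 (0.0197) vs 0.9609 (0.0198)

round(c(spatial = res$spearman_spatial$rho, env = res$spearman_env$rho), 3)
#> spatial     env
#>  -0.360  -0.374

head(res$scale_spatial)
#>   class upper_value median_ndep   mean_ndep  n
#> 1     1    23.49989 0.012857622 0.010657290 38
#> 2     2   551.98187 0.005046220 0.004796322 18
#> 3     3   971.20363 0.004598023 0.004281345 15
#> 4     4  1015.61075 0.008472572 0.008140056 30
#> 5     5  1460.04910 0.001839273 0.002507010 25
#> 6     6  2310.06091 0.002815557 0.002227383 15
```

Reading the output: the median EP is ~0.97 fresh vs ~0.96 air-dried and the
paired signed-rank test confirms a systematic EP decline (effect size
r = 0.67 across the 171 plot pairs). NDEP correlates negatively with both
spatial distance and environmental difference, and the Jenks scale table
shows the fidelity loss concentrating in scale class 1 — plot pairs less
than ~25 km apart lose roughly 2–4× more explanatory power than distant
pairs. The practical reading: air-dried archives are safest for questions
posed across large spatial or environmental contrasts.

The same workflow, split into narrative steps that write their tables under
`results/`, lives in `analysis/01_simulate.R` … `analysis/06_multiseed_study.R`
(simulation → pairwise EP → NDEP and scale classes → variation
partitioning and model selection → differential abundance → 50-seed
robustness study). Run them in order from the repository root.

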