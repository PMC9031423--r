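---
title: "Quantifying the fidelity of air-dried soil archives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the fidelity of air-dried soil archives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilNDEP)
```

## The question

Air-dried soil archives are the cheapest long-term record of soil microbial
communities, but drying perturbs the community before it is sequenced. The
question this package quantifies is not whether communities change — they
do — but whether the *source of variation* between samples survives
archiving: if site-to-site differences drive community structure in fresh
soil, do they still drive it after 200+ days of air-dried storage?

The unit of analysis is a pair of sampling plots. For one pair under one
treatment (fresh or air-dried), a PERMANOVA on Bray–Curtis dissimilarities
with plot identity as the factor yields an $R^2$, the *explanation
proportion* (EP): the fraction of community variation attributable to the
sampling location. Matching the fresh and air-dried EP of the same pair
gives the *normalised difference explanation proportion*

$$\mathrm{NDEP}_i \;=\; \frac{EP^{\mathrm{fresh}}_i - EP^{\mathrm{air\text{-}dried}}_i}{EP^{\mathrm{fresh}}_i},$$

a dimensionless fidelity loss: 0 means the archive preserves the variation
source perfectly, positive values mean the spatial signal weakened, and
(mildly) negative values are possible when the air-dried EP happens to
exceed the fresh one. With 19 plots there are $\binom{19}{2} = 171$ pairs
per treatment, i.e. 342 PERMANOVA groups in all.

## The pipeline, step by step

**Rarefaction.** Counts are subsampled *without replacement* (multivariate
hypergeometric) to a common depth before any dissimilarity is computed.
Sampling without replacement is variance-correct for fixed read pools;
a bootstrap (with replacement) mode exists for sensitivity checks. The
depth is a configuration value defaulting to the minimum sample total —
it is never hard-coded, because reasonable analyses of the same data have
used different depths.

**Technical replicates.** A two-sample comparison cannot feed a PERMANOVA,
so each plot's count vector is subsampled `n_replicates = 6` times (at
`replicate_depth`, default half the rarefaction depth) to create
equal-depth pseudo-replicates. The six draws per plot are pooled into one
PERMANOVA per pair, 6 vs 6. Per-pair, per-replicate RNG streams are derived
from the master seed and the pair label, so results are independent of
evaluation order. An alternative reading — averaging six single-replicate
runs — is available but not the default; with subsampling as the only
within-group variance the pooled design is the natural one.

**PERMANOVA.** One factor, $SS_{\mathrm{total}} = \frac1n \sum_{i<j}
d_{ij}^2$, $SS_{\mathrm{within}}$ summed per group, pseudo-$F$ on
$(a-1,\,n-a)$ degrees of freedom. With two groups of six there are only
462 distinct label splits, so the permutation null is *enumerated exactly*
whenever the split count is at most 10,000 (p-value = proportion of splits
with $F^{*} \ge F$, the identity split included, so $p \ge 1/462$);
otherwise random permutations with the add-one estimator
$(1 + \#\{F^* \ge F\})/(1+N)$ avoid $p = 0$. Permuted $F$ is compared via
$SS_{\mathrm{within}}$ (a monotone transform), which is numerically more
stable than ratios of small sums. If $SS_{\mathrm{within}} = 0$ the $R^2$
is still reported and $F$ is flagged degenerate rather than erroring.

**Distances between plots.** Spatial separation is the haversine
great-circle distance on a sphere of mean radius 6371.0088 km (an
ellipsoidal option exists; the difference is far below the resolution of
the scale classes). Environmental difference is the Euclidean distance
over min–max-normalised plot values of
pH, SOC, TN, TP, TK, sand, silt, clay, WC, AAT and AP — soil chemistry,
texture, water and the two climate variables. The variable list is a
parameter because different analyses may reasonably exclude climate; the
default includes it.

**EP comparison and NDEP scale analysis.** The matched EP series are
compared with the Wilcoxon signed-rank test (the paired member of the
rank-test family). Zero differences are dropped (Wilcoxon's rule; Pratt's
method is a flag), the exact null is used up to $n = 15$ by direct
enumeration of sign patterns (valid under tied ranks) and up to $n = 25$
via the rank-sum distribution when ranks are untied, the tie- and
continuity-corrected normal approximation beyond. The effect size is
$r = |Z|/\sqrt{n}$ with $n$ the number of non-zero pairs. NDEP is then
related to the two background distances by Spearman correlation
(average-rank ties), and binned into `k = 7` Jenks natural-breaks classes.
The Jenks optimisation is the exact dynamic program over distinct values
(ties can never straddle a class boundary), not the re-seeding heuristic —
determinism and testability against brute force were worth more than
speed at $n = 171$. Each class is reported by its *maximum* member
distance: the top class's value then equals the overall maximum pair
distance, which is how such tables are usually printed.

**Variation partitioning.** NDEP is regressed on spatial distance, on
environmental difference, and on both; adjusted $R^2$ values decompose
into pure and shared fractions ($a = R^2_{adj,12} - R^2_{adj,2}$, etc.).
Fractions may be negative and are reported unclipped. Aliased columns
contribute no degrees of freedom (the effective rank is used), so a
duplicated predictor lands entirely in the shared fraction. The second
explanatory set defaults to the scalar environmental difference; a mode
using the per-variable difference columns instead is provided, since
either could underlie a published two-circle decomposition.

**Best-subset regression.** All $2^p$ subsets of the per-variable
environmental differences (min–max normalised at the plot level *before*
taking absolute pair differences — the predictors are plot properties, so
they are standardised as such; difference-then-normalise is a flag) are
fitted by OLS with intercept. The intercept-only model competes too. The
default criterion is BIC, with adjusted $R^2$ and Mallows' $C_p$ reported
side by side because the selection criterion behind a published exhaustive
search is rarely stated. The *relative effect* of a selected predictor is
$100\,|\hat\beta_v| / \sum_w |\hat\beta_w|$; this definition reproduces,
to 0.01%, the printed percentages of the reference coefficient table
shipped in `inst/extdata` (see `coefficient_statistics()`), which is what
fixes the interpretation.

**Differential abundance.** On the rarefied table, OTUs present in
strictly more than 90% of samples are tested by paired signed-rank on
plot-matched relative abundances, Bonferroni-corrected over the OTUs that
have at least one non-zero paired difference (identically-zero OTUs are
flagged untestable and excluded from the family). Strict "more than" at
$n = 38$ means at least 35 samples.

## The synthetic generator

No public OTU table accompanies the motivating design, so the package
carries a generator whose defaults *are* the study conditions: 4 sites
with 5, 5, 6 and 3 plots (19 plots, 38 paired samples), inter-site
separations of roughly 500–2500 km, within-site scatter up to ~25 km, and
an environmental gradient (temperature, precipitation, pH, SOC, texture…)
that tracks latitude, deliberately confounding space with environment the
way real transects do.

Fresh communities are log-normal: per-OTU log intensity = OTU baseline
$\mathcal N(0, 1.5)$ + site effect $\mathcal N(0, 1.2)$ + loadings on two
environmental axes (scaled temperature and pH, total SD 0.8) + plot noise
$\mathcal N(0, 0.4)$, softmaxed into multinomial probabilities and sampled
at depth 5000.

Air-drying is a taxon-specific, *directionally consistent* perturbation:
a "responder" set (8 OTUs, mean log-fold-change +1.5, labelled
Firmicutes — spore-formers that bloom on desiccation) and a "sensitive"
set (12 OTUs, mean LFC −1.0, labelled Proteobacteria/Acidobacteria), each
with per-OTU spread (SD 0.3) shared across plots, plus a small plot-level
noise (SD 0.05 per OTU). Two design choices matter and were made on
mechanistic grounds:

* **The perturbed OTUs are cosmopolitan.** Their site, environmental and
  plot effects are attenuated (×0.2), so their baseline share is similar
  everywhere. A bloom that multiplies site-specific abundances amplifies
  pre-existing site contrasts instead of overwriting them — the fidelity
  loss then has the wrong sign at large scales. A bloom of ubiquitous taxa
  adds a *shared* component to every dried community, which is what
  erodes the between-plot signal, most strongly where that signal was
  weakest (within sites). This is the generative mechanism behind the
  scale effect, and it is also the biologically standard picture of
  drought responders.
* **Response variability lives at the OTU level, not the plot level.**
  Plot-specific drying noise adds between-plot divergence and *raises*
  the air-dried EP; consistent per-OTU responses with small plot noise
  reproduce the observed predominance of EP decline. The default noise
  SD (0.05 in log space) keeps the response realistic without flipping
  the sign of the phenomenon.

With these defaults a single run shows: median EP near 0.96 in both
treatments, EP declining in the large majority of pairs, mean NDEP of a
few thousandths with within-site pairs losing markedly more fidelity than
between-site pairs, negative NDEP–distance Spearman correlations on both
axes, and full recovery of the planted responder set by the differential
abundance stage — the same qualitative structure as the motivating study,
at desk scale. These are exactly the quantities the analysis scripts under
`analysis/` and `scripts/acceptance.R` recompute; the vignette asserts
nothing beyond them.

What the generator does **not** emulate: sequencing error, chimeras and
primer bias (explicit non-goals); the heavy-tailed richness of real soil
(hundreds of OTUs, not tens of thousands — prevalent OTUs therefore carry
a much larger summed relative abundance than in a real table); phylogenetic
correlation of responses; and within-site spatial autocorrelation beyond
the shared site effect. Passing tests therefore demonstrate that the
*statistics* behave correctly and that the *mechanism* produces the
documented phenomenon — not that real archives lose exactly so much
fidelity.

## Problem sizes and numerical conventions

The standard analysis size — used by the drivers, the tests and the
acceptance script — is 19 plots × 300 OTUs at depth 5000, rarefied to
4000, technical replicates at depth 2000, exact 462-split PERMANOVA per
pair. One full pipeline run takes a couple of seconds; the 50-seed
robustness study runs in under two minutes on one core.

Numerical conventions collected in one place: distance-matrix symmetry is
enforced by averaging with the transpose and tolerated to $10^{-12}$;
permutation comparisons use an additive $10^{-12}$-scaled epsilon;
variation-partitioning identities hold to $10^{-9}$ and are asserted at
that tolerance; Jenks ties never split; signed-rank zero differences drop
by default; Bonferroni uses the testable-OTU count; min–max statistics are
always computed over the 19 plots (environment is a plot property shared
by both treatments); and every stochastic step takes its stream from
`derive_seed(master, key)` so that no result depends on evaluation order.

## Known limitations

* EP pairs sharing a plot are statistically dependent; the 171 pairs are
  nevertheless treated as independent observations in the paired test and
  the regressions, mirroring the published procedure. P-values at those
  stages are therefore optimistic.
* The exact PERMANOVA p-value floor with 6+6 replicates is $1/462 \approx
  0.0022$; claims below that resolution are not possible per pair.
* Negative variation-partitioning fractions are reported as-is; only a
  rendering layer should floor them at zero.
* The generator's phylum labels are a convenience for reporting; no
  phylogeny is modelled and UniFrac-type dissimilarities are out of scope.
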