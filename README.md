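# enterotyper

Distance-based enterotype analysis of fecal-microbiota cohorts, in R.

Gut microbiome surveys repeatedly find that people's microbiota cluster
into a small number of recurring compositional configurations —
*enterotypes* — typically driven by the balance of Prevotellaceae against
Bacteroidaceae, Lachnospiraceae and Ruminococcaceae. Whether a given
cohort actually supports such discrete clusters, and whether taxon
abundances track host covariates such as bowel habit or body-mass index,
are statistical questions this package answers end to end for
family-level 16S count tables:

* **Data model & I/O** — sample × taxon count tables (TSV or dense
  BIOM-style JSON), taxonomy collapse to any rank, relative abundance,
  prevalence.
* **Alpha diversity** — Shannon (bits), bias-corrected Chao1, Good's
  coverage.
* **Enterotype fitting** — square-root Jensen–Shannon divergence
  `d(a,b) = sqrt(H((a+b)/2) − (H(a)+H(b))/2)`, UPGMA dendrograms,
  k-medoids (PAM) on the distance matrix, cluster number by the
  Calinski–Harabasz index, and validation by prediction strength (strong
  clustering at PS ≥ 0.9) and silhouette index (structure bands at
  0.25 / 0.5 / 0.75). A partition is *reliable* only when PS ≥ 0.9 and
  SI > 0.25.
* **Ordination** — PCA biplot coordinates/loadings and PCoA with
  explained-variance reporting.
* **Association statistics** — Welch's t, Mann–Whitney U, Fisher's exact,
  Holm correction, compact letter displays, Kendall tau-b, correlation
  networks filtered at p < 0.001 and |τ| > 0.2, and lean/obese (BMI < 25
  vs > 30) comparisons.
* **Synthetic cohorts** — a Dirichlet-multinomial generator with
  enterotype archetypes, realistic library depths, exact metadata strata,
  and copula-coupled ordinal questionnaire scores, so the whole pipeline
  is testable without any sequencing data.

The central fit is `enterotype()`, which returns a classed object with
`print`, `summary`, `plot` and `predict` methods; `run_pipeline()` chains
every stage from a single YAML/JSON config and writes TSV/newick
artifacts with a manifest. A thin command-line wrapper lives at
`inst/scripts/microbiota_pipeline.R`.

## Worked example

```r
library(enterotyper)

# a 120-subject synthetic cohort with the default two archetypes
coh <- generate_cohort(cohort_config(n_samples = 120, seed = 2024))
coh
#> synthetic_cohort: 120 samples, 66 taxa, 2 archetype(s)
#> archetype sizes: 34, 86
#> mean depth: 10374 reads

fit <- enterotype(coh$counts, k_range = 2:6, ps_repeats = 50, seed = 2024)
summary(fit)
#> Cluster validation report
#>   Cluster no. showing max CH score: 2
#>   Max CH score:        189.5
#>   Prediction strength: 1.00  -> strong clustering
#>   Silhouette index:    0.55  -> reasonable structure
#>   Reliable (PS >= 0.9 and SI > 0.25): yes
#>   CH by k:
#>     2     3     4     5     6
#> 189.5  97.7  66.9  50.8  41.3
#>   cluster sizes: 86, 34
#>   medoids: S0021, S0055
```

The CH profile peaks at k = 2 and both validation gates pass: the fitted
partition recovers the two planted archetypes (the 86/34 split matches
the generator's 86/34 assignment). On a single-archetype cohort the same
call reports SI ≤ 0.25 and `reliable: no`.

```r
div <- alpha_diversity(coh$counts)
sprintf("mean Good's coverage: %.4f", mean(div$goods_coverage))
#> [1] "mean Good's coverage: 0.9998"
sprintf("mean Shannon (bits): %.2f   mean Chao1: %.1f", mean(div$shannon), mean(div$chao1))
#> [1] "mean Shannon (bits): 3.37   mean Chao1: 41.4"

net <- build_network(coh$counts, items = coh$metadata[, c("Q7", "Q13", "Q21")])
net
#> correlation_network: 69 nodes, 10/2343 pairs pass (p < 0.001, |tau| > 0.2)
#>                a                b        tau      p_value
#>   Bacteroidaceae   Prevotellaceae -0.4686275 3.210610e-14
#>  Lachnospiraceae   Prevotellaceae -0.4652661 4.879793e-14
#>  Ruminococcaceae   Prevotellaceae -0.4159664 1.620528e-11
#>              Q21      Bacillaceae  0.3670746 4.968171e-08
#>              Q13 Lactobacillaceae  0.3620403 8.241573e-08
#>  ...
```

Coverage near 1 says the 10⁴-read depth all but exhausts a 66-family
community. The network recovers the anti-correlation between the
Prevotella- and Bacteroides-driven configurations and the planted
questionnaire couplings (dairy intake Q13 with Lactobacillaceae, natto
intake Q21 with Bacillaceae), while taxa left uncoupled pass the double
filter only rarely.

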