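---
title: "Methods: enterotype clustering and association analysis for fecal microbiota cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enterotype clustering and association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enterotyper)
```

## Scope and model

`enterotyper` implements the distance-based workflow used to ask whether a
cohort's gut microbiota falls into discrete, recurring compositional
configurations ("enterotypes") and whether taxon abundances track host
covariates. The input is a sample-by-taxon count table at the family rank
(or an OTU table plus a taxonomy to collapse with), sample metadata, and
optionally ordinal lifestyle-questionnaire scores.

The clustering model is deliberately nonparametric. Each sample is reduced
to its relative composition $p_i$, and samples are compared by the square
root of the Jensen–Shannon divergence,
$$d(a,b) = \sqrt{H\!\left(\tfrac{a+b}{2}\right) - \tfrac{H(a)+H(b)}{2}},$$
with $H$ the natural-log Shannon entropy and $0\log 0 = 0$. The square
root makes $d$ a metric bounded by $\sqrt{\ln 2} \approx 0.8326$.
Partitions are fitted by k-medoids (PAM) directly on this distance; the
number of clusters is chosen by the Calinski–Harabasz (CH) variance ratio;
and the chosen partition is accepted only if it passes two independent
validations:

* **prediction strength (PS)** — cross-validated stability: split the
  cohort 50/50, cluster both halves, classify each held-out sample to its
  nearest training medoid, and take the worst per-cluster fraction of
  held-out pairs that the training rule keeps together. PS $\ge 0.9$ is
  "strong clustering".
* **silhouette index (SI)** — cohesion versus separation,
  $s_i = (b_i - a_i)/\max(a_i, b_i)$ averaged over samples, with the
  conventional bands: $\le 0.25$ no substantial structure, $\le 0.5$ weak,
  $\le 0.75$ reasonable, above that strong.

A partition is reported *reliable* only when PS $\ge 0.9$ **and**
SI $> 0.25$. This two-gate rule is strict on purpose: on diffuse human
cohorts it frequently rejects the CH-optimal partition, which is a finding,
not a failure.

`enterotype()` is the package's central fit and returns an object carrying
the distance matrix, CH profile, selected partition, PS/SI and their
classifications, with `print`, `summary`, `plot` and `predict` methods.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k_range` | 2–10 | clusters | CH maxima in cohorts of this kind sit at 2–4; 10 gives headroom without noticeable cost |
| `ps_repeats` | 100 | splits | PS standard error ~0.01 at n = 200; both fold directions are always scored |
| `distance` | `sqrt-jsd` | – | metric form; plain JSD available for sensitivity checks |
| `ch_variant` | `pcoa` | – | CH needs a geometry; the PCoA embedding reproduces classic CH exactly for Euclidean input. A medoid-centrotype variant ships for sensitivity analysis |
| network filters | p < 0.001, &#124;tau&#124; > 0.2 | – | the conventional double filter for tau-b co-occurrence networks; both exposed in `build_network()` and the pipeline config |
| BMI cut-offs | lean < 25, obese > 30 | kg/m² | strict inequalities; 25–30 is excluded |
| letters / stars | alpha = 0.05; stars at 0.05/0.01 | – | matched to superscripted cohort-table conventions |

## The synthetic cohort generator

Downstream code is exercised end-to-end on simulated cohorts from a
Dirichlet-multinomial model: each sample draws an archetype from a mixture,
a composition from $\mathrm{Dirichlet}(c \cdot \mu_k)$ around the
archetype mean $\mu_k$ with precision $c$, a library depth from a rounded
normal clamped at 100 reads, and counts from a multinomial at that depth.
Defaults emulate a nationwide 516-subject adult cohort: 66 bacterial
families; depth 10252 ± 2406 reads/sample; seven regions of residence
(38/40/193/49/49/48/99) and a 325:191 female:male split hit exactly by
largest-remainder allocation; age ~ N(52.4, 13.4²) clamped to 21–88 and
BMI ~ N(22.3, 3.2²). Two default archetypes encode the familiar
Prevotellaceae-driven versus
Bacteroidaceae/Lachnospiraceae/Ruminococcaceae-driven configurations, at
mixing 0.3/0.7 (Prevotella-dominant guts are the minority in East-Asian
cohorts); mass not assigned to the named driver families follows a
geometric rank-abundance decay so minor families are unequal but
reproducible. Archetype concentration defaults to 200, which produces the
weakly separated, overlapping clusters typical of real cohorts rather than
toy blobs.

Ordinal questionnaire items are coupled to chosen families through a
Gaussian copula: the mean rank of the coupled families' relative abundances
is mapped to normal scores, a latent normal is drawn at correlation
$\rho = \sin(\pi\tau/2)$ (Greiner's relation, so the latent Kendall tau
equals the target), and the latent variable is cut at equal-probability
normal quantiles into the requested number of levels. Because the paper
trail for real instruments rarely fixes level counts, levels are
per-coupling configuration, defaulting to 5. Discretization attenuates the
observable tau-b; at 5 levels the attenuation is below ~0.01 for
$|\tau| \le 0.35$ (verified by simulation in the test suite), so recovery
tests use continuous-side tolerances. Default couplings: bowel-movement
frequency against Christensenellaceae/Mogibacteriaceae/Rikenellaceae at
$\tau = -0.26$, dairy intake against Lactobacillaceae at $0.25$, natto
intake against Bacillaceae at $0.34$.

What the generator does *not* emulate: sequencing error and chimeras,
compositional zero-inflation beyond what the Dirichlet-multinomial
produces, phylogenetic correlation between families, within-subject
longitudinal structure, and region- or gender-specific composition shifts
(metadata are assigned independently of the archetype). Passing tests
therefore demonstrate that the machinery recovers planted structure under
the stated statistical model — not that any real cohort has that structure.

## Numerical choices

* **PAM.** Deterministic BUILD (greedy seeding from the 1-medoid optimum)
  plus best-improvement SWAP, all ties broken toward the lowest sample
  index. For tiny instances (`choose(n, k)` ≤ 2000) the solver switches to
  exact enumeration: it costs the same there and sidesteps the shallow
  swap-stable local optima that BUILD+SWAP (in any implementation) hits on
  a few percent of small random instances.
* **CH at W = 0.** Identical points within clusters give a zero
  within-cluster dispersion; the index is reported as the capped sentinel
  `1e12` so argmax selection stays well defined.
* **k selection ties** go to the smaller k — determinism over faithfulness
  to an unspecified original.
* **PCoA** keeps positive-eigenvalue axes only; sqrt-JSD is a metric but
  not guaranteed Euclidean, so the magnitude of discarded negative
  eigenvalues is recorded on the ordination object.
* **Sign conventions.** PCA/PCoA axes are flipped so the
  largest-magnitude loading (or coordinate) on each axis is positive,
  making coordinates reproducible across platforms.
* **PS protocol.** 100 repeats of random 50/50 splits, both directions,
  singleton held-out clusters carry no pairs and are excluded from the
  per-repeat minimum; the seed is a required argument.
* **PS/SI at which k?** Validation statistics are computed at the
  CH-selected k by default; `force_k` reproduces fixed-k analyses.
* **Mann–Whitney** uses the tie-corrected normal approximation with
  continuity correction, switching to exact enumeration only for untied
  samples with both n ≤ 8 — ordinal questionnaire data are tie-heavy, so
  the approximation is the operative path.
* **Fisher's exact** two-sided p follows the probability-mass rule (sum of
  table probabilities ≤ the observed one's).
* **Kendall tau-b p-values** come from the tie-adjusted normal
  approximation of the concordance statistic; at cohort sizes of several
  hundred exact enumeration is neither feasible nor needed. A constant
  margin leaves tau *missing*, never zero — a silent zero would corrupt
  the network filters.
* **Compact letters** use insert-and-absorb, which always satisfies the
  defining invariant (two groups share a letter iff their adjusted p ≥
  alpha); the test suite verifies the invariant exhaustively on random
  instances of up to 8 groups.
* **Abundance scale.** Fractions internally, percentages in reports; the
  chosen tests are invariant to that scale.
* **Chao1** is the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$,
  defined even at $F_2 = 0$; the classic form is behind a flag. Shannon
  defaults to log base 2 with the base configurable. No numerical parity
  with any particular upstream pipeline's alpha-diversity output is
  claimed.

## Problem sizes in the test suite

Simulation-backed tests run at sizes chosen to keep sampling error well
inside the asserted tolerances: threshold-behavior checks at n = 200
samples (PS with 100 repeats; 25 repeats inside the 20-seed recovery
loops, where PS of strong clusters is far from the 0.9 gate); tau-b
recovery at n = 5000 where the tau standard error is ≈ 0.01; test
calibration at 10000 null replicates (binomial SE ≈ 0.002 on a 0.05
rate); network false-edge calibration over 50 cohorts of n = 500 with 12
independent taxa.

## Known limitations

* The clustering pipeline treats the distance matrix as exact; no
  uncertainty from finite sequencing depth is propagated into PS/SI.
* The CH index needs an embedding; for strongly non-Euclidean distances
  the PCoA and medoid variants can rank k differently, which is why both
  are shipped.
* Compositional closure induces weak negative dependence between taxa;
  the tau-b network inherits this, as it does in the field's standard
  practice, and the 0.2 magnitude filter is what keeps closure artifacts
  out at realistic family counts.
* `group_compare` tests each taxon marginally; no cross-taxon multivariate
  test is provided.
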