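# kinclique

Social-structure analysis for bachelor bands in multilevel primate
societies.

In species such as the golden snub-nosed monkey (*Rhinopithecus
roxellana*), surplus males form an all-male band (AMB) that shadows the
breeding band (BB) of one-male units. Within the AMB, males organise into
all-male units (AMUs) — but what holds an AMU together? kinclique turns
raw field observations — proximity scan samples, grooming bouts, agonistic
bouts, microsatellite genotypes and GPS tracks — into a quantitative
answer: it builds the affiliation networks, reconstructs the dominance
hierarchy and the pedigree-free relatedness structure, tracks day-to-day
alliance communities against inter-band distance, and attributes dyadic
affiliation to kinship versus age versus rank with a higher-order partial
Mantel test.

## What it computes

* **Affiliation** — half-weight index (HWI) association matrices from scan
  samples, `HWI = x / (x + y_ab + (y_a + y_b)/2)`; directional affiliation
  index (DAI) grooming matrices; hierarchical clustering into AMUs with a
  modularity-based cliquishness coefficient; thresholded sociogram export.
* **Dominance** — win/loss matrices from decided agonistic bouts, David's
  scores and normalized David's scores
  (`NDS = (DS + N(N−1)/2)/N`), hierarchy steepness (|OLS slope| of NDS on
  rank, with randomization p) and Landau linearity h′ with the
  unknown-dyad correction.
* **Kinship** — per-locus allele frequencies with an
  expectation–maximization null-allele model; pairwise Lynch–Ritland
  relatedness (reciprocal-reference, information-weighted, optionally
  null-corrected); UPGMA clustering on mean relatedness with Newick
  export; Na/Ho/He/F diversity statistics and Hardy–Weinberg chi-squared
  tests with sequential Bonferroni correction.
* **Communities** — time-decayed daily affiliation graphs, k-clique
  percolation communities (members may overlap), EB/NFB/LND turnover
  flags, daily AMB–BB haversine distances from GPS fixes, community-size
  vs distance models and leave-probability curves.
* **HPMT** — the higher-order partial Mantel test: the kth-order partial
  correlation of a tested matrix with the dependent matrix given any
  number of control matrices, built recursively from three (k−1)th-order
  partials; Monte-Carlo permutation p values `(n1+1)/(n2+1)`; coefficient
  of multiple determination `R² = 1 − Π(1 − r²)` over sequential partials;
  per-factor contribution rates `CR_f = R²(all) − R²(all∖f)`.
* **Synthetic herds** — a fully seeded generator (pedigree, genotypes with
  null-allele masking, behaviour streams under a logistic dyadic model,
  GPS tracks) with known ground truth, so the whole pipeline is testable
  without field data.

All user-facing functions take data frames and return tibbles or light S3
objects with `tidy()`, `glance()` and `autoplot()` methods, so results
drop straight into dplyr/ggplot2 workflows.

## Worked example

Simulate the default 21-male, 3-family herd observed for 90 days and run
the full pipeline:

```r
library(kinclique)

sc <- herd_scenario(seed = 1)
sc
#> <herd_scenario: 21 males in 3 families, 19 loci, 90 days, seed 1>

cfg <- pipeline_config(scenario = sc, n_perm = 999, seed = 1)
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   subgroups: 3 (Q = 0.292)
#>   steepness K = 0.755 (R2 = 0.987), linearity h' = 0.832
#>   HPMT CR: relatedness=0.436, age=0.038, rank=0.001 (R2 = 0.557)
```

The pipeline recovered the three planted families as three subgroups
(cliquishness Q = 0.292), found the steep, near-linear dominance hierarchy
implied by age-biased contest outcomes (K = 0.755, R² = 0.987, h′ =
0.832), and — the headline comparison — attributed dyadic proximity
overwhelmingly to kinship: controlling age and rank, relatedness keeps a
partial correlation of 0.70 with the HWI matrix,

```r
report$hpmt$tests$relatedness
#> higher-order partial Mantel test (order 2): r = 0.7041, p = 0.001
#>   (0 of 999 permutations, one.sided)

glance(report$hpmt$contribution)
#> # A tibble: 1 × 3
#>   r.squared cr.total n.factors
#> 1     0.557    0.474         3
```

and within-family association dwarfs between-family association:

```r
subgroup_contrast(report$affiliation$hwi,
                  setNames(sc$individuals$family, sc$individuals$id))
#> # A tibble: 1 × 2
#>   mean_within mean_between
#> 1       0.200       0.0511
```

These within/between magnitudes (≈0.20 vs ≈0.05) are the generator's
calibrated study conditions; the point of the run is that the estimators
recover them, the family partition, and the CR ordering
(kinship > age > rank) from raw event tables.

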