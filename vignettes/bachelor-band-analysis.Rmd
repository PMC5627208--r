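---
title: "Dissecting kin structure in a bachelor band: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting kin structure in a bachelor band: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kinclique analyses the social structure of all-male ("bachelor") bands in
multilevel primate societies, such as those of golden snub-nosed monkeys
(*Rhinopithecus roxellana*), where bachelor males shadow a breeding band of
one-male units and organise themselves into kin-structured all-male units
(AMUs). The package takes three behavioural event streams (proximity scans,
grooming bouts, agonistic bouts), microsatellite genotypes and GPS tracks,
and asks the central question: how much of the dyadic affiliation structure
is explained by kinship, once age and dominance rank are controlled?

This vignette documents the models, the tunable parameters and their
defaults, the synthetic-data generator used for validation, and the design
decisions taken where the methodological literature leaves choices open.

## Affiliation networks

**Half-weight index (HWI).** Association between two males a and b is the
Cairns–Schwager half-weight index over scan sampling periods,

$$\mathrm{HWI}_{ab} = \frac{x}{x + y_{ab} + \tfrac12 (y_a + y_b)},$$

with $x$ the number of scans with the pair together, $y_{ab}$ scans with
both seen but apart, and $y_a$, $y_b$ scans where only one was sighted. A
"sampling period" is one scan timestamp. The index corrects for unequal
sighting effort and lies in [0, 1]. Dyads never co-observed score 0;
individuals never observed at all are dropped with a warning rather than
imputed.

**Directional affiliation index (DAI).** Grooming is directed, so the DAI
from i to j defaults to the initiator-normalized share
$G_{ij} / \sum_k G_{ik}$ of i's initiated bouts. Because more than one
sensible normalization exists, `compute_dai()` also offers the dyadic-sum
share and a per-day rate behind its `denominator` argument; analyses in
this package use the initiator share unless stated.

**Subgroups and cliquishness.** `cluster_subgroups()` runs average-linkage
agglomerative clustering on the association distance $1 - \mathrm{HWI}$.
When the number of AMUs is not forced, the dendrogram cut is chosen to
maximize Newman modularity $Q$ of the partition on the weighted HWI graph,
and $Q$ of the chosen cut is reported as the cliquishness coefficient.
Operationalizing cliquishness as modularity is a design decision: it is the
standard quantity measuring how much within-group edge weight exceeds the
degree-preserving expectation, it needs no extra tuning, and it is testable
against a brute-force enumeration of all partitions on small graphs. Merge
ties break lexicographically, so clustering is invariant to input order.

## Dominance

Agonistic bouts in which one male acts agonistically (biting, fighting,
chasing, lunging, supplanting, vocal threatening) and the other responds
submissively (avoidance, fleeing, crouching) are decided; undecided bouts
are excluded and counted. From the win matrix, David's scores use the
dyadic win proportions $P_{ij} = w_{ij}/(w_{ij}+w_{ji})$:

$$DS_i = w_i + w_2{}_i - l_i - l_2{}_i,\qquad
  NDS_i = \frac{DS_i + N(N-1)/2}{N},$$

with $w_i = \sum_j P_{ij}$, $w_2{}_i = \sum_j P_{ij} w_j$ and the mirrored
loss terms. The raw-$P_{ij}$ form is the default; the sample-size-corrected
$D_{ij}$ variant is available for sparse matrices (under raw $P_{ij}$ a
never-interacting dyad contributes zero, which is documented behaviour).

*Steepness* is the absolute OLS slope of NDS on rank position $1..N$
(1 = despotic, 0 = egalitarian), with $R^2$ reported alongside; its p value
randomizes dyad outcomes binomially within the observed dyad totals
(score shuffling is available as an alternative). *Linearity* is Landau's
h with the unknown/tied-dyad correction $h' = h + 6u/(N^3 - N)$, where
unresolved dyads contribute half a win to each member; its p value
randomizes the direction of every decided dyad. For a complete transitive
matrix both statistics are exactly 1, which the tests assert for
$N = 3..10$.

## Kinship

**Null-allele EM.** Microsatellite null alleles fail to amplify: a
heterozygote carrying one is scored as a visible homozygote and a null
homozygote as missing. Per locus, the EM treats the true genotype as
latent; the E-step splits each observed homozygote between true homozygote
and heterozygote-with-null in proportion to their Hardy–Weinberg
probabilities and books missing calls as null/null, and the M-step counts
alleles. Convergence is declared at an L-infinity change below 1e-8 (cap
1000 iterations) and each run asserts the monotone likelihood property.
Treating every missing call as null/null slightly overstates the null
frequency when data are missing for technical reasons; with the ~4%
missingness typical here the bias is well inside the ±0.05 calibration
band the tests enforce.

**Lynch–Ritland relatedness.** The pairwise estimator uses each individual
of a dyad in turn as the regression reference; per locus,
$$\hat r = \frac{p_a(S_{bc}+S_{bd}) + p_b(S_{ac}+S_{ad}) - 4p_ap_b}
               {(1+S_{ab})(p_a+p_b) - 4p_ap_b},$$
where the $S$ are allele-identity indicators and $p$ the reference allele
frequencies. Loci combine as a ratio of summed numerators to summed
denominators — the denominator is the locus information weight — and the
dyad value averages the two reciprocal references. A reference direction
whose total information is zero is dropped rather than invalidating the
dyad. With null correction on, the identity indicators are replaced by
their posterior expectations given the observed phenotypes, the null
allele entering the formula as an allele of frequency $p_0$; this is a
documented stand-in for proprietary weighting schemes, and it reduces
exactly to the uncorrected estimator when $p_0 = 0$ (asserted to 1e-9).
Estimator calibration is checked by simulation: across 200 dyads at 19
loci the mean $\hat r$ must sit within ±0.05 of 0, 0.25 and 0.5 for
unrelated, half-sib and parent–offspring pairs.

**UPGMA on relatedness.** Individuals cluster by repeatedly merging the
two clusters with the highest mean cross-cluster relatedness
$\bar R_{ab} = \sum_{i\in a, j\in b} \hat r_{ij} / (n_a n_b)$; merge
heights are the relatedness at merge and ties break lexicographically. The
tree exports as Newick with branch lengths on a $(1-r)/2$ depth scale;
because merge relatedness need not decrease monotonically, negative branch
segments are clamped to zero (topology and merge heights are unaffected).

## Communities and band movement

Daily affiliation graphs accumulate co-presence events with an exponential
memory, $w_{ab}(t) = \sum_{s \le t} x_{ab}(s)\, 2^{-(t-s)/h}$, half-life
$h = 14$ days by default. Communities on each day are the k-clique
percolation communities (k = 3 by default, the smallest clique) of the
graph thresholded at $w^\*$: two k-cliques are adjacent when they share
k−1 members, and a community is a connected component of that adjacency,
so individuals may belong to several communities. The implementation is
verified exactly against a brute-force enumeration on all small graphs.

Two threshold conventions exist in the package, deliberately. The raw
`w_star` of `cpm_communities()` is a decayed-count threshold, matching the
weight formula. The pipeline, however, interprets its configured `w_star`
(default 2) in mean-events-per-day units and multiplies it by the decay
mass $\sum_{t} 2^{-t/h}$ of one daily event: at realistic scan rates
(~17 scans/day) a fixed raw threshold near 1 is crossed by essentially
every dyad within a week, and the whole band percolates into a single
permanent community, leaving nothing to track. The per-day scaling keeps
the threshold meaningful on day 3 and day 90 alike.

Day-to-day community identity is resolved by maximal Jaccard overlap (ties
to the larger community, then lexicographic), yielding per-individual
turnover flags: EB (existing member), NFB (newly joined that day), LND
(leaves before the next day). Band separation is the haversine distance
(sphere radius 6,371,000 m) between daily median GPS centroids;
`community_distance_model()` correlates daily community size with distance
and reports mean size in the bins <200, 200–300, 300–900 and >900 m —
breakpoints at which bachelor cohesion is expected to collapse, ramp,
peak and relax. `leave_probability()` bins member-days by each male's
outside-community contact rate and reports the fraction leaving next day.

## The higher-order partial Mantel test

The Mantel test correlates the strict upper triangles of two dyadic
matrices and permutes individuals to get a null. To attribute affiliation
to several correlated factors at once, the kth-order partial correlation
of the tested matrix **X** with the dependent matrix **Y** given controls
**Z**$_1..k$ is built from three (k−1)th-order partials by the classical
recursion

$$r_{XY\cdot Z_{1..k}} =
  \frac{r_{XY\cdot Z_{1..k-1}} - r_{XZ_k\cdot Z_{1..k-1}}\,
        r_{YZ_k\cdot Z_{1..k-1}}}
       {\sqrt{(1-r^2_{XZ_k\cdot Z_{1..k-1}})(1-r^2_{YZ_k\cdot Z_{1..k-1}})}}.$$

Controls peel in input order; exact arithmetic is order-invariant and the
tests bound floating drift at 1e-9 against an independent least-squares
residualization oracle. Significance permutes the rows and columns of
**X** only (raw-X permutation; **Y** and all **Z** stay fixed), with the
unbiased $P = (n_1+1)/(n_2+1)$ where $n_1$ of $n_2$ permutations strictly
exceed the observed statistic. Sidedness defaults to one-sided in the
direction of the observed correlation; because that direction is chosen
after seeing the data, this roughly doubles the type-I rate of a
fixed-direction test, so `"greater"`, `"less"` and `"two.sided"` are
available and the calibration suite checks the fixed-direction test
(rejection rate within [0.03, 0.07] at α = 0.05 over 500 null
replicates).

The joint explanatory power of factors $X_1..X_m$ is
$R^2 = 1 - \prod_i (1 - r^2_{YX_i\cdot X_{1..i-1}})$, and the contribution
rate of a factor is $CR_f = R^2(\text{all}) - R^2(\text{all} \setminus f)$
— its unique explained share. Each CR lies in [0, 1] and the CRs sum to at
most 1; note that the CR sum is *not* bounded by the full $R^2$ in
general — suppressor configurations (a control correlated with the tested
factor but not with **Y**) can push the sum slightly above it — so the
package asserts the bound on 1. A factor perfectly collinear with earlier
factors contributes nothing to $R^2$ (its sequential partial is taken as
0 instead of propagating a 0/0). Matrices are correlated as supplied:
relatedness and HWI are similarities while age/NDS differences are
distances, so signs are reported, never auto-flipped.

## The synthetic herd generator

No observational or genotype data are deposited for bachelor bands at this
resolution, so validation runs end-to-end on a generator with known ground
truth. Its defaults are the study conditions, chosen once:

* **Society**: 21 males in 3 families of 7, mirroring the size and AMU
  count of the band that motivated the package; 19 microsatellite loci
  with 5 visible alleles each and a 5% null rate; 90 observation days.
* **Pedigree**: each family holds up to two unrelated founders, remaining
  members are offspring of founder 1 with the dam being founder 2 or an
  unobserved outside female (probability 0.3), so families mix
  parent–offspring, full-sib and paternal half-sib dyads. Unobserved dams
  stay in the pedigree for correct relatedness bookkeeping but not in the
  band.
* **Ages**: founders 8–16 y, offspring 1–7 y; age classes JM < 3.5 y ≤
  SAM ≤ 7 y < AM use cutoffs from the colobine literature and are
  configurable (the bands themselves are arbitrary). True rank is age
  order, and the older male wins an agonistic bout with probability 0.9.
* **Behaviour**: per scan, each male is sighted with probability 0.95 and
  each sighted dyad is together with probability
  logistic$(b_0 + \beta_{kin} r_{ij} - \beta_{age}|\Delta age| -
  \beta_{rank}|\Delta rank| + \beta_{sub}\,\mathrm{same\ family} +
  c(d_t))$. The logistic dyadic model is the package's own stand-in — no
  distributional model is established for these data — and is labelled as
  such. Defaults $b_0 = -2.35$, $\beta_{kin} = 2$, $\beta_{age} = 0.1$/y,
  $\beta_{rank} = 0.02$/position, $\beta_{sub} = 0.8$ were calibrated once
  so that realized within-family HWI ≈ 0.2 and between ≈ 0.05, the
  magnitudes reported for real bachelor bands; a default run reproduces
  0.1997 and 0.0511.
* **Movement coupling**: $c(d_t)$ shifts daily cohesion by the AMB–BB
  distance — −1.2 log-odds under 200 m (males court individually), −0.2
  at 200–300 m, +0.5 at 300–900 m (peak alliance), −0.5 beyond 900 m —
  giving the inverted-U the community stage must detect. The default
  distance profile oscillates between ~100 and ~1100 m over 30-day
  periods.
* **Seeding**: one integer seed; each stage stream derives a fixed offset
  (13·seed + stage constant), so identical seeds give byte-identical
  bundles, which the tests assert file-by-file.

What the generator does *not* emulate: observation-level dependence among
dyads in a scan (sightings and co-presence are dyad-independent, so
"together" is not transitive within a scan), habitat and travel
constraints, female/OMU behaviour, takeover events, allelic dropout or
scoring error beyond the null-allele mechanism, and temporal
autocorrelation in behaviour beyond the distance profile. Passing the
recovery suites therefore demonstrates that the estimators invert the
generative model they were pointed at — kinship-driven affiliation,
age-linear dominance, distance-modulated cohesion — not that real field
data meet those assumptions.

## Numerical and policy choices

* Permutation p values use the unbiased $(n_1+1)/(n_2+1)$ with strict
  exceedance counting, which keeps the maximal-separation case at exactly
  $1/(n_2+1)$.
* Degenerate controls (|r| = 1) abort a partial-Mantel recursion with an
  error naming the offending control, except inside $R^2$ accumulation
  where perfect collinearity legitimately contributes zero.
* Dyads with no shared typed locus are `NA` and masked downstream;
  missing-data policy is pairwise deletion per locus.
* Negative contribution rates beyond 1e-8 (floating drift) are clipped to
  zero with a warning.
* All clustering and matching ties break lexicographically on labels; the
  outputs are invariant to row order of the inputs.
* Problem sizes used in the validation suites — 500 null replicates at
  n = 15 with 999 permutations for calibration, 200 dyads per class at 19
  loci for estimator recovery, 50 seeded herds at 700 scans for the
  end-to-end recovery property, 200 random graphs of at most 8 nodes for
  the percolation oracle — are the package's chosen desk-scale study
  conditions and are stated in the tests.

## Known limitations

* The DAI and affiliation-weight formulas in the methodological
  literature vary; the package picks explicit defaults and exposes the
  alternatives, but cross-study comparability requires fixing the same
  convention.
* The EM cannot separate null homozygotes from technically missing calls;
  loci with high genuine missingness will read as elevated null rates.
* `community_distance_model()` reports correlations and binned means, not
  a causal model; day-to-day autocorrelation inflates nominal
  significance of the correlation and should be interpreted accordingly.
* The HPMT, like all Mantel-family tests, assumes exchangeability of
  individuals under the null; strong block structure in the controls can
  make raw-X permutation liberal. A residualized-X permutation scheme is
  a natural extension and is deliberately not conflated with the raw-X
  default.
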