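---
title: "Antibody-reactivity band networks: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antibody-reactivity band networks: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A uni-dimensional immunoblot probed with a serum yields a banding pattern:
each band is a protein antigen of distinct molecular weight, scored present
(1) when the serum's IgG antibodies react with it and absent (0) otherwise.
Scoring a cohort of sera against the same antigen extract gives a binary
participants-by-bands matrix. Bands whose presence co-varies across sera
point to coordinated behaviour of the IgG-producing cell clones behind
them, so the co-occurrence structure can be read as a network: bands are
nodes, and a link is a statistically significant pairwise correlation.
`abnet` implements this analysis end to end for multi-group studies
(the motivating design has three cohorts of 50 women each -- without breast
pathology, H; benign breast pathology, BBP; breast cancer, BC -- scored on
121 bands), together with the statistics used to compare the resulting
group networks.

## From binary matrix to network

**Correlation.** For 0/1 data the Pearson coefficient between two bands
equals the phi coefficient of their 2x2 contingency table; `abnet` computes
it with `stats::cor()` and the test suite pins the equality against the
closed form to 1e-12. Bands present in every serum or in none have zero
variance; their correlations are undefined and they receive no links (the
count of such bands is carried in the adjacency object and the run
manifest) rather than aborting the run, so saturated bands in real cohorts
are tolerated.

**Significance.** Each pair is tested against zero correlation with

$$t = \frac{r\sqrt{n-2}}{\sqrt{1-r^2}}, \qquad \mathrm{df} = n - 2,$$

declaring a link when the two-tailed p-value falls below `alpha`
(equivalently, one-tailed $p < \alpha/2$; the two formulations are
identical and unit-tested as such). At the study's $n = 50$ and
$\alpha = 0.05$ the rule is a threshold at $|r| \approx 0.2787$
(`critical_r(50)`). Perfect correlations map to $p = 0$ directly instead
of dividing by zero. Negative significant correlations are links like any
other -- the intensity table depends on their sign. No multiplicity
correction is applied by default because the reference analysis tests all
7260 pairs at the raw level; `binarize(..., correction = "bonferroni")` or
`"BH"` is available when reproduction of raw-level link counts is not the
goal. The t reference distribution is an approximation for binary data at
moderate n; the suite checks its accept/reject decisions against a
permutation oracle at small n and its type-I rate by simulation (slightly
conservative, as the discreteness of phi suggests).

**Link bookkeeping.** The link count is the number of ones in the
symmetric adjacency B -- each unordered edge counted twice, i.e. the sum of
sociometric degrees. Two density conventions coexist: the default divides
unique edges by $n(n-1)$ (ordered pairs; a complete graph scores 0.5),
which is the convention that reproduces the published per-group densities
(e.g. 821 unique edges on 121 nodes gives 0.0565, printing as 0.06); the
standard undirected density is reported alongside as
`density_undirected`. Mean degree is links/nodes, which reproduces the
published H value exactly (1642/121 = 13.57); the published BBP and BC
means deviate slightly from their own link counts and are reported as
computed, not matched. The diameter is the longest shortest path over
*connected* pairs (component count attached), since the published tables
print finite diameters without asserting connectivity; an edgeless graph
has no diameter and yields `NA` with a warning. The most-connected node
breaks ties by smallest band id. Degree classes for the histogram are the
five published bins (2-6, 7-12, 13-18, 19-24, 25+), with degree < 2 as a
separate remainder; the hub rule is "strictly more than `hub_threshold`
links" (default 19), following the published wording, with the threshold
exposed because the 19-24 bin boundary makes the printed definition
ambiguous.

## Connection intensity

For node $i$: $N_i$ is its degree in B, $M_i$ the *signed* mean of the
Pearson coefficients over its $N_i$ significant pairs, and
$I_i = N_i M_i$; nodes are ranked by descending $I$ (ties by ascending
id). Isolated nodes take $M = I = 0$. At the group level $N_k$ counts the
ones in B, $M_k$ averages r over those entries (each unordered pair twice,
which leaves the mean unchanged by symmetry), and $I_k = M_k N_k$.

Two readings were genuinely open. First, the denominator of the published
group-mean formula is an undefined symbol; it is read here as the number
of significant correlations being averaged -- the only reading under which
the published per-node table (negative M values; near-zero M with large N)
is arithmetically consistent, as the suite verifies for all 363 printed
rows via $|N \cdot \mathrm{round}(M, 2) - I| \le 0.005N + 0.005$ (the
printed I was evidently computed from unrounded M). Second, M could have
averaged magnitudes or all pairs; both are ruled out by the same rows.

## Disconnection ledgers

Comparing group a's adjacency to group b's entrywise:
code 2 for a link present in a and absent in b (lost), code 1 for the
reverse (gained), 0 otherwise. The ledger collects, per node, the partners
of its code-2 entries, ordered by descending count (ties by ascending id),
retaining zero-loss nodes with empty lists; gains are reported alongside.
Comparisons are ordered -- "H vs BC" means links of H missing from BC.

The published disconnection table lists each lost pair once, under its
lower-numbered node (in every printed column each partner id exceeds its
row's node id), so its per-node counts are lower-node-attributed rather
than full disconnection degrees. `disconnection_ledger(...,
tabulation = "pairs_once")` reproduces that style; the default
`"per_node"` style lists both endpoints, satisfying the invariant that
each lost pair appears in exactly two rows and that losses in (a, b) equal
gains in (b, a).

The packaged transcription of that table is cell-for-cell faithful,
including its typographical defects: three rows whose printed count
differs from the printed list length (H vs BC node 12: 21 vs 19; H vs BBP
node 102: 7 vs 6; BBP vs BC node 6: 10 vs 9), one garbled id ("1092"),
and two partner ids below their row's node in the BBP vs BC column
(10 and 15, plausibly misprints of 100 and 115). The consistency tests
assert exact agreement everywhere outside this frozen defect set.

## Group comparison

Per-node degree vectors and per-node intensity vectors are compared across
groups with the Kruskal-Wallis rank test -- the only readings of
"differences between groups" consistent with 121 observations per group.
The H statistic is implemented from its rank formula with the tie
correction $1 - \sum_t (t^3 - t)/(N^3 - N)$ and the chi-square
approximation on $g - 1$ degrees of freedom, so its tie behaviour is
pinned by tests (including equality with `stats::kruskal.test()`, the
squared rank-sum z identity for two tie-free groups, a small-sample
permutation oracle, and null calibration by simulation). All-tied input is
degenerate and reported as $H = 0$, $p = 1$.

## The synthetic cohort generator

The raw sera matrices behind the reference tables are not deposited, so
the package carries a generator whose output stands in for them in every
downstream test. Participant $i$ draws a latent Gaussian vector

$$z_{ij} = \sqrt{\rho_b}\, g_i + \sqrt{\rho_w - \rho_b}\, h_{i,B(j)}
  + \sqrt{1 - \rho_w}\, e_{ij},$$

giving correlation $\rho_w$ within a block of bands and $\rho_b$ across
blocks, and band $j$ is scored present when $z_{ij}$ exceeds the
standard-normal quantile matching its prevalence (a Gaussian-copula
threshold model). This gives one dial for dependence at any prevalence,
which is why it was chosen over direct Bernoulli mixtures; the cost is
attenuation -- the realized phi is smaller than the latent rho -- so tests
compare orderings and calibrations, never rho values themselves.

Defaults mirror the study shape and are fixed once: 3 groups x 50
participants x 121 bands; band prevalences uniform on 0.1-0.6 (the source
reports no prevalence distribution; this range covers rare to common bands
without degenerate margins); blocks of ~10 consecutive bands; per-group
within-block correlations 0.5 / 0.35 / 0.2 inducing the BBP > H > BC
connectivity ordering. Cross-block correlation defaults to 0: a shared
factor across all bands, even a weak one, correlates every between-block
phi estimate within a cohort and makes cohort-level aggregates (total
links, mean intensity) swing widely between replicates, drowning the block
structure the generator exists to emulate; with independent blocks the
constructed group ordering is recovered essentially always at these
settings, which is the designed behaviour of the scenario. `rho_between`
remains available for users who want global dependence.

What the generator does *not* emulate: clone dynamics, antigen
cross-reactivity structure, gel-to-gel band-calling noise, or any fitted
relationship to real sera. Passing tests therefore demonstrate the
pipeline's correctness and calibration under a known dependence model, not
biological fidelity of the simulated cohorts.

## Numerical and testing choices

Simulation sizes are chosen to give stable checks at interactive cost:
type-I calibration uses ~2100 independent band pairs at n = 50 (11 cohorts
of 20 bands) judged within 3 Monte-Carlo standard errors of 0.05;
ordering recovery uses 100 seeded replicates of the full 121-band
three-group scenario; oracle equivalences (phi closed form at 1e-12,
Floyd-Warshall diameter, set-difference ledger totals) run on batches of
random instances up to 50 nodes. Every stochastic test fixes its seed;
`generate_cohort` is bit-reproducible given (config, seed) and restores
the caller's RNG stream. Degenerate inputs are contracts, not accidents:
zero-variance bands, edgeless graphs, empty cohorts, all-tied rank tests
and single-group pipelines each have a defined, tested behaviour.

## Known limitations

* The published group networks cannot be rebuilt exactly without the raw
  matrices; consistency with the printed tables is checked through the
  packaged fixtures instead (`fixtures_check()`), and the published
  standard deviations/variances of degree, two of the three printed mean
  degrees, and the abstract's headline lost-link totals are not derivable
  from printed data at all -- they are shipped as data, not asserted.
* The t significance rule is asymptotic; at n = 50 on binary data it is
  mildly conservative, and no exact or multiplicity-adjusted inference is
  attempted by default, by design.
* Band identity across cohorts is taken at face value (same id = same
  antigen); gel alignment and band calling are upstream of this package.
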