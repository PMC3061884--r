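---
title: "Complexity-corrected CNA co-occurrence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity-corrected CNA co-occurrence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdcoca)
```

## The model

### Data representation

The unit of analysis is the *status category*: one (cytogenetic band,
direction) pair, written `g-c8q24` (gain of 8q24) or `l-c8p23` (loss of
8p23). A cohort is a binary matrix $D \in \{0,1\}^{n \times m}$ with
$D_{ij} = 1$ iff sample $i$ carries category $j$. Gains and losses of the
same band are separate columns, so a band altered in both directions
across the cohort contributes two categories, and a single sample may
carry both. Construction (`build_status_matrix`) removes sex-chromosome
categories first (they are unreliable in legacy CGH series, where sex
chromosomes were often used as normalization controls) and then drops
categories altered in no sample, so every retained column has carrier
count $F_j = \sum_i D_{ij} \ge 1$.

### Complexity weights

Tumor genomes differ enormously in how many CNA they carry. The method
encodes this as a per-sample prior weight, the sample's share of all
alterations in the cohort:

$$Pw_r = \frac{\sum_j D_{rj}}{\sum_i \sum_j D_{ij}}.$$

Weights are computed once, on the full post-filter matrix; the pair of
columns being tested is *not* excluded. A sample with no CNA has weight
exactly 0 and can never be selected by the weighted null.

A second, descriptive complexity measure (`complexity_score`) counts, per
sample, each chromosome arm's gain flag and loss flag (at most 4 per
chromosome). It is used for cohort description and is rank-concordant
with the weights; it plays no role in the test itself.

### The permutation null

For a pair $(j, k)$ with observed Jaccard index
$J = N_{11}/(N_{11}+N_{10}+N_{01})$, each of $S$ permutations (default
5000) redraws *both* columns independently. A column with carrier count
$F_j$ is simulated by $F_j$ sequential draws without replacement, each
draw selecting a not-yet-selected sample with probability proportional to
its current weight, after which the remaining weights are renormalized.
This preserves $F_j$ exactly (the carrier-count preservation the model
asks for is realized as equality by construction). CICOCA mode replaces
the weights by $1/n$. The p-value is

$$p = C/S, \qquad C = \#\{s : J^{*(s)} \ge J\},$$

with $\ge$ in the exceedance (so a pair with $J = 0$ has $p = 1$
automatically, and $p$ may be exactly 0). An optional add-one smoothing
$(C+1)/(S+1)$ exists but is off by default to keep the printed
convention.

### Empirical FDR

At cutoff $\alpha$ over $M$ tested pairs with $R$ passing, the expected
null discoveries are $\alpha M$, giving $\widehat{FDR} = \alpha M / R$,
capped at 1, undefined (`NA`) when $R = 0$. This formula reproduces all
four published screen-table cells it was checked against.

## What the correction does — and does not — condition on

The null distribution of $J^*$ for a pair is a function of
$(F_j, F_k, Pw, n)$ and the exceedance threshold $J$ only. Two
consequences matter for interpreting results:

1. **Non-uniform weights inflate p globally.** For a perfectly
   overlapping pair, the weighted exceedance probability is
   $\sum_A q(A)^2$ over carrier subsets $A$, which by Cauchy–Schwarz is
   minimized by the uniform distribution. Concentrated weights therefore
   make the weighted p of a pair *at least* its uniform p: the weighted
   screen is strictly more conservative, which is exactly why it passes
   far fewer pairs at the same cutoff and why its discoveries are
   enriched for overlap *not* explainable by complex samples.

2. **The null does not see carrier identity.** Which particular samples
   carry the observed overlap enters only through the weight vector
   (carriers' events are part of the totals), never through conditioning.
   Two pairs in the same cohort with identical $(J, F_j, F_k)$ receive
   identical null distributions regardless of whether their carriers are
   simple or complex samples. The discrimination the method delivers in
   real data operates through the *margins*: associations arising in
   complex samples typically have inflated $F_j, F_k$ and depressed $J$,
   and the weighted null additionally discounts large overlaps wherever
   weights are concentrated. One acceptance-level check in the test suite
   operationalizes the stronger per-pair claim (matched-margin planted
   pairs separating by carrier class); by the argument above that check
   cannot pass and is deliberately left failing, with the directional
   statements that *are* true (weighted $\ge$ uniform; higher-burden
   placement $\Rightarrow$ higher weighted p, via the induced weight
   change) verified against the exact oracle instead.

## Numerical and design choices

- **Per-pair RNG substreams.** Each pair's Monte-Carlo stream is seeded by
  a deterministic hash of (root seed, sorted category ids), and the pair
  is simulated in canonical id order. Results are therefore bit-identical
  across pair-processing orders, matrix column permutations, and any
  parallel execution scheme; the compiled kernel carries its own mt19937
  so results do not depend on R's RNG kind or platform.
- **Exceedance comparison in integers.** $J^* \ge J$ is evaluated as
  $N_{11}^* (F_j + F_k - N_{11}) \ge N_{11} (F_j + F_k - N_{11}^*)$ —
  exact rational comparison, no floating-point ties.
- **Exact oracle.** `exact_null_oracle` enumerates every ordered draw
  sequence with its exact probability (guarded to $n \le 7$,
  $F \le 3$). In uniform mode it equals the hypergeometric tail
  $P(N_{11}^* \ge N_{11})$, which the tests verify exhaustively for all
  $n \le 7$ margins; in weighted mode it validates the Monte-Carlo kernel
  to within binomial error. Three independent routes (kernel, oracle,
  closed form) guard each other.
- **Pair universe.** By default only pairs with observed $N_{11} \ge 1$
  are tested. The published screens report far fewer "total associations"
  than $\binom{m}{2}$, implying such a filter; the threshold is exposed
  (`min_cooccurrence`, also a CLI flag) since the exact published rule is
  not recoverable.
- **Band mapping.** UCSC cytoBand files are 0-based half-open; segments
  use the same convention, and any overlap of at least 1 bp flags a band
  (band-resolution data gives no principled minimum-fraction rule; the
  simplest reproducible choice is used and is split-invariant). The
  packaged 320-band scheme (303 autosomal + 17 X/Y) is a *synthetic*
  scaffold of 5-Mb tiles: the granularity matches band-resolution CGH
  practice, but it is not a real ideogram, and analyses of real data
  should supply their own cytoband table.

## The synthetic cohort generator

`generate_cohort` emulates the one cohort feature the method is about:
heterogeneous per-sample CNA burden. Samples split into a "CNA simple"
class (background events $\sim$ NB(mean 2)) and a "CNA complex" class
(NB(mean 20)), negative binomial with dispersion 2 to mimic the
overdispersed burden distributions seen across tumor entities; the
complex fraction defaults to 0.3. Each sample's events are placed
uniformly over the category universe without replacement, so realized
counts equal drawn counts. Planted pairs set both categories in their
chosen carriers; by default planted columns are excluded from background
placement (`plant_exclusive = TRUE`) so a planted pair realizes exactly
the stated margins ($J = 1$, $F$ = carrier count) — the matched-margin
designs the tests rely on need this exactness, and carriers still receive
background everywhere else. Setting `plant_exclusive = FALSE` restores
fully additive background.

What the generator does *not* emulate: genomic linkage (real CNA span
adjacent bands, producing the strong intra-chromosomal association
structure seen in real screens), recurrent per-entity hotspots, and
correlated gain/loss mechanisms such as isochromosomes. A green
calibration or recovery test therefore establishes correctness of the
statistic under independent-column nulls, not biological realism of any
particular discovery.

## Known limitations

- $p = C/S$ has resolution $1/S$ and can be exactly 0; downstream
  multiple-testing procedures needing continuous p-values should use the
  smoothing option.
- The weighted null corrects for *global* weight concentration only (see
  above); it is not a per-sample conditional test.
- Complexity weights double-count very large segments at band resolution
  (a whole-arm gain contributes one event per band it covers).
- The exact oracle is exponential; it exists for validation, not
  analysis.
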