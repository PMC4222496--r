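---
title: "Reverse causal reasoning: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse causal reasoning: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcr)
```

## The problem

Over-representation analyses of differential expression ask *which
functional gene sets are enriched among the changed genes*. That framing
assumes changed RNA is a proxy for changed protein activity, and it
discards the direction of regulation. Reverse causal reasoning inverts the
question: given a knowledge graph of cause-and-effect statements
("kinase activity of AKT increases transcript X"), which upstream
controllers, set to *increased* or *decreased*, would have produced the
observed pattern of up- and down-regulated RNAs? The controller need not be
differentially expressed itself — insulin signalling can be inferred
increased in liver even though the insulin gene is transcribed in the
pancreas.

## The model

### Hypothesis networks (HYPs)

The knowledge graph is first collapsed to one edge per (source, target)
pair. `increases`/`directlyIncreases` collapse to sign +1,
`decreases`/`directlyDecreases` to −1 (the direct/indirect distinction
carries no information for this inference, so the two classes merge); a
pair supported by both sign classes becomes an *ambiguous* edge. Self-edges
are dropped with a warning — a node is never its own downstream readout.
Node identifiers are opaque, case-sensitive strings; cross-namespace or
cross-species identity must be resolved upstream in the measurement
mapping, which is where curated equivalence information belongs.

A HYP is the star network around one controller: its immediate
(path-length-1) collapsed edges onto *measured* RNA abundance nodes. A node
qualifies as measurable RNA when its term begins with `r(` or
`rnaAbundance(` (a configurable prefix list). Controllers with at least
`min_possible = 4` measured downstream RNAs are evaluated; the default
matches the convention that fewer nodes can never reach the 0.1
significance threshold, and it is exposed as a knob. Multi-edge paths are
deliberately out of scope: a HYP models only direct causal adjacency, and
longer-range reasoning is left to joining significant HYPs downstream of
this package.

A HYP is a qualitative analogue of a naive Bayes classifier: downstream
nodes are assumed conditionally independent given the controller's state.
The whole procedure — HYP generation, the population, both statistics —
uses the graph topology and the *measured set only*, never the observed
states, which is what makes one HYP set reusable across the real data and
every matched random data set.

### Trinary states

A measurement is reduced to +1/−1/0 with three thresholds applied jointly:
|fold change| ≥ 1.3 (signed linear scale; log2 input is converted via
sign(x)·2^|x|), adjusted p ≤ 0.05 (the table is expected to carry
BH-adjusted p-values already; the package does not re-adjust what an
upstream limma fit produced), and average abundance ≥ 32 (in the units of
the supplied abundance column — for classic Affymetrix arrays, normalised
intensity; the filter removes noise-dominated probes). All three cutoffs
are user-configurable. A gene measured by several probe sets changes if at
least one probe set meets the criteria; when probe sets disagree in
direction, the smallest adjusted p-value wins, ties fall back to the larger
|fold change|, and a still-unresolved conflict yields state 0 with a
warning. This tie policy is a package choice (the convention's sources are
silent): it is deterministic and favours the strongest evidence.

### Direction and the two statistics

A changed downstream node with state *s* seen through an edge of sign *e*
implies controller direction *s·e*. The HYP's direction is the majority of
implied directions; ambiguous-edge nodes imply nothing and are tallied
separately. A tie (including zero unambiguous evidence) gives direction
"none", with `correct` set to the tied count — such a HYP's concordance is
by construction ≥ 0.5 and it can never pass the filter, so the tie rule
cannot manufacture significance.

With k correct, c contra, and l ambiguous nodes (observed = k + c + l):

- **Concordance** is the upper binomial tail of k among the t = k + c
  unambiguous trials at p = ½ — the probability that a direction-less coin
  would match the assigned direction at least k times. Ambiguous nodes are
  excluded from the trials (the l-correction): they attest that the
  controller regulates the node but cannot score direction.
- **Richness** is the upper hypergeometric tail of observed = k + c + l
  (ambiguous nodes *do* count here) among the HYP's n downstream nodes,
  drawn from the population of N downstream nodes of all HYPs with m state
  changes. N and m are shared constants for a data set.

Both sums include the all-correct term j = t (resp. j = min(n, m)): the
closed forms 2^−k for all-correct HYPs only hold with the full tail, and
the package's tails are validated against exhaustive enumeration oracles
and against `pbinom`/`phyper` in the test suite. Tails are accumulated in
log space (`lchoose` + log-sum-exp), so values such as 10^−25 are exact to
double precision rather than underflowing. Empty tails (no trials, or no
observed nodes) return 1 by convention; p-values are kept at full precision
internally and rendered as two significant figures (half-up) only in
reports.

A mechanism is reported when *both* p-values are ≤ 0.1 (inclusive). No
multiple-testing correction is applied across HYPs: the threshold is
calibrated empirically against matched random data, not by FDR, and HYPs
are overlapping, dependent tests for which the calibration approach is the
more honest control.

## Randomization

Matched random data sets keep the population, the HYP set, and the counts
of up- and down-regulated nodes fixed, and permute only *which* population
nodes carry the changes: the changed set is sampled uniformly without
replacement, then split into the matched numbers of +1 and −1 (sampling
then splitting is equivalent to any joint scheme with the same marginals).
`threshold_sweep()` reports, per candidate threshold, the real significant
count against the median over random sets — the empirical false-positive
calibration. A single master seed drives everything; per-iteration seeds
are pre-drawn from it, so iteration i is reproducible in isolation and a
shorter run is a prefix of a longer one.

Both statistics are intrinsically biased towards significance for HYPs
with more downstream nodes. `size_bias_report()` quantifies this as the
Pearson correlation between log10 p-value and HYP size on null scores,
overall and restricted to HYPs with ≥ 4 observed changes — the restriction
under which concordance is actually consulted, and which removes most of
its bias. `loess_adjust_concordance()` (span 0.75, degree 2, fitted in
log10 space; the span is exposed since no canonical value exists)
subtracts the fitted size trend from log10 concordance. The adjustment is
off by default and returned *alongside* the raw p-value: it is a
re-ranking diagnostic, not a calibrated probability.

## The synthetic fixture

`fixture_spec()` emulates the statistical structure the statistics assume:
controllers `act(SYN:Ci)` over RNA leaves `r(SYN:Gj)`, with downstream
nodes independent given the controller state. Defaults — 20 controllers,
500 RNAs, out-degree uniform in 10–30, 30% repressing edges, 5%
double-signed (ambiguous) links, 2% background change rate — describe a
modest curated knowledge base and a quiet experiment; planted mechanisms
flip each non-ambiguous downstream RNA with a given penetrance in the
direction implied by the edge sign. Changed rows draw |fc| ~ U(1.5, 4),
adjusted p ~ U(10^−6, 0.04), abundance ~ U(50, 5000); unchanged rows fail
both the fold-change and p-value criteria. The exact magnitudes are
irrelevant once states are trinarised — only which side of the thresholds a
row falls on matters — which is why simple uniform draws suffice. Probes
are generated only for RNAs that actually join the graph; real platforms
measure many transcripts absent from any knowledge base, but such
measurements are dropped at the mapping step and would only add warning
noise to every run.

What passing tests on this fixture do show: correct tail computation,
correct bookkeeping of population/possible/observed, calibration of the
null, and recovery of planted signal (≥ 95% recovery with the planted
direction at penetrance 0.8, background 0.02, across 200 replicates). What
they do not show: robustness to correlated downstream nodes (co-regulation
violates the independence assumption and makes concordance anti-
conservative), curation biases of real knowledge bases, or probe
cross-hybridisation.

## Numerical and design notes

- Test-suite problem sizes: 1000 random iterations on a ~20-HYP fixture
  for calibration, 200–300 iterations for bias diagnostics, 200 fixture
  replicates for recovery — sizes at which every check runs in seconds
  while binomial confidence on the checked rates is adequate.
- The abundance filter is applied to the single supplied average-abundance
  column, not per sample group.
- HYP output order is deterministic (by controller id; score tables by
  concordance, then richness, then id), so identical inputs and seed give
  byte-identical outputs.
- Degenerate inputs: an all-ambiguous HYP has t = 0 trials and concordance
  1; a saturated data set (m = N) forces richness 1 for every HYP; zero
  state changes completes with a warning and all p-values 1; zero generated
  HYPs is a hard error pointing at the graph/mapping overlap.

## Limitations

Only path-length-1 mechanisms are evaluated; controller identity
resolution (orthologs, namespaces) is the caller's responsibility; the
statistics treat downstream nodes as independent, which real regulons
violate to varying degree; and inference is bounded by the knowledge
base — a mechanism absent from the graph, or with fewer than four measured
targets, can never be inferred.
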