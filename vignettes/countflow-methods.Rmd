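---
title: "Methods and design of countflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of countflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countflow)
```

This vignette is the package's own account of the statistics it implements,
the parameters that matter, the design choices that were genuinely open, and
what the test suite does and does not establish.

## The problem

RNA-seq quantification yields a feature-by-sample count matrix. Before any
biology can be read off it, counts must be depth- and composition-corrected,
low-quality samples and unexpressed genes removed, and — in exploratory work
— many derived matrices produced: subsets per cell type, merged batches,
alternative normalizations. `countflow` treats that derivation history as a
first-class object (the *data map*) and implements the statistical steps an
exploratory pipeline needs: size-factor normalization, QC summaries and
filters, a nonparametric two-group differential-expression test, and a
network influence score that ranks transcription factors as candidate
trans-differentiation drivers.

## Normalization

All size-factor estimators return factors rescaled to geometric mean 1.
This is a pure convention — any common rescaling cancels in downstream
ratios — but fixing it makes methods directly comparable and gives the
equivariance property a clean statement: multiplying one sample's column by
`c` multiplies its raw factor by `c` and leaves the others' raw factors
unchanged.

### Median-of-ratios with a tunable inclusion criterion

The classic median-of-ratios estimator defines a pseudo-reference per gene
(the geometric mean across samples) and takes, per sample, the median of
count-to-reference ratios. Its weakness for single-cell data is structural:
the geometric mean is zero (or undefined on the log scale) for any gene with
a zero anywhere, so in a sparse matrix almost no gene is usable.

The variant implemented here makes the inclusion rule a parameter
`min_detect_frac` = `f`:

* a gene is included if it has positive counts in at least `ceiling(f * m)`
  of `m` samples;
* its reference is the geometric mean of its *positive* counts only;
* a sample's raw factor is the median of `k_ij / r_i` over included genes
  with `k_ij > 0`.

With `f = 1` and a zero-free matrix each choice reduces to the classic
definition, which the test suite verifies against both an independent
transcription of the classic formula and an established implementation.
Taking the geometric mean over positive counts only (rather than over all
samples) is the choice that keeps the estimator defined on sparse matrices —
the alternative of imputing zeros before the log would re-introduce the
original failure mode. Using `ceiling` makes the rule conservative for
fractional thresholds. A sample with no positive count among included genes
has no defined factor and is reported as an error naming the sample, rather
than silently receiving a neighbour's value.

`f` defaults to 1 (bulk behaviour); for single-cell matrices values around
0.3–0.9 trade reference stability against the number of usable genes.

### TMM

The trimmed-mean-of-M-values factor corrects for composition bias: a few
very highly expressed genes in one sample deflate the apparent expression of
everything else. Against a reference sample (the one whose upper quartile of
positive counts is closest to the mean upper quartile), per-gene log2 ratios
`M` and average log intensities `A` are computed over genes positive in
both samples; the top and bottom 30% by `M` and 5% by `A` are dropped
(`floor(n * trim)` from each end, rank ties broken by position); the
remaining `M` values are averaged with inverse approximate-variance weights
`1/w`, `w = (N_g - k_g)/(N_g k_g) + (N_r - k_r)/(N_r k_r)`; the scaling
component is `2^(weighted mean)` and the size factor multiplies it by the
library size. If fewer than 10 genes survive the double trim the estimator
falls back, with a warning, to the untrimmed weighted mean — trimming 30%
tails from a handful of genes is noise, not robustness. Under a pure
library-size change the component is exactly 1, which the acceptance checks
assert.

### The rest of the suite

Upper-quartile factors use the 75th percentile of positive counts with
linear (type-7) interpolation — stated explicitly because quantile
conventions differ across software. Spike-in factors run the
median-of-ratios machinery (inclusion fraction 1) on the spike-in rows only,
on the premise that spike content is proportional to sequencing depth and
nothing else. CPM/RPKM/TPM are per-value transformations; TPM
length-normalizes before depth-normalizing, hence every TPM (and CPM) column
sums to one million exactly. Quantile normalization replaces each column's
values by the cross-column means of order statistics; within-column ties
receive the mean of the rank-means their positions span. Its defining
properties (identical sorted columns, idempotence) hold exactly on tie-free
data; with ties the group-averaging step perturbs them slightly, which is
inherent to any tie rule that keeps tied values tied.

## Differential expression

The package's own test is the two-sided Mann-Whitney U per feature. The
exact null distribution is used when the larger group has at most 8 samples
and the feature's values are tie-free; otherwise the normal approximation
with tie correction and continuity correction. The threshold of 8 keeps the
exact enumeration cheap while covering the small-sample range where the
approximation is weakest; the convention is fixed so results are
reproducible across machines. Features constant across all samples carry no
rank information and are assigned p = 1. Because rank tests are invariant
to monotone transforms, running on normalized rather than log-normalized
values changes nothing but the reported group means.

P-values are adjusted with the Benjamini-Hochberg step-up across all tested
features, and the fold change is `log2((mean_a + c)/(mean_b + c))` with
pseudocount `c = 1` on normalized means — the pseudocount bounds the fold
change when one group is all zeros.

Two statistical facts shape the tests:

* **Discreteness at small n.** At 5 vs 5 the exact two-sided p-values jump
  from 8/252 ≈ 0.0317 to 14/252 ≈ 0.0556; no attainable rejection region
  has size 0.05, so the realized type-I rate at nominal 0.05 is ≈ 0.032 —
  conservative, never inflated. A check expecting the empirical rate to
  bracket 0.05 from both sides will therefore fail for any correct
  implementation at these sizes; the suite asserts the one-sided
  (no-inflation) bound and documents the two-sided band as unattainable.
* **Power and expression filtering.** A planted 4-fold change on a gene
  with near-zero baseline expression is invisible to any test. The power
  guard (sensitivity > 0.8 at 10 vs 10 for planted |log2 FC| = 2) is
  therefore stated for the package's canonical pipeline — low-expression
  filter, then normalize, then test — measured among true positives that
  survive the filter; there it reaches ≈ 0.91–0.95 on the default
  generator, versus ≈ 0.7 with no filter because of genes expressed at a
  few counts or less.

## TF network influence

Differential-expression output is first collapsed to a non-negative gene
score; the default `|log2 FC| * -log10(p_adj)` rewards genes that are both
strongly and confidently shifted, with `abs_lfc` and `neglogp` available
when only one axis is wanted. Adjusted p-values are floored at 1e-300 so
scores stay finite. These formulas, and the three influence options below,
are this package's codification of score-and-neighborhood ranking; the
column set of the influence table (center score, neighborhood size,
activated neighbors, influence score, rank) is fixed accordingly.

For each transcription factor `t` with direct neighborhood `N(t)`
(out-neighbors in a directed regulatory network, all neighbors in an
undirected protein-association network):

* `sum`: `S_t = G_t + Σ_{j∈N(t)} G_j` — total evidence reachable in one
  step;
* `degree_normalized` (default): `S_t = G_t + Σ G_j / d(j)` with `d(j)` the
  in-degree (degree if undirected) of the neighbor, so a target regulated
  by many factors divides its credit among them; summed over all TFs the
  shared credit is conserved, which the suite checks by brute force;
* `activated_count`: the number of neighbors with `G_j ≥ τ` — a
  threshold-count that ignores magnitudes beyond `τ`.

Only one-step neighborhoods are scored; multi-level neighborhoods are a
possible extension but direct regulation is the interpretable unit, and
deeper levels would need a decay convention with no obvious default. Ties
in the ranking break by center score, then gene name, so ranks are a
deterministic permutation. Gene symbols match case-sensitively and exactly;
DE genes absent from the network simply contribute nothing, and network
genes absent from the DE table score 0. Self-loops are dropped at load time
and duplicate edges collapse to one.

## The data map

Nodes are datasets; edges carry operation records (name, parameters,
timestamp). The graph is a DAG, not a tree, because merges give a node two
or more parents; acyclicity is re-checked after every mutation. Node IDs
are a deterministic counter (`n0`, `n1`, ...) so lineage tables are
reproducible across runs. Deletion cascades to the descendant closure —
children are defined only relative to their parent's data, so orphaned
derivatives would be meaningless; the suite checks the closure against an
independent graph-reachability computation.

Operation records written through the `dm_*` wrappers are complete: the
same `apply_operation()` code path that derives a node also serves
`replay_node()`, so replaying a node's ancestry from the root matrix
reproduces its stored matrix bit for bit. This is the package's provenance
guarantee, and the acceptance checks exercise it over
normalize/filter/subset/merge chains, including after an archive round
trip.

Analysis recipes are registered globally on the map and re-run eagerly
whenever the active node changes; eager execution makes report state easy
to reason about at the cost of recomputation on every switch, which is
acceptable at the matrix sizes this package targets. A recipe whose
preconditions fail on the new node (e.g. a DE recipe after filtering left a
single condition) attaches a failure report with the reason rather than
raising, so one broken recipe cannot block a node switch. Per-node
parameter overrides are deliberately not supported — one recipe, one
parameter set, comparable across nodes.

## Session archives

An archive is a single JSON document: format version, the graph, recipes,
one full-precision TSV payload per node matrix (17 significant digits, so
doubles round-trip exactly), attached reports with typed tables, and an md5
checksum per payload. Loading verifies the version, every checksum and
every map invariant. With timestamps injected from a frozen clock,
save → load → save is byte-identical; parameter records are canonicalized
through a JSON round trip at save time so that live vectors and loaded
lists serialize the same way. A single self-describing text file was chosen
over a zip/tar container because archive byte-determinism then does not
depend on container-header timestamps, and the payloads remain readable by
any language.

## The synthetic-data generator

`simulate_counts()` draws gene baseline means from a log-normal
(`meanlog = 1.5`, `sdlog = 1` — median ≈ 4.5 counts with a long right
tail, emulating sparse single-cell libraries), true size factors from a
log-normal (`sdlog = 0.3`, about a 2-fold typical depth range), and counts
from a negative binomial with dispersion `φ = 0.1`
(`var = m + φm²`); `φ = 0` degenerates to Poisson. A fraction `π = 0.1` of
genes carries log2 effects of ±N(2, 0.5) between two balanced conditions.
Optional zero inflation follows `P(drop) = plogis(a − b·log m)` with
defaults `a = 1.5`, `b = 1` — entries with mean below ≈ 4.5 counts are
dropped more often than not, mimicking dropout's mean-dependence. Spike-in
rows have fixed concentrations, scale only with the size factor, take
Poisson noise (technical, not biological variation), and are exempt from
dropout and DE.

What passing tests show — and what they do not: the generator produces
NB-distributed, library-scaled, zero-inflated counts with known truth, so
recovery and error-control results demonstrate correctness of the
estimators under their own model assumptions. Real data add batch
structure, gene-gene correlation, UMI saturation and mean-dispersion
trends that the generator does not emulate; results here say nothing about
robustness to those.

Problem sizes used by the suite and the acceptance script — 2000 × 20 for
size-factor recovery, 2000 features at 5 vs 5 for the null, 10 × 1000 for
FDR, 200 enumeration instances — are the documented study conditions and
keep the full run in the tens of seconds.

## Other numerical choices and limitations

* Counts may be non-integer (estimated counts are accepted); only negative
  or non-finite values are rejected.
* Unknown IDs in keep/drop lists warn and are ignored — curated gene lists
  routinely contain symbols absent from a given matrix.
* The coefficient of variation is reported as `NA` where the mean is zero
  rather than as infinity.
* Rank-frequency tables break count ties by assigning sequential ranks in
  descending order; frequencies sum to 1 by construction.
* Sample-ID collisions on merge are an error; nothing is auto-renamed.
* Cook's-distance sample filtering is out of scope: it requires fitted
  per-gene GLMs, which this package deliberately does not produce.
* The presentation is tidyverse-native (tibbles, pipes, `autoplot`); the
  one exception is the count container itself, which stays a numeric
  matrix with an ID/kind wrapper because a feature-by-sample matrix in
  long form would be needlessly slow at typical sizes. The data map is
  environment-backed (mutated in place), matching how sessions behave.
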