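---
title: "Statistical methods behind enrichkit"
author: "enrichkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind enrichkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichkit)
```

# The question the toolkit answers

Given a genome-wide measure of differential behaviour — a ranking of genes
by a two-class contrast, a pre-computed ranking, or a single sample's
expression profile — is a predefined gene set (a pathway, a signature)
concentrated at one end of that ranking more than chance allows? enrichkit
implements four complementary answers: two-class GSEA with phenotype or
gene-set permutation, pre-ranked GSEA, single-sample GSEA (ssGSEA), and
over-representation analysis (ORA) of a discrete gene list. Everything runs
offline: gene set libraries are read from local GMT files and a seeded
synthetic-data generator supplies ground-truth inputs for verification.

# The running-sum enrichment statistic

Let the ranked list hold genes $g_1, \dots, g_N$ with ranking scores
$r_1 \ge \dots \ge r_N$, and let $S$ be a gene set matching $N_h$ of them.
Walking the list from top to bottom, the running sum gains
$|r_i|^p / \sum_{j \in S} |r_j|^p$ at each member ("hit") and loses
$1/(N - N_h)$ at each non-member. The enrichment score (ES) is the signed
maximum deviation of this curve from zero, so $ES \in [-1, 1]$: a set
concentrated at the top yields ES near $+1$, at the bottom near $-1$. The
weighting exponent $p$ defaults to 1; $p = 0$ gives every gene weight 1 and
reduces the ES to the classic signed two-sample Kolmogorov–Smirnov
supremum between the member and non-member rank distributions.

Two numerical choices matter here:

* The curve is computed as a difference of *cumulative-sum ratios*
  (`cumsum(w)/sum(w) - cumsum(miss)/(N - Nh)`), not by accumulating
  per-position increments. For $p = 0$ every curve value is then an exact
  ratio of integer counts, which makes the KS reduction bit-exact rather
  than merely close.
* The peak is the *first* position attaining the maximal $|curve|$. With
  continuous scores ties between the positive maximum and the negative
  minimum have probability zero; in the position-only fast path used for
  permutation nulls, an exact tie resolves to the positive extreme. Both
  rules are deterministic.

The *leading edge* is the set of member genes at or before the peak when
$ES \ge 0$, and at or after it (the mirror convention) when $ES < 0$.

# Ranking metrics for two-class designs

`score_genes()` converts a genes-by-samples matrix with a two-class
phenotype into a ranked list. Class A is the first-named class of the CLS
header. Metrics (per gene, classes A and B):

| metric | formula | notes |
|---|---|---|
| `signal_to_noise` (default) | $(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$ | each $\sigma$ floored at $0.2\,|\mu|$ and $10^{-8}$ |
| `t_test` | $(\mu_A - \mu_B)/\sqrt{\sigma_A^2/n_A + \sigma_B^2/n_B}$ | $\sigma$ floored at $10^{-8}$ only |
| `log2_ratio_of_classes` | $\log_2(\mu_A/\mu_B)$ | requires strictly positive means |
| `difference_of_classes` | $\mu_A - \mu_B$ | |

The signal-to-noise floor ($\sigma \leftarrow \max(\sigma,\,0.2|\mu|,\,
10^{-8})$) prevents near-constant genes from dominating the ranking through
a vanishing denominator; the relative part mirrors the long-standing
desktop-GSEA behaviour, and the absolute part only guards exact-zero
variance. The t-statistic keeps only the absolute guard, since its pooled
denominator is not conventionally floored. Ties in any ranking are broken
by ascending gene symbol, so every ranking is a unique total order
regardless of input row order or platform.

# Permutation null, NES, p-values, FDR

Significance comes from an empirical null of ES values
(`n_permutations = 1000` by default):

* **Gene-set permutation** (pre-ranked mode): each permutation rescores a
  uniformly random gene subset of the same matched size against the fixed
  ranking. Under exchangeability this is equivalent to permuting gene
  labels, and it is cheap because the ranking never changes.
* **Phenotype permutation**: each permutation shuffles the sample class
  labels (class sizes preserved), *recomputes the ranking metric*, re-sorts,
  and rescores every set. Re-ranking is essential: permuting samples
  invalidates the observed ranking, not just the set memberships.

The **NES** divides the observed ES by the mean magnitude of the same-sign
null values, making scores comparable across set sizes; positive and
negative tails are normalized separately because the two sides of the null
are not symmetric in general. The **empirical p-value** uses the same-sign
null $S$ with add-one smoothing,
$p = (1 + \#\{x \in S : |x| \ge |ES|\}) / (1 + |S|)$, so a finite
permutation run never reports $p = 0$; this makes the estimator slightly
conservative by construction. $ES = 0$ reports $p = 1$, and an empty
same-sign null reports $p = 1$ with a warning.

The **FDR q-value** follows the GSEA convention: all per-set null ES are
self-normalized (each by its own set's same-sign null mean) and pooled;
for a set with $NES^* \ge 0$,
$$ q = \frac{\#\{\text{pooled null } NES \ge NES^*\} / \#\{\text{pooled null } NES \ge 0\}}
           {\#\{\text{observed } NES \ge NES^*\} / \#\{\text{observed } NES \ge 0\}}, $$
mirrored with $\le$ for negative sets, clipped to $[0, 1]$. Because the raw
ratio need not be monotone in $|NES|$, each set's q is then replaced by the
minimum raw q over itself and all less extreme same-sign sets (the same
step-up enforcement BH uses), so q never decreases as significance grows.

Reproducibility is a contract, not an accident: one root seed is supplied;
gene-set permutation derives a per-set stream by a stable 31-bit hash of
the set name, so adding, removing or reordering sets never changes another
set's null; phenotype permutation draws its label shuffles once, before
any set is scored, so set order is again irrelevant. Identical seed and
configuration give bit-identical results, and a `--threads` flag can never
change them.

# ssGSEA

For one sample, genes are ranked by decreasing value (ties again by
symbol). With $\alpha = 0.25$ by default, the gene at rank position $i$
carries weight $(N - i + 1)^\alpha$ — the descending rank index raised to
$\alpha$ — if it is a set member, and non-members count 1. The score is the
*integrated* difference $\sum_i [P_{in}(i) - P_{out}(i)]$ between the
cumulative normalized member-weight distribution and the cumulative
non-member fraction, not the supremum. Implementations in the wild disagree
on whether the weight uses raw expression or the rank index; enrichkit uses
rank indices, which makes every score invariant under any strictly
increasing per-sample transform (log-normalization, quantile scaling) — a
property the test suite asserts exactly, not approximately. Cross-sample
normalization divides the whole set-by-sample score matrix by its global
range (max − min); a zero range (all scores equal) skips normalization
with a warning rather than dividing by zero. Scores are computed one
column at a time, so a sample's raw score can never depend on other
samples; only the optional normalization couples columns.

# Over-representation analysis

For a query of $n$ genes against a set of size $K$ inside a universe of
$N$ genes with overlap $k$, the p-value is the one-sided Fisher exact /
hypergeometric upper tail $P[X \ge k]$ ($k = 0$ gives exactly 1). The
default universe is the union of all library genes — self-contained and
reproducible; a custom background can be supplied. Per library,
Benjamini–Hochberg adjustment is applied across terms. The odds ratio is
the plain cross-product ratio of the 2×2 table; the Haldane 0.5 correction
is applied only when a zero cell would make it undefined. The combined
score is $-\ln(p) \cdot z$ with $z = (k - nK/N)/\sigma_{hyper}$, the
standardized deviation of the overlap from its hypergeometric expectation.
This $z$ is a deliberate local surrogate: the Enrichr service computes its
z from precomputed background rank deviations that exist only server-side,
so combined scores here match Enrichr's in spirit and scale, not digit for
digit — while the Fisher p-values match exactly.

# The synthetic-data generator

`plant_spec()` describes the simulated study: a universe of
`universe_size` genes (default 5000), `n_sets` random sets (default 50)
with sizes uniform in `set_size_range` (default 15–50), Gaussian
background noise (`noise_sd = 1`), and planted signal: genes of the
planted sets are shifted by `effect_size` (in `noise_sd` units, default 1)
— in class A only for expression matrices, or directly on the ranking
scores for pre-ranked lists. Defaults were chosen once as typical of a
moderately powered bulk two-class design; the effect is additive and
homoscedastic, which is the simplest model under which both
signal-to-noise and rank-based statistics behave predictably.

What the generator deliberately does **not** emulate: count-distribution
effects (negative binomial dispersion, dropout), correlated co-expression
within pathways, composition effects between overlapping sets, and batch
structure. Tests passing on this generator therefore demonstrate the
*statistical contracts* of the implementation — calibration under the
null, power against planted mean-shifts, determinism — not performance on
real single-cell data.

# Verification strategy and problem sizes

Every statistic is checked against an independent oracle or a
planted-truth simulation, at sizes chosen to finish a full run in about a
minute:

* running-sum ES vs a naively coded incremental walk: 1000 random
  instances, $N \le 100$, agreement $\le 10^{-12}$; positive weights are
  used there because at $p = 0$ curve values are exact rationals and an
  exact $|max| = |min|$ tie makes the *sign* of ES convention-dependent —
  the $p = 0$ case has its own bit-exact ECDF comparison on 100 instances;
* null calibration on a global-null pre-ranked simulation, 200 sets ×
  1000 permutations (fraction of $p \le 0.05$ and KS uniformity);
* planted recovery: effect 2, set size 30, universe 5000, 20 replicates,
  1000 permutations each;
* Fisher p vs exhaustive log-binomial tail sums over every 2×2 table with
  $N \le 60$ (about 630,000 tables);
* ssGSEA vs a quadratic two-pass oracle plus exact monotone-transform
  invariance, 100 samples of 100 genes;
* the gene-permutation null mean vs an independent 10,000-draw Monte-Carlo
  simulation; the prerank ES additionally cross-checked against
  `fgsea::calcGseaStat` on random instances.

The phenotype-permutation planted-recovery check runs at 5 replicates of
200 permutations (universe 500, 10 sets) — smaller than the pre-ranked
recovery study because each phenotype permutation re-ranks the whole
matrix, and a strong planted effect makes the outcome insensitive to the
replicate count.

# Degenerate inputs and edge policies

* Sets matching fewer than `min_set_size` (15) or more than
  `max_set_size` (500) genes are skipped and listed, not scored.
* A set matching *all* ranked genes is an error (the decrement is
  undefined), as is an empty intersection.
* If every in-set ranking score is exactly zero under $p > 0$, weights are
  undefined; the kernel falls back to unweighted increments with a
  warning.
* Expression input rejects NA tokens by default (silent imputation would
  change statistics); an explicit flag drops affected genes instead.
  Duplicate gene rows keep the highest-mean row, deterministically.
* Gene symbols are upper-cased everywhere on load, so matching across
  GMT, RNK, CLS, GCT and query files is case-insensitive.
* Empty descriptions are written to GMT as `"na"`, the common convention.

# Known limitations

* Empirical p-values are bounded below by $1/(n_{perm}+1)$; distinguishing
  very small p-values needs more permutations (no distribution-fitting
  refinement of the far tail is attempted).
* Phenotype permutation recomputes the metric per permutation in plain R;
  it is comfortable at thousands of genes and tens of samples, but very
  large single-cell matrices are better served by the pre-ranked route.
* The combined score's z is the local hypergeometric surrogate described
  above.
* ORA is enrichment-only (one-sided); depletion appears only as an odds
  ratio below 1.
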