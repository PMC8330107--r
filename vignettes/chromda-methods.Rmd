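---
title: "Detecting differentially active chromatin domains with chromDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially active chromatin domains with chromDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genes that share a chromatin domain — a TAD or a compartment domain called
from Hi-C data — are physically co-confined and often co-regulated. When two
sample groups are compared (tumor vs. normal tissue, mutant vs. wild-type,
molecular subtypes), standard differential expression treats every gene
independently and cannot say whether a *domain* changed activity as a unit.
chromDA asks exactly that: given a domain partition, a genes-by-samples
expression matrix and a two-level sample annotation, which domains show
coordinated expression changes between the two conditions?

The package answers in two stages, mirroring how the statistics are
organized internally:

1. a genome-wide concordance test (is there more within-domain concordance
   of fold-changes than chance allows?), and
2. a per-domain caller returning the significantly differentially active
   domains.

## Inputs and preprocessing

Domains arrive as BED (converted to 1-based GRanges on read), genes as
GFF3/GTF or a minimal TSV; genes are assigned to the domain containing
their TSS (start of a + gene, end of a − gene), with one fallback: a gene
whose TSS lies in an inter-domain gap but whose 3' end lies inside a domain
is assigned to that domain. A TSS exactly on a domain start belongs to that
domain; on the end-exclusive bound, to the next.

Count-like matrices are filtered to genes with at least 5 reads in at least
80% of samples, and each sample is scaled by its upper quartile (×1000).
Only domains with at least 3 member genes, and no more genes than the 99th
empirical percentile of the per-domain gene counts, are tested. We use the
empirical (type 1) quantile so the cap is always an observed count; with
few domains an interpolated quantile could drop the largest legitimate
domain.

Gene-level log2 fold-changes come from a moderated two-sample test written
into the package: gene-wise pooled variances are shrunk toward a prior
variance whose scale and degrees of freedom are estimated by method of
moments on the log sample variances (a Newton inversion of the trigamma
function), and p values use a t distribution with residual + prior degrees
of freedom. The test suite cross-checks it against an established
empirical-Bayes implementation; a plain Welch t is available as a fallback
mode. The sign convention is condition 2 over condition 1, condition order
being the order of first appearance in the sample annotation
(`flipConditions` reverses it).

## Stage 1: fold-change concordance

For a domain with member log2 fold-changes $l_1, \dots, l_n$ the
fold-change concordance score is

$$
\mathrm{FCC} = \left[\frac{2}{n}\sum_i \mathbb{1}(l_i < 0) - 1\right]
\cdot \left[2\,\frac{\sum_i |l_i|\,\mathbb{1}(l_i < 0)}{\sum_i |l_i|} - 1\right],
$$

the product of a sign-balance and a magnitude-balance bracket. It is 1 when
all genes move in the same direction (either direction), near 0 when signs
and magnitudes carry no shared pattern, and approaches −1 when most genes
agree but the few dissenters carry much larger fold-changes. Genes with a
fold-change of exactly 0 have no sign and are excluded from their domain's
score; a domain with no informative gene scores 0 and is flagged degenerate.
FCC is invariant to positive rescaling, to a global sign flip and to gene
order, and under independent equiprobable signs a 2-gene domain is fully
concordant half the time and a 3-gene domain a quarter of the time — the
package's acceptance checks recompute these baselines by Monte Carlo.

Domains are ranked by decreasing FCC and the cumulative sum forms the
observed curve. The null curve repeats the computation after permuting
gene-to-domain assignments, with permutations restricted to equal-sized
expression classes (5 by default) built from a per-gene expression summary,
so that permuted domains keep a realistic mix of expression levels; the
pointwise 95th percentile over permutations is retained as a single null
curve ("pointwise" is the only reading that yields a curve). The AUC ratio
is the trapezoidal area under the observed curve over that of the null
curve; values above 1 indicate genome-wide concordance beyond chance.

Two notes on this construction. First, because the reference is a 95th
percentile rather than a mean, the ratio is conservative: on data with no
signal it concentrates *below* 1, and with only a few hundred domains the
calibration suite shows it ranges roughly 0.7–1.0 (the deficit and its
spread both shrink as the number of domains grows; genome-wide partitions
have thousands). Second, the expression classes default to the per-gene
mean of the normalized matrix; when TPM-style length-corrected summaries
are available they can be passed via `classValues` — classes are rank-based,
so any monotone transform of the same summary gives identical classes. The
classes are built from all samples pooled; the package does not build them
per condition.

## Stage 2: differentially active domains

Each tested domain gets two statistics:

- **mFC**, the mean of its member genes' log2 fold-changes, and
- **mCor**, the mean Pearson correlation over all unordered member-gene
  pairs, computed across *all* samples (conditions pooled) on
  quantile-normalized log2 values. Pairs involving a zero-variance gene are
  undefined and skipped.

Quantile normalization is rank-mean: every sample's values are replaced by
the mean of the column-sorted matrix at their rank, ties receiving the mean
of their tied reference values.

Each statistic is tested against its own empirical null:

- mFC against gene-to-domain permutations within the same expression
  classes as stage 1, two-sided via the absolute value:
  $p = (1 + \#\{|\mathrm{mFC}^\ast| \ge |\mathrm{mFC}|\})/(1 + B)$.
- mCor against a cross-boundary null: for a domain with $k$ genes, $k$
  flanking genes are taken from the two adjacent domains — $\lceil k/2
  \rceil$ from the left and $\lfloor k/2 \rfloor$ from the right, closest
  to the boundary first, one side supplying the other's shortfall from that
  single adjacent domain — and the mean of all $k \times \#\mathrm{flank}$
  cross-correlations is recorded. Pooling these means over all domains
  gives the null; the one-sided p value counts null values at or above the
  observed mCor. We read "$k$ genes from the left-side and right-side
  adjacent domains" as $k$ in total; `kPerSide = TRUE` switches to the
  other reading. A single-dataset run pools only its own domains; a
  precomputed pool spanning several datasets can be supplied via
  `crossBoundaryNull`.

Both empirical p values carry the +1/+1 pseudo-count, so they live on the
grid $\{i/(B+1)\}$ and are never 0. They are combined one-sided by
Stouffer's method, $z_i = \Phi^{-1}(1-p_i)$,
$p_\mathrm{comb} = 1 - \Phi((z_1+z_2)/\sqrt 2)$, adjusted by
Benjamini-Hochberg, and a domain is called differentially active at
adjusted $p \le 0.01$ by default. The direction of change is reported
separately as the sign of mFC.

## Companion analyses

- **Artificial partitions** place domain borders at the midpoints of
  consecutive real domains, so every artificial domain straddles exactly
  one real boundary; artificial domains whose genes all originate from a
  single real domain are excluded. Running the caller on this partition is
  the negative control for boundary relevance.
- **Shared boundaries** between two partitions are matched at 40-kb bins
  within a ±2-bin radius, start and end boundaries separately, and the two
  shares averaged. Each query boundary counts at most once.
- **Immune domains**: per-gene Pearson correlation of log10 expression with
  tumor purity, averaged per domain; domains at or below the 0.05-quantile
  of the non-significant domains' averages are flagged. The threshold is
  always recomputed from the data at hand, never hard-coded.
- **Gene-family networks** connect genes sharing a domain (on domains where
  at least half the genes belong to the family) and compare observed edge
  counts with resamples that preserve chromosome representation and gene
  contiguity, re-drawing any sampled cluster dominated (≥ 80%) by one
  family.
- **Conserved regions** match significant domains across datasets at ≥ 80%
  *reciprocal* base-pair overlap (the stricter, symmetric reading of the
  overlap rule), group matches by connected components, keep regions with
  at least 3 genes common to all matched domains, and merge regions sharing
  ≥ 80% of those genes.
- **Differential interactome**: given per-pixel contact significance
  matrices ($S = -\log_{10} p$) for two conditions, $\Delta S = S_1 - S_2$
  is tested against the pooled $\Delta S$ of all pixels within a 2-Mb
  separation across chromosomes, two-tailed with the same pseudo-count (and
  "greater or equal" in the survival count, keeping p grid-valued and
  positive). The tested pixel itself remains in the background pool — the
  conservative choice. Direction is the sign of $\Delta S$ (+1 = stronger
  in condition 1); the per-domain summary signs $-\log_{10} p$ by a
  configurable `positiveCondition` so either condition can be drawn as the
  positive axis. Any coverage equalization between the two contact maps
  belongs upstream in the significance caller.

## The synthetic generator

`simulateDataset()` emulates exactly the structure the statistics assume:
a tiling domain partition, genes with TSSs inside domains, log-normal
count-like expression (log-scale noise sd 0.5 around per-gene baselines,
so the 5-read/80% filter is exercised), planted active domains that shift
all member genes by `effectLfc` in condition 2 and share a latent factor
$x = \sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ giving an exact target
intra-domain correlation in expectation, and immune domains whose genes are
negatively coupled to a per-sample purity covariate.
`simulateInteractionPair()` produces two symmetric strength matrices with a
distance-decay baseline, equal-variance noise at every pixel (the baseline
carries a positive floor so strengths never truncate at zero, keeping
per-pixel differences exchangeable between conditions) and optional planted
gain blocks.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: library-size and GC biases beyond a global
scale, count overdispersion structure of real RNA-seq, baseline
co-expression among unplanted neighbors, copy-number effects, cell-type
mixtures beyond the single purity covariate, and realistic Hi-C noise.
Calibration and recovery results here say the statistics do what they claim
under their own model, not that the model captures every property of tumor
cohorts.

## Numerical choices and problem sizes

- Permutation defaults: 10,000 (`nPerm`); high-precision runs use 100,000.
  One top-level seed; each stochastic stage derives its own sub-seed, so
  adding a stage never perturbs another stage's stream.
- The calibration and recovery suites run at 200 domains, ~1,100 genes,
  30–40 samples per condition and 2,000 permutations over 10–20 seeds —
  large enough for stable fractions, small enough to keep the default test
  run fast.
- Degenerate inputs: all-zero fold-change domains score FCC 0 and are
  flagged; domains whose member pairs are all zero-variance are excluded
  from the caller with a warning; expression classes with fewer than 2
  genes merge into their neighbor; a p value of exactly 1 dominates the
  Stouffer combination ($z = -\infty$).
- Ties: expression-class boundaries break ties by gene id; quantile
  normalization averages tied reference values; empirical counts use ≥ so
  ties favor the null.

## Limitations

The caller tests domains marginally; overlapping signals (a planted domain
next to a correlated neighbor) are not deconvolved. The cross-boundary null
borrows genes only from immediately adjacent domains, so chromosome ends
and filtered-out neighbors shrink the pool. The AUC ratio inherits the
conservatism described above for small domain counts. And the moderated
test assumes a two-group design without covariates — batch or purity
adjustment must happen upstream, or purity-driven domains can be flagged
(not corrected) downstream.
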