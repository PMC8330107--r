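# chromDA — differential activity of chromatin domains

Genes sharing a chromatin domain (a TAD or compartment domain called from
Hi-C) are physically co-confined and often co-regulated. chromDA takes a
domain partition (BED), gene annotations (GFF3/GTF or TSV), a genes ×
samples expression matrix and a two-level sample annotation, and asks which
domains change activity *as a unit* between the two conditions — tumor vs.
normal, mutant vs. wild-type, subtype vs. subtype.

It is intended for computational biologists analyzing matched Hi-C and
RNA-seq cohorts who want a domain-level complement to gene-level
differential expression.

## The statistics

**Stage 1 — genome-wide concordance.** Each domain with member log2
fold-changes *l*₁…*l*ₙ gets a fold-change concordance score

    FCC = [ (2/n) Σ 1(lᵢ<0) − 1 ] · [ 2 Σ|lᵢ|·1(lᵢ<0) / Σ|lᵢ| − 1 ]

— 1 when all genes move together, ≈0 with no shared pattern, → −1 when a
few dissenters dominate in magnitude. Domains are ranked by decreasing FCC;
the cumulative-sum curve is compared (trapezoidal AUC ratio) against the
pointwise 95th percentile of curves from gene-to-domain permutations
restricted to expression quintiles. AUC ratio > 1: fold-changes are more
concordant within domains than chance allows.

**Stage 2 — per-domain calls.** Each domain's mean fold-change (mFC) is
tested two-sided against the same stratified permutations, and its mean
pairwise gene correlation (mCor, quantile-normalized values, all samples)
one-sided against a cross-boundary null built from equally many flanking
genes of the adjacent domains. The two empirical p values (+1/+1
pseudo-count, never 0) are combined with one-sided Stouffer, BH-adjusted,
and domains with adjusted p ≤ 0.01 are reported as differentially active,
with direction = sign(mFC).

Companion procedures: artificial midpoint partitions (boundary negative
control), shared-boundary ratio between partitions, immune-domain flagging
from tumor-purity correlations, gene-family co-domain network enrichment,
conserved differentially active regions across datasets, and a differential
interactome test on precomputed per-pixel contact significance
(ΔS = S₁ − S₂ against a 2-Mb background pool).

## Worked example

Everything below is generated — no downloads. The generator plants 8
differentially active domains (log2 effect 1.5, intra-domain correlation
0.5) among 50 domains, 20 samples per condition:

```r
library(chromDA)

cfg <- simConfig(nChrom = 2, domainsPerChrom = 25, samplesPerCondition = 20,
                 plantedActiveDomains = 8, effectLfc = 1.5,
                 intraDomainRho = 0.5, seed = 101)
sim <- simulateDataset(cfg)

runFCC(sim$ds, sim$domains, sim$genes, nPerm = 1000, seed = 3)
#> FCCResult with 50 domains
#>   AUC ratio: 1.311  ( 1000 permutations, seed 3 )
#>   fully concordant (FCC = 1): 34.0%

da <- runDomainActivity(sim$ds, sim$domains, sim$genes, nPerm = 1000, seed = 3)
da
#> DomainActivityResult with 50 tested domains
#>   significant (p_adj <= 0.01 ): 8
#>   mFC permutations: 1000 ; cross-boundary null size: 50

head(as.data.frame(domainTable(da))[, c("domain_id", "n_genes", "mfc",
                                        "mcor", "p_comb", "p_adj")], 3)
#>   domain_id n_genes       mfc      mcor       p_comb        p_adj
#> 1     D0006       6 -1.424079 0.7026859 0.0001345671 0.0009611936
#> 2     D0018       7 -1.449334 0.7918906 0.0001345671 0.0009611936
#> 3     D0020       3 -1.592169 0.7832216 0.0001345671 0.0009611936

setequal(significantDomains(da),
         subset(sim$truth, type != "null")$domain_id)
#> [1] TRUE
```

The AUC ratio of 1.31 says fold-changes concentrate within domains
genome-wide; the caller then recovers exactly the 8 planted domains at
adjusted p ≤ 0.01, with mFC giving the size and direction of each domain's
shift and mCor its internal co-expression.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/chromda simulate --seed 101 --planted 8 --out simdir
Rscript inst/scripts/chromda activity --domains simdir/domains.bed \
    --genes simdir/genes.tsv --expr simdir/expression.tsv \
    --cond simdir/conditions.tsv --n-perm 1000 --seed 3 --out outdir
```

Exit codes: 0 success, 1 internal error, 2 validation/usage. Every output
directory contains a `manifest.json` (version, config, input digests, seed)
from which the run is reproducible.

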