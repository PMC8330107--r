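## Shared fixture builders. Everything is generated in code; nothing is read
## from disk except files the tests themselves write to tempdir().

## Minimal domain GRanges from BED-style (0-based half-open) coordinates.
domainsFromBed <- function(chrom, start0, end0, ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0))
  names(gr) <- if (is.null(ids)) sprintf("D%04d", seq_along(gr)) else ids
  gr
}

## Minimal gene GRanges from BED-style coordinates (uses the package's
## internal constructor so TSS conventions match the readers).
genesFromBed <- function(gene_id, chrom, strand, start0, end0) {
  chromDA:::makeGenes(gene_id, chrom, strand, start0 + 1, end0)
}

## Small deterministic expression matrix with two conditions.
tinyExpression <- function(nGenes = 20, nPerCond = 5, seed = 42,
                           baseMean = 100) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * 2 * nPerCond, baseMean),
              nrow = nGenes,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("S%03d", seq_len(2 * nPerCond))))
  ExpressionData(m, rep(c("A", "B"), each = nPerCond))
}

## Brute-force FCC: literal transcription of the two-bracket formula.
fccOracle <- function(lfc) {
  lfc <- lfc[lfc != 0]
  n <- length(lfc)
  d <- as.numeric(sign(lfc) == -1)
  a <- 2 / n * sum(d) - 1
  b <- 2 * sum(abs(lfc) * d) / sum(abs(lfc)) - 1
  a * b
}

## Brute-force BH: sort ascending, p * n / rank, cumulative min from the top.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Brute-force rank-mean quantile normalization (loop form, tie groups get
## the mean of their reference values).
qnormOracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    for (i in seq_along(xj)) {
      # positions of this value's tie group in the sorted column
      pos <- which(sort(xj) == xj[i])
      out[i, j] <- mean(ref[pos])
    }
  }
  out
}
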