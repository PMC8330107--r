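#' Assign genes to chromatin domains by TSS
#'
#' Each gene is assigned to the domain containing its TSS. If no domain
#' contains the TSS but a domain contains the gene's 3' end, the gene is
#' assigned to that domain (rescues genes whose promoter falls in a gap
#' between domains). Genes matching neither rule stay unassigned.
#'
#' @param genes gene \link[GenomicRanges]{GRanges} from \code{\link{readGenes}}.
#' @param domains domain GRanges from \code{\link{readDomains}}.
#' @return a named list (domain id -> character vector of member gene ids,
#'   ordered by TSS) for every domain with at least one gene; unassigned gene
#'   ids are stored in \code{attr(, "unassigned")}.
#' @export
assignGenesToDomains <- function(genes, domains) {
  domains <- validateDomains(domains)
  assertThat(is(genes, "GRanges") && !is.null(genes$tss),
             "genes must come from readGenes()/makeGenes()")
  chrom <- as.character(GenomicRanges::seqnames(genes))
  assigned <- rep(NA_character_, length(genes))

  pointAssign <- function(pos, todo) {
    pts <- GenomicRanges::GRanges(chrom[todo],
                                  IRanges::IRanges(pos[todo], pos[todo]))
    ov <- GenomicRanges::findOverlaps(pts, domains, ignore.strand = TRUE)
    hit <- rep(NA_integer_, sum(todo))
    hit[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    hit
  }

  todo <- rep(TRUE, length(genes))
  hit <- pointAssign(genes$tss, todo)
  assigned[todo][!is.na(hit)] <- names(domains)[hit[!is.na(hit)]]
  # fallback: TSS in a gap, 3' end inside a domain
  todo <- is.na(assigned)
  if (any(todo)) {
    hit <- pointAssign(genes$gene_end, todo)
    assigned[todo][!is.na(hit)] <- names(domains)[hit[!is.na(hit)]]
  }

  keep <- !is.na(assigned)
  ord <- order(assigned[keep], genes$tss[keep], names(genes)[keep])
  ids <- names(genes)[keep][ord]
  doms <- assigned[keep][ord]
  map <- split(ids, factor(doms, levels = unique(doms)))
  map <- map[order(match(names(map), names(domains)))]
  attr(map, "unassigned") <- names(genes)[!keep]
  map
}

#' Filter domains by gene count
#'
#' Retains domains with at least \code{minGenes} member genes and no more than
#' the \code{maxGenesQuantile} quantile of the pre-filter gene-count
#' distribution (a dataset-specific cap on unusually gene-dense domains).
#'
#' @param map domain-to-gene list from \code{\link{assignGenesToDomains}}.
#' @param minGenes minimum member genes (default 3).
#' @param maxGenesQuantile quantile of the observed gene counts used as the
#'   upper cap (default 0.99; empirical quantile of the count distribution,
#'   so the cap is always an observed count).
#' @return the filtered map (same structure, attribute "unassigned" preserved).
#' @export
filterDomains <- function(map, minGenes = 3, maxGenesQuantile = 0.99) {
  assertThat(length(map) > 0, "domain-gene map is empty")
  counts <- lengths(map)
  cap <- as.numeric(quantile(counts, maxGenesQuantile, type = 1))
  keep <- counts >= minGenes & counts <= cap
  if (!any(keep)) chromdaValidationError("no testable domains after filtering")
  out <- map[keep]
  attr(out, "unassigned") <- attr(map, "unassigned")
  out
}

#' Filter genes by read coverage
#'
#' Keeps a gene iff at least \code{minSampleFrac} of the samples have at least
#' \code{minReads} reads, the standard low-expression filter for count-like
#' RNA-seq matrices.
#'
#' @param ds expression \link[SummarizedExperiment]{SummarizedExperiment}.
#' @param minReads minimum per-sample value (default 5).
#' @param minSampleFrac minimum fraction of samples at or above
#'   \code{minReads} (default 0.80).
#' @return the filtered SummarizedExperiment.
#' @export
filterGenesByCoverage <- function(ds, minReads = 5, minSampleFrac = 0.80) {
  m <- exprValues(ds)
  keep <- rowMeans(m >= minReads) >= minSampleFrac
  ds[keep, ]
}

#' Upper-quartile normalization
#'
#' Divides each sample by its (nonzero) 75th percentile and multiplies by a
#' constant, putting libraries of different depth on a common scale.
#'
#' @param ds expression SummarizedExperiment.
#' @param scale multiplier after division (default 1000).
#' @return SummarizedExperiment with normalized \code{"values"} assay.
#' @export
upperQuartileNormalize <- function(ds, scale = 1000) {
  m <- exprValues(ds)
  uq <- apply(m, 2, function(x) quantile(x[x > 0], 0.75, names = FALSE))
  assertThat(all(is.finite(uq)) && all(uq > 0),
             "a sample has no positive values; cannot upper-quartile normalize")
  m2 <- sweep(m, 2, uq, "/") * scale
  SummarizedExperiment::assay(ds, "values") <- m2
  ds
}

#' Quantile normalization (rank-mean)
#'
#' Forces every sample to share one value distribution: the reference
#' distribution is the row mean of the column-sorted matrix; each sample's
#' values are replaced by the reference value of their rank, with ties
#' receiving the mean of their tied reference values.
#'
#' @param x numeric matrix (genes x samples) or an expression
#'   SummarizedExperiment.
#' @return same type as the input, quantile-normalized.
#' @export
quantileNormalize <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "values") <-
      quantileNormalize(exprValues(x))
    return(x)
  }
  assertThat(is.matrix(x) && ncol(x) >= 2, "need a matrix with >= 2 columns")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    sx <- x[o, j]
    grp <- cumsum(c(TRUE, diff(sx) != 0))  # runs of tied values
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  out
}

#' Bin genes into equal-sized expression classes
#'
#' Builds the expression strata used by the gene-to-domain permutation nulls:
#' genes are ranked by a per-gene summary of expression level (mean TPM-like
#' value) and split into \code{nClasses} contiguous, equal-sized classes. Ties
#' are broken by gene id for determinism. Classes with fewer than 2 genes are
#' merged into their lower neighbor with a warning.
#'
#' @param classValues named numeric vector: per-gene expression summary.
#' @param nClasses number of classes (default 5; 1 disables stratification).
#' @return integer vector of class labels (1..nClasses), named by gene.
#' @export
expressionClasses <- function(classValues, nClasses = 5) {
  n <- length(classValues)
  assertThat(n >= 1, "no genes to classify")
  nClasses <- max(1L, min(as.integer(nClasses), n))
  ord <- order(classValues, names(classValues))
  cls <- integer(n)
  cls[ord] <- ceiling(seq_len(n) * nClasses / n)
  names(cls) <- names(classValues)
  # merge undersized classes (possible only for tiny inputs)
  repeat {
    tab <- table(factor(cls, levels = sort(unique(cls))))
    small <- names(tab)[tab < 2]
    if (length(small) == 0 || length(tab) == 1) break
    warning("expression class with < 2 genes merged with its neighbor")
    s <- as.integer(small[1])
    others <- setdiff(sort(unique(cls)), s)
    nb <- others[which.min(abs(others - s))]
    cls[cls == s] <- nb
  }
  cls
}
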