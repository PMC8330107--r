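#' @importFrom S4Vectors DataFrame
NULL

## Shared preparation for the FCC and differential-activity stages:
## coverage filter -> upper-quartile normalization -> gene-level fold-changes
## (moderated by default) -> quantile-normalized log values for correlations
## -> gene-to-domain assignment -> domain size filter -> expression classes.
prepareActivityInputs <- function(ds, domains, genes,
                        countFilter = TRUE, minReads = 5, minSampleFrac = 0.80,
                        uqNormalize = TRUE, uqScale = 1000,
                        minGenes = 3, maxGenesQuantile = 0.99,
                        lfcMode = c("moderated", "mean"), pseudocount = 1,
                        classValues = NULL, nClasses = 5,
                        flipConditions = FALSE) {
  lfcMode <- match.arg(lfcMode)
  if (flipConditions) {
    cond <- exprCondition(ds)
    SummarizedExperiment::colData(ds)$condition <-
      factor(cond, levels = rev(levels(cond)))
  }
  if (countFilter) ds <- filterGenesByCoverage(ds, minReads, minSampleFrac)
  assertThat(nrow(ds) > 0, "no genes left after the coverage filter")
  dsn <- if (uqNormalize) upperQuartileNormalize(ds, scale = uqScale) else ds

  de <- moderatedDETest(dsn, moderated = (lfcMode == "moderated"))
  lfc <- if (lfcMode == "moderated") {
    structure(de$lfc, names = de$gene_id)
  } else {
    computeLfc(dsn, pseudocount = pseudocount)
  }

  logm <- log2(exprValues(dsn) + 1)
  qnorm <- quantileNormalize(logm)

  map <- assignGenesToDomains(genes, domains)
  # restrict to genes actually measured
  measured <- rownames(dsn)
  map <- lapply(map, function(g) g[g %in% measured])
  map <- map[lengths(map) > 0]
  assertThat(length(map) > 0, "no domain contains any measured gene")
  map <- filterDomains(map, minGenes = minGenes,
                       maxGenesQuantile = maxGenesQuantile)

  if (is.null(classValues)) classValues <- rowMeans(exprValues(dsn))
  list(ds = dsn, de = de, lfc = lfc, qnorm = qnorm, map = map,
       domains = validateDomains(domains), classValues = classValues,
       nClasses = nClasses)
}

#' Mean fold-change (mFC) per domain
#'
#' Arithmetic mean of the member genes' log2 fold-changes. Domains with no
#' gene in \code{lfc} are dropped with a warning.
#'
#' @param lfc named per-gene log2 fold-changes.
#' @param map domain-to-gene list.
#' @return named numeric vector of per-domain mFC.
#' @export
domainMFC <- function(lfc, map) {
  has <- vapply(map, function(g) sum(g %in% names(lfc)) > 0, logical(1))
  if (!all(has)) {
    warning(sum(!has), " domain(s) without fold-change information excluded")
    map <- map[has]
  }
  vapply(map, function(g) mean(lfc[g[g %in% names(lfc)]]), numeric(1))
}

#' Mean pairwise expression correlation (mCor) per domain
#'
#' Mean Pearson correlation across all samples (both conditions pooled) over
#' all unordered pairs of member genes, computed on quantile-normalized
#' values. Pairs involving a zero-variance gene are undefined and skipped.
#'
#' @param qnormValues quantile-normalized genes x samples matrix.
#' @param map domain-to-gene list.
#' @return named numeric vector of per-domain mCor (NA if no defined pair).
#' @export
domainMCor <- function(qnormValues, map) {
  assertThat(ncol(qnormValues) >= 3, "mCor needs >= 3 samples")
  vapply(map, function(g) {
    g <- g[g %in% rownames(qnormValues)]
    if (length(g) < 2) return(NA_real_)
    sub <- qnormValues[g, , drop = FALSE]
    C <- suppressWarnings(cor(t(sub)))
    vals <- C[upper.tri(C)]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Empirical p values for mFC via gene-to-domain permutations
#'
#' Gene-to-domain assignments are permuted within expression classes; the
#' two-sided empirical p value of each domain is
#' (1 + #\{permutations with |mFC_perm| >= |mFC_obs|\}) / (1 + nPerm), so p is
#' never 0 and lies on the grid \{i/(nPerm+1)\}.
#'
#' @param mfcObs named observed per-domain mFC (as from \code{domainMFC}).
#' @param lfc named per-gene log2 fold-changes.
#' @param map domain-to-gene list.
#' @param classValues named per-gene expression summary for the classes.
#' @param nPerm number of permutations.
#' @param nClasses number of expression classes (default 5).
#' @param seed integer seed.
#' @return named numeric vector of empirical p values in (0, 1].
#' @export
empiricalPMfc <- function(mfcObs, lfc, map, classValues, nPerm = 10000,
                          nClasses = 5, seed = 1) {
  if (nPerm < 100) {
    warning("fewer than 100 permutations: p-value resolution floor is ",
            format(1 / (nPerm + 1), digits = 3))
  }
  genes <- unlist(map, use.names = FALSE)
  dom <- factor(rep(names(map), lengths(map)), levels = names(map))
  v <- unname(lfc[genes])
  sizes <- lengths(map)
  cls <- expressionClasses(classValues[genes], nClasses)
  absObs <- abs(mfcObs[names(map)])
  cnt <- integer(length(map))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- permuteWithinClasses(cls)
      mfcPerm <- rowsum(v[perm], dom)[, 1] / sizes
      cnt <- cnt + (abs(mfcPerm) >= absObs)
    }
  })
  p <- (1 + cnt) / (1 + nPerm)
  names(p) <- names(map)
  p
}

#' Build the cross-boundary correlation null
#'
#' For each domain D with k member genes, k genes are taken from the two
#' flanking domains (ceiling(k/2) from the left, floor(k/2) from the right,
#' closest to the boundary first; if one side runs short the other supplies
#' the remainder from that single adjacent domain). The mean of all k x
#' #flank cross-correlations (D gene vs flank gene) is recorded, and these
#' means are pooled over all domains into one null distribution for mCor.
#'
#' @param qnormValues quantile-normalized genes x samples matrix.
#' @param map domain-to-gene list (defines the tested domains and their genes).
#' @param domains domain GRanges (defines chromosome order and adjacency).
#' @param kPerSide if TRUE, take k genes from each side instead of k total.
#' @return numeric vector of pooled cross-boundary mean correlations, named by
#'   the contributing domain id; domains with no flanking genes are skipped.
#' @export
buildCrossBoundaryNull <- function(qnormValues, map, domains,
                                   kPerSide = FALSE) {
  domains <- domains[names(domains) %in% names(map)]
  domains <- GenomicRanges::sort(domains)
  chroms <- as.character(GenomicRanges::seqnames(domains))
  out <- numeric(0)
  for (ch in unique(chroms)) {
    ids <- names(domains)[chroms == ch]
    if (length(ids) < 2) next
    for (i in seq_along(ids)) {
      dGenes <- map[[ids[i]]]
      k <- length(dGenes)
      # closest-first flank candidates: left domain reversed, right in order
      leftPool <- if (i > 1) rev(map[[ids[i - 1]]]) else character(0)
      rightPool <- if (i < length(ids)) map[[ids[i + 1]]] else character(0)
      if (kPerSide) {
        flank <- c(head(leftPool, k), head(rightPool, k))
      } else {
        nL <- min(ceiling(k / 2), length(leftPool))
        nR <- min(k - nL, length(rightPool))
        # one side short: the other side supplies the remainder
        nL <- min(k - nR, length(leftPool))
        flank <- c(head(leftPool, nL), head(rightPool, nR))
      }
      if (length(flank) == 0) next
      C <- suppressWarnings(
        cor(t(qnormValues[dGenes, , drop = FALSE]),
            t(qnormValues[flank, , drop = FALSE]))
      )
      v <- mean(C, na.rm = TRUE)
      if (is.finite(v)) {
        names(v) <- ids[i]
        out <- c(out, v)
      }
    }
  }
  out
}

#' Empirical p value for mCor against the cross-boundary null
#'
#' One-sided: high within-domain correlation relative to cross-boundary
#' correlations is significant. p = (1 + #\{null >= mCor_obs\}) / (1 + #null).
#'
#' @param mcorObs observed per-domain mCor values (vectorized).
#' @param null pooled cross-boundary mean correlations from
#'   \code{\link{buildCrossBoundaryNull}}.
#' @return numeric p values in (0, 1], same names as \code{mcorObs}.
#' @export
empiricalPMcor <- function(mcorObs, null) {
  assertThat(length(null) > 0, "cross-boundary null is empty")
  vapply(mcorObs, function(x) {
    if (is.na(x)) return(NA_real_)
    (1 + sum(null >= x)) / (1 + length(null))
  }, numeric(1))
}

#' Stouffer combination of two one-sided p values
#'
#' z_i = qnorm(1 - p_i); p_comb = 1 - pnorm((z_1 + z_2)/sqrt(2)), clipped into
#' (0, 1].
#'
#' @param p1,p2 p values in (0, 1] (vectorized).
#' @return combined p values in (0, 1].
#' @export
stoufferCombine <- function(p1, p2) {
  assertThat(all(p1 > 0 & p1 <= 1, na.rm = TRUE) &&
               all(p2 > 0 & p2 <= 1, na.rm = TRUE),
             "p values must lie in (0, 1]")
  z <- (qnorm(1 - p1) + qnorm(1 - p2)) / sqrt(2)
  pmin(pmax(1 - pnorm(z), .Machine$double.xmin), 1)
}

#' Call differentially active chromatin domains
#'
#' The full per-domain pipeline: preprocessing and filters, gene-level
#' fold-changes, per-domain mFC and mCor, empirical p values from the
#' expression-stratified gene-to-domain permutation null (mFC, two-sided) and
#' the cross-boundary correlation null (mCor, one-sided), one-sided Stouffer
#' combination, Benjamini-Hochberg adjustment and significance flagging.
#'
#' @param ds expression SummarizedExperiment (count-like values).
#' @param domains domain GRanges.
#' @param genes gene GRanges.
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @param nPerm gene-to-domain permutations for the mFC null (default 10000).
#' @param nClasses expression classes for the permutations (default 5).
#' @param seed integer seed.
#' @param crossBoundaryNull optional precomputed pooled null (e.g. pooled over
#'   several datasets); defaults to the current dataset's own pool.
#' @param ... preprocessing options (see \code{\link{runFCC}}).
#' @return a \linkS4class{DomainActivityResult}; rows sorted by p_adj then
#'   p_comb.
#' @export
runDomainActivity <- function(ds, domains, genes, alpha = 0.01,
                              nPerm = 10000, nClasses = 5, seed = 1,
                              crossBoundaryNull = NULL, ...) {
  prep <- prepareActivityInputs(ds, domains, genes, nClasses = nClasses, ...)
  seeds <- stageSeeds(seed, 2)
  mfc <- domainMFC(prep$lfc, prep$map)
  mcor <- domainMCor(prep$qnorm, prep$map)
  pMfc <- empiricalPMfc(mfc, prep$lfc, prep$map, prep$classValues,
                        nPerm = nPerm, nClasses = nClasses, seed = seeds[1])
  if (is.null(crossBoundaryNull)) {
    crossBoundaryNull <- buildCrossBoundaryNull(prep$qnorm, prep$map,
                                                prep$domains)
  }
  pMcor <- empiricalPMcor(mcor, crossBoundaryNull)
  keep <- !is.na(mcor)
  if (!all(keep)) {
    warning(sum(!keep), " domain(s) with undefined mCor ",
            "(all member pairs zero-variance) excluded")
    prep$map <- prep$map[keep]
    mfc <- mfc[keep]; mcor <- mcor[keep]
    pMfc <- pMfc[keep]; pMcor <- pMcor[keep]
  }
  pComb <- stoufferCombine(pMfc, pMcor)
  pAdj <- bhAdjust(pComb)
  dom <- prep$domains[names(prep$map)]
  tab <- S4Vectors::DataFrame(
    domain_id = names(prep$map),
    chrom = as.character(GenomicRanges::seqnames(dom)),
    start = GenomicRanges::start(dom),
    end = GenomicRanges::end(dom),
    n_genes = unname(lengths(prep$map)),
    mfc = unname(mfc),
    mcor = unname(mcor),
    p_mfc = unname(pMfc),
    p_mcor = unname(pMcor),
    p_comb = unname(pComb),
    p_adj = unname(pAdj),
    direction = sign(unname(mfc)),
    significant = unname(pAdj) <= alpha
  )
  tab <- tab[order(tab$p_adj, tab$p_comb), ]
  new("DomainActivityResult",
      table = tab, alpha = alpha,
      crossBoundaryNull = unname(crossBoundaryNull),
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      params = list(nClasses = nClasses))
}
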