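#' Artificial cross-boundary domain partition
#'
#' Builds, per chromosome, artificial domains spanning from the midpoint of
#' each real domain to the midpoint of the next, so that every artificial
#' domain straddles exactly one real boundary. Used as a negative control: if
#' boundaries matter, differential activity should drop on this partition.
#' When \code{genes} is supplied, artificial domains whose assigned genes all
#' originate from a single real domain are excluded (their gene content is
#' indistinguishable from a real domain's).
#'
#' @param domains real domain GRanges.
#' @param genes optional gene GRanges enabling the single-origin exclusion.
#' @return GRanges of artificial domains named \code{A0001...}, with metadata
#'   column \code{boundary} (the real boundary position straddled).
#' @export
artificialPartition <- function(domains, genes = NULL) {
  domains <- validateDomains(domains)
  chroms <- as.character(GenomicRanges::seqnames(domains))
  parts <- list()
  for (ch in unique(chroms)) {
    d <- domains[chroms == ch]
    if (length(d) < 2) next
    mid <- GenomicRanges::start(d) + floor(GenomicRanges::width(d) / 2)
    n <- length(d)
    parts[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(mid[-n], mid[-1] - 1L),
      boundary = GenomicRanges::end(d)[-n]
    )
  }
  assertThat(length(parts) > 0,
             "no chromosome has >= 2 domains; no artificial partition")
  art <- suppressWarnings(do.call(c, unname(parts)))
  names(art) <- sprintf("A%04d", seq_along(art))
  if (!is.null(genes)) {
    amap <- assignGenesToDomains(genes, art)
    rmap <- assignGenesToDomains(genes, domains)
    geneToReal <- structure(rep(names(rmap), lengths(rmap)),
                            names = unlist(rmap, use.names = FALSE))
    mixed <- vapply(amap, function(g) {
      origins <- unique(geneToReal[g])
      origins <- origins[!is.na(origins)]
      length(origins) >= 2
    }, logical(1))
    keepIds <- names(amap)[mixed]
    art <- art[names(art) %in% keepIds]
  }
  art
}

#' Fraction of shared domain boundaries between two partitions
#'
#' Boundaries are binned at \code{binSize}; a boundary of partition A is
#' shared if partition B (same chromosome) has a boundary of the same kind
#' (start or end) within \code{toleranceBins} bins. Start and end boundaries
#' are matched separately and the final ratio is the mean of the two shares.
#'
#' @param domainsA,domainsB domain GRanges.
#' @param binSize bin size in bp (default 40000).
#' @param toleranceBins tolerance radius in bins (default 2, i.e. 80 kb).
#' @return fraction in [0, 1].
#' @export
sharedBoundaryRatio <- function(domainsA, domainsB, binSize = 40000,
                                toleranceBins = 2) {
  assertThat(length(domainsA) > 0 && length(domainsB) > 0,
             "both partitions must be non-empty")
  binsOf <- function(d, what) {
    pos <- if (what == "start") GenomicRanges::start(d) else
      GenomicRanges::end(d)
    split(floor(pos / binSize), as.character(GenomicRanges::seqnames(d)))
  }
  shareOf <- function(what) {
    a <- binsOf(domainsA, what)
    b <- binsOf(domainsB, what)
    hits <- 0L; total <- 0L
    for (ch in names(a)) {
      qa <- a[[ch]]
      qb <- b[[ch]]
      total <- total + length(qa)
      if (is.null(qb)) next
      hits <- hits + sum(vapply(qa, function(x)
        any(abs(qb - x) <= toleranceBins), logical(1)))
    }
    hits / total
  }
  mean(c(shareOf("start"), shareOf("end")))
}

#' Flag immune domains by tumor-purity correlation
#'
#' For every gene, the Pearson correlation between log10(expression + 1) and
#' per-sample tumor purity is computed across samples; correlations are
#' averaged per domain. Domains at or below the 0.05-quantile of the
#' reference (non-significant) domains' averages are flagged: strongly
#' negative purity correlation marks expression driven by non-tumor
#' (immune/stromal) infiltration rather than tumor-cell chromatin state.
#'
#' @param ds expression SummarizedExperiment (TPM-like values recommended).
#' @param map domain-to-gene list.
#' @param purity named per-sample purity vector; samples without purity are
#'   dropped (at least 80\% of samples must have purity).
#' @param quantileCut reference quantile defining the threshold (default 0.05).
#' @param reference character vector of domain ids to derive the threshold
#'   from (typically the non-significant domains); defaults to all domains.
#' @return data.frame with domain_id, purity_cor (domain average) and
#'   immune (logical flag); the threshold is in \code{attr(, "threshold")}.
#' @export
flagImmuneDomains <- function(ds, map, purity, quantileCut = 0.05,
                              reference = NULL) {
  m <- exprValues(ds)
  common <- intersect(colnames(m), names(purity))
  assertThat(length(common) / ncol(m) >= 0.80,
             "purity available for fewer than 80% of samples")
  pv <- purity[common]
  assertThat(sd(pv) > 0, "purity vector is constant")
  lm10 <- log10(m[, common, drop = FALSE] + 1)
  geneCor <- suppressWarnings(as.numeric(cor(t(lm10), pv)))
  names(geneCor) <- rownames(m)
  domCor <- vapply(map, function(g) {
    v <- geneCor[g[g %in% names(geneCor)]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (is.null(reference)) reference <- names(map)
  refVals <- domCor[names(domCor) %in% reference]
  refVals <- refVals[is.finite(refVals)]
  assertThat(length(refVals) > 0, "no reference domains with defined purity correlation")
  thr <- as.numeric(quantile(refVals, quantileCut, type = 7))
  out <- data.frame(domain_id = names(domCor),
                    purity_cor = unname(domCor),
                    immune = !is.na(domCor) & domCor <= thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

## Observed co-domain edge count for a gene set: sum over qualifying domains
## (>= minAnnotFrac of member genes in the set) of C(k, 2) where k is the
## number of set genes in the domain.
familyEdges <- function(map, members, minAnnotFrac = 0.5) {
  sum(vapply(map, function(g) {
    k <- sum(g %in% members)
    if (k >= 2 && k / length(g) >= minAnnotFrac) k * (k - 1) / 2 else 0
  }, numeric(1)))
}

#' Gene-family co-domain network enrichment
#'
#' For each gene family, genes are connected if they share a domain (on
#' domains where at least half the member genes belong to the family); the
#' observed edge count is compared with the mean over resamples in which each
#' contiguous cluster of family genes is replaced by an equally sized cluster
#' of contiguous annotated genes on the same chromosome (re-drawn whenever 80\%
#' or more of the sampled genes belong to one family). An observed/expected
#' ratio well above 1 means family members co-locate in domains beyond what
#' genomic contiguity alone explains.
#'
#' @param map domain-to-gene list.
#' @param genes gene GRanges (defines chromosome and TSS order).
#' @param families named character vector gene_id -> family (first-level).
#' @param nPerm number of resamples (default 100).
#' @param seed integer seed.
#' @param minAnnotFrac minimum fraction of a domain's genes annotated to the
#'   family for the domain to qualify (default 0.5).
#' @return data.frame with family, n_genes, observed_edges, expected_edges.
#' @export
familyNetworkEnrichment <- function(map, genes, families, nPerm = 100,
                                    seed = 1, minAnnotFrac = 0.5) {
  placed <- unlist(map, use.names = FALSE)
  families <- families[names(families) %in% names(genes)]
  # annotated genes in TSS order per chromosome
  ann <- names(families)
  gsub <- genes[ann]
  ord <- order(as.character(GenomicRanges::seqnames(gsub)), gsub$tss, ann)
  annOrd <- ann[ord]
  annChrom <- as.character(GenomicRanges::seqnames(gsub))[ord]
  famOf <- families[annOrd]

  famList <- unique(families)
  rows <- list()
  withSeed(seed, {
    for (fam in famList) {
      members <- names(families)[families == fam]
      if (sum(members %in% placed) < 2) next
      obs <- familyEdges(map, members, minAnnotFrac)
      # contiguous clusters of this family in the annotated gene order
      isFam <- famOf == fam
      runs <- rle(isFam)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      clusters <- Map(seq, starts[runs$values], ends[runs$values])
      expSum <- 0
      for (b in seq_len(nPerm)) {
        sampled <- character(0)
        for (cl in clusters) {
          ch <- annChrom[cl[1]]
          pool <- which(annChrom == ch)
          k <- length(cl)
          if (length(pool) < k) { sampled <- c(sampled, annOrd[cl]); next }
          for (tryi in 1:50) {
            s <- sample(length(pool) - k + 1, 1)
            win <- pool[s:(s + k - 1)]
            # reject windows dominated by a single family
            if (max(table(famOf[win])) / k < 0.8) break
          }
          sampled <- c(sampled, annOrd[win])
        }
        expSum <- expSum + familyEdges(map, unique(sampled), minAnnotFrac)
      }
      rows[[fam]] <- data.frame(family = fam,
                                n_genes = length(members),
                                observed_edges = obs,
                                expected_edges = expSum / nPerm,
                                stringsAsFactors = FALSE)
    }
  })
  if (length(rows) == 0) {
    return(data.frame(family = character(0), n_genes = integer(0),
                      observed_edges = numeric(0),
                      expected_edges = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Conserved differentially active regions across datasets
#'
#' Significant domains from several datasets are matched all-vs-all at
#' reciprocal base-pair overlap >= \code{overlapFrac}; connected sets of
#' matching domains define candidate conserved regions (span: smallest start
#' to largest end). Regions keeping at least \code{minGenes} genes at the
#' intersection of the matching domains are retained, and regions sharing at
#' least \code{mergeGeneFrac} of their intersect genes are merged.
#'
#' @param significantSets named list (one entry per dataset) of significant
#'   domain GRanges.
#' @param genes gene GRanges (TSS-based membership for the intersections).
#' @param overlapFrac minimum reciprocal overlap (default 0.80).
#' @param minGenes minimum intersect gene count (default 3).
#' @param mergeGeneFrac gene-sharing fraction triggering a merge (default 0.80).
#' @return data.frame with chrom, start, end, n_datasets, n_genes, genes
#'   (comma-separated), one row per conserved region.
#' @export
conservedRegions <- function(significantSets, genes, overlapFrac = 0.80,
                             minGenes = 3, mergeGeneFrac = 0.80) {
  assertThat(length(significantSets) >= 2, "need >= 2 datasets")
  all <- list()
  for (dsName in names(significantSets)) {
    g <- significantSets[[dsName]]
    if (length(g) == 0) next
    g$dataset <- dsName
    all[[dsName]] <- g
  }
  pool <- do.call(c, unname(all))
  if (is.null(pool) || length(pool) < 2) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_datasets = integer(0),
                      n_genes = integer(0), genes = character(0)))
  }
  ov <- GenomicRanges::findOverlaps(pool, drop.self = TRUE,
                                    drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(pool[qh], pool[sh]))
  recip <- inter / GenomicRanges::width(pool[qh]) >= overlapFrac &
    inter / GenomicRanges::width(pool[sh]) >= overlapFrac
  # keep only cross-dataset matches
  recip <- recip & pool$dataset[qh] != pool$dataset[sh]
  qh <- qh[recip]; sh <- sh[recip]
  if (length(qh) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_datasets = integer(0),
                      n_genes = integer(0), genes = character(0)))
  }
  # connected components via union-find
  parent <- seq_along(pool)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_along(qh)) {
    a <- find(qh[e]); b <- find(sh[e])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(pool), find, integer(1))
  tss <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(genes)),
                                IRanges::IRanges(genes$tss, genes$tss))
  names(tss) <- names(genes)
  regions <- list()
  for (cid in unique(comp[comp %in% comp[duplicated(comp)]])) {
    idx <- which(comp == cid)
    if (length(idx) < 2) next
    members <- pool[idx]
    # intersect genes: TSS inside every matched domain
    sets <- lapply(seq_along(members), function(i) {
      hit <- GenomicRanges::findOverlaps(tss, members[i])
      names(tss)[S4Vectors::queryHits(hit)]
    })
    interGenes <- Reduce(intersect, sets)
    if (length(interGenes) < minGenes) next
    regions[[length(regions) + 1]] <- list(
      chrom = as.character(GenomicRanges::seqnames(members))[1],
      start = min(GenomicRanges::start(members)),
      end = max(GenomicRanges::end(members)),
      datasets = unique(members$dataset),
      genes = sort(interGenes)
    )
  }
  # merge regions sharing >= mergeGeneFrac of intersect genes
  merged <- TRUE
  while (merged && length(regions) > 1) {
    merged <- FALSE
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (j <= i) next
        a <- regions[[i]]; b <- regions[[j]]
        if (a$chrom != b$chrom) next
        shared <- length(intersect(a$genes, b$genes)) /
          min(length(a$genes), length(b$genes))
        if (shared >= mergeGeneFrac) {
          regions[[i]] <- list(chrom = a$chrom,
                               start = min(a$start, b$start),
                               end = max(a$end, b$end),
                               datasets = union(a$datasets, b$datasets),
                               genes = sort(union(a$genes, b$genes)))
          regions[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  if (length(regions) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_datasets = integer(0),
                      n_genes = integer(0), genes = character(0)))
  }
  data.frame(
    chrom = vapply(regions, `[[`, character(1), "chrom"),
    start = vapply(regions, `[[`, numeric(1), "start"),
    end = vapply(regions, `[[`, numeric(1), "end"),
    n_datasets = vapply(regions, function(r) length(r$datasets), integer(1)),
    n_genes = vapply(regions, function(r) length(r$genes), integer(1)),
    genes = vapply(regions, function(r) paste(r$genes, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE
  )
}
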