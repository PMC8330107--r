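#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the data the pipeline consumes: a domain partition,
#' genes with TSSs inside domains, a count-like expression matrix for two
#' conditions, per-sample purity, and planted structure (differentially
#' active domains with a shared latent factor, immune domains coupled to
#' purity).
#'
#' @param nChrom number of chromosomes.
#' @param domainsPerChrom domains per chromosome.
#' @param genesPerDomain integer range (min, max) of genes per domain.
#' @param samplesPerCondition samples in each of the two conditions.
#' @param plantedActiveDomains number of differentially active domains to
#'   plant (half up, half down).
#' @param effectLfc log2 expression shift of planted domains in condition 2.
#' @param intraDomainRho latent-factor correlation among genes of a planted
#'   domain (0 <= rho < 1).
#' @param immuneDomains number of domains whose genes are negatively coupled
#'   to purity.
#' @param immuneCoupling strength of the purity coupling (log-scale slope).
#' @param noiseSd per-gene log-scale noise standard deviation.
#' @param baselineLogMean,baselineLogSd log-scale distribution of per-gene
#'   baseline expression.
#' @param domainWidth domain width in bp.
#' @param seed integer seed; recorded in every output.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nChrom = 4, domainsPerChrom = 50,
                      genesPerDomain = c(3, 8), samplesPerCondition = 30,
                      plantedActiveDomains = 0, effectLfc = 1,
                      intraDomainRho = 0.5, immuneDomains = 0,
                      immuneCoupling = 1.5, noiseSd = 0.5,
                      baselineLogMean = log(100), baselineLogSd = 1,
                      domainWidth = 400000, seed = 1) {
  cfg <- list(nChrom = as.integer(nChrom),
              domainsPerChrom = as.integer(domainsPerChrom),
              genesPerDomain = as.integer(genesPerDomain),
              samplesPerCondition = as.integer(samplesPerCondition),
              plantedActiveDomains = as.integer(plantedActiveDomains),
              effectLfc = effectLfc,
              intraDomainRho = intraDomainRho,
              immuneDomains = as.integer(immuneDomains),
              immuneCoupling = immuneCoupling,
              noiseSd = noiseSd,
              baselineLogMean = baselineLogMean,
              baselineLogSd = baselineLogSd,
              domainWidth = as.integer(domainWidth),
              seed = as.integer(seed))
  assertThat(cfg$nChrom >= 1 && cfg$domainsPerChrom >= 1 &&
               cfg$samplesPerCondition >= 2, "counts must be >= 1 (samples >= 2)")
  assertThat(length(cfg$genesPerDomain) == 2 &&
               cfg$genesPerDomain[1] >= 1 &&
               cfg$genesPerDomain[1] <= cfg$genesPerDomain[2],
             "genesPerDomain must be an increasing pair")
  assertThat(cfg$intraDomainRho >= 0 && cfg$intraDomainRho < 1,
             "intraDomainRho must be in [0, 1)")
  nDom <- cfg$nChrom * cfg$domainsPerChrom
  assertThat(cfg$plantedActiveDomains + cfg$immuneDomains <= nDom,
             "more planted domains than domains")
  maxGenes <- cfg$genesPerDomain[2]
  assertThat(cfg$domainWidth >= 2 * maxGenes * 100,
             "infeasible geometry: genes do not fit in the domains")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a full synthetic dataset with planted structure
#'
#' Expression is log-normal: log(x) = baseline + condition effect (planted
#' domains only) + sqrt(rho) * latent domain factor + sqrt(1-rho) * gene
#' noise, then exponentiated and rounded to a count-like scale. Planted
#' active domains shift all member genes by effectLfc (log2) in condition 2
#' and share a latent factor inducing the target intra-domain correlation;
#' immune domains couple member genes negatively to a per-sample purity
#' covariate.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return list with \code{domains} (GRanges), \code{genes} (GRanges),
#'   \code{ds} (expression SummarizedExperiment), \code{purity} (named
#'   vector) and \code{truth} (data.frame: domain_id, type, effect).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(cfg$seed, {
    w <- cfg$domainWidth
    nDom <- cfg$nChrom * cfg$domainsPerChrom
    chrom <- rep(paste0("chr", seq_len(cfg$nChrom)), each = cfg$domainsPerChrom)
    idxIn <- rep(seq_len(cfg$domainsPerChrom), cfg$nChrom)
    startBed <- (idxIn - 1) * w          # 0-based
    domains <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(startBed + 1, startBed + w))
    names(domains) <- sprintf("D%04d", seq_len(nDom))

    sizeRange <- seq(cfg$genesPerDomain[1], cfg$genesPerDomain[2])
    nGenes <- sizeRange[sample.int(length(sizeRange), nDom, replace = TRUE)]
    geneRows <- list()
    gi <- 0
    for (d in seq_len(nDom)) {
      k <- nGenes[d]
      pos <- sort(sample(seq(startBed[d] + 2500, startBed[d] + w - 3000),
                         k))
      for (j in seq_len(k)) {
        gi <- gi + 1
        strand <- sample(c("+", "-"), 1)
        len <- sample(500:2000, 1)
        s1 <- if (strand == "+") pos[j] else pos[j] - len + 1
        e1 <- s1 + len - 1
        geneRows[[gi]] <- data.frame(
          gene_id = sprintf("G%05d", gi), chrom = chrom[d], strand = strand,
          start1 = s1, end1 = e1, domain = names(domains)[d],
          stringsAsFactors = FALSE)
      }
    }
    gdf <- do.call(rbind, geneRows)
    genes <- makeGenes(gdf$gene_id, gdf$chrom, gdf$strand, gdf$start1, gdf$end1)

    # planted structure
    planted <- sample(nDom, cfg$plantedActiveDomains + cfg$immuneDomains)
    activeIds <- planted[seq_len(cfg$plantedActiveDomains)]
    immuneIds <- setdiff(planted, activeIds)
    dirUp <- rep(c(TRUE, FALSE), length.out = length(activeIds))

    nS <- 2 * cfg$samplesPerCondition
    cond <- rep(c("cond1", "cond2"), each = cfg$samplesPerCondition)
    samples <- sprintf("S%03d", seq_len(nS))
    purity <- round(runif(nS, 0.3, 0.95), 3)
    names(purity) <- samples

    G <- nrow(gdf)
    base <- rnorm(G, cfg$baselineLogMean, cfg$baselineLogSd)
    logx <- matrix(rep(base, nS), nrow = G)
    rho <- cfg$intraDomainRho
    for (d in seq_len(nDom)) {
      rows <- which(gdf$domain == names(domains)[d])
      isActive <- d %in% activeIds
      isImmune <- d %in% immuneIds
      if (isActive && rho > 0) {
        f <- rnorm(nS)  # shared latent factor
        eps <- matrix(rnorm(length(rows) * nS), nrow = length(rows))
        z <- sqrt(rho) * matrix(rep(f, each = length(rows)),
                                nrow = length(rows)) + sqrt(1 - rho) * eps
      } else {
        z <- matrix(rnorm(length(rows) * nS), nrow = length(rows))
      }
      logx[rows, ] <- logx[rows, ] + cfg$noiseSd * z
      if (isActive) {
        shift <- cfg$effectLfc * log(2) *
          if (dirUp[match(d, activeIds)]) 1 else -1
        logx[rows, cond == "cond2"] <- logx[rows, cond == "cond2"] + shift
      }
      if (isImmune) {
        pc <- scale(purity)[, 1]
        logx[rows, ] <- logx[rows, ] -
          cfg$immuneCoupling * matrix(rep(pc, each = length(rows)),
                                      nrow = length(rows))
      }
    }
    values <- round(exp(logx))
    rownames(values) <- gdf$gene_id
    colnames(values) <- samples
    ds <- ExpressionData(values, cond)

    type <- rep("null", nDom)
    type[activeIds] <- ifelse(dirUp, "active_up", "active_down")
    type[immuneIds] <- "immune"
    effect <- rep(0, nDom)
    effect[activeIds] <- cfg$effectLfc * ifelse(dirUp, 1, -1)
    truth <- data.frame(domain_id = names(domains), type = type,
                        effect = effect, stringsAsFactors = FALSE)
    list(domains = domains, genes = genes, ds = ds, purity = purity,
         truth = truth, seed = cfg$seed)
  })
}

#' Write a simulated dataset bundle in the pipeline's input formats
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if missing).
#' @return named character vector of the written file paths.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(domains = file.path(dir, "domains.bed"),
             genes = file.path(dir, "genes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             purity = file.path(dir, "purity.tsv"),
             truth = file.path(dir, "truth.tsv"))
  d <- sim$domains
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(d)),
                    start = GenomicRanges::start(d) - 1L,  # 1-based -> BED
                    end = GenomicRanges::end(d),
                    name = names(d))
  write.table(bed, paths["domains"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- sim$genes
  writeTsv(data.frame(gene_id = names(g),
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      strand = as.character(GenomicRanges::strand(g)),
                      start = GenomicRanges::start(g) - 1L,
                      end = GenomicRanges::end(g)),
           paths["genes"])
  m <- exprValues(sim$ds)
  writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
           paths["expression"])
  writeTsv(data.frame(sample = colnames(m),
                      condition = as.character(exprCondition(sim$ds))),
           paths["conditions"])
  writeTsv(data.frame(sample = names(sim$purity), purity = sim$purity),
           paths["purity"])
  writeTsv(sim$truth, paths["truth"])
  paths
}

#' Simulate a pair of interaction-strength matrices
#'
#' Both conditions share a distance-decay baseline strength with independent
#' symmetric noise of equal variance at every pixel; planted blocks add extra
#' strength to intra-block pixels of one condition (gain in condition 1).
#' The baseline carries a positive floor so the additive noise never
#' truncates at zero and per-pixel strength differences stay exchangeable
#' between the two conditions.
#'
#' @param nBins matrix dimension.
#' @param binSize bin size in bp (default 40000).
#' @param chrom chromosome name.
#' @param gainBlocks list of integer bin ranges (e.g.
#'   \code{list(c(10, 20))}) gaining strength in condition 1.
#' @param gainStrength added -log10(p) inside gain blocks (default 2).
#' @param noiseSd per-pixel noise sd (default 0.3).
#' @param decayScale distance-decay scale in bins (default 20).
#' @param baseFloor minimum baseline strength (default 1.5), keeping
#'   baseline + noise away from the zero truncation.
#' @param seed integer seed.
#' @return list with \code{m1}, \code{m2} (\linkS4class{InteractionMatrix})
#'   and \code{truth} (data.frame of planted blocks).
#' @export
simulateInteractionPair <- function(nBins = 100, binSize = 40000,
                                    chrom = "chr1", gainBlocks = list(),
                                    gainStrength = 2, noiseSd = 0.3,
                                    decayScale = 20, baseFloor = 1.5,
                                    seed = 1) {
  withSeed(seed, {
    sep <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
    baseS <- 3 * exp(-sep / decayScale) + baseFloor
    noise <- function() {
      e <- matrix(rnorm(nBins^2, sd = noiseSd), nBins)
      s <- (e + t(e)) / sqrt(2)  # symmetric, per-pixel sd = noiseSd
      diag(s) <- rnorm(nBins, sd = noiseSd)
      s
    }
    S1 <- baseS + noise()
    S2 <- baseS + noise()
    for (blk in gainBlocks) {
      idx <- seq(blk[1], blk[2])
      S1[idx, idx] <- S1[idx, idx] + gainStrength
    }
    S1 <- pmax(S1, 0); S2 <- pmax(S2, 0)
    truth <- if (length(gainBlocks)) {
      data.frame(block_start = vapply(gainBlocks, `[`, numeric(1), 1),
                 block_end = vapply(gainBlocks, `[`, numeric(1), 2),
                 gain = gainStrength)
    } else {
      data.frame(block_start = numeric(0), block_end = numeric(0),
                 gain = numeric(0))
    }
    list(m1 = InteractionMatrix(S1, chrom, binSize),
         m2 = InteractionMatrix(S2, chrom, binSize),
         truth = truth, seed = seed)
  })
}
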