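#' Fold-change concordance (FCC) score of one domain
#'
#' The FCC of a domain with member log2 fold-changes lfc_1..lfc_n is the
#' product of a sign-balance term, (2/n) * #\{lfc_i < 0\} - 1, and a
#' magnitude-balance term, 2 * sum(|lfc_i| over negatives)/sum(|lfc_i|) - 1.
#' It is 1 when all genes change in the same direction, near 0 when signs and
#' magnitudes show no concordance, and near -1 when most genes agree but the
#' few discordant ones carry much larger absolute fold-changes.
#'
#' Genes with lfc exactly 0 carry no sign and are excluded; a domain whose
#' informative set is empty gets FCC = 0 with attribute \code{degenerate}.
#'
#' @param lfc numeric vector of member-gene log2 fold-changes.
#' @return a single numeric in [-1, 1].
#' @examples
#' fccScore(c(1.2, 0.3, 2.0))   # full concordance: 1
#' fccScore(c(2, 0.5, -1, -3))  # balanced signs: 0
#' @export
fccScore <- function(lfc) {
  lfc <- lfc[is.finite(lfc)]
  assertThat(length(lfc) >= 1, "fccScore needs at least one finite value")
  lfc <- lfc[lfc != 0]
  if (length(lfc) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n <- length(lfc)
  neg <- lfc < 0
  signBal <- 2 * sum(neg) / n - 1
  magBal <- 2 * sum(abs(lfc)[neg]) / sum(abs(lfc)) - 1
  signBal * magBal
}

## Vectorized FCC over many domains: lfc is the per-slot fold-change vector,
## dom an integer/factor group index of equal length. Zero lfc slots are
## excluded per domain; all-zero domains get 0.
fccAll <- function(lfc, dom) {
  dom <- as.factor(dom)
  nz <- lfc != 0
  neg <- lfc < 0 & nz
  ninf <- rowsum(as.numeric(nz), dom)[, 1]
  cneg <- rowsum(as.numeric(neg), dom)[, 1]
  sAbs <- rowsum(abs(lfc), dom)[, 1]
  sAbsNeg <- rowsum(abs(lfc) * neg, dom)[, 1]
  fcc <- (2 * cneg / ninf - 1) * (2 * sAbsNeg / pmax(sAbs, .Machine$double.xmin) - 1)
  fcc[ninf == 0] <- 0
  fcc
}

#' Ranked cumulative-sum curve of FCC scores
#'
#' Domains are ranked by decreasing FCC; curve[k] is the sum of the k largest
#' scores. The genome-wide concordance signal is the area under this curve
#' relative to a permutation null.
#'
#' @param fcc numeric vector of per-domain FCC scores.
#' @return numeric vector of cumulative sums, length = number of domains.
#' @export
rankedCumsum <- function(fcc) {
  assertThat(length(fcc) >= 1, "need at least one domain")
  cumsum(sort(fcc, decreasing = TRUE))
}

## Draw one within-class permutation of slot indices.
permuteWithinClasses <- function(classes) {
  perm <- seq_along(classes)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Permutation null curve for the genome-wide FCC analysis
#'
#' Gene-to-domain assignments are permuted within equal-sized expression
#' classes (so permuted domains keep a realistic expression-level mix); the
#' per-domain FCC and its ranked cumulative-sum curve are recomputed for every
#' permutation, and the pointwise \code{quantileLevel} quantile across
#' permutations is retained as the single null curve.
#'
#' @param lfc named per-gene log2 fold-changes (names = gene ids).
#' @param map domain-to-gene list (already filtered).
#' @param classValues named per-gene expression summary used to build the
#'   classes (e.g. mean TPM-like value).
#' @param nPerm number of permutations (>= 1).
#' @param nClasses number of expression classes (default 5; 1 disables
#'   stratification).
#' @param quantileLevel pointwise quantile retained (default 0.95).
#' @param seed integer seed (mandatory for reproducibility).
#' @return numeric null curve of length = number of domains, with attributes
#'   \code{nPerm} and \code{aucNull} (trapezoidal AUC of the curve).
#' @export
permutationNullCurve <- function(lfc, map, classValues, nPerm = 10000,
                                 nClasses = 5, quantileLevel = 0.95, seed) {
  assertThat(nPerm >= 1, "nPerm must be >= 1")
  genes <- unlist(map, use.names = FALSE)
  assertThat(all(genes %in% names(lfc)), "lfc missing for some mapped genes")
  assertThat(all(genes %in% names(classValues)),
             "classValues missing for some mapped genes")
  dom <- factor(rep(names(map), lengths(map)), levels = names(map))
  v <- unname(lfc[genes])
  cls <- expressionClasses(classValues[genes], nClasses)
  D <- length(map)
  curves <- matrix(NA_real_, nrow = D, ncol = nPerm)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- permuteWithinClasses(cls)
      curves[, b] <- rankedCumsum(fccAll(v[perm], dom))
    }
  })
  nullCurve <- apply(curves, 1, quantile, probs = quantileLevel,
                     names = FALSE, type = 7)
  attr(nullCurve, "nPerm") <- as.integer(nPerm)
  attr(nullCurve, "aucNull") <- pracma::trapz(seq_len(D), nullCurve)
  nullCurve
}

#' AUC ratio between observed and null cumulative-sum curves
#'
#' Trapezoidal area under the observed curve divided by the area under the
#' permutation-null curve, both indexed by rank 1..D. A ratio above 1 means
#' expression changes are more concordant within domains than expected.
#'
#' @param observedCurve,nullCurve numeric curves of equal length >= 2.
#' @return a single positive numeric.
#' @export
aucRatio <- function(observedCurve, nullCurve) {
  assertThat(length(observedCurve) == length(nullCurve),
             "curves must have equal length")
  assertThat(length(observedCurve) >= 2, "curves must have length >= 2")
  x <- seq_along(observedCurve)
  aucNull <- pracma::trapz(x, nullCurve)
  assertThat(is.finite(aucNull) && aucNull > 0,
             "degenerate null curve (AUC <= 0)")
  pracma::trapz(x, observedCurve) / aucNull
}

#' Summaries of fully concordant domains
#'
#' Fraction of domains with FCC exactly 1 ("fully concordant") and, among
#' those, the fraction composed of exactly 3 genes (the smallest testable
#' size, where full concordance arises by chance 25\% of the time under
#' independent equiprobable signs).
#'
#' @param fcc named per-domain FCC scores.
#' @param map domain-to-gene list giving member counts, or a named integer
#'   vector of member counts.
#' @return list with \code{frac_fcc1} and \code{frac_fcc1_of_size3} (NaN when
#'   no domain is fully concordant).
#' @export
fullyConcordantSummary <- function(fcc, map) {
  sizes <- if (is.list(map)) lengths(map) else map
  full <- fcc == 1
  frac1 <- mean(full)
  n3 <- if (any(full)) {
    mean(sizes[names(fcc)[full]] == 3)
  } else NaN
  list(frac_fcc1 = frac1, frac_fcc1_of_size3 = n3)
}

#' Genome-wide FCC analysis
#'
#' Runs the first stage of the pipeline end to end: coverage filter,
#' upper-quartile normalization, gene-level log2 fold-changes, gene-to-domain
#' assignment and domain size filtering, per-domain FCC, ranked cumulative-sum
#' curves, expression-stratified permutation null and the AUC ratio.
#'
#' @param ds expression SummarizedExperiment (count-like values).
#' @param domains domain GRanges.
#' @param genes gene GRanges.
#' @param nPerm permutations for the null curve (default 10000; use 100000 to
#'   match high-precision runs).
#' @param nClasses expression classes (default 5).
#' @param quantileLevel pointwise null quantile (default 0.95).
#' @param seed integer seed.
#' @param ... preprocessing options passed to the shared preparation step
#'   (\code{countFilter}, \code{minGenes}, \code{maxGenesQuantile},
#'   \code{lfcMode}, \code{classValues}, ...).
#' @return an \linkS4class{FCCResult}.
#' @export
runFCC <- function(ds, domains, genes, nPerm = 10000, nClasses = 5,
                   quantileLevel = 0.95, seed = 1, ...) {
  prep <- prepareActivityInputs(ds, domains, genes, nClasses = nClasses, ...)
  dom <- factor(rep(names(prep$map), lengths(prep$map)),
                levels = names(prep$map))
  slots <- unlist(prep$map, use.names = FALSE)
  fcc <- fccAll(unname(prep$lfc[slots]), dom)
  names(fcc) <- names(prep$map)
  obs <- rankedCumsum(fcc)
  nullCurve <- permutationNullCurve(prep$lfc, prep$map, prep$classValues,
                                    nPerm = nPerm, nClasses = nClasses,
                                    quantileLevel = quantileLevel, seed = seed)
  ratio <- aucRatio(obs, as.numeric(nullCurve))
  new("FCCResult",
      fcc = fcc,
      nGenes = lengths(prep$map),
      observedCurve = obs,
      nullCurve = as.numeric(nullCurve),
      aucRatio = ratio,
      nPerm = as.integer(nPerm),
      seed = as.integer(seed),
      params = list(nClasses = nClasses, quantileLevel = quantileLevel))
}
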