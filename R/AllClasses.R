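#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DataFrame
NULL

#' FCCResult: genome-wide fold-change concordance result
#'
#' Holds the per-domain FCC scores, the observed ranked cumulative-sum curve,
#' the permutation-null curve (pointwise 95th percentile by default) and the
#' AUC ratio between the two.
#'
#' @slot fcc named numeric vector of per-domain FCC scores in [-1, 1].
#' @slot nGenes named integer vector, informative (nonzero-LFC) genes per domain.
#' @slot observedCurve cumulative sums of FCC ranked in decreasing order.
#' @slot nullCurve pointwise quantile of the permuted cumulative-sum curves.
#' @slot aucRatio observed AUC over null AUC (trapezoidal).
#' @slot nPerm number of permutations used for the null curve.
#' @slot seed integer seed used for the permutations.
#' @slot params list of extra parameters (n_classes, quantile level).
#' @export
setClass("FCCResult", representation(
  fcc = "numeric",
  nGenes = "integer",
  observedCurve = "numeric",
  nullCurve = "numeric",
  aucRatio = "numeric",
  nPerm = "integer",
  seed = "integer",
  params = "list"
))

setValidity("FCCResult", function(object) {
  msg <- character(0)
  if (length(object@fcc) &&
      any(object@fcc < -1 - 1e-9 | object@fcc > 1 + 1e-9, na.rm = TRUE)) {
    msg <- c(msg, "fcc scores must lie in [-1, 1]")
  }
  if (length(object@observedCurve) && length(object@nullCurve) &&
      length(object@observedCurve) != length(object@nullCurve)) {
    msg <- c(msg, "observed and null curves must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' DomainActivityResult: per-domain differential activity calls
#'
#' The main output container: one row per tested domain with mFC, mCor, the
#' two empirical p values, the Stouffer-combined p, the BH-adjusted p, the
#' direction of change and the significance flag.
#'
#' @slot table a \link[S4Vectors]{DataFrame} with columns domain_id, chrom,
#'   start, end, n_genes, mfc, mcor, p_mfc, p_mcor, p_comb, p_adj, direction,
#'   significant; sorted by p_adj then p_comb.
#' @slot alpha significance threshold on the adjusted combined p value.
#' @slot crossBoundaryNull numeric vector: the pooled cross-boundary mean
#'   correlations used as the mCor null.
#' @slot nPerm number of gene-to-domain permutations for the mFC null.
#' @slot seed integer seed.
#' @slot params list of run parameters.
#' @export
setClass("DomainActivityResult", representation(
  table = "DataFrame",
  alpha = "numeric",
  crossBoundaryNull = "numeric",
  nPerm = "integer",
  seed = "integer",
  params = "list"
))

setValidity("DomainActivityResult", function(object) {
  tab <- object@table
  need <- c("domain_id", "n_genes", "mfc", "mcor", "p_mfc", "p_mcor",
            "p_comb", "p_adj", "direction", "significant")
  if (!all(need %in% colnames(tab))) {
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  }
  pcols <- c("p_mfc", "p_mcor", "p_comb", "p_adj")
  for (cn in pcols) {
    v <- tab[[cn]]
    if (length(v) && any(v <= 0 | v > 1, na.rm = TRUE)) {
      return(sprintf("%s must lie in (0, 1]", cn))
    }
  }
  if (length(object@crossBoundaryNull) &&
      any(abs(object@crossBoundaryNull) > 1 + 1e-9)) {
    return("cross-boundary null correlations must lie in [-1, 1]")
  }
  TRUE
})

#' InteractionMatrix: per-pixel chromatin contact significance
#'
#' A symmetric matrix of interaction strengths S = -log10(p) of contact
#' significance for one chromosome and one condition, at a fixed bin size.
#' Absent pixels are NA.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin size in bp.
#' @slot S symmetric numeric matrix, values >= 0 where present, NA if absent.
#' @export
setClass("InteractionMatrix", representation(
  chrom = "character",
  binSize = "numeric",
  S = "matrix"
))

setValidity("InteractionMatrix", function(object) {
  S <- object@S
  if (nrow(S) != ncol(S)) return("S must be square")
  if (object@binSize <= 0) return("binSize must be positive")
  if (any(S < 0, na.rm = TRUE)) return("interaction strengths must be >= 0")
  pres <- !is.na(S)
  if (!identical(pres, t(pres)) || any(abs(S - t(S)) > 1e-8, na.rm = TRUE)) {
    return("S must be symmetric (including the NA pattern)")
  }
  TRUE
})

#' Construct an InteractionMatrix
#'
#' @param S square symmetric numeric matrix of -log10(p) strengths (NA = absent).
#' @param chrom chromosome name.
#' @param binSize bin size in bp.
#' @return an \linkS4class{InteractionMatrix}.
#' @examples
#' m <- matrix(c(1, 2, 2, 1), 2, 2)
#' InteractionMatrix(m, "chr1", 40000)
#' @export
InteractionMatrix <- function(S, chrom, binSize) {
  new("InteractionMatrix", chrom = as.character(chrom),
      binSize = as.numeric(binSize), S = S)
}

setMethod("show", "FCCResult", function(object) {
  cat("FCCResult with", length(object@fcc), "domains\n")
  cat("  AUC ratio:", format(object@aucRatio, digits = 4),
      " (", object@nPerm, "permutations, seed", object@seed, ")\n")
  fc <- mean(object@fcc == 1)
  cat("  fully concordant (FCC = 1):", sprintf("%.1f%%", 100 * fc), "\n")
})

setMethod("show", "DomainActivityResult", function(object) {
  tab <- object@table
  cat("DomainActivityResult with", nrow(tab), "tested domains\n")
  cat("  significant (p_adj <=", object@alpha, "):",
      sum(tab$significant), "\n")
  cat("  mFC permutations:", object@nPerm,
      "; cross-boundary null size:", length(object@crossBoundaryNull), "\n")
})

#' Accessors for result objects
#'
#' \code{domainTable} returns the per-domain result table;
#' \code{significantDomains} the ids of domains passing the threshold;
#' \code{aucRatioOf} the observed/null AUC ratio of an FCC result.
#'
#' @param x a result object.
#' @return \code{domainTable}: a \link[S4Vectors]{DataFrame};
#'   \code{significantDomains}: character vector;
#'   \code{aucRatioOf}: a single numeric.
#' @rdname accessors
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' @rdname accessors
#' @export
setGeneric("significantDomains", function(x) standardGeneric("significantDomains"))

#' @rdname accessors
#' @export
setGeneric("aucRatioOf", function(x) standardGeneric("aucRatioOf"))

#' @rdname accessors
setMethod("domainTable", "DomainActivityResult", function(x) x@table)

#' @rdname accessors
setMethod("significantDomains", "DomainActivityResult", function(x) {
  as.character(x@table$domain_id[x@table$significant])
})

#' @rdname accessors
setMethod("aucRatioOf", "FCCResult", function(x) x@aucRatio)
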