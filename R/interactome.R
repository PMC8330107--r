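#' Difference of interaction strength between two conditions
#'
#' Elementwise S1 - S2 on pixels present in both matrices; pixels absent in
#' either are absent (NA) in the result.
#'
#' @param m1,m2 \linkS4class{InteractionMatrix} objects with matching
#'   chromosome, bin size and dimension.
#' @return numeric matrix of per-pixel differences (NA = absent), with
#'   attributes \code{chrom} and \code{binSize}.
#' @export
deltaS <- function(m1, m2) {
  assertThat(m1@chrom == m2@chrom, "chromosome mismatch")
  assertThat(m1@binSize == m2@binSize, "bin size mismatch")
  assertThat(all(dim(m1@S) == dim(m2@S)), "matrix shape mismatch")
  d <- m1@S - m2@S
  attr(d, "chrom") <- m1@chrom
  attr(d, "binSize") <- m1@binSize
  d
}

#' Pooled background distribution of interaction-strength differences
#'
#' Collects the differences of all pixels whose two bins are separated by at
#' most \code{window} bp, across all supplied chromosomes; this short-range
#' pool is the empirical reference against which any single pixel's difference
#' is tested.
#'
#' @param deltaMatrices a single difference matrix from \code{\link{deltaS}}
#'   or a list of them (one per chromosome).
#' @param window maximum genomic separation in bp (default 2e6).
#' @return numeric vector of pooled background differences.
#' @export
backgroundDistribution <- function(deltaMatrices, window = 2e6) {
  if (is.matrix(deltaMatrices)) deltaMatrices <- list(deltaMatrices)
  pool <- numeric(0)
  for (d in deltaMatrices) {
    binSize <- attr(d, "binSize")
    assertThat(!is.null(binSize) && window >= binSize,
               "window must be >= bin size")
    n <- nrow(d)
    maxOff <- floor(window / binSize)
    idx <- which(upper.tri(d, diag = TRUE), arr.ind = TRUE)
    sep <- idx[, 2] - idx[, 1]
    vals <- d[idx[sep <= maxOff, , drop = FALSE]]
    pool <- c(pool, vals[!is.na(vals)])
  }
  assertThat(length(pool) > 0, "empty background pool")
  pool
}

#' Empirical two-tailed p value for an interaction-strength difference
#'
#' p = (1 + #\{|background| >= |delta|\}) / (1 + #background), with direction
#' sign(delta): +1 when the contact is more significant in condition 1, -1 in
#' condition 2.
#'
#' @param delta a single difference or a difference matrix.
#' @param background pooled background from
#'   \code{\link{backgroundDistribution}}.
#' @return for a scalar: list(p, direction); for a matrix: list of two
#'   matrices \code{p} and \code{direction} (NA where absent).
#' @export
empiricalTwoTailedP <- function(delta, background) {
  assertThat(length(background) > 0, "background is empty")
  absBg <- sort(abs(background))
  n <- length(absBg)
  pOf <- function(x) {
    # count of |background| >= |x| via binary search on the sorted values:
    # n minus the strictly-smaller count, so exact ties count as >=
    (1 + (n - findInterval(abs(x), absBg, left.open = TRUE))) / (1 + n)
  }
  if (is.matrix(delta)) {
    p <- delta; dir <- delta
    ok <- !is.na(delta)
    p[ok] <- vapply(delta[ok], pOf, numeric(1))
    dir[ok] <- sign(delta[ok])
    list(p = p, direction = dir)
  } else {
    list(p = pOf(delta), direction = sign(delta))
  }
}

#' Per-domain signed interaction significance summary
#'
#' For each (differentially active) domain, collects the -log10 empirical p
#' values of its intra-domain pixels, signed by which condition the contact
#' was more frequent in, and groups them by the domain's activity direction.
#'
#' @param activityTable per-domain table (\code{domainTable} of a
#'   \linkS4class{DomainActivityResult}) or any data.frame with domain_id,
#'   chrom, start, end, direction, significant.
#' @param pMatrix,directionMatrix matrices from
#'   \code{\link{empiricalTwoTailedP}} for one chromosome.
#' @param chrom chromosome of the matrices.
#' @param binSize bin size in bp.
#' @param positiveCondition which condition gets the positive sign in the
#'   signed -log10(p) values (default 2, e.g. tumor when condition 2 is
#'   tumor).
#' @param onlySignificant restrict to significant domains (default TRUE).
#' @return data.frame with domain_id, domain_direction, bin_i, bin_j,
#'   signed_logp.
#' @export
domainInteractomeSummary <- function(activityTable, pMatrix, directionMatrix,
                                     chrom, binSize, positiveCondition = 2,
                                     onlySignificant = TRUE) {
  tab <- as.data.frame(activityTable)
  if (onlySignificant && "significant" %in% colnames(tab)) {
    tab <- tab[tab$significant, , drop = FALSE]
  }
  tab <- tab[tab$chrom == chrom, , drop = FALSE]
  n <- nrow(pMatrix)
  sgn <- if (positiveCondition == 1) 1 else -1
  out <- list()
  for (i in seq_len(nrow(tab))) {
    b1 <- floor(tab$start[i] / binSize) + 1
    b2 <- ceiling(tab$end[i] / binSize)
    if (b1 > n || b2 < 1) next  # domain outside matrix extent
    b1 <- max(b1, 1); b2 <- min(b2, n)
    idx <- which(upper.tri(pMatrix, diag = FALSE), arr.ind = TRUE)
    idx <- idx[idx[, 1] >= b1 & idx[, 2] <= b2, , drop = FALSE]
    if (nrow(idx) == 0) next
    pv <- pMatrix[idx]
    dv <- directionMatrix[idx]
    ok <- !is.na(pv)
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      domain_id = tab$domain_id[i],
      domain_direction = tab$direction[i],
      bin_i = idx[ok, 1], bin_j = idx[ok, 2],
      signed_logp = sgn * dv[ok] * -log10(pv[ok]),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(domain_id = character(0), domain_direction = numeric(0),
                      bin_i = integer(0), bin_j = integer(0),
                      signed_logp = numeric(0)))
  }
  do.call(rbind, out)
}
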