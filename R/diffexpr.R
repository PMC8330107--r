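#' Per-gene log2 fold-change of mean expression
#'
#' lfc(g) = log2((mean in condition 2 + pseudocount) / (mean in condition 1 +
#' pseudocount)), on whatever normalized scale the input carries. Condition
#' order is the level order of \code{colData(ds)$condition}.
#'
#' @param ds expression SummarizedExperiment.
#' @param pseudocount added to both means before the ratio (default 1).
#' @return named numeric vector of per-gene log2 fold-changes.
#' @export
computeLfc <- function(ds, pseudocount = 1) {
  m <- exprValues(ds)
  cond <- exprCondition(ds)
  g1 <- cond == levels(cond)[1]
  g2 <- cond == levels(cond)[2]
  assertThat(any(g1) && any(g2), "both conditions need at least one sample")
  log2((rowMeans(m[, g2, drop = FALSE]) + pseudocount) /
         (rowMeans(m[, g1, drop = FALSE]) + pseudocount))
}

## Newton inversion of the trigamma function, used to estimate the prior
## degrees of freedom of the variance shrinkage from the spread of the
## log sample variances.
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_real_)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (iter in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Moderated two-sample differential expression test
#'
#' An empirical-Bayes two-group test on (already log-scale) expression values:
#' gene-wise residual variances are shrunk toward a pooled prior variance whose
#' scale and degrees of freedom are estimated by method of moments on the log
#' sample variances, and the two-sided p value is taken from a t distribution
#' with residual + prior degrees of freedom. With \code{moderated = FALSE} a
#' plain Welch t-test is used instead.
#'
#' @param ds expression SummarizedExperiment; values are log2-transformed
#'   internally when \code{log2Transform = TRUE} (default, with offset +1).
#' @param moderated use variance shrinkage (default) or Welch's t.
#' @param log2Transform transform values as log2(x + 1) before testing.
#' @return a data.frame with columns gene_id, lfc, t_stat, p, p_adj, rank
#'   (rank 1 = smallest p).
#' @export
moderatedDETest <- function(ds, moderated = TRUE, log2Transform = TRUE) {
  m <- exprValues(ds)
  if (log2Transform) m <- log2(m + 1)
  cond <- exprCondition(ds)
  i1 <- which(cond == levels(cond)[1])
  i2 <- which(cond == levels(cond)[2])
  n1 <- length(i1); n2 <- length(i2)
  assertThat(n1 >= 2 && n2 >= 2, "need >= 2 samples per condition")
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  lfc <- m2 - m1
  v1 <- apply(m[, i1, drop = FALSE], 1, var)
  v2 <- apply(m[, i2, drop = FALSE], 1, var)

  if (moderated) {
    df <- n1 + n2 - 2
    assertThat(df > 0, "zero residual degrees of freedom")
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df  # pooled gene-wise variance
    s2pos <- pmax(s2, 1e-12)
    z <- log(s2pos)
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigammaInverse(evar)
      s20 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s20 <- exp(mean(e))
    }
    s2post <- if (is.finite(d0)) (d0 * s20 + df * s2) / (d0 + df) else
      rep(s20, length(s2))
    tstat <- lfc / sqrt(s2post * (1 / n1 + 1 / n2))
    dft <- df + d0
    p <- if (is.finite(dft)) 2 * pt(-abs(tstat), df = dft) else
      2 * pnorm(-abs(tstat))
    attr(p, "prior") <- NULL
    prior <- list(df_prior = d0, var_prior = s20, df_residual = df)
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    tstat <- lfc / se
    dft <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tstat), df = dft)
    prior <- list(df_prior = 0, var_prior = NA_real_,
                  df_residual = NA_real_)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(
    gene_id = rownames(m),
    lfc = unname(lfc),
    t_stat = unname(tstat),
    p = unname(p),
    p_adj = unname(bhAdjust(p)),
    stringsAsFactors = FALSE
  )
  out$rank <- rank(out$p, ties.method = "first")
  attr(out, "prior") <- prior
  out
}
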