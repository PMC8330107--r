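#' @importFrom stats cor pnorm pt qnorm quantile rnorm runif sd var median
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

## Validation errors get their own condition class so the CLI can map them to
## exit code 2 while internal errors stay at 1.
chromdaValidationError <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("chromda_validation_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

assertThat <- function(ok, msg) {
  if (!isTRUE(ok)) chromdaValidationError(msg)
  invisible(TRUE)
}

#' Derive independent per-stage seeds from one top-level seed
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' user-supplied seed, so that adding or removing one stage does not perturb
#' the random stream of the others.
#'
#' @param seed single integer seed.
#' @param n number of stage seeds to derive.
#' @return integer vector of length \code{n}, each in \code{[1, 2^31-2]}.
#' @keywords internal
stageSeeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## Evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's stream afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment written out explicitly: p values are sorted in
#' decreasing order, scaled by n/rank, and a running minimum is taken from the
#' top, capped at 1.
#'
#' @param p numeric vector of p values in (0, 1].
#' @return adjusted p values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03, 0.9))
#' @export
bhAdjust <- function(p) {
  assertThat(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
             "p values must be finite and in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
}
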