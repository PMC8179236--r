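# Internal helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

# Evaluate code under a temporary RNG state; NULL seed leaves the RNG alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation from a master seed (kept < 2^31).
deriveSeed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483399) * 7919 + 104729 * k) %%
    2147483399L + 1L
}

# Smoothed Gaussian random field on an nr x nc grid, rescaled to unit sd.
# Separable moving-average smoothing of white noise; the smoothing halfwidth
# sets the spatial correlation length in cells.
smoothField <- function(nr, nc, halfwidth = 4L) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (halfwidth > 0) {
    k <- rep(1 / (2L * halfwidth + 1L), 2L * halfwidth + 1L)
    smooth1 <- function(m) {
      n <- nrow(m)
      # replicate edge rows, filter all columns in one call
      mp <- m[pmin(pmax(seq_len(n + 2L * halfwidth) - halfwidth, 1L), n), ,
              drop = FALSE]
      out <- unclass(stats::filter(mp, k, sides = 2))
      matrix(out[halfwidth + seq_len(n), ], n, ncol(m))
    }
    z <- smooth1(z)
    z <- t(smooth1(t(z)))
  }
  s <- sd(as.numeric(z))
  if (s > 0) z <- z / s
  z
}

#' Weighted quantile (replication-consistent type 7)
#'
#' Interpolated inverse of the weighted empirical CDF. Weights are first
#' normalised to mean one (so the rule is invariant to rescaling all
#' weights), then the type-7 plotting position h = (n - 1) q + 1 is located
#' on the cumulative-weight scale, interpolating linearly where h spans a
#' boundary between distinct values. With equal weights this is exactly
#' \code{stats::quantile(type = 7)}.
#'
#' @param x numeric values.
#' @param w positive weights (same length as x).
#' @param q quantile levels in [0, 1].
#' @return numeric vector of quantiles.
#' @examples
#' weightedQuantile(c(1000, 2000), c(1, 9), 0.9)
#' @export
weightedQuantile <- function(x, w, q) {
  stopifnot(length(x) == length(w), length(x) > 0,
            all(is.finite(x)), all(is.finite(w)), all(w > 0),
            all(q >= 0 & q <= 1))
  n <- length(x)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] * n / sum(w)
  cw <- cumsum(w)
  # value at cumulative position j in (0, n]: first x whose cum weight >= j
  vat <- function(j) x[pmin(findInterval(j, cw, left.open = TRUE) + 1L, n)]
  h <- (n - 1) * q + 1
  k <- pmin(floor(h), n - 1L)
  k <- pmax(k, 1L)
  g <- h - k
  lo <- vat(k)
  hi <- vat(k + 1)
  unname(lo + g * (hi - lo))
}
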