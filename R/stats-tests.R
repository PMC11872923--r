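# Elementary statistics used throughout: Pearson correlation and the Wilcoxon
# signed-rank test versus a hypothesized location (exact for small n, Pratt
# handling of zeros, tie-corrected normal approximation otherwise).

#' Pearson correlation with a t-approximation p-value
#'
#' @param x,y Numeric vectors of equal length.
#' @return List of class `correlation_result`: `r`, `n`, `p` (two-sided).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("pearson needs at least 3 complete pairs")
  xm <- x - mean(x); ym <- y - mean(y)
  denom <- sqrt(sum(xm^2) * sum(ym^2))
  if (denom == 0) stopf("zero variance in x or y")
  r <- sum(xm * ym) / denom
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, n = n, p = p), class = "correlation_result")
}

#' Wilcoxon signed-rank test against a location
#'
#' Exact null distribution (enumeration over sign patterns via the
#' generating-function recursion, valid with ties through average ranks) for
#' n <= `exact_max`; tie/zero-corrected normal approximation with continuity
#' correction otherwise. Zeros are handled by Pratt's method: they enter the
#' ranking of absolute values and are then discarded.
#'
#' @param x Numeric vector.
#' @param mu0 Hypothesized location.
#' @param alternative `"two.sided"`, `"greater"` (location > mu0) or `"less"`.
#' @param exact_max Largest number of non-zero differences for which the exact
#'   distribution is used (default 25).
#' @return List: `statistic` (W+, sum of positive signed ranks), `n`
#'   (non-zero differences), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, mu0 = 0,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- x[is.finite(x)] - mu0
  if (!length(d)) stopf("no finite observations")
  if (all(d == 0)) {
    warnf("all observations equal mu0; test degenerate")
    return(list(statistic = 0, n = 0L, p = 1, method = "degenerate"))
  }
  r_all <- rank(abs(d))           # Pratt: zeros participate in ranking
  nz <- d != 0
  rk <- r_all[nz]
  sgn <- sign(d[nz])
  n <- sum(nz)
  W <- sum(rk[sgn > 0])
  if (n <= exact_max) {
    # exact distribution of W+ over the 2^n equiprobable sign patterns,
    # computed by convolution over doubled (integer) ranks
    d2 <- as.integer(round(2 * rk))
    tot <- sum(d2)
    f <- numeric(tot + 1L); f[1] <- 1
    for (w in d2) {
      g <- numeric(tot + 1L)
      g[seq_len(tot + 1L - w) + w] <- f[seq_len(tot + 1L - w)]
      f <- f + g
    }
    probs <- f / 2^n
    W2 <- as.integer(round(2 * W))
    p_ge <- sum(probs[(W2 + 1L):(tot + 1L)])
    p_le <- sum(probs[1:(W2 + 1L)])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction over the full (Pratt) ranking
    ties <- table(r_all)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu)
    cc <- 0.5 * sign(z)
    z <- (z - cc) / sqrt(sig2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z, lower.tail = TRUE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    p <- min(1, p)
    method <- "normal"
  }
  list(statistic = W, n = n, p = p, method = method)
}
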