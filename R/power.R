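#' Power of the two-sided Pearson correlation test
#'
#' Standard approximate power calculation: the critical correlation comes
#' from the t quantile with n - 2 df, the alternative is mapped through the
#' Fisher z transform with the small-sample bias term r / (2(n - 1)), and
#' power is evaluated under the normal approximation with standard deviation
#' 1 / sqrt(n - 3).
#'
#' @param r True absolute correlation under the alternative, in (0, 1).
#' @param n Number of paired observations (>= 4).
#' @param alpha Two-sided significance level (default 0.1, the threshold used
#'   to mask the association matrix).
#' @return Power in (0, 1).
#' @export
correlation_power <- function(r, n, alpha = 0.1) {
  if (n < 4) abort("`n` must be >= 4")
  rc <- critical_r(n, alpha)
  zr <- atanh(r) + r / (2 * (n - 1))
  zrc <- atanh(rc)
  pnorm((zr - zrc) * sqrt(n - 3)) + pnorm((-zr - zrc) * sqrt(n - 3))
}

#' Minimum detectable correlation at a given power
#'
#' Solves [correlation_power()] for the smallest absolute Pearson correlation
#' detectable with the requested power, i.e. the effect size below which the
#' p > `alpha` mask of the association matrix is expected to discard real
#' associations. Shrinks monotonically as more cell types with matched
#' ChIP-seq and RNA-seq become available.
#'
#' @param n Number of paired observations (cell types), >= 4.
#' @param power Target power in (0, 1) (default 0.8).
#' @param alpha Two-sided significance level (default 0.1).
#' @return Minimum detectable |r|, in (0, 1).
#' @examples
#' round(detectable_correlation(21), 2)  # 0.52
#' round(detectable_correlation(5), 2)   # 0.92
#' @export
detectable_correlation <- function(n, power = 0.8, alpha = 0.1) {
  if (n < 4) abort("`n` must be >= 4")
  if (power <= 0 || power >= 1) abort("`power` must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  stats::uniroot(function(r) correlation_power(r, n, alpha) - power,
                 interval = c(1e-8, 1 - 1e-10), tol = 1e-10)$root
}

#' Concordance correlation coefficient
#'
#' Lin's agreement coefficient between paired measurements, using population
#' (1/n) moments: `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`.
#' Used to compare expression quantifications across processing pipelines
#' (rank-transformed expression agrees across sources far better than raw
#' values).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return CCC in \[-1, 1\].
#' @export
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 2) abort("need at least 2 paired observations")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) abort("degenerate input: zero variance and equal means")
  2 * sxy / denom
}
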