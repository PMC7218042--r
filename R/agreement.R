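#' Pairwise coefficient of variation between two observers
#'
#' Root-mean-square within-pair CV for paired positive readings: for each
#' treatment i, the within-pair SD is \eqn{s_i = |x_i - y_i| / \sqrt 2} and
#' the pair mean \eqn{m_i = (x_i + y_i)/2}; the CV is
#' \eqn{100 \sqrt{\mathrm{mean}_i (s_i/m_i)^2}} percent. This is the standard
#' test-retest CV for ratio-scale data and is invariant to common rescaling.
#'
#' @param x,y Paired positive readings (same treatments, two observers).
#' @return CV in percent (scalar).
#' @export
#' @examples
#' pairwise_cv(c(100, 50), c(121, 50)) # only the first pair disagrees
pairwise_cv <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("readings must be finite")
  m <- (x + y) / 2
  if (any(m <= 0)) stop("pair means must be positive")
  s <- abs(x - y) / sqrt(2)
  100 * sqrt(mean((s / m)^2))
}

#' Bland-Altman agreement analysis for two observers
#'
#' Per-treatment differences d_i = x_i - y_i; bias = mean(d); limits of
#' agreement = bias +/- 2 * SD(d). The multiplier is exactly 2 (the
#' convention of the reproducibility literature this package follows), not
#' 1.96. The per-treatment (mean, difference) pairs are returned for
#' plotting.
#'
#' @param x,y Paired readings, n >= 2.
#' @return A `bland_altman_result`: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`, and `points` (data frame of pair means and differences).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 2 * sd_diff, loa_high = bias + 2 * sd_diff,
                 n = n,
                 points = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, limits of agreement (%.4g, %.4g), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
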