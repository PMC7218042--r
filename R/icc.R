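#' Intraclass correlation, two-way random effects, absolute agreement,
#' single rater
#'
#' Computes ICC(A,1) in the McGraw-Wong nomenclature from the mean squares of
#' the treatments x observers two-way layout (one reading per cell):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (treatment), column
#' (observer) and residual mean squares. Observers are treated as a random
#' sample of possible readers and systematic observer offsets count against
#' agreement (absolute agreement, not consistency). The 95% CI is the
#' standard F-based interval with Satterthwaite degrees of freedom.
#'
#' Works on the full matrix or any column subset, so the same routine serves
#' the pairwise and the all-observer analyses.
#'
#' @param x Numeric matrix, treatments in rows, observers in columns; no
#'   missing cells, n >= 2 rows, k >= 2 columns.
#' @param conf Confidence level, default 0.95.
#' @return An `icc_result`: list with `estimate`, `ci_low`, `ci_high`,
#'   `model_label`, `n`, `k`, and `low_n` (TRUE when n < 5, flagging an
#'   unstable interval).
#' @export
#' @examples
#' m <- cbind(A = c(10, 12, 19, 8), B = c(11, 12, 18, 9))
#' icc_agreement(m)
icc_agreement <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("readings matrix has missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 treatments and 2 observers")
  ms <- .two_way_ms(x)
  if (ms$SST <= 0) stop("ICC undefined: zero total variance")
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE
  alpha <- 1 - conf

  if (MSE <= .Machine$double.eps * ms$SST && MSC <= .Machine$double.eps * ms$SST) {
    # perfect agreement: all columns identical, variance entirely between rows
    est <- 1; ci <- c(1, 1)
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lo, min(hi, 1))
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 model_label = "two-way random, absolute agreement, single rater (ICC(A,1))",
                 conf = conf, n = n, k = k, low_n = n < 5),
            class = "icc_result")
}

# mean squares of the two-way layout without interaction (1 reading per cell)
.two_way_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm - g)^2)
  SSC <- n * sum((cm - g)^2)
  SST <- sum((x - g)^2)
  SSE <- SST - SSR - SSC
  list(MSR = SSR / (n - 1), MSC = SSC / (k - 1),
       MSE = SSE / ((n - 1) * (k - 1)), SST = SST)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (%d%%CI %.3f-%.3f)  [%s; n=%d, k=%d]%s\n",
              x$estimate, round(100 * x$conf), x$ci_low, x$ci_high,
              x$model_label, x$n, x$k,
              if (x$low_n) "  ** n < 5: interval unstable **" else ""))
  invisible(x)
}
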