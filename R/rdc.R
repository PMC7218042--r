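#' 95th percentile of the range of k iid standard normals
#'
#' Quantile of the distribution of max - min of k independent N(0,1)
#' variables, obtained by numeric quadrature of the range CDF
#' \deqn{F(r) = k \int \phi(x) [\Phi(x+r) - \Phi(x)]^{k-1} dx}
#' and root-finding. For k = 2 the closed form
#' \eqn{\sqrt 2\, \Phi^{-1}(1 - (1-p)/2)} is recovered to ~1e-9. Values are
#' cached per (k, p) within a session.
#'
#' @param k Number of variables (observers), >= 2.
#' @param p Probability, default 0.95.
#' @return The quantile (scalar). For k = 3, p = 0.95 this is 3.31449.
#' @export
normal_range_quantile <- function(k, p = 0.95) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  key <- sprintf("q_%d_%.10f", k, p)
  if (!is.null(.range_q_cache[[key]])) return(.range_q_cache[[key]])
  cdf <- function(r)
    integrate(function(x) k * dnorm(x) * (pnorm(x + r) - pnorm(x))^(k - 1),
              -Inf, Inf, rel.tol = 1e-11)$value
  q <- uniroot(function(r) cdf(r) - p, interval = c(1e-8, 20),
               tol = 1e-10)$root
  .range_q_cache[[key]] <- q
  q
}
.range_q_cache <- new.env(parent = emptyenv())

#' Reproducibility coefficient (RDC) for multi-observer ratio-scale readings
#'
#' The RDC is the maximum ratio between the k observers' readings of the same
#' treatment expected in 95% of cases; 1 means perfect reproducibility. It is
#' estimated on the log scale by variance components:
#' \enumerate{
#'   \item log-transform the readings (all must be > 0);
#'   \item estimate the within-treatment (inter-observer) SD \eqn{\hat\sigma}
#'     as the square root of the one-way residual mean square, treatments
#'     being the random blocks;
#'   \item with q the 95th percentile of the range of k iid standard normals
#'     ([normal_range_quantile()]), \eqn{RDC = \exp(q \hat\sigma)}: under the
#'     log-normal error model the log of the max/min ratio within a treatment
#'     is \eqn{\sigma} times the range of k standard normals.
#' }
#' The 95% CI is a seeded nonparametric bootstrap resampling treatments
#' (rows) with replacement, percentile method.
#'
#' @param x Matrix of strictly positive readings, treatments x observers.
#' @param n_bootstrap Bootstrap replicates for the CI (default 2000); 0
#'   disables the CI (bounds NA).
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level, default 0.95.
#' @param p Coverage probability defining the RDC, default 0.95.
#' @return An `rdc_result`: `estimate` (>= 1), `ci_low`, `ci_high`,
#'   `sigma_within_log`, `q95_range_k`, `n`, `k`, `n_bootstrap`, `seed`.
#' @export
#' @examples
#' m <- exp(matrix(rnorm(75, 4, 0.5), 25, 3) + rnorm(75, 0, 0.1))
#' rdc(m, n_bootstrap = 200, seed = 1)
rdc <- function(x, n_bootstrap = 2000L, seed = NULL, conf = 0.95, p = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x) || any(x <= 0))
    stop("RDC requires strictly positive, complete readings")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 treatments and 2 observers")
  lx <- log(x)
  q <- normal_range_quantile(k, p)
  sigma <- .sigma_within_log(lx)
  est <- exp(q * sigma)

  if (sigma == 0) {
    ci <- c(1, 1)
  } else if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      exp(q * .sigma_within_log(lx[idx, , drop = FALSE]))
    }, numeric(1))
    ci <- unname(quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 sigma_within_log = sigma, q95_range_k = q,
                 n = n, k = k, n_bootstrap = n_bootstrap, seed = seed,
                 conf = conf),
            class = "rdc_result")
}

# within-treatment SD on the log scale: sqrt of the one-way residual MS
.sigma_within_log <- function(lx) {
  n <- nrow(lx); k <- ncol(lx)
  sqrt(sum((lx - rowMeans(lx))^2) / (n * (k - 1)))
}

#' @export
print.rdc_result <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "CI not computed"
        else sprintf("%d%%CI %.3f-%.3f", round(100 * x$conf), x$ci_low, x$ci_high)
  cat(sprintf("RDC %.3f (%s)  [sigma_log %.4f, q %.4f, n=%d, k=%d, B=%d]\n",
              x$estimate, ci, x$sigma_within_log, x$q95_range_k,
              x$n, x$k, x$n_bootstrap))
  invisible(x)
}
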