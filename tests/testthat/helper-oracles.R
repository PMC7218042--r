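# Independent brute-force oracles and shared fixtures.
# The oracles deliberately use explicit loops / first-principles formulas so
# they share no code path with the implementation they check.

# ICC(A,1) from explicit double sums over the two-way layout
oracle_icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- sum(x) / (n * k)
  SSR <- 0; for (i in 1:n) SSR <- SSR + k * (sum(x[i, ]) / k - g)^2
  SSC <- 0; for (j in 1:k) SSC <- SSC + n * (sum(x[, j]) / n - g)^2
  SST <- 0; for (i in 1:n) for (j in 1:k) SST <- SST + (x[i, j] - g)^2
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
  MSE <- (SST - SSR - SSC) / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Friedman chi-square from rank sums (no-ties formula)
oracle_friedman <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- t(apply(x, 1, rank))
  Rj <- colSums(R)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

# one 6-connected dilation by scanning every voxel's neighborhood
oracle_dilate6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (mask[z, y, x]) { out[z, y, x] <- TRUE; next }
    nb <- FALSE
    if (z > 1)    nb <- nb || mask[z - 1, y, x]
    if (z < d[1]) nb <- nb || mask[z + 1, y, x]
    if (y > 1)    nb <- nb || mask[z, y - 1, x]
    if (y < d[2]) nb <- nb || mask[z, y + 1, x]
    if (x > 1)    nb <- nb || mask[z, y, x - 1]
    if (x < d[3]) nb <- nb || mask[z, y, x + 1]
    out[z, y, x] <- nb
  }
  out
}

# worked 6x3 readings matrix; frozen ICC(A,1) computed with oracle_icc_a1
icc_fixture <- rbind(c(100, 104, 96), c(150, 142, 158), c(80, 85, 78),
                     c(200, 190, 210), c(120, 118, 125), c(90, 94, 88))
icc_fixture_value <- 0.982253429813

# 8x3 fixture: no ties within rows, a clear third-observer effect, and an
# outlier row so the per-column Shapiro-Wilk gate rejects normality
friedman_fixture <- rbind(c(12, 15, 18), c(20, 18, 25), c(14, 13, 16),
                          c(300, 280, 330), c(9, 11, 12.5), c(17, 19, 21),
                          c(22, 21, 24), c(13, 14, 12))

# digital sphere mask of given voxel radius centered in a cubic grid
make_sphere_mask <- function(radius, pad = 3L) {
  n <- 2L * (radius + pad) + 1L
  c0 <- radius + pad + 1L
  idx <- seq_len(n) - c0
  (outer(outer(idx^2, idx^2, `+`), idx^2, `+`)) <= radius^2
}

# lognormal readings matrix with known between/within log-scale SDs
make_readings <- function(n, k, sigma_b, sigma_w, mu = 5, seed = 1) {
  set.seed(seed)
  B <- rnorm(n, 0, sigma_b)
  exp(mu + matrix(B, n, k) + matrix(rnorm(n * k, 0, sigma_w), n, k))
}

# minimal valid observer table around a given TD matrix (treatments x obs)
table_from_td <- function(td) {
  n <- nrow(td); k <- ncol(td)
  data.frame(
    treatment_id = rep(sprintf("T%03d", 1:n), each = k),
    observer_id = rep(LETTERS[1:k], n),
    TV_ml = 100, TLV_ml = 1500, THLV_ml = 1400,
    TD_Gy = as.vector(t(td)), THLD_Gy = 40,
    stringsAsFactors = FALSE)
}
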