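#' Normality-gated location comparison across observers
#'
#' Tests whether observers differ systematically in location, choosing the
#' test family by a per-column Shapiro-Wilk gate: if every observer column is
#' compatible with normality at `alpha`, the parametric family is used
#' (paired t test for each observer pair, additive two-way ANOVA with
#' treatment and observer factors for the overall observer effect); otherwise
#' the non-parametric family (Wilcoxon signed-rank pairwise, Friedman
#' overall). The ANOVA is additive because with one reading per cell the
#' treatment x observer interaction is not estimable.
#'
#' Pairs whose differences are all exactly zero have an undefined signed-rank
#' statistic; such pairs (and a fully constant matrix) are flagged
#' `degenerate` instead of carrying a p-value.
#'
#' @param x Readings matrix, treatments x observers, n >= 3.
#' @param alpha Gate level for the Shapiro-Wilk test, default 0.05.
#' @return A `comparison_result`: `normality_p` (per column), `family`
#'   ("parametric" or "non-parametric"), `overall` (method, statistic,
#'   p_value, degenerate), `pairwise` (data frame with one row per observer
#'   pair: statistic, p_value, degenerate).
#' @export
compare_readers <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need n >= 3 for normality testing")
  if (k < 2) stop("need at least 2 observers")
  obs <- colnames(x)
  if (is.null(obs)) obs <- .observer_labels(k)

  norm_p <- vapply(seq_len(k), function(j) {
    col <- x[, j]
    if (stats::var(col) == 0) return(NA_real_)  # constant column: SW undefined
    shapiro.test(col)$p.value
  }, numeric(1))
  parametric <- all(!is.na(norm_p)) && all(norm_p > alpha)
  family <- if (parametric) "parametric" else "non-parametric"

  pairs <- utils::combn(k, 2)
  pairwise <- data.frame(obs1 = obs[pairs[1, ]], obs2 = obs[pairs[2, ]],
                         statistic = NA_real_, p_value = NA_real_,
                         degenerate = FALSE, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    d <- x[, pairs[1, p]] - x[, pairs[2, p]]
    if (all(d == 0)) { pairwise$degenerate[p] <- TRUE; next }
    if (parametric) {
      if (sd(d) == 0) {
        # constant nonzero difference: the t statistic diverges, p -> 0
        pairwise$statistic[p] <- sign(mean(d)) * Inf
        pairwise$p_value[p] <- 0
      } else {
        tt <- t.test(x[, pairs[1, p]], x[, pairs[2, p]], paired = TRUE)
        pairwise$statistic[p] <- unname(tt$statistic)
        pairwise$p_value[p] <- tt$p.value
      }
    } else {
      wt <- suppressWarnings(
        wilcox.test(x[, pairs[1, p]], x[, pairs[2, p]], paired = TRUE,
                    exact = FALSE, correct = TRUE))
      pairwise$statistic[p] <- unname(wt$statistic)
      pairwise$p_value[p] <- wt$p.value
    }
  }

  if (all(apply(x, 1, function(r) length(unique(r)) == 1L))) {
    overall <- list(method = if (parametric) "two-way ANOVA (observer effect)"
                             else "Friedman",
                    statistic = NA_real_, p_value = NA_real_,
                    degenerate = TRUE)
  } else if (parametric) {
    long <- data.frame(value = as.vector(x),
                       treatment = factor(rep(seq_len(n), k)),
                       observer = factor(rep(obs, each = n)))
    fit <- summary(aov(value ~ treatment + observer, data = long))[[1]]
    i <- match("observer", trimws(rownames(fit)))
    overall <- list(method = "two-way ANOVA (observer effect)",
                    statistic = fit[i, "F value"],
                    p_value = fit[i, "Pr(>F)"],
                    degenerate = FALSE)
  } else {
    ft <- friedman.test(x)
    overall <- list(method = "Friedman",
                    statistic = unname(ft$statistic),
                    p_value = ft$p.value, degenerate = FALSE)
  }

  structure(list(normality_p = setNames(norm_p, obs), alpha = alpha,
                 family = family, overall = overall, pairwise = pairwise),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Observer comparison (", x$family, " family; Shapiro-Wilk gate at alpha = ",
      x$alpha, ")\n", sep = "")
  ov <- x$overall
  if (ov$degenerate) cat("overall: degenerate (no variation)\n")
  else cat(sprintf("overall %s: statistic %.4g, p = %.4g\n",
                   ov$method, ov$statistic, ov$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
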