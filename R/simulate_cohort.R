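#' Simulate a multi-observer cohort table
#'
#' Draws one reading per (treatment, observer, quantity) from the log-normal
#' model of [cohort_model()] and assembles the long-format observer table.
#' THLV is not drawn: it is recomputed per row as TLV - TV, mirroring how
#' non-tumoral liver volume is obtained in practice (subtraction of the
#' delineated tumor from the whole liver).
#'
#' Because TV and TLV are drawn independently, a treatment can occasionally be
#' drawn with a tumor larger than its liver. Such degenerate treatments are
#' redrawn wholesale (patient effects and all observer errors for that
#' treatment) with a warning, up to `max_retries` times; persistent failure
#' signals incompatible model parameters. A row-level redraw of the observer
#' error alone could not repair a violation driven by the between-patient
#' draws, hence the block-level policy.
#'
#' @param model A `cohort_model`.
#' @param seed RNG seed; defaults to the seed stored in the model. Identical
#'   model + seed gives a byte-identical table.
#' @param max_retries Redraw attempts per degenerate treatment (default 100).
#' @return An `observer_dose_table`: data frame with columns `treatment_id`,
#'   `observer_id`, `TV_ml`, `TLV_ml`, `THLV_ml`, `TD_Gy`, `THLD_Gy`, one row
#'   per (treatment, observer), complete blocks.
#' @export
#' @examples
#' tab <- simulate_cohort(default_cohort_model(seed = 42))
#' head(tab)
simulate_cohort <- function(model, seed = model$seed, max_retries = 100L) {
  stopifnot(inherits(model, "cohort_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_treatments
  k <- model$n_observers
  qs <- .quantities

  draw_block <- function() {
    B <- rnorm(length(qs), 0, model$sigma_between)          # patient effects
    E <- matrix(rnorm(k * length(qs)), k) %*% diag(model$sigma_within)
    logx <- matrix(model$mu_log, k, length(qs), byrow = TRUE) +
      matrix(B, k, length(qs), byrow = TRUE) + model$bias + E
    exp(logx)  # k x 4, columns TV TLV TD THLD
  }

  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    blk <- draw_block()
    tries <- 0L
    while (any(blk[, "TV"] >= blk[, "TLV"])) {
      tries <- tries + 1L
      if (tries > max_retries)
        stop("simulate_cohort: treatment ", i, " still has TV >= TLV after ",
             max_retries, " redraws; model parameters are incompatible")
      blk <- draw_block()
    }
    if (tries > 0L)
      warning("simulate_cohort: redrew treatment ", i, " ", tries,
              " time(s) to enforce TV < TLV")
    blocks[[i]] <- blk
  }

  vals <- do.call(rbind, blocks)  # (n*k) x 4, observer fastest
  df <- data.frame(
    treatment_id = rep(sprintf("T%03d", seq_len(n)), each = k),
    observer_id = rep(.observer_labels(k), n),
    TV_ml = vals[, "TV"],
    TLV_ml = vals[, "TLV"],
    THLV_ml = vals[, "TLV"] - vals[, "TV"],
    TD_Gy = vals[, "TD"],
    THLD_Gy = vals[, "THLD"],
    stringsAsFactors = FALSE
  )
  observer_table(df)
}

.observer_labels <- function(k) {
  if (k <= 26) LETTERS[seq_len(k)] else sprintf("O%02d", seq_len(k))
}
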