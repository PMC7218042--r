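#' Clinical dose-threshold rules
#'
#' A threshold rule classifies a treatment as "target reached" when the
#' stated quantity lies strictly beyond the cutoff in the stated direction.
#' A value exactly at the cutoff is NOT reached — a deterministic boundary
#' convention; with continuous doses the boundary has measure zero.
#'
#' `builtin_rules()` returns the three standard SIRT targets: tumor efficacy
#' TD > 200 Gy, and healthy-liver safety THLD < 50 Gy and THLD < 75 Gy.
#'
#' @param quantity "TD" or "THLD".
#' @param cutoff Threshold in Gy, > 0.
#' @param direction "greater_than" or "less_than".
#' @param label Optional label; defaults to e.g. "TD > 200 Gy".
#' @return A `threshold_rule`.
#' @export
threshold_rule <- function(quantity, cutoff,
                           direction = c("greater_than", "less_than"),
                           label = NULL) {
  quantity <- match.arg(quantity, c("TD", "THLD"))
  direction <- match.arg(direction)
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(label))
    label <- sprintf("%s %s %g Gy", quantity,
                     if (direction == "greater_than") ">" else "<", cutoff)
  structure(list(quantity = quantity, cutoff = cutoff,
                 direction = direction, label = label),
            class = "threshold_rule")
}

#' @rdname threshold_rule
#' @export
builtin_rules <- function() {
  list(threshold_rule("TD", 200, "greater_than"),
       threshold_rule("THLD", 50, "less_than"),
       threshold_rule("THLD", 75, "less_than"))
}

#' Classify a measurement against a dose-target rule
#'
#' @param measurement A `dosimetry_measurement`, a one-row table slice, or a
#'   bare numeric value of the rule's quantity.
#' @param rule A `threshold_rule`.
#' @return Logical: TRUE if the target is reached (strict inequality).
#' @export
#' @examples
#' classify_target(238, threshold_rule("TD", 200, "greater_than")) # TRUE
#' classify_target(200, threshold_rule("TD", 200, "greater_than")) # FALSE
classify_target <- function(measurement, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  value <- if (is.numeric(measurement)) {
    measurement
  } else {
    v <- measurement[[rule$quantity]]
    if (is.null(v)) v <- measurement[[.quantity_cols[[rule$quantity]]]]
    v
  }
  if (is.null(value) || length(value) != 1L || !is.finite(value))
    stop("measurement lacks a finite value for ", rule$quantity)
  if (rule$direction == "greater_than") value > rule$cutoff
  else value < rule$cutoff
}

#' Cross-observer classification discordance for a dose-target rule
#'
#' Applies the rule to every (treatment, observer) reading and counts the
#' treatments whose per-observer classifications are not all identical —
#' the patients who would be managed differently depending on who performed
#' the dosimetry.
#'
#' @param table An `observer_dose_table` (complete blocks enforced).
#' @param rule A `threshold_rule`.
#' @return A `concordance_result`: `n_treatments`, `n_discordant`,
#'   `fraction_discordant`, `rule_label`, and `per_treatment` (data frame
#'   with the classification of each observer and a `discordant` flag).
#' @export
discordance_fraction <- function(table, rule) {
  table <- observer_table(as.data.frame(table))
  stopifnot(inherits(rule, "threshold_rule"))
  m <- readings_matrix(table, rule$quantity)
  cls <- if (rule$direction == "greater_than") m > rule$cutoff else m < rule$cutoff
  disc <- apply(cls, 1, function(r) any(r != r[1]))
  per <- data.frame(treatment_id = rownames(m), cls, discordant = disc,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(n_treatments = nrow(m), n_discordant = sum(disc),
                 fraction_discordant = mean(disc), rule_label = rule$label,
                 per_treatment = per),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d treatments (%.0f%%) classified differently across observers\n",
              x$rule_label, x$n_discordant, x$n_treatments,
              100 * x$fraction_discordant))
  invisible(x)
}
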