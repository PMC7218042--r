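#' Validate and construct an observer dose table
#'
#' The canonical long-format container: one row per (treatment, observer)
#' carrying TV_ml, TLV_ml, THLV_ml, TD_Gy, THLD_Gy. Validation enforces:
#' complete blocks (every treatment has a row for every observer), strictly
#' positive volumes, non-negative doses, TV < TLV, and THLV consistent with
#' TLV - TV within `thlv_tol` ml (default 0.5 ml, the rounding granularity of
#' exported volumes).
#'
#' @param df A data frame with the documented columns.
#' @param thlv_tol Tolerance (ml) on |THLV - (TLV - TV)|.
#' @return The validated table, classed `observer_dose_table`.
#' @export
observer_table <- function(df, thlv_tol = 0.5) {
  req <- c("treatment_id", "observer_id", unname(.quantity_cols))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("observer table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$treatment_id <- as.character(df$treatment_id)
  df$observer_id <- as.character(df$observer_id)

  treatments <- unique(df$treatment_id)
  observers <- unique(df$observer_id)
  tab <- table(df$treatment_id, df$observer_id)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    stop("incomplete blocks: expected exactly one row per ",
         "(treatment, observer); first offender: treatment ",
         rownames(tab)[bad[1, 1]], ", observer ", colnames(tab)[bad[1, 2]])
  }
  vols <- c("TV_ml", "TLV_ml", "THLV_ml")
  for (v in vols)
    if (any(!is.finite(df[[v]]) | df[[v]] <= 0))
      stop("non-positive value in column ", v, " (row ",
           which(!is.finite(df[[v]]) | df[[v]] <= 0)[1], ")")
  for (d in c("TD_Gy", "THLD_Gy"))
    if (any(!is.finite(df[[d]]) | df[[d]] < 0))
      stop("negative or missing value in column ", d, " (row ",
           which(!is.finite(df[[d]]) | df[[d]] < 0)[1], ")")
  if (any(df$TV_ml >= df$TLV_ml))
    stop("TV must be < TLV (row ", which(df$TV_ml >= df$TLV_ml)[1], ")")
  resid <- abs(df$THLV_ml - (df$TLV_ml - df$TV_ml))
  if (any(resid > thlv_tol))
    stop("THLV inconsistent with TLV - TV beyond ", thlv_tol,
         " ml at row ", which(resid > thlv_tol)[1])

  attr(df, "n_treatments") <- length(treatments)
  attr(df, "n_observers") <- length(observers)
  class(df) <- unique(c("observer_dose_table", class(df)))
  df
}

#' Read / write an observer dose table as CSV
#'
#' The CSV schema is
#' `treatment_id,observer_id,TV_ml,TLV_ml,THLV_ml,TD_Gy,THLD_Gy`.
#' Reading validates the table (complete blocks, positivity, THLV
#' consistency) and fails with a named validation error otherwise.
#'
#' @param path File path.
#' @param table An `observer_dose_table` (or coercible data frame).
#' @return `read_observer_table` returns a validated `observer_dose_table`;
#'   `write_observer_table` returns `path` invisibly.
#' @export
read_observer_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  observer_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observer_table
#' @export
write_observer_table <- function(table, path) {
  table <- observer_table(as.data.frame(table))
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract a treatments x observers readings matrix for one quantity
#'
#' @param table An `observer_dose_table`.
#' @param quantity One of "TV", "TLV", "THLV", "TD", "THLD".
#' @param observers Optional subset of observer ids (for pairwise analyses).
#' @return Numeric matrix, rows = treatments, columns = observers, with
#'   dimnames.
#' @export
readings_matrix <- function(table, quantity, observers = NULL) {
  quantity <- match.arg(quantity, names(.quantity_cols))
  col <- .quantity_cols[[quantity]]
  obs <- sort(unique(table$observer_id))
  if (!is.null(observers)) {
    if (!all(observers %in% obs)) stop("unknown observer id")
    obs <- observers
  }
  trt <- unique(table$treatment_id)
  m <- matrix(NA_real_, length(trt), length(obs),
              dimnames = list(trt, obs))
  idx <- cbind(match(table$treatment_id, trt), match(table$observer_id, obs))
  keep <- !is.na(idx[, 2])
  m[idx[keep, , drop = FALSE]] <- table[[col]][keep]
  if (anyNA(m)) stop("incomplete blocks for quantity ", quantity)
  m
}
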