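#' Extract the four dosimetric quantities from an observer's segmentation
#'
#' Given a phantom's dose grid and one observer's liver and tumor masks:
#' TV is the voxel count of the union of tumor masks times the voxel volume
#' (multiple lesions are pooled into a single total tumoral volume before
#' averaging the dose); TLV likewise on the liver mask; THLV = TLV - TV
#' exactly; TD is the mean dose over the tumor region and THLD the mean dose
#' over liver-minus-tumor. Volumes are plain voxel counts — no
#' partial-volume weighting — matching the granularity of slice-wise manual
#' contouring. Lung shunt is fixed at 0%, so all injected activity is
#' hepatic by construction.
#'
#' @param phantom A `digital_phantom` (provides voxel geometry).
#' @param dose_grid Dose array from [local_deposition_dose()].
#' @param liver_mask Observer's liver segmentation (logical array).
#' @param tumor_masks List of observer tumor segmentations; their union is
#'   the total tumor region and must lie inside `liver_mask`.
#' @param observer_id Identifier stored with the measurement.
#' @return A `dosimetry_measurement`: `TV`, `TLV`, `THLV` (ml), `TD`, `THLD`
#'   (Gy), `observer_id`, and `td_defined` (FALSE when the tumor region is
#'   empty, in which case TD is NA).
#' @export
extract_measurements <- function(phantom, dose_grid, liver_mask, tumor_masks,
                                 observer_id = "A") {
  stopifnot(inherits(phantom, "digital_phantom"))
  if (!identical(dim(dose_grid), dim(phantom$activity)))
    stop("dose grid dimensions differ from phantom grid")
  if (!is.list(tumor_masks)) tumor_masks <- list(tumor_masks)
  tumor <- Reduce(`|`, tumor_masks, init = array(FALSE, dim(dose_grid)))
  if (any(tumor & !liver_mask)) stop("tumor voxels outside the liver mask")
  vml <- prod(phantom$voxel_size) / 1000

  TLV <- sum(liver_mask) * vml
  TV <- sum(tumor) * vml
  healthy <- liver_mask & !tumor
  td_defined <- any(tumor)
  TD <- if (td_defined) mean(dose_grid[tumor]) else NA_real_
  THLD <- if (any(healthy)) mean(dose_grid[healthy]) else NA_real_
  structure(list(TV = TV, TLV = TLV, THLV = TLV - TV, TD = TD, THLD = THLD,
                 observer_id = observer_id, td_defined = td_defined),
            class = "dosimetry_measurement")
}

#' @export
print.dosimetry_measurement <- function(x, ...) {
  cat(sprintf("Observer %s: TV %.1f ml, TLV %.1f ml, THLV %.1f ml, TD %s Gy, THLD %.1f Gy\n",
              x$observer_id, x$TV, x$TLV, x$THLV,
              if (x$td_defined) sprintf("%.1f", x$TD) else "undefined",
              x$THLD))
  invisible(x)
}
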