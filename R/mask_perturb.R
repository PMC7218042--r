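#' Binary 3-D morphology on logical arrays
#'
#' One iteration of dilation (erosion) with the 6-connected cross structuring
#' element: a voxel is added if any (kept if every) face neighbor is inside
#' the mask, with out-of-grid voxels treated as background. Implemented by
#' zero-padded array shifts; `iterations` repeats the unit operation, so the
#' effective margin is `iterations` voxels along each axis.
#'
#' @param mask 3-D logical array.
#' @param iterations Number of unit dilations/erosions, >= 0.
#' @return Logical array of the same dimensions.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- .morph_once(mask, dilate = TRUE)
  mask
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- .morph_once(mask, dilate = FALSE)
  mask
}

.morph_once <- function(mask, dilate) {
  acc <- mask
  for (axis in 1:3) for (off in c(-1L, 1L)) {
    sh <- .shift_array(mask * 1, axis, off) > 0
    acc <- if (dilate) acc | sh else acc & sh
  }
  acc
}

#' Perturb a segmentation mask to emulate an observer's delineation
#'
#' Emulates inter-observer contouring variability in two stages: a
#' deterministic morphological margin (dilation for `margin > 0`, erosion
#' for `margin < 0`, in voxels), then seeded random flips of boundary
#' voxels — each voxel of the inner boundary (mask voxels with an exposed
#' face) or outer boundary (background voxels touching the mask) is flipped
#' independently with probability `boundary_flip_prob`. The result is
#' optionally re-clipped to a containing mask (tumors must stay inside the
#' observer's liver).
#'
#' @param mask Non-empty 3-D logical array.
#' @param margin Signed margin in voxels (default 0).
#' @param boundary_flip_prob Probability of flipping each boundary voxel,
#'   in [0, 1] (default 0).
#' @param seed RNG seed for the flips.
#' @param clip_to Optional logical array the result is intersected with.
#' @return Perturbed logical mask; `margin = 0`, `boundary_flip_prob = 0`
#'   returns the input unchanged.
#' @export
perturb_mask <- function(mask, margin = 0L, boundary_flip_prob = 0,
                         seed = NULL, clip_to = NULL) {
  if (!any(mask)) stop("mask is empty")
  if (boundary_flip_prob < 0 || boundary_flip_prob > 1)
    stop("boundary_flip_prob must be in [0, 1]")
  out <- mask
  if (margin > 0) out <- dilate_mask(out, margin)
  if (margin < 0) {
    out <- erode_mask(out, -margin)
    if (!any(out))
      stop("erosion emptied the mask: perturbation too aggressive")
  }
  if (boundary_flip_prob > 0) {
    if (!is.null(seed)) set.seed(seed)
    inner <- out & !erode_mask(out, 1L)
    outer <- dilate_mask(out, 1L) & !out
    boundary <- which(inner | outer)
    flip <- boundary[stats::runif(length(boundary)) < boundary_flip_prob]
    out[flip] <- !out[flip]
  }
  if (!is.null(clip_to)) out <- out & clip_to
  if (!any(out)) stop("perturbation emptied the mask")
  out
}
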