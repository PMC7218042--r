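#' Local-deposition absorbed dose of a Y-90 phantom
#'
#' The local-deposition method assumes every Y-90 decay deposits its beta
#' energy in the voxel containing it, so the absorbed dose to completion of
#' decay is
#' \deqn{D_{voxel} = k \cdot A_{voxel} / m_{voxel}}
#' with \eqn{m_{voxel}} = density x voxel volume and k the total energy
#' released per GBq ([y90_energy_per_gbq()], 49.3908 J/GBq). Energy is
#' conserved exactly: sum(dose * mass) = k * sum(activity).
#'
#' @param phantom A `digital_phantom`.
#' @return 3-D dose grid in Gy, same dimensions as the activity grid.
#' @export
#' @examples
#' # 1 GBq spread uniformly in exactly 1 kg of tissue gives ~49.4 Gy
local_deposition_dose <- function(phantom) {
  stopifnot(inherits(phantom, "digital_phantom"))
  voxel_volume_l <- prod(phantom$voxel_size) / 1e6  # mm^3 -> L
  if (voxel_volume_l <= 0) stop("zero voxel volume")
  if (phantom$density <= 0) stop("zero density")
  mass_kg <- phantom$density * voxel_volume_l
  .y90_j_per_gbq * phantom$activity / mass_kg
}
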