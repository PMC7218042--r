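#' Physical constants for Y-90 local-deposition dosimetry
#'
#' `y90_energy_per_gbq()` returns the total energy (J) released per GBq of
#' Y-90 activity integrated to complete decay:
#' \deqn{k = E_{mean} \cdot T_{1/2} / \ln 2}
#' with mean beta energy per decay \eqn{E_{mean} = 0.9267} MeV and half-life
#' \eqn{T_{1/2} = 64.05} h, giving 49.3908 J/GBq. This is the proportionality
#' constant of the local-deposition method: each decay deposits its energy in
#' the voxel containing it, so absorbed dose is k * activity / voxel mass.
#'
#' @return Energy in joules released per GBq to complete decay (scalar).
#' @export
#' @examples
#' y90_energy_per_gbq() # 49.3908 J/GBq
y90_energy_per_gbq <- function() .y90_j_per_gbq

.y90_mean_energy_mev <- 0.9267
.y90_half_life_h <- 64.05
.mev_to_j <- 1.602176634e-13
.y90_j_per_gbq <- .y90_mean_energy_mev * .mev_to_j *
  (.y90_half_life_h * 3600) / log(2) * 1e9

# dosimetric quantities handled throughout, with units
.quantities <- c("TV", "TLV", "TD", "THLD")
.quantity_units <- c(TV = "ml", TLV = "ml", THLV = "ml", TD = "Gy", THLD = "Gy")
.quantity_cols <- c(TV = "TV_ml", TLV = "TLV_ml", THLV = "THLV_ml",
                    TD = "TD_Gy", THLD = "THLD_Gy")
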