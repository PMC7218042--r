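small_geo <- phantom_geometry(dim = c(40, 40, 40), voxel_size = c(4, 4, 4),
                              liver_semiaxes = c(70, 60, 45),
                              tumors = list(list(center = c(20, 10, 5),
                                                 radius = 18)))

test_that("activity is partitioned by the uptake ratio and conserved", {
  ph <- build_phantom(small_geo, total_activity = 2.0, uptake_ratio = 1)
  vals <- ph$activity[ph$liver_mask]
  expect_true(all(abs(vals - vals[1]) < 1e-15))         # uniform uptake
  expect_lt(abs(sum(ph$activity) - 2.0) / 2.0, 1e-9)    # conservation
  expect_true(all(ph$activity[!ph$liver_mask] == 0))

  ph4 <- build_phantom(small_geo, total_activity = 2.0, uptake_ratio = 4)
  tum <- ph4$tumor_masks[[1]]
  vt <- sum(tum); vl <- sum(ph4$liver_mask)
  expected_frac <- 4 * vt / (4 * vt + (vl - vt))        # closed-form partition
  expect_equal(sum(ph4$activity[tum]) / sum(ph4$activity), expected_frac,
               tolerance = 1e-12)

  outside <- phantom_geometry(dim = c(40, 40, 40),
                              liver_semiaxes = c(40, 40, 30),
                              tumors = list(list(center = c(60, 0, 0),
                                                 radius = 10)))
  expect_error(build_phantom(outside), "inside")
  expect_error(build_phantom(small_geo, total_activity = -1), "negative")
})

test_that("local deposition dose matches the decay-energy integral", {
  # 1 GBq spread uniformly in exactly 1 kg: 10x10x10 voxels of 1 ml at
  # density 1 kg/L
  mask <- array(FALSE, c(14, 14, 14)); mask[3:12, 3:12, 3:12] <- TRUE
  act <- array(0, dim(mask)); act[mask] <- 1 / 1000
  ph <- digital_phantom(act, mask, voxel_size = c(10, 10, 10), density = 1)
  dose <- local_deposition_dose(ph)
  lambda <- log(2) / (64.05 * 3600)
  oracle <- integrate(function(t) 1e9 * exp(-lambda * t) * 0.9267 *
                        1.602176634e-13, 0, 64.05 * 3600 * 80,
                      rel.tol = 1e-12)$value
  expect_lt(abs(mean(dose[mask]) - oracle) / oracle, 0.005)
  # linearity and the zero case
  ph2 <- ph; ph2$activity <- 2 * ph$activity
  expect_equal(local_deposition_dose(ph2), 2 * dose)
  ph0 <- ph; ph0$activity[] <- 0
  expect_true(all(local_deposition_dose(ph0) == 0))
})

test_that("energy is conserved voxel-wise, with and without PET blur", {
  for (fwhm in c(0, 8)) {
    ph <- build_phantom(small_geo, total_activity = 1.98, uptake_ratio = 4,
                        blur_fwhm_mm = fwhm)
    dose <- local_deposition_dose(ph)
    mass_kg <- ph$density * prod(ph$voxel_size) / 1e6
    lhs <- sum(dose) * mass_kg
    rhs <- y90_energy_per_gbq() * sum(ph$activity)
    expect_lt(abs(lhs - rhs) / rhs, 1e-9)
  }
})

test_that("mask perturbation: identity, monotonicity, brute-force dilation", {
  sph <- make_sphere_mask(10)
  expect_identical(perturb_mask(sph), sph)                 # zero spec
  grown <- perturb_mask(sph, margin = 1)
  shrunk <- perturb_mask(sph, margin = -1)
  expect_gt(sum(grown), sum(sph))
  expect_lt(sum(shrunk), sum(sph))
  expect_identical(grown, oracle_dilate6(sph))             # neighborhood scan
  expect_true(all(sph[shrunk]) && all(grown[sph]))         # nesting
  # seeded flips are deterministic and stay on the boundary
  f1 <- perturb_mask(sph, boundary_flip_prob = 0.3, seed = 9)
  f2 <- perturb_mask(sph, boundary_flip_prob = 0.3, seed = 9)
  expect_identical(f1, f2)
  interior <- erode_mask(sph, 1)
  expect_true(all(f1[interior]))                           # interior untouched
  expect_error(perturb_mask(make_sphere_mask(2), margin = -3), "emptied")
})

test_that("measurement extraction obeys the volume and dose identities", {
  ph <- build_phantom(small_geo, uptake_ratio = 4, blur_fwhm_mm = 8)
  dose <- local_deposition_dose(ph)
  meas <- extract_measurements(ph, dose, ph$liver_mask, ph$tumor_masks, "A")
  expect_identical(meas$THLV, meas$TLV - meas$TV)
  d_liver <- mean(dose[ph$liver_mask])
  expect_equal(meas$TLV * d_liver, meas$TV * meas$TD + meas$THLV * meas$THLD,
               tolerance = 1e-12)
  # uniform phantom: tumor and healthy-liver dose coincide
  phu <- build_phantom(small_geo, uptake_ratio = 1)
  du <- local_deposition_dose(phu)
  mu <- extract_measurements(phu, du, phu$liver_mask, phu$tumor_masks, "A")
  expect_equal(mu$TD, mu$THLD, tolerance = 1e-12)
  # 1000 voxels at 4 mm isotropic = 64.0 ml
  cube <- array(FALSE, dim(ph$activity)); cube[11:20, 11:20, 11:20] <- TRUE
  liver_all <- array(TRUE, dim(ph$activity))
  phc <- digital_phantom(array(0, dim(ph$activity)) , liver_all, list(cube))
  mc <- extract_measurements(phc, local_deposition_dose(phc), liver_all,
                             list(cube), "A")
  expect_equal(mc$TV, 64.0)
  # empty tumor region: TD undefined but flagged, not an error
  m0 <- extract_measurements(ph, dose, ph$liver_mask, list(), "A")
  expect_false(m0$td_defined)
  expect_true(is.na(m0$TD))
  # tumor voxels outside the observer liver are rejected
  expect_error(extract_measurements(ph, dose, erode_mask(ph$liver_mask, 8),
                                    ph$tumor_masks, "A"), "outside")
})

test_that("phantom cohorts feed the agreement layer end to end", {
  tab <- simulate_phantom_cohort(
    n_treatments = 4, n_observers = 3, seed = 21,
    geometry = phantom_geometry(dim = c(32, 32, 32),
                                liver_semiaxes = c(55, 45, 38),
                                tumors = list(list(center = c(15, 5, 3),
                                                   radius = 14))),
    tumor_radius_meanlog = log(14), tumor_radius_sdlog = 0.15,
    tumor_radius_range = c(10, 17))
  expect_s3_class(tab, "observer_dose_table")
  expect_equal(nrow(tab), 12)
  expect_identical(tab, simulate_phantom_cohort(
    n_treatments = 4, n_observers = 3, seed = 21,
    geometry = phantom_geometry(dim = c(32, 32, 32),
                                liver_semiaxes = c(55, 45, 38),
                                tumors = list(list(center = c(15, 5, 3),
                                                   radius = 14))),
    tumor_radius_meanlog = log(14), tumor_radius_sdlog = 0.15,
    tumor_radius_range = c(10, 17)))
  m <- readings_matrix(tab, "TD")
  expect_true(all(m > 0))
  expect_s3_class(icc_agreement(m), "icc_result")
})
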