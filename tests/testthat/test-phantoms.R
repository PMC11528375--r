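test_that("voxelized phantom volumes match closed forms", {
  sph <- sphere_fixture()
  vx <- sum(sph$mask$values) * prod(sph$mask$spacing) / 1000
  expect_lt(abs(vx / sph$spec$analytic_truth$volume_cm3 - 1), 0.01)

  # capsule closed forms: V = pi r^2 L + 4/3 pi r^3, S = 2 pi r L + 4 pi r^2
  cap <- capsule_fixture()$spec$analytic_truth
  expect_equal(cap$volume_cm3, (pi * 25 * 20 + 4 / 3 * pi * 125) / 1000)
  expect_equal(cap$surface_cm2, (2 * pi * 5 * 20 + 4 * pi * 25) / 100)
  expect_equal(cap$vs_ratio_cm, cap$volume_cm3 / cap$surface_cm2,
               tolerance = 1e-12)
  expect_equal(round(cap$volume_cm3, 3), 2.094)
  expect_equal(round(cap$vs_ratio_cm, 3), 0.222)

  ell <- ellipsoid_fixture()$spec$analytic_truth
  expect_equal(ell$aspect_ratio, 0.5)
  expect_equal(ell$sphericity, 0.5)
  expect_equal(ell$diameter_cm, 4)
  expect_equal(ell$r_in_max_mm, 10)
  expect_equal(ell$r_cir_min_mm, 20)
})

test_that("voxelized volume converges to the analytic volume as spacing shrinks", {
  errs <- vapply(c(1.0, 0.5), function(s) {
    ph <- make_phantom(phantom_spec("sphere", r = 9.2, spacing = s),
                       noise_sd = 0)
    abs(sum(ph$mask$values) * s^3 / 1000 /
          ph$spec$analytic_truth$volume_cm3 - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 1e-9)
  expect_lt(errs[2], 0.01)
})

test_that("rigid rotation leaves the analytic dimensionless truth unchanged", {
  base <- phantom_spec("capsule", r = 5, L = 20, spacing = 0.5)
  rot <- phantom_spec("capsule", r = 5, L = 20, spacing = 0.5,
                      rotation = rotation_xyz(c(1.1, 0.4, -0.6)))
  t1 <- make_phantom(base, noise_sd = 0)$spec$analytic_truth
  t2 <- make_phantom(rot, noise_sd = 0)$spec$analytic_truth
  for (k in c("sphericity", "roundness", "aspect_ratio"))
    expect_identical(t1[[k]], t2[[k]])
})

test_that("a phantom that cannot fit reports the overflowing axis", {
  spec <- phantom_spec("sphere", r = 9.2, spacing = 0.5)
  expect_error(make_phantom(spec, grid_shape = c(20, 45, 45)), "axis 1")
  expect_error(phantom_spec("ellipsoid", a = 10, b = 15, c = 5), "a >= b >= c")
  expect_error(phantom_spec("sphere", r = -1), "r > 0")
})

test_that("bent tube phantom voxelizes but carries no analytic truth", {
  cl <- cbind(seq(-15, 15, length.out = 7),
              8 * sin(seq(0, pi, length.out = 7)), 0)
  ph <- make_phantom(phantom_spec("bent_tube", r = 4, centerline = cl,
                                  spacing = 1), noise_sd = 0)
  expect_true(sum(ph$mask$values) > 0)
  expect_null(ph$spec$analytic_truth)
})

test_that("cohort simulation is reproducible and structurally complete", {
  p <- cohort_sim_params(n_patients = 20, seed = 11)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  expect_equal(nrow(a), 20 * 2 * 2)
  expect_setequal(names(a), c("patient_id", "hemisphere", "age", "sex",
                              "rater", "volume_cm3", "aspect_ratio",
                              "diameter_cm", "roundness", "sphericity",
                              "vs_ratio"))
  expect_equal(nrow(unique(a[, c("patient_id", "hemisphere", "rater")])),
               nrow(a))
  c2 <- simulate_cohort(cohort_sim_params(n_patients = 20, seed = 12))
  expect_false(identical(a$volume_cm3, c2$volume_cm3))
})

test_that("degenerate noise collapses rater-1 volumes onto the age law", {
  p <- cohort_sim_params(n_patients = 15, residual_sd = 0, sex_offset = 0,
                         hemisphere_offset = 0, rater2_noise_sd = 0,
                         descriptor_sds = c(aspect_ratio = 0, diameter_cm = 0,
                                            roundness = 0, sphericity = 0,
                                            vs_ratio = 0),
                         seed = 3)
  tab <- simulate_cohort(p)
  r1 <- tab[tab$rater == 1, ]
  k <- (1.7 - 3.7) / (90 - 55)^2
  expect_equal(r1$volume_cm3, pmax(3.7 + k * (r1$age - 55)^2, 0.5),
               tolerance = 1e-12)
  # same patient, both hemispheres: identical measurement
  split_v <- split(r1$volume_cm3, r1$patient_id)
  expect_true(all(vapply(split_v, function(v) diff(range(v)) == 0,
                         logical(1))))
})

test_that("simulator recovers the configured group offsets at large n", {
  p <- cohort_sim_params(n_patients = 2000, seed = 101)
  tab <- simulate_cohort(p)
  r1 <- tab[tab$rater == 1, ]
  dm <- mean(r1$volume_cm3[r1$sex == "M"]) - mean(r1$volume_cm3[r1$sex == "F"])
  se_m <- sqrt(stats::var(r1$volume_cm3[r1$sex == "M"]) / sum(r1$sex == "M") +
               stats::var(r1$volume_cm3[r1$sex == "F"]) / sum(r1$sex == "F"))
  expect_lt(abs(dm - p$sex_offset), 3 * se_m)
  dh <- mean(r1$volume_cm3[r1$hemisphere == "R"]) -
        mean(r1$volume_cm3[r1$hemisphere == "L"])
  se_h <- sqrt(2 * stats::var(r1$volume_cm3) / (nrow(r1) / 2))
  expect_lt(abs(dh - p$hemisphere_offset), 3 * se_h)
})

test_that("calibration noise is derived from the target R^2, not hard-coded", {
  p1 <- cohort_sim_params(n_patients = 10, residual_sd = 0.3)
  p2 <- cohort_sim_params(n_patients = 10, residual_sd = 0.6)
  # more rater-1 variance must imply more calibration noise for equal R^2
  expect_gt(p2$rater2_noise_sd, p1$rater2_noise_sd)
  v <- calibration_noise_sd(p1)
  expect_equal(v, p1$rater2_noise_sd)
})
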