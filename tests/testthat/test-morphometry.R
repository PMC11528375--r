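test_that("mesh volume and area are exact on a cube and fail when open", {
  cube <- box_mesh(c(20, 20, 20))
  vs <- compute_volume_surface(cube)
  expect_equal(unname(vs["volume_cm3"]), 8, tolerance = 1e-12)
  expect_equal(unname(vs["surface_cm2"]), 24, tolerance = 1e-12)
  open_mesh <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(compute_volume_surface(open_mesh), "boundary edge")
})

test_that("capsule mesh measurements match the closed forms within 2%", {
  cap <- capsule_fixture()
  vs <- compute_volume_surface(cap$mesh)
  tr <- cap$spec$analytic_truth
  expect_lt(abs(vs["volume_cm3"] / tr$volume_cm3 - 1), 0.02)
  expect_lt(abs(vs["surface_cm2"] / tr$surface_cm2 - 1), 0.02)
})

test_that("maximum inscribed sphere radius is recovered for all phantoms", {
  expect_lt(abs(max_inscribed_sphere(sphere_fixture()$field)$r_in_max - 9.2),
            0.25)
  expect_lt(abs(max_inscribed_sphere(ellipsoid_fixture()$field)$r_in_max - 10),
            0.3)
  cap <- max_inscribed_sphere(capsule_fixture()$field)
  expect_lt(abs(cap$r_in_max - 5), 0.25)
})

test_that("smallest enclosing sphere solves the textbook configurations", {
  two <- min_enclosing_sphere(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(two$r_cir_min, 5, tolerance = 1e-9)
  expect_equal(two$center, c(5, 0, 0), tolerance = 1e-9)
  cube <- as.matrix(expand.grid(c(0, 20), c(0, 20), c(0, 20)))
  expect_equal(min_enclosing_sphere(cube)$r_cir_min, 10 * sqrt(3),
               tolerance = 1e-9)
  one <- min_enclosing_sphere(matrix(c(1, 2, 3), 1))
  expect_equal(one$r_cir_min, 0)
})

test_that("smallest enclosing sphere matches brute force on seeded clouds", {
  for (n in c(12, 30, 60)) {
    set.seed(n)
    pts <- matrix(rnorm(3 * n), ncol = 3) %*% diag(c(3, 1, 0.5))
    fast <- min_enclosing_sphere(pts)
    brute <- hippomorph:::brute_enclosing_sphere(pts)
    expect_equal(fast$r_cir_min, brute$r_cir_min, tolerance = 1e-6)
    d <- sqrt(rowSums(sweep(pts, 2, fast$center)^2))
    expect_lte(max(d), fast$r_cir_min * (1 + 1e-9) + 1e-9)
  }
})

test_that("smallest enclosing sphere is optimal on 250 seeded points", {
  set.seed(250)
  pts <- matrix(rnorm(750), ncol = 3)
  fit <- min_enclosing_sphere(pts)
  d <- sqrt(rowSums(sweep(pts, 2, fit$center)^2))
  expect_lte(max(d), fit$r_cir_min * (1 + 1e-9) + 1e-9)
  # optimality certificate: support points on the boundary whose convex
  # hull contains the centre (otherwise the ball could shrink)
  sup <- pts[d > fit$r_cir_min - 1e-6, , drop = FALSE]
  expect_gte(nrow(sup), 2)
  dirs <- sweep(sup, 2, fit$center)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # centre lies in the convex hull of the support directions iff the
  # minimum-norm point of that hull is the origin (else the ball shrinks);
  # enumerate Caratheodory subsets and project exactly
  min_norm <- Inf
  for (k in 1:min(4, nrow(dirs))) {
    for (S in utils::combn(nrow(dirs), k, simplify = FALSE)) {
      D <- dirs[S, , drop = FALSE]
      G <- D %*% t(D)
      lam <- tryCatch(solve(G + diag(1e-10, k), rep(1, k)),
                      error = function(e) NULL)
      if (is.null(lam)) next
      lam <- lam / sum(lam)
      if (all(lam >= -1e-9))
        min_norm <- min(min_norm, sqrt(max(t(lam) %*% G %*% lam, 0)))
    }
  }
  expect_lt(min_norm, 1e-4)
})

test_that("sphericity follows its definition and stays in (0, 1]", {
  expect_equal(sphericity(list(r_in_max = 0.4, r_cir_min = 1)), 0.4)
  sph <- sphere_fixture()
  d <- describe_shape(sph$field, mesh = sph$mesh)
  expect_gte(d$sphericity, 0.95)
  expect_lte(d$sphericity, 1)
  expect_error(sphericity(list(r_in_max = -1, r_cir_min = 2)), "positive")
})

test_that("corner detection sees one uniform region on a sphere", {
  sph <- sphere_fixture()
  fit <- max_inscribed_sphere(sph$field)
  cs <- detect_corners(sph$mesh, fit$r_in_max, sph$field)
  expect_equal(cs$n, 1L)
  expect_lt(abs(cs$radii[1] / 9.2 - 1), 0.05)
})

test_that("corner detection isolates the two capsule caps", {
  cap <- capsule_fixture()
  fit <- max_inscribed_sphere(cap$field)
  cs <- detect_corners(cap$mesh, fit$r_in_max, cap$field)
  expect_equal(cs$n, 2L)
  expect_true(all(abs(cs$radii / 5 - 1) < 0.10))
  # the regions sit at the two ends of the long axis
  axd <- cap$spec$rotation %*% c(1, 0, 0)
  proj <- (sweep(cap$mesh$vertices, 2, colMeans(cap$mesh$vertices)) %*% axd)[, 1]
  means <- vapply(cs$regions, function(ix) mean(proj[ix]), numeric(1))
  expect_true(min(means) < -8 && max(means) > 8)
})

test_that("ellipsoid corner radii reach the analytic tip curvature radius", {
  ell <- ellipsoid_fixture()
  fit <- max_inscribed_sphere(ell$field)
  cs <- detect_corners(ell$mesh, fit$r_in_max, ell$field)
  # smallest touching-ball radius on the surface = c^2 / a = 5 mm
  expect_lt(abs(min(cs$r_vertex) / 5 - 1), 0.15)
  # the largest corner regions concentrate at the +-a tips
  axd <- ell$spec$rotation %*% c(1, 0, 0)
  proj <- (sweep(ell$mesh$vertices, 2, colMeans(ell$mesh$vertices)) %*% axd)[, 1]
  big2 <- order(vapply(cs$regions, length, integer(1)), decreasing = TRUE)[1:2]
  means <- vapply(cs$regions[big2], function(ix) mean(proj[ix]), numeric(1))
  expect_true(min(means) < -10 && max(means) > 10)
})

test_that("roundness follows its definition on arithmetic and phantoms", {
  expect_equal(roundness(list(radii = c(0.2, 0.4)), list(r_cir_min = 0.6)),
               0.5)
  expect_equal(roundness(list(radii = c(0.2, 0.4)),
                         list(r_cir_min = 0.6, r_in_max = 0.3),
                         denominator = "inscribed"), 1)
  sph <- sphere_fixture()
  ds <- describe_shape(sph$field, mesh = sph$mesh)
  expect_lt(abs(ds$roundness - 1), 0.05)
  cap <- capsule_fixture()
  dc <- describe_shape(cap$field, mesh = cap$mesh)
  expect_lt(abs(dc$roundness - 1 / 3), 0.05)
  expect_error(roundness(list(radii = numeric()), list(r_cir_min = 1)),
               "empty")
})

test_that("principal axes recover the generators of a rotated ellipsoid", {
  ell <- ellipsoid_fixture()
  ax <- principal_axes(ell$field)
  expect_equal(ax$extents, c(40, 30, 20), tolerance = 0.02)
  gen <- ell$spec$rotation
  for (k in 1:3) {
    ang <- acos(min(abs(sum(ax$directions[, k] * gen[, k])), 1)) * 180 / pi
    expect_lt(ang, 3)
  }
  expect_lt(max(abs(crossprod(ax$directions) - diag(3))), 1e-6)
})

test_that("principal extents are box side lengths for boxes and isotropic for spheres", {
  bm <- box_mask(c(40, 20, 10), spacing = 0.5)
  bf <- reinitialize_sdf(bm)
  ax <- principal_axes(bf)
  # centre-to-centre extents run half a voxel short on each side
  expect_true(all(abs(ax$extents - c(40, 20, 10)) <= 0.5 + 1e-6))
  expect_lt(abs(aspect_ratio(ax) - 0.25), 0.02)

  sph <- sphere_fixture()
  axs <- principal_axes(sph$field)
  expect_lt(diff(range(axs$extents)) / max(axs$extents), 0.03)
  expect_lt(abs(aspect_ratio(axs) - 1), 0.03)
})

test_that("aspect ratio is the extent quotient", {
  expect_equal(aspect_ratio(list(extents = c(40, 20, 10))), 0.25)
  ell <- ellipsoid_fixture()
  expect_equal(aspect_ratio(principal_axes(ell$field)), 0.5,
               tolerance = 0.02 / 0.5)
})

test_that("the full sphere description matches all closed forms", {
  sph <- sphere_fixture()
  d <- describe_shape(sph$field, mesh = sph$mesh)
  expect_lt(abs(d$volume_cm3 / 3.2618 - 1), 0.01)
  expect_lt(abs(d$diameter_cm / 1.84 - 1), 0.03)
  expect_gte(d$sphericity, 0.95); expect_lte(d$sphericity, 1)
  expect_lt(abs(d$roundness - 1), 0.05)
  expect_lt(abs(d$aspect_ratio - 1), 0.03)
  expect_lt(abs(d$vs_ratio_cm / (0.92 / 3) - 1), 0.03)
  expect_equal(d$vs_ratio_cm * d$sv_ratio_per_cm, 1, tolerance = 1e-9)
  expect_gte(d$diameter_cm, 2 * (3 * d$volume_cm3 / (4 * pi))^(1 / 3))
})

test_that("ellipsoid sphericity equals its aspect ratio (both c/a)", {
  ell <- ellipsoid_fixture()
  d <- describe_shape(ell$field, mesh = ell$mesh)
  expect_lt(abs(d$sphericity - 0.5), 0.04)
  expect_lt(abs(d$aspect_ratio - 0.5), 0.04)
  expect_lt(abs(d$sphericity - d$aspect_ratio), 0.04)
})

test_that("descriptors obey the scaling laws", {
  half <- make_phantom(phantom_spec("capsule", r = 2.5, L = 10,
                                    spacing = 0.25), noise_sd = 0)
  base <- make_phantom(phantom_spec("capsule", r = 5, L = 20, spacing = 0.5),
                       noise_sd = 0)
  dbl <- make_phantom(phantom_spec("capsule", r = 10, L = 40, spacing = 1),
                      noise_sd = 0)
  ds <- lapply(list(half, base, dbl),
               function(p) describe_shape(reinitialize_sdf(p$mask)))
  for (s_i in c(1, 3)) {
    s <- c(0.5, 1, 2)[s_i]
    expect_lt(abs(ds[[s_i]]$volume_cm3 / (ds[[2]]$volume_cm3 * s^3) - 1), 0.02)
    expect_lt(abs(ds[[s_i]]$surface_cm2 / (ds[[2]]$surface_cm2 * s^2) - 1), 0.02)
    expect_lt(abs(ds[[s_i]]$diameter_cm / (ds[[2]]$diameter_cm * s) - 1), 0.02)
    expect_lt(abs(ds[[s_i]]$vs_ratio_cm / (ds[[2]]$vs_ratio_cm * s) - 1), 0.02)
    for (k in c("sphericity", "roundness", "aspect_ratio"))
      expect_lt(abs(ds[[s_i]][[k]] / ds[[2]][[k]] - 1), 0.02)
  }
})

test_that("mesh-based and voxel-count volumes agree at 0.5 mm spacing", {
  for (f in list(sphere_fixture(), capsule_fixture(), ellipsoid_fixture())) {
    vx <- sum(f$mask$values) * prod(f$mask$spacing) / 1000
    vm <- compute_volume_surface(f$mesh)["volume_cm3"]
    expect_lt(abs(vm / vx - 1), 0.02)
  }
})

test_that("rotation changes sphericity and aspect ratio by less than 2%", {
  aligned <- make_phantom(phantom_spec("ellipsoid", a = 20, b = 15, c = 10,
                                       spacing = 0.5), noise_sd = 0)
  da <- describe_shape(reinitialize_sdf(aligned$mask))
  dr <- describe_shape(ellipsoid_fixture()$field,
                       mesh = ellipsoid_fixture()$mesh)
  expect_lt(abs(da$sphericity / dr$sphericity - 1), 0.02)
  expect_lt(abs(da$aspect_ratio / dr$aspect_ratio - 1), 0.02)
})

test_that("mask-initialized and evolved twins describe alike on clean data", {
  sph <- sphere_fixture()
  d0 <- describe_shape(sph$field, mesh = sph$mesh)
  fe <- evolve_level_set(sph$mask, sph$image,
                         evolution_params(iterations = 150))
  de <- describe_shape(fe)
  for (k in c("volume_cm3", "surface_cm2", "diameter_cm", "sphericity",
              "roundness", "aspect_ratio", "vs_ratio_cm"))
    expect_lt(abs(de[[k]] / d0[[k]] - 1), 0.03)
})
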