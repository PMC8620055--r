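test_that("object_volume is voxel count times voxel volume", {
  expect_equal(object_volume(1, c(2, 0.5, 0.5)), 0.5)
  expect_equal(object_volume(1000, c(1, 1, 1)), 1000)
  expect_error(object_volume(0, c(1, 1, 1)), class = "glomseg_bad_input")
  iso <- c(0.5, 0.5, 0.5)
  ball <- ball_mask(10, iso)
  expect_equal(object_volume(sum(ball), iso), sphere_volume(10),
               tolerance = 0.02)
})

test_that("mesh surface area matches closed forms", {
  iso <- c(0.5, 0.5, 0.5)
  ball <- ball_mask(10, iso)
  a <- surface_area(ball, iso)
  expect_equal(a, sphere_surface(10), tolerance = 0.03)
  cube <- box_mask(c(20, 20, 20), iso)
  expect_equal(surface_area(cube, iso), 6 * 400, tolerance = 0.05)
  # anisotropic light-sheet spacing stresses the mesh scaling
  aniso <- c(2, 0.5, 0.5)
  expect_equal(surface_area(ball_mask(10, aniso), aniso),
               sphere_surface(10), tolerance = 0.08)
})

test_that("mesh surface error shrinks monotonically with voxel size", {
  errs <- vapply(c(2, 1, 0.5), function(h) {
    sp <- rep(h, 3)
    abs(surface_area(ball_mask(10, sp), sp) - sphere_surface(10)) /
      sphere_surface(10)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("single-voxel objects fall back to face area", {
  sp <- c(2, 0.5, 0.5)
  one <- array(1L, dim = c(1, 1, 1))
  # 2 faces of each orientation
  expect_equal(surface_area(one, sp),
               2 * (0.5 * 0.5) + 2 * (2 * 0.5) + 2 * (2 * 0.5))
  expect_equal(surface_area(one, sp, method = "faces"),
               surface_area(one, sp))
})

test_that("face counting overestimates curved surfaces as documented", {
  iso <- c(0.5, 0.5, 0.5)
  ball <- ball_mask(10, iso)
  faces <- surface_area(ball, iso, method = "faces")
  # exposed-face area of a voxelized ball tends to 6r^2*pi = 1.5x sphere
  expect_gt(faces / sphere_surface(10), 1.4)
})

test_that("compactness has its analytic values and properties", {
  r <- 10
  expect_equal(compactness(sphere_volume(r), sphere_surface(r)), 1)
  a <- 7
  expect_equal(compactness(a^3, 6 * a^2), pi / 6)
  # scale invariance at three scales
  for (s in c(0.1, 3, 42)) {
    expect_equal(compactness(sphere_volume(r * s), sphere_surface(r * s)), 1)
    expect_equal(compactness((a * s)^3, 6 * (a * s)^2), pi / 6)
  }
  # the sphere maximizes compactness among analytic test solids
  expect_lt(compactness(a^3, 6 * a^2), 1)                       # cube
  v_ell <- 4 / 3 * pi * 5 * 5 * 10
  s_ell <- prolate_surface(5, 10)                               # 2:1 spheroid
  expect_lt(compactness(v_ell, s_ell), 1)
  rr <- 3; h <- 8                                               # cylinder
  expect_lt(compactness(pi * rr^2 * h, 2 * pi * rr * h + 2 * pi * rr^2), 1)
  expect_error(compactness(-1, 5), class = "glomseg_bad_input")
})

test_that("sample_summary computes densities and means", {
  sp <- c(10, 10, 10)
  tissue <- binary_stack(array(1L, dim = c(25, 100, 100)), sp) # 0.25 mm^3
  objects <- data.frame(label = 1:2, volume = c(2e6, 3e6),
                        surface = c(6e4, 8e4),
                        compactness = c(0.5, 0.6),
                        ellipsoid_volume = c(3e6, 4e6), ratio = c(0.7, 0.75),
                        centroid_z = 0, centroid_y = 0, centroid_x = 0,
                        edge = FALSE)
  s <- sample_summary(objects, tissue)
  expect_equal(s$tissue_volume, 0.25)
  expect_equal(s$glomerular_volume, 0.005)
  expect_equal(s$volume_density, 2)
  expect_equal(s$numerical_density, 8)
  # identities re-assertable from raw fields
  expect_equal(s$volume_density,
               100 * s$glomerular_volume / s$tissue_volume)
  expect_equal(s$numerical_density, s$n_glomeruli / s$tissue_volume)
  expect_lte(s$glomerular_volume, s$tissue_volume)
  expect_equal(unname(s$mean_sd_volume["mean"]), 2.5e6)
  # population SD, denominator n
  expect_equal(unname(s$mean_sd_volume["sd"]), 5e5)
  # edge objects count for densities but not for means
  objects$edge <- c(FALSE, TRUE)
  s2 <- sample_summary(objects, tissue)
  expect_equal(s2$n_glomeruli, 2)
  expect_equal(s2$n_measured, 1)
  expect_equal(unname(s2$mean_sd_volume["mean"]), 2e6)
  # degenerate inputs
  empty <- objects[0, ]
  s3 <- sample_summary(empty, tissue)
  expect_equal(s3$n_glomeruli, 0)
  expect_equal(s3$volume_density, 0)
  expect_true(is.na(s3$mean_sd_surface["mean"]))
  expect_error(sample_summary(objects,
                              binary_stack(array(0L, dim = c(2, 2, 2)), sp)),
               class = "glomseg_bad_input")
})

test_that("shrinkage reports per-dimension and ellipsoid-volume percentages", {
  s <- shrinkage(c(10, 10, 10), c(9, 9, 9))
  expect_equal(s$dim_shrinkage, rep(10, 3))
  expect_equal(s$volume_shrinkage, 100 * (1 - 0.9^3), tolerance = 1e-12)
  expect_equal(shrinkage(c(10, 8, 6), c(10, 8, 6))$volume_shrinkage, 0)
  s2 <- shrinkage(c(10, 8, 6), 0.887 * c(10, 8, 6))
  expect_equal(s2$volume_shrinkage, 100 * (1 - 0.887^3), tolerance = 1e-9)
  expect_equal(s2$volume_shrinkage, 30.2, tolerance = 0.01)
  expect_warning(shrinkage(c(10, 10, 10), c(11, 9, 9)),
                 class = "glomseg_swelling")
  # the ellipsoid volume identity
  expect_equal(s$volume_before, 4 / 3 * pi * 5 * 5 * 5)
})

test_that("object_morphometry ties the pieces together", {
  iso <- c(0.5, 0.5, 0.5)
  arr <- array(0L, dim = c(36, 36, 36))
  ball <- ball_mask(6, iso)
  arr[2:(1 + dim(ball)[1]), 2:(1 + dim(ball)[2]), 2:(1 + dim(ball)[3])] <-
    ball
  labs <- make_label_stack(arr, iso)
  m <- object_morphometry(labs, 1L)
  expect_equal(nrow(m), 1)
  expect_equal(m$volume, sum(ball) * prod(iso))
  expect_equal(m$surface, sphere_surface(6), tolerance = 0.05)
  # compactness recomputable from its own fields
  expect_equal(m$compactness, compactness(m$volume, m$surface))
  expect_lte(m$compactness, 1.05)
  expect_gte(m$ratio, 0.8)
})
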