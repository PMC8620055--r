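test_that("volume_distribution bins object volumes", {
  sp <- c(2, 0.5, 0.5)
  arr <- array(0L, dim = c(5, 9, 9))
  arr[2, 2, 2] <- 1L; arr[2, 5, 5] <- 2L; arr[4, 8, 8] <- 3L
  cv <- volume_distribution(make_label_stack(arr, sp))
  # three 1-voxel objects: all mass at 0.5 um^3
  expect_equal(length(cv$positions), 1)
  expect_equal(cv$positions, 0.5)
  expect_equal(cv$frequencies, 3)
  # empty label stack errors
  expect_error(volume_distribution(make_label_stack(array(0L, dim = c(3, 3, 3)),
                                                    sp)),
               class = "glomseg_bad_input")
})

test_that("screen_by_volume keeps strictly larger objects", {
  sp <- c(1, 1, 1)
  arr <- array(0L, dim = c(14, 30, 30))
  arr[2, 2, 2] <- 1L                      # 1 um^3
  arr[2, 6, 6] <- 2L                      # 1 um^3
  arr[3:12, 3:22, 3:22] <- 3L             # 4000 um^3
  labs <- make_label_stack(arr, sp)
  s <- screen_by_volume(labs, min_volume = 1000)
  expect_equal(s$kept_labels, 3L)
  expect_equal(s$stage, "volume")
  # a zero-ish threshold keeps everything
  s0 <- screen_by_volume(labs, min_volume = 1e-9)
  expect_setequal(s0$kept_labels, 1:3)
  # threshold removing everything warns
  expect_warning(screen_by_volume(labs, min_volume = 1e9),
                 class = "glomseg_empty_screen")
})

test_that("screens are anti-monotone in their threshold", {
  sp <- c(1, 1, 1)
  set.seed(31)
  arr <- array(0L, dim = c(20, 20, 20))
  # a few boxes of varied size
  arr[1:3, 1:3, 1:3] <- 1L
  arr[6:12, 1:5, 1:5] <- 2L
  arr[1:10, 8:18, 8:18] <- 3L
  arr[15:16, 2:3, 8:16] <- 4L
  labs <- make_label_stack(arr, sp)
  thresholds <- c(5, 50, 200, 1200)
  kept <- lapply(thresholds, function(t)
    suppressWarnings(screen_by_volume(labs, t)$kept_labels))
  for (q in seq_len(length(kept) - 1))
    expect_true(all(kept[[q + 1]] %in% kept[[q]]))
})

test_that("enclosing_ellipsoid matches closed forms", {
  # 8 corners of a cube of side 2: circumscribed sphere radius sqrt(3)
  pts <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- enclosing_ellipsoid_volume(pts)
  expect_equal(v, 4 / 3 * pi * 3^1.5, tolerance = 5e-3)
  # general box: affine image of the cube
  half <- c(5, 2, 1)
  ptsb <- as.matrix(expand.grid(c(-1, 1) * half[1], c(-1, 1) * half[2],
                                c(-1, 1) * half[3]))
  expect_equal(enclosing_ellipsoid_volume(ptsb), box_mvee_volume(half),
               tolerance = 5e-3)
  # voxelized solid ball: near-spherical MVEE of the voxel centers
  m <- ball_mask(10, c(0.5, 0.5, 0.5))
  co <- which(m == 1L, arr.ind = TRUE)
  ctr <- sweep(co - 1, 2, c(0.5, 0.5, 0.5), "*")
  expect_equal(enclosing_ellipsoid_volume(ctr), sphere_volume(10),
               tolerance = 0.1)
})

test_that("degenerate point sets are inflated so Vell > 0", {
  sp <- c(2, 0.5, 0.5)
  one <- matrix(c(0, 0, 0), 1, 3)
  v <- enclosing_ellipsoid_volume(one, spacing = sp)
  # MVEE of a single voxel's corners: circumscribed ellipsoid of its box
  expect_equal(v, 4 / 3 * pi * 3^1.5 * prod(sp / 2), tolerance = 5e-3)
  expect_gt(v, 0)
  # collinear points get inflated too
  line <- cbind(seq(0, 10, 0.5), 0, 0)
  expect_gt(enclosing_ellipsoid_volume(line, spacing = sp), 0)
  expect_error(enclosing_ellipsoid_volume(one), class = "glomseg_bad_input")
})

test_that("shape_ratio separates balls from tubes", {
  iso <- c(0.5, 0.5, 0.5)
  ball <- ball_mask(10, iso)
  sr <- shape_ratio(ball, iso)
  expect_gte(sr$ratio, 0.85)
  expect_lte(sr$ratio, 1)
  expect_equal(sr$v_obj, sum(ball) * 0.125)
  # thin straight tube scores far below the ball
  tube <- box_mask(c(2, 2, 100), iso)
  srt <- shape_ratio(tube, iso)
  expect_lt(srt$ratio, 0.45)
  expect_gt(sr$ratio - srt$ratio, 0.4)
  # a voxelized ellipsoid nearly fills its own enclosing ellipsoid
  ell <- ellipsoid_mask(c(6, 9, 12), iso)
  sre <- shape_ratio(ell, iso)
  expect_gte(sre$ratio, 0.85)
  expect_lte(sre$ratio, 1)
})

test_that("dilation cannot shrink Vobj or Vell; ratio converges with resolution", {
  iso <- c(1, 1, 1)
  m <- ball_mask(6, iso)
  sr1 <- shape_ratio(m, iso)
  dil <- array(as.integer(glomseg:::.dilate1(m > 0L)), dim = dim(m))
  sr2 <- shape_ratio(dil, iso)
  expect_gte(sr2$v_obj, sr1$v_obj)
  expect_gte(sr2$v_ell, sr1$v_ell * (1 - 0.02)) # 2% certification slack
  # finer voxels bring a convex solid's ratio closer to its continuous
  # value (1 for a ball)
  coarse <- shape_ratio(ball_mask(10, c(1, 1, 1)), c(1, 1, 1))$ratio
  fine <- shape_ratio(ball_mask(10, c(0.5, 0.5, 0.5)),
                      c(0.5, 0.5, 0.5))$ratio
  expect_lt(abs(1 - fine), abs(1 - coarse))
})

test_that("screen_by_shape keeps globular objects", {
  sp <- c(1, 1, 1)
  arr <- array(0L, dim = c(26, 26, 60))
  ball <- ball_mask(6, sp)                       # globular, ratio ~0.9
  arr[2:(1 + dim(ball)[1]), 2:(1 + dim(ball)[2]), 2:(1 + dim(ball)[3])] <-
    ball
  arr[20:23, 20:23, 3:58] <- 2L                  # long tube, low ratio
  labs <- make_label_stack(arr, sp)
  vol <- screen_by_volume(labs, min_volume = 1)
  s <- screen_by_shape(labs, vol, min_ratio = 0.5)
  expect_equal(s$kept_labels, 1L)
  expect_equal(s$stage, "shape")
  # min_ratio ~ 0 keeps everything
  s0 <- screen_by_shape(labs, vol, min_ratio = 1e-9)
  expect_setequal(s0$kept_labels, 1:2)
  # ratios land where geometry says they should (the 6 um ball is only 6
  # voxels in radius here, so corner inflation costs it more than the
  # r = 10 um case above)
  expect_gt(s$table$ratio[1], 0.7)
  expect_lt(s$table$ratio[2], 0.45)
  # per-stage CSV export carries kept flags
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(s, path)
  tab <- read.csv(path)
  expect_equal(tab$kept_flag, c(TRUE, FALSE))
  expect_equal(unique(tab$stage), "shape")
})

test_that("object_table reports centroids, volumes and edge contact", {
  sp <- c(2, 0.5, 0.5)
  arr <- array(0L, dim = c(6, 10, 10))
  arr[2:3, 2:3, 2:3] <- 1L
  arr[1, 6, 6] <- 2L  # touches the z face
  tab <- object_table(make_label_stack(arr, sp))
  expect_equal(tab$voxel_count, c(8L, 1L))
  expect_equal(tab$volume, c(8, 1) * 0.5)
  # voxel centers at (index-1)*spacing: z indices 2:3 -> 2 and 4 um
  expect_equal(tab$centroid_z[1], 3)
  expect_equal(tab$centroid_y[1], (0.5 + 1) / 2)
  expect_equal(tab$edge, c(FALSE, TRUE))
})
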