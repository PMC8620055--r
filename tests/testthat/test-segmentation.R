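test_that("binarize applies a strict threshold", {
  sp <- c(1, 1, 1)
  uni <- voxel_stack(array(50L, dim = c(3, 3, 3)), sp)
  expect_true(all(binarize(uni, 112.9)$mask == 0L))
  two <- voxel_stack(array(c(40L, 200L), dim = c(1, 1, 2)), sp)
  expect_identical(as.integer(binarize(two, 112.9)$mask), c(0L, 1L))
  # boundary bin is excluded by strictness
  at <- voxel_stack(array(113L, dim = c(1, 1, 1)), sp)
  expect_identical(as.integer(binarize(at, 113)$mask), 0L)
})

test_that("lectin threshold retains only the expected tissue fraction", {
  set.seed(21)
  n <- 1e6
  arr <- array(as.integer(pmin(pmax(round(rnorm(n, 80, 10)), 0), 255)),
               dim = c(100, 100, 100))
  stack <- voxel_stack(arr, c(1, 1, 1))
  fit <- fit_gaussian(grey_histogram(stack))
  thr <- lectin_threshold(fit)
  frac <- mean(binarize(stack, thr)$mask)
  p <- 1 - stats::pnorm(K_SD_DEFAULT)
  # within 3 binomial SDs of the nominal exclusion rate, and surely <= 0.002
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n) + 2e-4)
  expect_lte(frac, 0.002)
})

test_that("median_filter_3d matches a brute-force majority oracle", {
  set.seed(22)
  sp <- c(1, 1, 1)
  # random masks, including a solid cube and an all-ones mask
  masks <- list(
    array(as.integer(runif(7 * 8 * 9) < 0.5), dim = c(7, 8, 9)),
    array(as.integer(runif(6 * 6 * 6) < 0.2), dim = c(6, 6, 6)),
    {
      cube <- array(0L, dim = c(13, 13, 13)); cube[3:11, 3:11, 3:11] <- 1L
      cube
    },
    array(1L, dim = c(5, 5, 5))
  )
  for (m in masks) {
    got <- median_filter_3d(binary_stack(m, sp), 3L)$mask
    expect_identical(got, median3d_oracle(m, 3L))
  }
})

test_that("median_filter_3d suppresses isolated voxels, keeps solids", {
  sp <- c(1, 1, 1)
  lone <- array(0L, dim = c(9, 9, 9)); lone[5, 5, 5] <- 1L
  expect_true(all(median_filter_3d(binary_stack(lone, sp))$mask == 0L))
  ones <- array(1L, dim = c(5, 5, 5))
  expect_true(all(median_filter_3d(binary_stack(ones, sp))$mask == 1L))
  expect_error(median_filter_3d(binary_stack(ones, sp), 7L),
               class = "glomseg_bad_input")
  expect_error(median_filter_3d(binary_stack(ones, sp), 4L),
               class = "glomseg_bad_input")
})

test_that("median_filter_3d is monotone in mask inclusion", {
  set.seed(23)
  sp <- c(1, 1, 1)
  for (rep in 1:5) {
    m1 <- array(as.integer(runif(8 * 8 * 8) < 0.3), dim = c(8, 8, 8))
    extra <- array(as.integer(runif(8 * 8 * 8) < 0.2), dim = c(8, 8, 8))
    m2 <- pmax(m1, extra)
    f1 <- median_filter_3d(binary_stack(m1, sp))$mask
    f2 <- median_filter_3d(binary_stack(m2, sp))$mask
    expect_true(all(f1 <= f2))
  }
})

test_that("label_components honours connectivity and counts voxels", {
  sp <- c(1, 1, 1)
  corner <- array(0L, dim = c(3, 3, 3))
  corner[1, 1, 1] <- 1L; corner[2, 2, 2] <- 1L
  expect_equal(label_components(binary_stack(corner, sp), 26L)$n_objects, 1L)
  expect_equal(label_components(binary_stack(corner, sp), 6L)$n_objects, 2L)
  empty <- label_components(binary_stack(array(0L, dim = c(3, 3, 3)), sp))
  expect_equal(empty$n_objects, 0L)
  # voxel-count conservation on a random mask
  set.seed(24)
  m <- array(as.integer(runif(10 * 12 * 14) < 0.3), dim = c(10, 12, 14))
  lab <- label_components(binary_stack(m, sp), 26L)
  expect_equal(sum(tabulate(lab$labels[lab$labels > 0], lab$n_objects)),
               sum(m))
  # labels are contiguous 1..n
  expect_setequal(unique(as.integer(lab$labels)),
                  0:lab$n_objects)
})

test_that("relabelling leaves the partition unchanged", {
  set.seed(25)
  m <- array(as.integer(runif(8 * 10 * 10) < 0.25), dim = c(8, 10, 10))
  sp <- c(2, 0.5, 0.5)
  l1 <- label_components(binary_stack(m, sp), 26L)
  # reverse the mask traversal by flipping all axes: labels permute but the
  # partition into components must be identical
  mf <- m[dim(m)[1]:1, dim(m)[2]:1, dim(m)[3]:1]
  l2 <- label_components(binary_stack(mf, sp), 26L)
  expect_equal(l1$n_objects, l2$n_objects)
  c1 <- sort(tabulate(l1$labels[l1$labels > 0], l1$n_objects))
  c2 <- sort(tabulate(l2$labels[l2$labels > 0], l2$n_objects))
  expect_equal(c1, c2)
})

test_that("binary and label stacks round-trip through TIFF", {
  set.seed(26)
  m <- array(as.integer(runif(4 * 6 * 6) < 0.4), dim = c(4, 6, 6))
  sp <- c(2, 0.5, 0.5)
  b <- binary_stack(m, sp)
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask_stack(b, path)
  r <- read_stack(path, sp)
  expect_identical(array(as.integer(r$voxels > 0), dim = dim(m)), m)
  lab <- label_components(b, 26L)
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_mask_stack(lab, path2)
  r2 <- read_stack(path2, sp)
  expect_identical(array(as.integer(r2$voxels), dim = dim(m)), lab$labels)
})
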