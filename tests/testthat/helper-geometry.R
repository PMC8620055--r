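# Geometric fixtures built in code: voxelized solids and their closed-form
# surface/volume oracles.

# voxelized ball of radius r (um), centered, voxel centers at (i-1)*sp
ball_mask <- function(r, spacing) {
  n <- ceiling(2 * r / spacing) + 5
  ax <- lapply(1:3, function(q) ((seq_len(n[q]) - 1) - n[q] / 2) * spacing[q])
  arr <- array(0L, dim = n)
  for (i in seq_len(n[3])) {
    d2 <- outer(ax[[1]]^2, ax[[2]]^2, "+") + ax[[3]][i]^2
    arr[, , i] <- (d2 <= r^2) + 0L
  }
  arr
}

# voxelized axis-aligned solid box of physical dims (lz, ly, lx) um
box_mask <- function(dims, spacing, pad = 3L) {
  nv <- round(dims / spacing)
  arr <- array(0L, dim = nv + 2L * pad)
  arr[pad + seq_len(nv[1]), pad + seq_len(nv[2]), pad + seq_len(nv[3])] <- 1L
  arr
}

# voxelized solid ellipsoid with semi-axes (az, ay, ax) um
ellipsoid_mask <- function(semi, spacing) {
  n <- ceiling(2 * semi / spacing) + 5
  ax <- lapply(1:3, function(q) ((seq_len(n[q]) - 1) - n[q] / 2) * spacing[q])
  arr <- array(0L, dim = n)
  for (i in seq_len(n[3])) {
    d2 <- outer(ax[[1]]^2 / semi[1]^2, ax[[2]]^2 / semi[2]^2, "+") +
      ax[[3]][i]^2 / semi[3]^2
    arr[, , i] <- (d2 <= 1) + 0L
  }
  arr
}

sphere_surface <- function(r) 4 * pi * r^2
sphere_volume <- function(r) 4 / 3 * pi * r^3

# closed-form surface of a prolate spheroid, semi-axes (a, a, c), c > a
prolate_surface <- function(a, c) {
  e <- sqrt(1 - a^2 / c^2)
  2 * pi * a^2 * (1 + c / (a * e) * asin(e))
}

# exact minimum-volume enclosing ellipsoid of a solid box with half-sides h:
# affine image of the cube, whose MVEE is the circumscribed sphere, so the
# semi-axes are sqrt(3) * h
box_mvee_volume <- function(half_sides) 4 / 3 * pi * prod(sqrt(3) * half_sides)

make_label_stack <- function(arr, spacing) {
  storage.mode(arr) <- "integer"
  structure(list(labels = arr, n_objects = max(arr), spacing = spacing),
            class = "label_stack")
}

# integer-grey histogram curve from draws clipped to [0, 255]
draws_curve <- function(x) {
  x <- pmin(pmax(round(x), 0), 255)
  frequency_curve(0:255, tabulate(x + 1L, 256L))
}

# brute-force 3D binary majority filter with edge replication (R loops);
# independent of the Rcpp path it checks
median3d_oracle <- function(mask, window = 3L) {
  d <- dim(mask)
  h <- window %/% 2
  out <- array(0L, dim = d)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    kk <- pmin(pmax((k - h):(k + h), 1), d[1])
    jj <- pmin(pmax((j - h):(j + h), 1), d[2])
    ii <- pmin(pmax((i - h):(i + h), 1), d[3])
    cnt <- sum(mask[kk, jj, ii])
    out[k, j, i] <- as.integer(2 * cnt > window^3)
  }
  out
}
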