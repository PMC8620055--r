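# Synthetic cleared-kidney-cortex phantoms with voxel-level ground truth.
#
# The phantom emulates the three voxel populations of a lectin-labelled
# cleared-kidney stack -- dark mounting medium, self-fluorescent tissue
# with Gaussian greys, and bright lectin-labelled structures -- plus the
# object classes the screening stages must separate: globular glomeruli
# with irregular (lobulated) surfaces, thin straight tubules standing in
# for peritubular capillaries, a few glomerulus-volume bent tubes standing
# in for arteriolar segments (shape-screen decoys), and isolated bright
# artifact voxels. Greys are drawn per voxel with Gaussian noise so the
# tissue/lectin populations overlap into a continuum: the statistical
# thresholding stage has a real job to do.

#' Phantom specification
#'
#' Defaults describe a 64 x 256 x 256 voxel stack at light-sheet spacing
#' (2, 0.5, 0.5) um, i.e. a 128 um cube of cortex. Forty glomeruli of
#' radius 8.5 +/- 1 um are planted: the stack cannot physically hold
#' glomeruli of full biological size (~25 um radius), so the phantom is an
#' explicitly scaled-down cortex sample in which relative contrasts --
#' object/tissue grey separation, the debris-to-glomerulus volume gap, the
#' tube-vs-blob shape gap -- are preserved.
#'
#' @param shape `(nz, ny, nx)` voxels.
#' @param spacing `(dz, dy, dx)` um.
#' @param margin voxels of dark mounting medium kept free on each face
#'   `(z, y, x)`.
#' @param background_level,tissue_level,glomerulus_grey,tubule_grey,artifact_grey
#'   `(mean, sd)` grey levels of the respective voxel populations. The
#'   glomerulus mean must exceed `tissue mean + 3.29 * tissue sd` so
#'   planted objects survive the lectin threshold by construction.
#' @param glomerulus_count planned number of glomeruli.
#' @param glomerulus_radius `(mean, sd)` um; draws are clamped to
#'   mean +/- 2.5 sd.
#' @param lobulation surface-irregularity amplitude in `[0, 1)`: the local
#'   radius is modulated by up to this fraction.
#' @param tubule_count,tubule_radius,tubule_length thin straight bright
#'   cylinders; length is drawn uniformly from the given `(min, max)` um.
#' @param large_tube_count,large_tube_radius,large_tube_length bent bright
#'   tubes of glomerulus-scale volume (shape-screen decoys).
#' @param artifact_voxel_rate isolated bright voxels per 1000 voxels.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 256L, 256L),
                         spacing = c(2, 0.5, 0.5),
                         margin = c(3L, 10L, 10L),
                         background_level = c(5, 2),
                         tissue_level = c(80, 10),
                         glomerulus_count = 40L,
                         glomerulus_radius = c(8.5, 1),
                         lobulation = 0.15,
                         glomerulus_grey = c(190, 12),
                         tubule_count = 250L,
                         tubule_radius = 1.5,
                         tubule_length = c(15, 40),
                         tubule_grey = c(170, 12),
                         large_tube_count = 5L,
                         large_tube_radius = 4,
                         large_tube_length = 100,
                         artifact_voxel_rate = 0.05,
                         artifact_grey = c(230, 10),
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               margin = as.integer(margin),
               background_level = background_level,
               tissue_level = tissue_level,
               glomerulus_count = as.integer(glomerulus_count),
               glomerulus_radius = glomerulus_radius,
               lobulation = lobulation, glomerulus_grey = glomerulus_grey,
               tubule_count = as.integer(tubule_count),
               tubule_radius = tubule_radius, tubule_length = tubule_length,
               tubule_grey = tubule_grey,
               large_tube_count = as.integer(large_tube_count),
               large_tube_radius = large_tube_radius,
               large_tube_length = large_tube_length,
               artifact_voxel_rate = artifact_voxel_rate,
               artifact_grey = artifact_grey, seed = as.integer(seed))
  if (any(spec$spacing <= 0) || any(spec$shape < 8))
    glomseg_error("bad shape/spacing", "glomseg_bad_input")
  if (spec$glomerulus_grey[1] <= spec$tissue_level[1] +
      K_SD_DEFAULT * spec$tissue_level[2])
    glomseg_error(
      "glomerulus grey must exceed tissue mean + 3.29 * tissue sd",
      "glomseg_bad_input")
  if (spec$lobulation < 0 || spec$lobulation >= 1)
    glomseg_error("lobulation must be in [0, 1)", "glomseg_bad_input")
  counts <- c(spec$glomerulus_count, spec$tubule_count,
              spec$large_tube_count)
  if (any(counts < 0) || spec$glomerulus_radius[1] <= 0 ||
      spec$tubule_radius <= 0 || spec$large_tube_radius <= 0)
    glomseg_error("counts must be >= 0 and radii > 0", "glomseg_bad_input")
  structure(spec, class = "phantom_spec")
}

# class codes of the ground-truth class stack
PHANTOM_CLASSES <- c(background = 0L, tissue = 1L, glomerulus = 2L,
                     tubule = 3L, large_tube = 4L, artifact = 5L)

# linear indices of voxels within `radius` of segment p0-p1 (um coords),
# evaluated chunk-wise so bounding boxes stay small for oblique segments
.capsule_indices <- function(d, sp, p0, p1, radius) {
  seg <- p1 - p0
  len <- sqrt(sum(seg^2))
  n_chunk <- max(1L, ceiling(len / 4))
  u <- if (len > 0) seg / len else c(1, 0, 0)
  out <- vector("list", n_chunk)
  for (ch in seq_len(n_chunk)) {
    a <- p0 + seg * (ch - 1) / n_chunk
    b <- p0 + seg * ch / n_chunk
    lo <- pmin(a, b) - radius - sp
    hi <- pmax(a, b) + radius + sp
    iz <- max(1, floor(lo[1] / sp[1]) + 1):min(d[1], ceiling(hi[1] / sp[1]) + 1)
    iy <- max(1, floor(lo[2] / sp[2]) + 1):min(d[2], ceiling(hi[2] / sp[2]) + 1)
    ix <- max(1, floor(lo[3] / sp[3]) + 1):min(d[3], ceiling(hi[3] / sp[3]) + 1)
    g <- expand.grid(z = iz, y = iy, x = ix)
    P <- cbind((g$z - 1) * sp[1], (g$y - 1) * sp[2], (g$x - 1) * sp[3])
    W <- sweep(P, 2, p0)
    t <- pmin(pmax(W %*% u, 0), len)
    D2 <- rowSums((W - tcrossprod(t, u))^2)
    keep <- D2 <= radius^2
    out[[ch]] <- g$z[keep] + d[1] * (g$y[keep] - 1) +
      d[1] * d[2] * (g$x[keep] - 1)
  }
  unique(unlist(out))
}

# dilate a logical 3D array by one voxel under 26-connectivity
.dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(arr, dz, dy, dx) {
    res <- array(FALSE, d)
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    res[zs, ys, xs] <- arr[zs - dz, ys - dy, xs - dx]
    res
  }
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out | shift(m, dz, dy, dx)
  }
  out
}

#' Generate a synthetic phantom stack with ground truth
#'
#' Deterministic for a fixed spec (including its seed). Glomeruli are
#' rasterized as spheroids whose radius is perturbed by a smooth angular
#' modulation of amplitude `lobulation * radius` (globular but irregular
#' surfaces); centers are rejection-sampled so glomeruli never overlap and
#' never touch a stack face. Tubules are kept out of a one-voxel halo
#' around every glomerulus so ground-truth labels cannot merge with decoys
#' under 26-connectivity.
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (an 8-bit [voxel_stack]) and `truth`
#'   (a `ground_truth`: glomerulus `label_stack`, per-voxel `class_stack`,
#'   and `planted_params` with each glomerulus's center, nominal and
#'   equivalent radius, and true rasterized voxel volume).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    glomseg_error("expected a phantom_spec", "glomseg_bad_input")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  cls <- array(PHANTOM_CLASSES[["background"]], dim = d)
  mg <- spec$margin
  tz <- (mg[1] + 1):(d[1] - mg[1])
  ty <- (mg[2] + 1):(d[2] - mg[2])
  tx <- (mg[3] + 1):(d[3] - mg[3])
  cls[tz, ty, tx] <- PHANTOM_CLASSES[["tissue"]]
  # physical bounds of the tissue box
  tlo <- (c(tz[1], ty[1], tx[1]) - 1) * sp
  thi <- (c(tz[length(tz)], ty[length(ty)], tx[length(tx)]) - 1) * sp

  # ---- glomeruli ----------------------------------------------------------
  labels <- array(0L, dim = d)
  n_glom <- spec$glomerulus_count
  centers <- matrix(0, n_glom, 3)
  radii <- numeric(n_glom)
  if (n_glom > 0) {
    rmu <- spec$glomerulus_radius[1]; rsd <- spec$glomerulus_radius[2]
    for (g in seq_len(n_glom)) {
      r <- pmin(pmax(rnorm(1, rmu, rsd), rmu - 2.5 * rsd), rmu + 2.5 * rsd)
      placed <- FALSE
      for (att in seq_len(1000L)) {
        clearance <- r * (1 + spec$lobulation) + 2
        ctr <- tlo + clearance +
          runif(3) * pmax(thi - tlo - 2 * clearance, 0)
        if (any(thi - tlo < 2 * clearance)) break
        ok <- TRUE
        if (g > 1) {
          dd <- sqrt(rowSums(sweep(centers[seq_len(g - 1), , drop = FALSE],
                                   2, ctr)^2))
          ok <- all(dd > radii[seq_len(g - 1)] * (1 + spec$lobulation) +
                      clearance)
        }
        if (ok) { centers[g, ] <- ctr; radii[g] <- r; placed <- TRUE; break }
      }
      if (!placed)
        glomseg_error(sprintf(
          "could not place glomerulus %d without overlap: object density too high for the volume",
          g), "glomseg_placement")
    }
    for (g in seq_len(n_glom)) {
      r <- radii[g]; ctr <- centers[g, ]
      rmax <- r * (1 + spec$lobulation)
      iz <- max(1, floor((ctr[1] - rmax) / sp[1]) + 1):
        min(d[1], ceiling((ctr[1] + rmax) / sp[1]) + 1)
      iy <- max(1, floor((ctr[2] - rmax) / sp[2]) + 1):
        min(d[2], ceiling((ctr[2] + rmax) / sp[2]) + 1)
      ix <- max(1, floor((ctr[3] - rmax) / sp[3]) + 1):
        min(d[3], ceiling((ctr[3] + rmax) / sp[3]) + 1)
      grid <- expand.grid(z = iz, y = iy, x = ix)
      P <- cbind((grid$z - 1) * sp[1] - ctr[1],
                 (grid$y - 1) * sp[2] - ctr[2],
                 (grid$x - 1) * sp[3] - ctr[3])
      dist <- sqrt(rowSums(P^2))
      # smooth angular modulation: a few random cosine lobes
      nl <- 6L
      V <- matrix(rnorm(nl * 3), nl, 3)
      V <- V / sqrt(rowSums(V^2))
      amp <- rnorm(nl)
      ph <- runif(nl, 0, 2 * pi)
      U <- P / pmax(dist, 1e-9)
      f <- numeric(nrow(P))
      for (l in seq_len(nl))
        f <- f + amp[l] * cos(3 * (U %*% V[l, ]) + ph[l])
      f <- f / max(abs(f), 1e-9)
      inside <- dist <= r * (1 + spec$lobulation * f)
      lin <- grid$z[inside] + d[1] * (grid$y[inside] - 1) +
        d[1] * d[2] * (grid$x[inside] - 1)
      labels[lin] <- g
      cls[lin] <- PHANTOM_CLASSES[["glomerulus"]]
    }
  }

  # ---- tubules and large tubes -------------------------------------------
  # two-voxel halo: one voxel is not enough, the median filter can bridge
  # a single-voxel gap between a glomerulus and a touching tube
  forbidden <- if (n_glom > 0) .dilate1(.dilate1(labels > 0L)) else
    array(FALSE, dim = d)
  in_tissue_box <- array(FALSE, dim = d)
  in_tissue_box[tz, ty, tx] <- TRUE
  stamp <- function(lin, class_code) {
    lin <- lin[in_tissue_box[lin] & !forbidden[lin] &
                 cls[lin] != PHANTOM_CLASSES[["glomerulus"]]]
    cls[lin] <<- class_code
    lin
  }
  if (spec$tubule_count > 0) {
    for (t in seq_len(spec$tubule_count)) {
      p0 <- tlo + runif(3) * (thi - tlo)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- runif(1, spec$tubule_length[1], spec$tubule_length[2])
      p1 <- pmin(pmax(p0 + dir * len, tlo), thi)
      stamp(.capsule_indices(d, sp, p0, p1, spec$tubule_radius),
            PHANTOM_CLASSES[["tubule"]])
    }
  }
  if (spec$large_tube_count > 0) {
    for (t in seq_len(spec$large_tube_count)) {
      # bent tube: circular arc in a random plane
      c0 <- tlo + runif(3) * (thi - tlo)
      e1 <- rnorm(3); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- rnorm(3); e2 <- e2 - sum(e2 * e1) * e1
      e2 <- e2 / sqrt(sum(e2^2))
      arc_r <- 40
      theta <- seq(0, spec$large_tube_length / arc_r, length.out = 40)
      pts <- t(vapply(theta, function(th)
        c0 + arc_r * (cos(th) - 1) * e1 + arc_r * sin(th) * e2,
        numeric(3)))
      for (q in 1:3) pts[, q] <- pmin(pmax(pts[, q], tlo[q]), thi[q])
      for (s in seq_len(nrow(pts) - 1))
        stamp(.capsule_indices(d, sp, pts[s, ], pts[s + 1, ],
                               spec$large_tube_radius),
              PHANTOM_CLASSES[["large_tube"]])
    }
  }

  # ---- artifacts ----------------------------------------------------------
  n_art <- round(spec$artifact_voxel_rate * prod(d) / 1000)
  if (n_art > 0) {
    tissue_idx <- which(cls == PHANTOM_CLASSES[["tissue"]])
    art <- sample(tissue_idx, min(n_art, length(tissue_idx)))
    cls[art] <- PHANTOM_CLASSES[["artifact"]]
  }

  # ---- greys --------------------------------------------------------------
  grey <- array(0, dim = d)
  draw <- function(code, level) {
    idx <- which(cls == PHANTOM_CLASSES[[code]])
    if (length(idx)) grey[idx] <<- rnorm(length(idx), level[1], level[2])
    idx
  }
  draw("background", spec$background_level)
  draw("tissue", spec$tissue_level)
  draw("glomerulus", spec$glomerulus_grey)
  draw("tubule", spec$tubule_grey)
  draw("large_tube", spec$tubule_grey)
  draw("artifact", spec$artifact_grey)
  grey <- array(as.integer(pmin(pmax(round(grey), 0), 255)), dim = d)

  params <- if (n_glom > 0) {
    vol <- tabulate(labels[labels > 0L], n_glom) * voxel_volume(sp)
    data.frame(label = seq_len(n_glom),
               center_z = centers[, 1], center_y = centers[, 2],
               center_x = centers[, 3],
               nominal_radius = radii,
               true_voxel_volume = vol,
               equivalent_radius = (3 * vol / (4 * pi))^(1 / 3))
  } else {
    data.frame(label = integer(0), center_z = numeric(0),
               center_y = numeric(0), center_x = numeric(0),
               nominal_radius = numeric(0), true_voxel_volume = numeric(0),
               equivalent_radius = numeric(0))
  }
  truth <- structure(
    list(label_stack = structure(list(labels = labels,
                                      n_objects = n_glom, spacing = sp),
                                 class = "label_stack"),
         class_stack = cls,
         planted_params = params,
         spec = spec),
    class = "ground_truth")
  list(stack = voxel_stack(grey, sp, 8L), truth = truth)
}

#' Per-class greyscale histograms of a phantom
#'
#' Decomposes the stack's greyscale histogram by ground-truth class so the
#' Gaussian-fit stage can be checked against known class membership.
#' Classes with no voxels yield an all-zero curve.
#'
#' @param stack the phantom [voxel_stack].
#' @param truth its `ground_truth`.
#' @return Named list of [frequency_curve]s, one per class.
#' @export
histogram_of_truth <- function(stack, truth) {
  if (!identical(dim(stack$voxels), dim(truth$class_stack)))
    glomseg_error("stack and truth shapes differ", "glomseg_bad_input")
  out <- lapply(names(PHANTOM_CLASSES), function(nm) {
    idx <- truth$class_stack == PHANTOM_CLASSES[[nm]]
    frequency_curve(0:255,
                    tabulate(as.integer(stack$voxels[idx]) + 1L, 256L))
  })
  setNames(out, names(PHANTOM_CLASSES))
}
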