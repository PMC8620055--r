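# Volume- and shape-based screening of lectin-labelled objects.
#
# After greyscale segmentation most objects are small non-glomerular debris
# (peritubular capillary fragments, arteriolar segments, residual
# artifacts). Two successive screens remove them: a volume screen at an
# inflexion-point threshold of the object-volume distribution, then a shape
# screen on the Vobj/Vell ratio (object volume over the volume of its
# smallest enclosing ellipsoid), which is near 1 for globular glomeruli and
# low for elongated or bent tubes.

#' Per-object bookkeeping table
#'
#' One row per labelled object: voxel count, physical volume, centroid (um,
#' z/y/x), bounding box (voxel indices) and whether the object touches a
#' stack face (such objects have clipped morphology).
#'
#' @param labels a `label_stack`.
#' @return A data.frame with one row per label.
#' @export
object_table <- function(labels) {
  d <- dim(labels$labels)
  idx <- which(labels$labels > 0L)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), voxel_count = integer(0),
                      volume = numeric(0), centroid_z = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      zmin = integer(0), zmax = integer(0),
                      ymin = integer(0), ymax = integer(0),
                      xmin = integer(0), xmax = integer(0),
                      edge = logical(0)))
  lab <- labels$labels[idx]
  co <- arrayInd(idx, d)
  sp <- labels$spacing
  cnt <- tabulate(lab, labels$n_objects)
  sums <- rowsum(cbind(co[, 1], co[, 2], co[, 3]), lab)
  agg_min <- function(v) tapply(v, lab, min)
  agg_max <- function(v) tapply(v, lab, max)
  zmin <- agg_min(co[, 1]); zmax <- agg_max(co[, 1])
  ymin <- agg_min(co[, 2]); ymax <- agg_max(co[, 2])
  xmin <- agg_min(co[, 3]); xmax <- agg_max(co[, 3])
  vols <- cnt * voxel_volume(sp)
  data.frame(
    label = seq_len(labels$n_objects),
    voxel_count = cnt,
    volume = vols,
    centroid_z = (sums[, 1] / cnt - 1) * sp[1],
    centroid_y = (sums[, 2] / cnt - 1) * sp[2],
    centroid_x = (sums[, 3] / cnt - 1) * sp[3],
    zmin = as.integer(zmin), zmax = as.integer(zmax),
    ymin = as.integer(ymin), ymax = as.integer(ymax),
    xmin = as.integer(xmin), xmax = as.integer(xmax),
    edge = zmin == 1L | ymin == 1L | xmin == 1L |
      zmax == d[1] | ymax == d[2] | xmax == d[3]
  )
}

# extract an object's mask as a small padded subarray
.object_subarray <- function(labels, row, pad = 0L) {
  d <- dim(labels$labels)
  zr <- max(1, row$zmin - pad):min(d[1], row$zmax + pad)
  yr <- max(1, row$ymin - pad):min(d[2], row$ymax + pad)
  xr <- max(1, row$xmin - pad):min(d[3], row$xmax + pad)
  sub <- labels$labels[zr, yr, xr, drop = FALSE]
  list(mask = array(as.integer(sub == row$label), dim = dim(sub)),
       origin = c(zr[1], yr[1], xr[1]))
}

#' Object-volume frequency distribution
#'
#' Histogram of physical object volumes on a logarithmic volume axis
#' (objects span several decades); positions are geometric bin centres in
#' um^3.
#'
#' @param x a `label_stack` or an [object_table()] data.frame.
#' @param n_bins number of log-spaced bins (default 40).
#' @return A [frequency_curve].
#' @export
volume_distribution <- function(x, n_bins = 40L) {
  tab <- if (is.data.frame(x)) x else object_table(x)
  v <- tab$volume
  if (length(v) == 0)
    glomseg_error("no objects to build a volume distribution",
                  "glomseg_bad_input")
  if (length(unique(v)) == 1L)
    return(frequency_curve(v[1], length(v)))
  edges <- exp(seq(log(min(v)), log(max(v)), length.out = n_bins + 1))
  edges[1] <- edges[1] * (1 - 1e-9)
  edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-9)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  centers <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  frequency_curve(centers, counts)
}

#' Shape-ratio frequency distribution
#'
#' Linear binning on `[0, 1]`; positions are bin centres.
#'
#' @param ratios Vobj/Vell values.
#' @param n_bins number of bins (default 25).
#' @return A [frequency_curve].
#' @export
ratio_distribution <- function(ratios, n_bins = 25L) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(findInterval(pmin(ratios, 1 - 1e-12), edges), n_bins)
  frequency_curve((edges[-1] + edges[-(n_bins + 1)]) / 2, counts)
}

.screened <- function(kept_labels, threshold_used, stage, table) {
  if (length(kept_labels) == 0)
    glomseg_warning(sprintf("%s screen removed every object", stage),
                    "glomseg_empty_screen")
  structure(list(kept_labels = kept_labels, threshold_used = threshold_used,
                 stage = stage, table = table),
            class = "screened_objects")
}

#' @export
print.screened_objects <- function(x, ...) {
  cat(sprintf("<screened_objects> stage %s: %d kept (threshold %.4g)\n",
              x$stage, length(x$kept_labels), x$threshold_used))
  invisible(x)
}

#' Volume screen
#'
#' Keeps objects whose physical volume is strictly greater than
#' `min_volume`. When `min_volume` is `NULL` it is derived automatically as
#' an inflexion point of the log-binned volume distribution: the valley
#' between the debris and glomerulus populations when one exists, else the
#' curvature knee of the monotone curve.
#'
#' @param labels a `label_stack`.
#' @param min_volume um^3 cut-off, or `NULL` for automatic.
#' @param strategy inflexion strategy for the automatic cut-off:
#'   `"valley"`, `"knee"`, or `"auto"` (valley with knee fallback).
#' @param n_bins bins of the volume distribution.
#' @param smoothing_window passed to [find_inflexion()].
#' @return A `screened_objects` (stage `"volume"`).
#' @export
screen_by_volume <- function(labels, min_volume = NULL,
                             strategy = c("auto", "valley", "knee"),
                             n_bins = 40L, smoothing_window = 5L) {
  strategy <- match.arg(strategy)
  tab <- object_table(labels)
  if (is.null(min_volume)) {
    curve <- volume_distribution(tab, n_bins)
    min_volume <- .inflexion_with_fallback(curve, strategy, smoothing_window)
  }
  if (min_volume <= 0)
    glomseg_error("min_volume must be > 0", "glomseg_bad_input")
  kept <- tab$label[tab$volume > min_volume]
  .screened(kept, min_volume, "volume", tab)
}

.inflexion_with_fallback <- function(curve, strategy, smoothing_window) {
  if (strategy == "knee")
    return(find_inflexion(curve, "knee", smoothing_window))
  tryCatch(
    find_inflexion(curve, "valley", smoothing_window),
    glomseg_no_valley = function(e) {
      if (strategy == "valley") stop(e)
      find_inflexion(curve, "knee", smoothing_window)
    })
}

# -- Minimum-volume enclosing ellipsoid (Khachiyan) ------------------------

#' Minimum-volume enclosing ellipsoid of a point set
#'
#' Khachiyan's barycentric-coordinate ascent, run to a relative tolerance,
#' then scaled minimally so that every input point is contained (which makes
#' the reported volume a certified upper bound of the true minimum).
#' Degenerate sets (fewer than 4 points, or coplanar/collinear) are handled
#' by inflating each point to the 8 corners of its voxel, so the ellipsoid
#' volume is always positive.
#'
#' @param points n x 3 matrix of voxel centers in um (z, y, x).
#' @param tol relative convergence tolerance (default 1e-3).
#' @param spacing voxel spacing used for degenerate-set inflation; `NULL`
#'   disables inflation and errors on degenerate sets.
#' @param max_iter iteration cap.
#' @return List with `volume` (um^3), `center`, and shape matrix `A`
#'   (ellipsoid `{x : (x-c)' A (x-c) <= 1}`).
#' @export
enclosing_ellipsoid <- function(points, tol = 1e-3, spacing = NULL,
                                max_iter = 20000L) {
  P <- as.matrix(points)
  if (ncol(P) != 3) glomseg_error("points must be n x 3", "glomseg_bad_input")
  degenerate <- nrow(P) < 4 ||
    qr(sweep(P, 2, colMeans(P)))$rank < 3
  if (degenerate) {
    if (is.null(spacing))
      glomseg_error("degenerate point set and no spacing for inflation",
                    "glomseg_bad_input")
    P <- .inflate_corners(P, spacing)
    if (qr(sweep(P, 2, colMeans(P)))$rank < 3)
      glomseg_error("point set degenerate even after inflation",
                    "glomseg_bad_input")
  }
  n <- nrow(P)
  Q <- t(cbind(P, 1))                      # 4 x n
  u <- rep(1 / n, n)
  err <- Inf
  it <- 0L
  while (err > tol && it < max_iter) {
    X <- Q %*% (u * t(Q))                  # 4 x 4
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    maximum <- M[j]
    step <- (maximum - 4) / (4 * (maximum - 1))
    u <- u * (1 - step)
    u[j] <- u[j] + step
    err <- maximum / 4 - 1
    it <- it + 1L
  }
  ctr <- drop(crossprod(u, P))
  S <- crossprod(P, u * P) - tcrossprod(ctr)
  A <- solve(S) / 3
  # certify containment: scale so max quadratic form is exactly <= 1
  D <- sweep(P, 2, ctr)
  q <- rowSums((D %*% A) * D)
  s <- max(q, 1)
  A <- A / s
  vol <- 4 / 3 * pi / sqrt(det(A))
  list(volume = vol, center = ctr, A = A, iterations = it)
}

#' @rdname enclosing_ellipsoid
#' @export
enclosing_ellipsoid_volume <- function(points, tol = 1e-3, spacing = NULL,
                                       max_iter = 20000L) {
  enclosing_ellipsoid(points, tol, spacing, max_iter)$volume
}

# replace each center by the 8 corners of its voxel
.inflate_corners <- function(P, spacing) {
  h <- as.numeric(spacing) / 2
  offs <- as.matrix(expand.grid(z = c(-1, 1) * h[1], y = c(-1, 1) * h[2],
                                x = c(-1, 1) * h[3]))
  out <- matrix(0, nrow(P) * 8, 3)
  for (q in 1:8)
    out[seq(q, by = 8, length.out = nrow(P)), ] <-
      sweep(P, 2, offs[q, ], "+")
  out
}

#' Vobj/Vell shape ratio of a labelled object
#'
#' `Vobj` is the voxel-count volume. `Vell` is the volume of the smallest
#' ellipsoid enclosing the object's voxel solid: the enclosing ellipsoid of
#' the boundary-voxel centers is computed first, then minimally scaled to
#' cover every corner of every boundary voxel. Because the voxel solid is
#' then fully contained, the ratio lies in `(0, 1]`. Globular objects score
#' near 1; straight tubes near 0.37 (the box limit) and bent tubes lower.
#'
#' @param mask 3D 0/1 array holding the object (a tight subarray is fine).
#' @param spacing `(dz, dy, dx)` in um.
#' @param tol Khachiyan tolerance.
#' @return List with `ratio`, `v_obj` and `v_ell` (um^3).
#' @export
shape_ratio <- function(mask, spacing, tol = 1e-3) {
  d <- dim(mask)
  n_vox <- sum(mask)
  if (n_vox == 0) glomseg_error("empty object", "glomseg_bad_input")
  v_obj <- n_vox * voxel_volume(spacing)
  bidx <- boundary_voxels_cpp(as.integer(mask), d[1], d[2], d[3])
  co <- arrayInd(bidx, d)
  pts <- sweep(co - 1, 2, as.numeric(spacing), "*")
  if (nrow(pts) < 4 || qr(sweep(pts, 2, colMeans(pts)))$rank < 3) {
    ell <- enclosing_ellipsoid(pts, tol, spacing = spacing)
    v_ell <- ell$volume
  } else {
    # huge boundary sets (merged capillary networks) are thinned with a
    # deterministic stride before the Khachiyan iteration; the subsequent
    # corner-covering scale step uses every boundary voxel, so the result
    # is still a certified enclosing ellipsoid of the whole object
    fit_pts <- pts
    max_fit <- 6000L
    if (nrow(fit_pts) > max_fit)
      fit_pts <- fit_pts[seq(1, nrow(fit_pts),
                             length.out = max_fit), , drop = FALSE]
    ell <- enclosing_ellipsoid(fit_pts, tol)
    # scale minimally to cover all 8 corners of every boundary voxel
    corners <- .inflate_corners(pts, spacing)
    D <- sweep(corners, 2, ell$center)
    s <- max(rowSums((D %*% ell$A) * D), 1)
    v_ell <- ell$volume * s^1.5
  }
  list(ratio = v_obj / v_ell, v_obj = v_obj, v_ell = v_ell)
}

#' Shape screen
#'
#' Keeps objects whose Vobj/Vell ratio is strictly greater than
#' `min_ratio`. When `min_ratio` is `NULL` it is derived as the valley of
#' the ratio distribution (knee fallback under `strategy = "auto"`).
#'
#' @param labels the `label_stack` the objects live in.
#' @param screened a `screened_objects` from [screen_by_volume()] (its
#'   kept labels are the candidates).
#' @param min_ratio cut-off in (0, 1), or `NULL` for automatic.
#' @param strategy inflexion strategy (see [screen_by_volume()]).
#' @param n_bins bins of the ratio distribution.
#' @param smoothing_window passed to [find_inflexion()].
#' @param tol Khachiyan tolerance.
#' @return A `screened_objects` (stage `"shape"`) whose `table` gains
#'   `v_ell` and `ratio` columns for the candidate objects.
#' @export
screen_by_shape <- function(labels, screened, min_ratio = NULL,
                            strategy = c("auto", "valley", "knee"),
                            n_bins = 25L, smoothing_window = 3L,
                            tol = 1e-3) {
  strategy <- match.arg(strategy)
  tab <- screened$table
  cand <- screened$kept_labels
  tab$v_ell <- NA_real_
  tab$ratio <- NA_real_
  for (lb in cand) {
    row <- tab[tab$label == lb, ]
    sub <- .object_subarray(labels, row)
    sr <- shape_ratio(sub$mask, labels$spacing, tol)
    tab$v_ell[tab$label == lb] <- sr$v_ell
    tab$ratio[tab$label == lb] <- sr$ratio
  }
  if (is.null(min_ratio)) {
    curve <- ratio_distribution(tab$ratio[tab$label %in% cand], n_bins)
    min_ratio <- .inflexion_with_fallback(curve, strategy, smoothing_window)
  }
  if (min_ratio <= 0 || min_ratio >= 1)
    glomseg_error("min_ratio must be in (0, 1)", "glomseg_bad_input")
  kept <- intersect(cand, tab$label[!is.na(tab$ratio) & tab$ratio > min_ratio])
  .screened(kept, min_ratio, "shape", tab)
}

#' Export a per-stage object table as CSV
#' @param screened a `screened_objects`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screened, path) {
  tab <- screened$table
  tab$kept_flag <- tab$label %in% screened$kept_labels
  tab$stage <- screened$stage
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
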