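# Statistical thresholding: greyscale histograms, Gaussian fit of the
# self-fluorescent tissue population, and inflexion-point threshold
# detection. The lectin threshold is mean + 3.29 SD of the fitted tissue
# Gaussian: it excludes a fixed, operator-independent fraction of tissue
# voxels (Phi(3.29) ~ 0.9995) regardless of how bright a given sample is.

#' Constant multiplying the tissue SD in the lectin threshold
#' @export
K_SD_DEFAULT <- 3.29

#' Construct a frequency curve
#'
#' Ordered abscissa (grey level, object volume in um^3, or a dimensionless
#' ratio) with non-negative frequencies. Positions must be strictly
#' increasing. Single-bin curves are representable (they arise from
#' one-object volume distributions); operations that need structure, such
#' as [find_inflexion()], impose their own minimum length.
#'
#' @param positions numeric, strictly increasing.
#' @param frequencies numeric, non-negative, same length.
#' @return A `frequency_curve`.
#' @export
frequency_curve <- function(positions, frequencies) {
  positions <- as.numeric(positions)
  frequencies <- as.numeric(frequencies)
  if (length(positions) != length(frequencies) || length(positions) < 1)
    glomseg_error("positions/frequencies must be equal-length, non-empty",
                  "glomseg_bad_input")
  if (any(diff(positions) <= 0))
    glomseg_error("positions must be strictly increasing", "glomseg_bad_input")
  if (any(frequencies < 0) || any(!is.finite(frequencies)))
    glomseg_error("frequencies must be finite and >= 0", "glomseg_bad_input")
  structure(list(positions = positions, frequencies = frequencies),
            class = "frequency_curve")
}

#' @export
print.frequency_curve <- function(x, ...) {
  cat(sprintf("<frequency_curve> %d positions in [%.4g, %.4g], total mass %.4g\n",
              length(x$positions), min(x$positions), max(x$positions),
              sum(x$frequencies)))
  invisible(x)
}

#' Write / read a frequency curve as 2-column CSV
#' @param curve a [frequency_curve].
#' @param path CSV path.
#' @return `path` invisibly / a [frequency_curve].
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(data.frame(position = curve$positions,
                       frequency = curve$frequencies),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  d <- read.csv(path)
  frequency_curve(d[[1]], d[[2]])
}

#' Greyscale histogram of an 8-bit stack
#'
#' 256-position frequency curve over grey levels 0..255. Frequencies sum to
#' the total voxel count.
#'
#' @param stack an 8-bit [voxel_stack].
#' @return A [frequency_curve].
#' @export
grey_histogram <- function(stack) {
  if (!inherits(stack, "voxel_stack") || stack$bit_depth != 8L)
    glomseg_error("grey_histogram needs an 8-bit voxel_stack",
                  "glomseg_bad_input")
  frequency_curve(0:255, tabulate(as.integer(stack$voxels) + 1L, 256L))
}

# centered moving average; partial windows at the edges
.smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  h <- window %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# local maxima of a smoothed curve, endpoints included, plateaus collapsed
# to their centre; returns indices ordered by decreasing height
.find_peaks <- function(s) {
  n <- length(s)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || s[i] >= s[i - 1]
    right_ok <- i == n || s[i] >= s[i + 1]
    is_peak[i] <- left_ok && right_ok
  }
  # collapse runs of equal-height contiguous peaks; zero-height plateaus
  # (e.g. empty histogram tails) are not populations and never count
  idx <- which(is_peak & s > 0)
  if (length(idx) == 0) return(integer(0))
  runs <- split(idx, cumsum(c(1, diff(idx) != 1 | s[idx[-1]] != s[idx[-length(idx)]])))
  centers <- vapply(runs, function(r) r[ceiling(length(r) / 2)], 0L)
  centers[order(s[centers], decreasing = TRUE)]
}

#' Locate an inflexion-point threshold on a frequency curve
#'
#' Two operationalizations are provided because curves of different stages
#' have different shapes. `"valley"` smooths the curve with a centered
#' moving average and returns the position of the minimum between the two
#' largest local maxima; it suits bimodal curves (background vs tissue grey
#' levels, tube vs glomerulus shape ratios). `"knee"` returns the position
#' of maximum discrete curvature of the smoothed `log(1 + frequency)`
#' curve; it suits monotone-decreasing curves with no interior valley
#' (object-volume distributions dominated by small debris).
#'
#' @param curve a [frequency_curve].
#' @param strategy `"valley"` or `"knee"`.
#' @param smoothing_window odd integer, moving-average width in bins.
#' @return The threshold position (same units as `curve$positions`).
#'   `"valley"` signals a condition of class `glomseg_no_valley` when the
#'   curve has no interior valley; callers may retry with `"knee"`.
#' @export
find_inflexion <- function(curve, strategy = c("valley", "knee"),
                           smoothing_window = 5L) {
  strategy <- match.arg(strategy)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    glomseg_error("smoothing_window must be odd and >= 1", "glomseg_bad_input")
  n <- length(curve$positions)
  if (n < 2L * smoothing_window)
    glomseg_error("curve too short for the smoothing window",
                  "glomseg_bad_input")
  f <- curve$frequencies
  if (strategy == "valley") {
    s <- .smooth_ma(f, smoothing_window)
    peaks <- .find_peaks(s)
    # a population must be more than sampling noise on another one's flank:
    # secondary peaks below 0.5% of the main peak height do not count
    if (length(peaks) > 1)
      peaks <- peaks[s[peaks] >= 0.005 * s[peaks[1]]]
    if (length(peaks) < 2)
      glomseg_error("no valley: curve has fewer than two populations",
                    "glomseg_no_valley")
    # among adjacent peak pairs, take the most prominent separation:
    # valley depth relative to the smaller peak (ties: tallest pair).
    # On a genuinely bimodal curve this is the valley between the two
    # largest maxima; on multi-modal curves it finds the population gap
    # instead of a dip inside one population.
    peaks <- sort(peaks)
    best <- NULL
    for (q in seq_len(length(peaks) - 1)) {
      p1 <- peaks[q]; p2 <- peaks[q + 1]
      if (p2 - p1 < 2) next
      inner <- (p1 + 1):(p2 - 1)
      depth <- min(s[inner])
      hmin <- min(s[p1], s[p2])
      score <- (hmin - depth) / hmin
      tall <- s[p1] + s[p2]
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 && tall > best$tall)) {
        best <- list(score = score, tall = tall, inner = inner,
                     depth = depth)
      }
    }
    if (is.null(best) || best$score <= 0)
      glomseg_error("no valley: dominant peaks are adjacent",
                    "glomseg_no_valley")
    ties <- best$inner[s[best$inner] == best$depth]
    curve$positions[ties[ceiling(length(ties) / 2)]]
  } else {
    s <- .smooth_ma(log1p(f), smoothing_window)
    # curvature in bin-index space; exclude 2 bins at each end where the
    # finite differences are one-sided
    d1 <- c(s[2] - s[1], (s[3:n] - s[1:(n - 2)]) / 2, s[n] - s[n - 1])
    d2 <- c(0, s[3:n] - 2 * s[2:(n - 1)] + s[1:(n - 2)], 0)
    kappa <- abs(d2) / (1 + d1^2)^1.5
    interior <- 3:(n - 2)
    curve$positions[interior[which.max(kappa[interior])]]
  }
}

#' Gaussian fit of a frequency curve
#'
#' Least-squares fit of `F = amplitude * exp(-0.5 * ((x - mean) / sd)^2)`
#' over a restricted position range, as used both for the tissue greyscale
#' population and for per-glomerulus parameter distributions. The start is
#' derivative-free and deterministic: amplitude and mean from the in-range
#' peak, sd from the half-width at half maximum.
#'
#' @param curve a [frequency_curve].
#' @param fit_range `c(low, high)` positions delimiting the fitted range;
#'   `NULL` fits the whole curve.
#' @return A `gaussian_fit` with fields `amplitude`, `mean`, `sd`,
#'   `r_squared` and the `fit_range` used.
#' @export
fit_gaussian <- function(curve, fit_range = NULL) {
  x <- curve$positions
  f <- curve$frequencies
  if (!is.null(fit_range)) {
    keep <- x >= fit_range[1] & x <= fit_range[2]
    x <- x[keep]; f <- f[keep]
  }
  if (sum(f > 0) < 5)
    glomseg_error("fit range must contain >= 5 positions with frequency > 0",
                  "glomseg_fit_error")
  a0 <- max(f)
  m0 <- x[which.max(f)]
  half <- which(f >= a0 / 2)
  hwhm <- max(abs(x[half] - m0))
  s0 <- max(hwhm / 1.1774, diff(range(x)) / 100, 1e-6)
  fit <- tryCatch(
    nls(f ~ A * exp(-0.5 * ((x - m) / s)^2),
        start = list(A = a0, m = m0, s = s0),
        algorithm = "port",
        lower = c(A = 1e-12, m = min(x) - diff(range(x)),
                  s = 1e-9),
        control = list(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct SSE minimization from the same start
    obj <- function(p) {
      if (p[3] <= 0) return(1e300)
      sum((f - p[1] * exp(-0.5 * ((x - p[2]) / p[3])^2))^2)
    }
    op <- stats::optim(c(a0, m0, s0), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    if (op$convergence != 0)
      glomseg_error(
        sprintf("Gaussian fit failed to converge (start A=%.3g m=%.3g s=%.3g)",
                a0, m0, s0),
        "glomseg_fit_error")
    pars <- c(A = op$par[1], m = op$par[2], s = abs(op$par[3]))
  } else {
    pars <- coef(fit)
  }
  if (pars["s"] <= 0 || pars["A"] <= 0)
    glomseg_error("Gaussian fit collapsed (sd or amplitude <= 0)",
                  "glomseg_fit_error")
  pred <- pars["A"] * exp(-0.5 * ((x - pars["m"]) / pars["s"])^2)
  sstot <- sum((f - mean(f))^2)
  r2 <- if (sstot > 0) 1 - sum((f - pred)^2) / sstot else 1
  structure(
    list(amplitude = unname(pars["A"]), mean = unname(pars["m"]),
         sd = unname(pars["s"]), r_squared = max(0, min(1, r2)),
         fit_range = if (is.null(fit_range)) range(x) else fit_range),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> amplitude %.4g, mean %.4g, sd %.4g, R^2 %.4f\n",
              x$amplitude, x$mean, x$sd, x$r_squared))
  invisible(x)
}

#' Lectin threshold from a tissue Gaussian fit
#'
#' `mean + k * sd` of the fitted tissue population, continuous (voxels are
#' later kept when strictly above it). With the default `k = 3.29` the
#' expected fraction of tissue voxels above the threshold is
#' `1 - pnorm(3.29)` (about 5e-4), so at least 99.5% of non-labelled voxels
#' are excluded whatever the sample's brightness.
#'
#' @param fit a `gaussian_fit` of the tissue population.
#' @param k SD multiplier (default [K_SD_DEFAULT]).
#' @return Continuous grey-level threshold.
#' @export
lectin_threshold <- function(fit, k = K_SD_DEFAULT) {
  if (!inherits(fit, "gaussian_fit"))
    glomseg_error("expected a gaussian_fit", "glomseg_bad_input")
  thr <- fit$mean + k * fit$sd
  if (thr >= 255)
    glomseg_error(
      sprintf("tissue population saturates dynamic range (threshold %.1f >= 255)",
              thr),
      "glomseg_saturated")
  thr
}

#' Background threshold between mounting medium and tissue
#'
#' Valley of the greyscale histogram between the dark mounting-medium spike
#' and the self-fluorescent tissue bell.
#'
#' @param curve greyscale [frequency_curve] of an 8-bit stack.
#' @param smoothing_window odd moving-average width (bins).
#' @return Grey-level threshold.
#' @export
background_threshold <- function(curve, smoothing_window = 5L) {
  find_inflexion(curve, "valley", smoothing_window)
}

#' Default Gaussian fit range for the tissue population
#'
#' From the background threshold up the right flank to the first grey level
#' where frequency drops below 1% of the tissue peak, so that the bright
#' lectin tail does not bias the fit.
#'
#' @param curve greyscale [frequency_curve].
#' @param background_grey background/tissue threshold.
#' @return `c(low, high)` grey levels.
#' @export
tissue_fit_range <- function(curve, background_grey) {
  x <- curve$positions
  f <- curve$frequencies
  in_tissue <- x > background_grey
  if (!any(in_tissue))
    glomseg_error("no positions above the background threshold",
                  "glomseg_bad_input")
  peak_i <- which(in_tissue)[which.max(f[in_tissue])]
  cutoff <- f[peak_i] * 0.01
  right <- which(x > x[peak_i] & f < cutoff)
  hi <- if (length(right)) x[min(right)] else max(x)
  c(background_grey, hi)
}

#' Bundle the four derived thresholds
#'
#' @param background_grey grey level separating mounting medium from tissue.
#' @param lectin_grey grey level `mean + k*sd` of the tissue fit.
#' @param min_volume um^3 cut-off of the volume screen.
#' @param min_ratio Vobj/Vell cut-off of the shape screen.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(background_grey, lectin_grey, min_volume,
                          min_ratio) {
  if (!(background_grey >= 0 && background_grey < lectin_grey &&
        lectin_grey <= 255))
    glomseg_error("need 0 <= background_grey < lectin_grey <= 255",
                  "glomseg_bad_input")
  if (min_volume <= 0) glomseg_error("min_volume must be > 0",
                                     "glomseg_bad_input")
  if (min_ratio <= 0 || min_ratio >= 1)
    glomseg_error("min_ratio must be in (0, 1)", "glomseg_bad_input")
  structure(list(background_grey = background_grey, lectin_grey = lectin_grey,
                 min_volume = min_volume, min_ratio = min_ratio),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("<threshold_set> background %.2f, lectin %.2f, ",
                     "min volume %.4g um^3, min ratio %.3f\n"),
              x$background_grey, x$lectin_grey, x$min_volume, x$min_ratio))
  invisible(x)
}
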