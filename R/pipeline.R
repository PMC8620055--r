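# End-to-end orchestration and validation against ground truth.

#' Pipeline configuration
#'
#' Every automatically derived quantity can be overridden; precedence is
#' caller override > automatic derivation. Overridden thresholds are
#' echoed in the run report's provenance so the analysis remains auditable.
#'
#' @param k_sd SD multiplier of the lectin threshold (default 3.29).
#' @param median_window 3D median filter width (voxels per axis).
#' @param connectivity 6 or 26.
#' @param surface_method `"mesh"` or `"faces"` (see [surface_area()]).
#' @param smooth_sigma mesh pre-smoothing sigma, voxels.
#' @param smoothing_window histogram smoothing for inflexion detection.
#' @param volume_strategy,shape_strategy inflexion strategy per stage
#'   (`"auto"`, `"valley"`, `"knee"`).
#' @param n_bins_volume,n_bins_ratio histogram bins of the two screens.
#' @param background_grey,lectin_grey,min_volume,min_ratio manual
#'   threshold overrides (`NULL` = derive automatically).
#' @param exclude_edge exclude edge-touching objects from morphometric
#'   means.
#' @param mvee_tol Khachiyan tolerance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_sd = K_SD_DEFAULT, median_window = 3L,
                            connectivity = 26L,
                            surface_method = "mesh", smooth_sigma = 1.0,
                            smoothing_window = 5L,
                            volume_strategy = "auto",
                            shape_strategy = "auto",
                            n_bins_volume = 40L, n_bins_ratio = 25L,
                            background_grey = NULL, lectin_grey = NULL,
                            min_volume = NULL, min_ratio = NULL,
                            exclude_edge = TRUE, mvee_tol = 1e-3) {
  structure(as.list(environment()), class = "pipeline_config")
}

.empty_report <- function(config, diagnostics) {
  structure(list(
    thresholds = NULL, stage_counts = c(grey = 0L, volume = 0L, shape = 0L),
    objects = data.frame(), summary = NULL, distributions = list(),
    diagnostics = diagnostics,
    provenance = list(config = unclass(config),
                      package_version = as.character(packageVersion("glomseg")))
  ), class = "run_report")
}

#' Run the full identification pipeline on a stack
#'
#' Executes, in order: 8-bit conversion, greyscale histogram, background
#' (mounting-medium/tissue) threshold, Gaussian fit of the tissue
#' population, lectin threshold at `mean + k_sd * sd`, binarization, 3D
#' median filtering, connected-component labelling, volume screen, shape
#' screen, per-object morphometry, per-sample summary, and Gaussian fits
#' of the per-glomerulus parameter distributions (when at least 10
#' glomeruli remain). Every derived threshold and per-stage object count
#' is recorded.
#'
#' @param stack an 8- or 16-bit [voxel_stack].
#' @param config a [pipeline_config()].
#' @return A `run_report`. A stack with no detectable tissue/background
#'   structure yields a report with zero objects and a diagnostic, not an
#'   error.
#' @export
run_pipeline <- function(stack, config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, glomseg_error = function(e) {
      glomseg_error(sprintf("stage %s: %s", name, conditionMessage(e)),
                    class(e)[1])
    })
  }
  stack8 <- stage("to_8bit", to_8bit(stack))
  curve <- stage("grey_histogram", grey_histogram(stack8))
  bg <- config$background_grey
  if (is.null(bg)) {
    bg <- tryCatch(
      background_threshold(curve, config$smoothing_window),
      glomseg_no_valley = function(e) e)
    if (inherits(bg, "condition"))
      return(.empty_report(config, paste("background threshold:",
                                         conditionMessage(bg))))
  }
  if (is.null(config$lectin_grey)) {
    fit <- stage("fit_gaussian",
                 fit_gaussian(curve, tissue_fit_range(curve, bg)))
    lectin <- stage("lectin_threshold", lectin_threshold(fit, config$k_sd))
  } else {
    fit <- NULL
    lectin <- config$lectin_grey
  }
  tissue_mask <- stage("binarize", binarize(stack8, bg))
  lectin_mask <- stage("binarize", binarize(stack8, lectin))
  filtered <- stage("median_filter_3d",
                    median_filter_3d(lectin_mask, config$median_window))
  labels <- stage("label_components",
                  label_components(filtered, config$connectivity))
  n_grey <- labels$n_objects
  if (n_grey == 0)
    return(.empty_report(config, "no objects above the lectin threshold"))
  vol_screen <- stage("screen_by_volume", withCallingHandlers(
    screen_by_volume(labels, config$min_volume, config$volume_strategy,
                     config$n_bins_volume, config$smoothing_window),
    glomseg_empty_screen = function(w) invokeRestart("muffleWarning")))
  shape_screen <- if (length(vol_screen$kept_labels)) {
    stage("screen_by_shape", withCallingHandlers(
      screen_by_shape(labels, vol_screen, config$min_ratio,
                      config$shape_strategy, config$n_bins_ratio,
                      smoothing_window = 3L, tol = config$mvee_tol),
      glomseg_empty_screen = function(w) invokeRestart("muffleWarning")))
  } else {
    .screened(integer(0), NA_real_, "shape", vol_screen$table)
  }
  kept <- shape_screen$kept_labels
  thresholds <- tryCatch(
    threshold_set(bg, lectin, vol_screen$threshold_used,
                  min(max(shape_screen$threshold_used, 1e-6), 1 - 1e-6)),
    glomseg_error = function(e) NULL)
  objects <- if (length(kept)) {
    stage("object_morphometry",
          object_morphometry(labels, kept, config$surface_method,
                             config$smooth_sigma, config$mvee_tol,
                             screen_table = shape_screen$table))
  } else data.frame()
  summary <- if (length(kept)) {
    stage("sample_summary",
          sample_summary(objects, tissue_mask, config$exclude_edge))
  } else NULL
  meas <- if (length(kept) && config$exclude_edge)
    objects[!objects$edge, , drop = FALSE] else objects
  dists <- list()
  if (nrow(meas) >= 10) {
    for (p in c("surface", "volume", "compactness")) {
      dists[[p]] <- tryCatch(
        parameter_distribution(meas[[p]], parameter_name = p),
        glomseg_error = function(e) NULL)
    }
  }
  structure(list(
    thresholds = thresholds,
    tissue_fit = fit,
    stage_counts = c(grey = n_grey,
                     volume = length(vol_screen$kept_labels),
                     shape = length(kept)),
    labels = labels,
    kept_labels = kept,
    tissue_mask = tissue_mask,
    objects = objects,
    summary = summary,
    distributions = dists,
    diagnostics = character(0),
    provenance = list(
      config = unclass(config),
      derived = list(background_grey = bg, lectin_grey = lectin,
                     min_volume = vol_screen$threshold_used,
                     min_ratio = shape_screen$threshold_used),
      overridden = names(Filter(Negate(is.null),
                                unclass(config)[c("background_grey",
                                                  "lectin_grey",
                                                  "min_volume",
                                                  "min_ratio")])),
      package_version = as.character(packageVersion("glomseg")))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  stage counts:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$thresholds)) print(x$thresholds)
  if (!is.null(x$summary)) print(x$summary)
  if (length(x$diagnostics)) cat("  diagnostics:", x$diagnostics, "\n")
  invisible(x)
}

#' Score detected glomeruli against ground truth
#'
#' Greedy nearest-centroid matching within `match_radius`: detected and
#' reference centroids are paired closest-first, each at most once.
#' Detections with no matched reference are false positives; references
#' with no matched detection are false negatives; both are normalized to
#' the reference count and expressed as percentages.
#'
#' @param detected a `run_report`, or a list with `labels` (`label_stack`)
#'   and `kept_labels`.
#' @param truth a `ground_truth`.
#' @param match_radius um; default is the mean planted glomerulus radius.
#' @return A `validation_report`.
#' @export
validate_detection <- function(detected, truth, match_radius = NULL) {
  if (!identical(dim(detected$labels$labels),
                 dim(truth$label_stack$labels)))
    glomseg_error("detected and truth stacks have different shapes",
                  "glomseg_bad_input")
  if (is.null(match_radius))
    match_radius <- mean(truth$planted_params$nominal_radius)
  det_tab <- object_table(detected$labels)
  det_tab <- det_tab[det_tab$label %in% detected$kept_labels, , drop = FALSE]
  tp <- truth$planted_params
  n_truth <- nrow(tp)
  n_det <- nrow(det_tab)
  if (n_truth == 0)
    glomseg_error("ground truth contains no glomeruli", "glomseg_bad_input")
  dm <- matrix(Inf, n_det, n_truth)
  for (q in seq_len(n_det))
    dm[q, ] <- sqrt((det_tab$centroid_z[q] - tp$center_z)^2 +
                      (det_tab$centroid_y[q] - tp$center_y)^2 +
                      (det_tab$centroid_x[q] - tp$center_x)^2)
  pairs <- which(dm <= match_radius, arr.ind = TRUE)
  matches <- data.frame(truth_label = integer(0), detected_label = integer(0),
                        distance = numeric(0))
  if (nrow(pairs)) {
    ord <- order(dm[pairs])
    used_d <- logical(n_det); used_t <- logical(n_truth)
    for (q in ord) {
      di <- pairs[q, 1]; ti <- pairs[q, 2]
      if (used_d[di] || used_t[ti]) next
      used_d[di] <- TRUE; used_t[ti] <- TRUE
      matches <- rbind(matches, data.frame(
        truth_label = tp$label[ti], detected_label = det_tab$label[di],
        distance = dm[di, ti]))
    }
  }
  fp <- n_det - nrow(matches)
  fn <- n_truth - nrow(matches)
  structure(list(
    n_truth = n_truth, n_detected = n_det,
    false_positive_pct = 100 * fp / n_truth,
    false_negative_pct = 100 * fn / n_truth,
    matches = matches, match_radius = match_radius
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d truth, %d detected: FP %.2f%%, FN %.2f%%\n",
    x$n_truth, x$n_detected, x$false_positive_pct, x$false_negative_pct))
  invisible(x)
}

#' Write a run report as JSON (+ CSV object table)
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    thresholds = if (!is.null(report$thresholds))
      unclass(report$thresholds),
    stage_counts = as.list(report$stage_counts),
    summary = if (!is.null(report$summary)) {
      s <- unclass(report$summary)
      s$mean_sd_surface <- as.list(s$mean_sd_surface)
      s$mean_sd_volume <- as.list(s$mean_sd_volume)
      s$mean_sd_compactness <- as.list(s$mean_sd_compactness)
      s
    },
    distributions = lapply(report$distributions, function(dd) {
      if (is.null(dd)) return(NULL)
      list(parameter = dd$parameter_name, n = dd$n_objects,
           amplitude = dd$fit$amplitude, mean = dd$fit$mean,
           sd = dd$fit$sd, r_squared = dd$fit$r_squared,
           poor_fit = dd$poor_fit)
    }),
    diagnostics = report$diagnostics,
    provenance = report$provenance
  )
  path <- file.path(dir, "run_report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (nrow(report$objects) > 0)
    write.csv(report$objects, file.path(dir, "objects.csv"),
              row.names = FALSE)
  invisible(path)
}
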