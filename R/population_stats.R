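# Relative-frequency distributions of per-glomerulus parameters and their
# Gaussian fits (same fitting engine as the greyscale stage).

#' Relative-frequency distribution of a glomerular parameter with
#' Gaussian fit
#'
#' Histograms the values over `[min, max]` with `n_bins` equal-width bins,
#' converts counts to relative frequencies (%), and fits
#' `F = A * exp(-0.5 * ((P - mu) / sigma)^2)` to the bin centres with
#' [fit_gaussian()]. Fifteen bins match the granularity at which such
#' distributions are usually plotted.
#'
#' @param values per-glomerulus values (surface um^2, volume um^3, or
#'   dimensionless compactness); at least 10.
#' @param n_bins equal-width bins (default 15).
#' @param parameter_name label stored with the result.
#' @return A `parameter_distribution` with `curve` (relative frequencies,
#'   summing to 100), `fit`, `n_objects`, `parameter_name`, and a
#'   `poor_fit` flag when the Gaussian explains the histogram badly
#'   (R^2 < 0.9).
#' @export
parameter_distribution <- function(values, n_bins = 15L,
                                   parameter_name = "parameter") {
  values <- as.numeric(values)
  if (length(values) < 10)
    glomseg_error("need at least 10 values", "glomseg_bad_input")
  if (diff(range(values)) == 0)
    glomseg_error("degenerate spread: all values are equal",
                  "glomseg_bad_input")
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  edges[1] <- edges[1] - abs(edges[1]) * 1e-12 - 1e-300
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     n_bins)
  rel <- 100 * counts / length(values)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  curve <- frequency_curve(centers, rel)
  fit <- fit_gaussian(curve)
  structure(list(parameter_name = parameter_name, curve = curve, fit = fit,
                 n_objects = length(values),
                 poor_fit = fit$r_squared < 0.9),
            class = "parameter_distribution")
}

#' @export
print.parameter_distribution <- function(x, ...) {
  cat(sprintf(
    "<parameter_distribution> %s, n = %d: mu %.4g, sigma %.4g, R^2 %.3f%s\n",
    x$parameter_name, x$n_objects, x$fit$mean, x$fit$sd, x$fit$r_squared,
    if (x$poor_fit) " (poor fit)" else ""))
  invisible(x)
}
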