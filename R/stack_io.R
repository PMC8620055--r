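# Stack containers and TIFF I/O.
#
# No TIFF reader is available among the package's allowed dependencies, so a
# minimal baseline-TIFF codec is implemented here: uncompressed, greyscale,
# 8- or 16-bit, single- or multi-page, either byte order on input. That is
# exactly the class of file a light-sheet stack export produces after
# greyscale conversion; anything fancier (compression, RGB, tiles) is
# rejected with a clear error rather than mis-read.

#' Construct a voxel stack
#'
#' A `voxel_stack` couples a 3D greyscale lattice with its physical voxel
#' spacing. Axis order is fixed as (z, y, x), matching the page-major layout
#' of a multi-page TIFF; `spacing` is stored in the same order, in
#' micrometres. Typical light-sheet geometry is `c(2, 0.5, 0.5)`, i.e. a
#' 0.5 um lateral pixel and a 2 um step between planes (voxel volume
#' 0.5 um^3).
#'
#' @param voxels 3D integer array, dim `(nz, ny, nx)`, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param spacing numeric length-3, `(dz, dy, dx)` in micrometres, all > 0.
#' @param bit_depth 8 or 16.
#' @return A `voxel_stack` object.
#' @export
voxel_stack <- function(voxels, spacing, bit_depth = 8L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    glomseg_error("voxels must be a 3D array (z, y, x)", "glomseg_bad_input")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    glomseg_error("spacing must be 3 positive numbers (dz, dy, dx)",
                  "glomseg_bad_input")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    glomseg_error("bit_depth must be 8 or 16", "glomseg_bad_input")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    glomseg_error("grey values outside [0, 2^bit_depth - 1]",
                  "glomseg_bad_input")
  structure(
    list(voxels = voxels, spacing = spacing, bit_depth = bit_depth),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<voxel_stack> %d x %d x %d voxels (z,y,x), %d-bit, spacing %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$bit_depth, x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical volume of one voxel, in cubic micrometres
#' @param spacing `(dz, dy, dx)` in micrometres, or an object carrying
#'   a `spacing` field.
#' @return Voxel volume in um^3.
#' @export
voxel_volume <- function(spacing) {
  if (is.list(spacing)) spacing <- spacing$spacing
  prod(spacing)
}

# -- TIFF plumbing ---------------------------------------------------------

# tag ids used by the baseline writer/reader
.TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples = 277L,
  rows_per_strip = 278L, strip_bytes = 279L
)

.read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

.tiff_read_ifd <- function(raw, off, endian) {
  n <- .read_uint(raw, off, 2, endian)
  entries <- vector("list", n)
  for (e in seq_len(n)) {
    base <- off + 2 + (e - 1) * 12
    tag <- .read_uint(raw, base, 2, endian)
    typ <- .read_uint(raw, base + 2, 2, endian)
    cnt <- .read_uint(raw, base + 4, 4, endian)
    tsize <- c(1, 1, 2, 4, 8)[typ]
    if (is.na(tsize)) tsize <- 4
    nbytes <- tsize * cnt
    vals <- if (nbytes <= 4) {
      vapply(seq_len(cnt), function(q)
        .read_uint(raw, base + 8 + (q - 1) * tsize, tsize, endian), 0)
    } else {
      ptr <- .read_uint(raw, base + 8, 4, endian)
      vapply(seq_len(cnt), function(q)
        .read_uint(raw, ptr + (q - 1) * tsize, tsize, endian), 0)
    }
    entries[[e]] <- list(tag = tag, values = vals)
  }
  next_off <- .read_uint(raw, off + 2 + n * 12, 4, endian)
  list(entries = entries, next_offset = next_off)
}

.ifd_tag <- function(ifd, tag, default = NULL) {
  for (e in ifd$entries) if (e$tag == tag) return(e$values)
  default
}

#' Read a greyscale TIFF stack
#'
#' Reads a single- or multi-page uncompressed greyscale TIFF (8- or 16-bit,
#' little- or big-endian) into a [voxel_stack]. Page order maps to z. TIFF
#' files do not reliably carry physical voxel geometry, so spacing is
#' supplied by the caller.
#'
#' @param path path to the TIFF file.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @return A [voxel_stack].
#' @export
read_stack <- function(path, spacing) {
  if (!file.exists(path))
    glomseg_error(paste0("cannot read file: ", path), "glomseg_io_error")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8)
    glomseg_error("not a TIFF file (truncated header)", "glomseg_io_error")
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    glomseg_error("not a TIFF file (bad byte-order mark)", "glomseg_io_error")
  if (.read_uint(raw, 2, 2, endian) != 42)
    glomseg_error("not a TIFF file (bad magic)", "glomseg_io_error")
  off <- .read_uint(raw, 4, 4, endian)
  pages <- list()
  shape <- NULL
  bits <- NULL
  while (off != 0) {
    ifd <- .tiff_read_ifd(raw, off, endian)
    w <- .ifd_tag(ifd, .TIFF_TAGS["width"])
    h <- .ifd_tag(ifd, .TIFF_TAGS["length"])
    b <- .ifd_tag(ifd, .TIFF_TAGS["bits"], 1)
    comp <- .ifd_tag(ifd, .TIFF_TAGS["compression"], 1)
    phot <- .ifd_tag(ifd, .TIFF_TAGS["photometric"], 1)
    spp <- .ifd_tag(ifd, .TIFF_TAGS["samples"], 1)
    so <- .ifd_tag(ifd, .TIFF_TAGS["strip_offsets"])
    sb <- .ifd_tag(ifd, .TIFF_TAGS["strip_bytes"])
    if (is.null(w) || is.null(h) || is.null(so))
      glomseg_error("malformed TIFF page (missing required tags)",
                    "glomseg_io_error")
    if (comp[1] != 1)
      glomseg_error("compressed TIFF not supported", "glomseg_io_error")
    if (spp[1] != 1 || phot[1] > 1 || length(b) > 1)
      glomseg_error("non-greyscale TIFF (RGB/palette) rejected",
                    "glomseg_io_error")
    if (!b[1] %in% c(8, 16))
      glomseg_error("only 8- and 16-bit greyscale TIFF supported",
                    "glomseg_io_error")
    if (is.null(shape)) {
      shape <- c(h, w); bits <- b[1]
    } else if (!identical(shape, c(h, w)) || bits != b[1]) {
      glomseg_error("inconsistent page shapes or bit depths",
                    "glomseg_io_error")
    }
    if (is.null(sb)) sb <- rep(w * h * (b[1] / 8) / length(so), length(so))
    bytes <- raw(0)
    for (s in seq_along(so))
      bytes <- c(bytes, raw[(so[s] + 1):(so[s] + sb[s])])
    vals <- if (b[1] == 8) {
      as.integer(bytes)
    } else {
      lo <- as.integer(bytes[seq(1, length(bytes), 2)])
      hi <- as.integer(bytes[seq(2, length(bytes), 2)])
      if (endian == "little") lo + 256L * hi else hi + 256L * lo
    }
    # row-major page (rows = y, cols = x) -> matrix [y, x]
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    off <- ifd$next_offset
  }
  nz <- length(pages)
  arr <- array(0L, dim = c(nz, shape[1], shape[2]))
  for (k in seq_len(nz)) arr[k, , ] <- pages[[k]]
  voxel_stack(arr, spacing, bit_depth = as.integer(bits))
}

.write_uint <- function(x, size) {
  b <- integer(size)
  for (q in seq_len(size)) {
    b[q] <- x %% 256
    x <- x %/% 256
  }
  as.raw(b)
}

#' Write a stack as a multi-page greyscale TIFF
#'
#' Baseline uncompressed little-endian TIFF, one strip per page. The
#' write/read round trip is bit-identical for valid stacks.
#'
#' @param stack a [voxel_stack] (or a binary/label stack coerced by the
#'   caller to integer `voxels`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  arr <- stack$voxels
  d <- dim(arr)
  nz <- d[1]; h <- d[2]; w <- d[3]
  bps <- stack$bit_depth
  bpp <- bps / 8
  page_bytes <- w * h * bpp
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.write_uint(42, 2), con)
  data_start <- 8
  ifd_start <- data_start + nz * page_bytes
  n_tags <- 9L
  ifd_size <- 2 + n_tags * 12 + 4
  writeBin(.write_uint(ifd_start, 4), con)
  for (k in seq_len(nz)) {
    page <- t(arr[k, , ])           # column-major -> row-major bytes
    v <- as.integer(page)
    if (bps == 8) {
      writeBin(as.raw(v), con)
    } else {
      b <- raw(2 * length(v))
      b[seq(1, length(b), 2)] <- as.raw(v %% 256L)
      b[seq(2, length(b), 2)] <- as.raw(v %/% 256L)
      writeBin(b, con)
    }
  }
  tag_entry <- function(tag, type, count, value) {
    c(.write_uint(tag, 2), .write_uint(type, 2), .write_uint(count, 4),
      .write_uint(value, 4))
  }
  for (k in seq_len(nz)) {
    offset <- data_start + (k - 1) * page_bytes
    nxt <- if (k < nz) ifd_start + k * ifd_size else 0
    ifd <- c(
      .write_uint(n_tags, 2),
      tag_entry(256, 3, 1, w),
      tag_entry(257, 3, 1, h),
      tag_entry(258, 3, 1, bps),
      tag_entry(259, 3, 1, 1),    # no compression
      tag_entry(262, 3, 1, 1),    # black is zero
      tag_entry(273, 4, 1, offset),
      tag_entry(277, 3, 1, 1),
      tag_entry(278, 3, 1, h),
      tag_entry(279, 4, 1, page_bytes),
      .write_uint(nxt, 4)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

#' Convert a stack to 8-bit
#'
#' 16-bit stacks are linearly rescaled so that the observed minimum maps to
#' 0 and the observed maximum to 255 (rounded to nearest integer); 8-bit
#' input is returned unchanged. Min-max scaling is the operator-independent
#' choice: it involves no display-range judgement. A fixed range can be
#' supplied instead for cross-sample comparability.
#'
#' @param stack a [voxel_stack].
#' @param range optional fixed `c(low, high)` used instead of the observed
#'   min/max; values outside are clipped.
#' @return An 8-bit [voxel_stack].
#' @export
to_8bit <- function(stack, range = NULL) {
  if (!inherits(stack, "voxel_stack"))
    glomseg_error("expected a voxel_stack", "glomseg_bad_input")
  if (stack$bit_depth == 8L && is.null(range)) return(stack)
  v <- stack$voxels
  if (is.null(range)) range <- range(v)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    glomseg_warning("stack has zero dynamic range; all voxels map to 0",
                    "glomseg_degenerate")
    out <- array(0L, dim = dim(v))
  } else {
    x <- (as.numeric(v) - lo) / (hi - lo)
    x[x < 0] <- 0; x[x > 1] <- 1
    out <- array(as.integer(round(255 * x)), dim = dim(v))
  }
  voxel_stack(out, stack$spacing, bit_depth = 8L)
}
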