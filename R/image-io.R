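#' Calibrated grayscale image
#'
#' Container for a 2-D grayscale intensity grid with physical pixel size.
#' The coordinate convention used throughout the package: matrices are
#' row-major with origin top-left; x is the column axis; angles are
#' measured from +x, anticlockwise positive (y up).
#'
#' @param pixels numeric matrix of intensities (finite, >= 0).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param bit_depth source bit depth (e.g. 8, 16), or `NULL` if unknown.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, bit_depth = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_data("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_data("intensities must be finite and >= 0")
  assert_scalar_num(pixel_size_um, "pixel_size_um")
  if (pixel_size_um <= 0) stop_data("pixel_size_um must be > 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 bit_depth = bit_depth),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated_image: %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Z-stack of calibrated images
#'
#' @param planes list of `calibrated_image` objects sharing shape and
#'   calibration.
#' @param z_step_um axial step between planes in micrometres (> 0).
#' @return An object of class `z_stack`.
#' @export
z_stack <- function(planes, z_step_um) {
  if (!length(planes) || !all(vapply(planes, inherits, TRUE, "calibrated_image")))
    stop_data("planes must be a non-empty list of calibrated_image")
  assert_scalar_num(z_step_um, "z_step_um")
  if (z_step_um <= 0) stop_data("z_step_um must be > 0")
  dims <- vapply(planes, function(p) dim(p$pixels), integer(2))
  cals <- vapply(planes, function(p) p$pixel_size_um, numeric(1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_data("all planes must share the same shape")
  if (any(abs(cals - cals[1]) > 1e-9))
    stop_data("all planes must share the same calibration")
  structure(list(planes = planes, z_step_um = z_step_um), class = "z_stack")
}

#' RGB image
#'
#' @param pixels numeric array h x w x 3 with channel values in \[0, 255\].
#' @param pixel_size_um optional micrometres per pixel.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, pixel_size_um = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop_data("pixels must be an h x w x 3 array")
  if (any(pixels < 0) || any(pixels > 255))
    stop_data("channel values must lie in [0, 255]")
  if (!is.null(pixel_size_um)) {
    assert_scalar_num(pixel_size_um, "pixel_size_um")
    if (pixel_size_um <= 0) stop_data("pixel_size_um must be > 0")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

calib_sidecar <- function(path) paste0(path, ".calib")

## resolve um/px: explicit override > TIFF resolution tags > sidecar > NULL
resolve_calibration <- function(path, info, pixel_size_um) {
  if (!is.null(pixel_size_um)) return(pixel_size_um)
  xres <- info$x.resolution %||% attr(info, "x.resolution")
  unit <- info$resolution.unit %||% attr(info, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    per_um <- switch(as.character(unit %||% "inch"),
                     cm = xres / 1e4, inch = xres / 25400, xres / 1e4)
    if (per_um > 0) return(1 / per_um)
  }
  sc <- calib_sidecar(path)
  if (file.exists(sc)) {
    v <- suppressWarnings(as.numeric(readLines(sc, n = 1L)))
    if (is.finite(v) && v > 0) return(v)
  }
  NULL
}

#' Read a calibrated image, z-stack or RGB image
#'
#' Reads TIFF (grayscale single page, multi-page z-stack, or RGB) and PNG
#' (RGB). Pixel calibration is resolved with precedence: the
#' `pixel_size_um` override, then TIFF resolution tags, then a plain-text
#' `<path>.calib` sidecar written by [write_image()]. Operations needing
#' physical units error when none is available.
#'
#' Integer TIFF/PNG data are rescaled back to native integer intensities
#' using the stored bit depth.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_um optional calibration override (um per pixel).
#' @param z_step_um axial step for multi-page TIFFs (default 1).
#' @return A `calibrated_image`, `z_stack` or `rgb_image`.
#' @export
read_image <- function(path, pixel_size_um = NULL, z_step_um = 1) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3 && dim(px)[3] >= 3)
      return(rgb_image(round(px[, , 1:3] * 255), pixel_size_um = pixel_size_um))
    cal <- pixel_size_um %||% {
      sc <- calib_sidecar(path)
      if (file.exists(sc)) as.numeric(readLines(sc, n = 1L)) else NULL
    }
    if (is.null(cal)) stop_data("no calibration available for ", path)
    return(calibrated_image(px * 255, cal, bit_depth = 8L))
  }
  if (!ext %in% c("tif", "tiff")) stop_data("unsupported format: .", ext)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample %||% 8L
  scale <- 2^bits - 1
  first <- pages[[1]]
  if (length(dim(first)) == 3 && dim(first)[3] >= 3)
    return(rgb_image(round(first[, , 1:3] * 255), pixel_size_um = pixel_size_um))
  cal <- resolve_calibration(path, info, pixel_size_um)
  if (is.null(cal)) stop_data("no calibration available for ", path,
                              " (supply pixel_size_um)")
  planes <- lapply(pages, function(p) {
    ## TIFF stores integers at the native depth; restore them exactly
    ## (and drop the metadata attributes readTIFF attaches)
    m <- round(p * scale)
    attributes(m) <- list(dim = dim(m))
    calibrated_image(m, cal, bit_depth = as.integer(bits))
  })
  if (length(planes) == 1L) planes[[1]] else z_stack(planes, z_step_um)
}

#' Write a calibrated image, z-stack or RGB image
#'
#' Grayscale data are written as 16-bit TIFF (8-bit when the source depth
#' is 8); z-stacks as multi-page TIFF; RGB as 8-bit TIFF or PNG by
#' extension. Pixel calibration is recorded in a plain-text `<path>.calib`
#' sidecar (um per pixel) that [read_image()] honours.
#'
#' @param image a `calibrated_image`, `z_stack` or `rgb_image`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(image, "rgb_image")) {
    arr <- image$pixels / 255
    if (ext == "png") png::writePNG(arr, path)
    else tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    if (!is.null(image$pixel_size_um))
      writeLines(format(image$pixel_size_um, digits = 15), calib_sidecar(path))
    return(invisible(path))
  }
  planes <- if (inherits(image, "z_stack")) image$planes else list(image)
  bits <- planes[[1]]$bit_depth %||% 16L
  if (!bits %in% c(8L, 16L)) bits <- 16L
  scale <- 2^bits - 1
  mats <- lapply(planes, function(p) {
    m <- p$pixels / scale
    if (any(m > 1)) stop_data("intensities exceed the representable range")
    m
  })
  tiff::writeTIFF(if (length(mats) == 1L) mats[[1]] else mats, path,
                  bits.per.sample = as.integer(bits))
  writeLines(format(planes[[1]]$pixel_size_um, digits = 15),
             calib_sidecar(path))
  invisible(path)
}

#' Rescale an image to 8-bit
#'
#' Linear rescale of intensities to integers 0-255. Bounds are taken
#' either from intensity percentiles or from the data min/max; they are
#' recorded on the result for provenance. A constant image yields an
#' all-zero result flagged as degenerate.
#'
#' @param image a `calibrated_image`.
#' @param probs length-2 percentile pair in \[0, 1\] defining the rescale
#'   bounds (default `c(0, 1)`, i.e. min/max).
#' @return A `calibrated_image` with integer pixels in 0-255, bit depth 8,
#'   and attributes `rescale_bounds` and `degenerate`.
#' @export
to_8bit <- function(image, probs = c(0, 1)) {
  stopifnot(inherits(image, "calibrated_image"))
  if (length(probs) != 2 || any(probs < 0 | probs > 1) || probs[1] >= probs[2])
    stop_data("probs must be an increasing pair in [0, 1]")
  bounds <- unname(stats::quantile(image$pixels, probs))
  degenerate <- bounds[2] <= bounds[1]
  px <- if (degenerate) {
    matrix(0, nrow(image$pixels), ncol(image$pixels))
  } else {
    round(pmin(pmax((image$pixels - bounds[1]) / diff(bounds), 0), 1) * 255)
  }
  out <- calibrated_image(px, image$pixel_size_um, bit_depth = 8L)
  attr(out, "rescale_bounds") <- bounds
  attr(out, "degenerate") <- degenerate
  if (degenerate)
    warning("constant image: 8-bit conversion is degenerate (all zero)",
            call. = FALSE)
  out
}

#' Tile an image into a near-equal grid of ROIs
#'
#' Partitions the image into `rows x cols` tiles. Remainder pixels are
#' assigned to the last row/column so the tiles cover the image exactly.
#'
#' @param image a `calibrated_image` (or plain matrix).
#' @param rows,cols grid dimensions (default 3 x 3).
#' @return A list of tiles; each element has `pixels` (or a
#'   `calibrated_image` when the input was calibrated) and `offset`
#'   (top-left row/col of the tile within the parent, 1-based).
#' @export
grid_rois <- function(image, rows = 3, cols = 3) {
  m <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (nrow(m) < rows || ncol(m) < cols)
    stop_data("image too small for a ", rows, " x ", cols, " grid")
  rb <- floor(nrow(m) / rows); cb <- floor(ncol(m) / cols)
  out <- vector("list", rows * cols)
  k <- 1L
  for (i in seq_len(rows)) {
    r0 <- (i - 1L) * rb + 1L
    r1 <- if (i == rows) nrow(m) else i * rb
    for (j in seq_len(cols)) {
      c0 <- (j - 1L) * cb + 1L
      c1 <- if (j == cols) ncol(m) else j * cb
      sub <- m[r0:r1, c0:c1, drop = FALSE]
      tile <- if (inherits(image, "calibrated_image"))
        calibrated_image(sub, image$pixel_size_um, image$bit_depth)
      else list(pixels = sub)
      tile$offset <- c(row = r0, col = c0)
      out[[k]] <- tile
      k <- k + 1L
    }
  }
  out
}
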