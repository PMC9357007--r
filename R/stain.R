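#' HSB threshold box
#'
#' A hue/saturation/brightness box on the 0-255 integer scales (the
#' ImageJ convention; hue is a 0-255 wheel). `wrap = TRUE` marks a hue
#' interval that crosses the 255 -> 0 seam, in which case a pixel is
#' in-box when its hue is >= `h_lo` or <= `h_hi`.
#'
#' @param h_lo,h_hi,s_lo,s_hi,b_lo,b_hi bounds, each in 0-255, inclusive.
#' @param wrap logical; hue interval wraps across the seam.
#' @return An object of class `hsb_box`.
#' @export
hsb_box <- function(h_lo, h_hi, s_lo, s_hi, b_lo, b_hi, wrap = FALSE) {
  v <- c(h_lo, h_hi, s_lo, s_hi, b_lo, b_hi)
  if (any(v < 0 | v > 255)) stop_data("HSB bounds must lie in [0, 255]")
  if (!wrap && (h_lo > h_hi || s_lo > s_hi || b_lo > b_hi))
    stop_data("lo bound exceeds hi bound (set wrap = TRUE for hue seams)")
  structure(list(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
                 b_lo = b_lo, b_hi = b_hi, wrap = wrap),
            class = "hsb_box")
}

#' Shipped stain threshold profiles
#'
#' * `picrosirius`: the fibrillar-collagen (red) box H 200-240,
#'   S 150-255, B 0-255 on the 0-255 hue wheel.
#' * `birefringence`: red (the picrosirius box), yellow H 30-60 and green
#'   H 70-140, each with S 150-255, B 0-255. The yellow/green hue bounds
#'   are package defaults, exposed so they can be edited.
#' * `dab`: a brown box (H 0-30, S 50-255, B 20-220) for DAB-positive
#'   tissue; a package default.
#'
#' @param profile one of "picrosirius", "birefringence", "dab".
#' @return Named list of [hsb_box()] objects.
#' @export
stain_boxes <- function(profile = c("picrosirius", "birefringence", "dab")) {
  profile <- match.arg(profile)
  red <- hsb_box(200, 240, 150, 255, 0, 255)
  switch(profile,
    picrosirius = list(red = red),
    birefringence = list(red = red,
                         yellow = hsb_box(30, 60, 150, 255, 0, 255),
                         green = hsb_box(70, 140, 150, 255, 0, 255)),
    dab = list(dab = hsb_box(0, 30, 50, 255, 20, 220)))
}

#' Convert RGB to HSB channels (0-255 integer scales)
#'
#' Standard hue/saturation/brightness conversion with all three channels
#' scaled to 0-255 integers and hue on a 0-255 wheel. Greys (S = 0) get
#' hue 0 by convention.
#'
#' @param image an [rgb_image()], or an h x w x 3 array in \[0, 255\].
#' @return A list of integer matrices `h`, `s`, `b`.
#' @export
rgb_to_hsb <- function(image) {
  arr <- if (inherits(image, "rgb_image")) image$pixels else image
  d <- dim(arr)
  rgb <- rbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]),
               as.vector(arr[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(h = matrix(as.integer(round(hsv[1, ] * 255)), d[1], d[2]),
       s = matrix(as.integer(round(hsv[2, ] * 255)), d[1], d[2]),
       b = matrix(as.integer(round(hsv[3, ] * 255)), d[1], d[2]))
}

## inverse conversion; h, s, b integer vectors on 0-255 -> 3 x n RGB 0-255
hsb_to_rgb <- function(h, s, b) {
  col <- grDevices::hsv(h / 255, s / 255, b / 255)
  grDevices::col2rgb(col)
}

in_hsb_box <- function(hsb, box) {
  hue_ok <- if (isTRUE(box$wrap)) hsb$h >= box$h_lo | hsb$h <= box$h_hi
            else hsb$h >= box$h_lo & hsb$h <= box$h_hi
  hue_ok & hsb$s >= box$s_lo & hsb$s <= box$s_hi &
    hsb$b >= box$b_lo & hsb$b <= box$b_hi
}

boxes_overlap <- function(a, b) {
  rng <- function(lo, hi, wrap) if (wrap) c(seq(lo, 255), seq(0, hi)) else seq(lo, hi)
  length(intersect(rng(a$h_lo, a$h_hi, isTRUE(a$wrap)),
                   rng(b$h_lo, b$h_hi, isTRUE(b$wrap)))) > 0 &&
    a$s_lo <= b$s_hi && b$s_lo <= a$s_hi &&
    a$b_lo <= b$b_hi && b$b_lo <= a$b_hi
}

#' Stain-class area fractions by HSB thresholding
#'
#' Segments each stain class by its HSB box and reports class areas as
#' fractions of the tissue area. Tissue is defined by a non-white rule:
#' a pixel is tissue when its brightness is at most `tissue_b_max` OR its
#' saturation is at least `tissue_s_min` (defaults 230 and 30), which
#' excludes the white slide background.
#'
#' @param image an [rgb_image()].
#' @param boxes named list of [hsb_box()] objects (see [stain_boxes()]).
#' @param tissue_b_max,tissue_s_min tissue-mask cutoffs (0-255).
#' @param allow_overlap by default overlapping class boxes are an error;
#'   set `TRUE` to permit them (fractions may then sum above 1).
#' @return An object of class `stain_area_result`: list with
#'   `class_fractions`, `class_areas_px`, `tissue_area_px`.
#' @export
stain_area <- function(image, boxes = stain_boxes("picrosirius"),
                       tissue_b_max = 230, tissue_s_min = 30,
                       allow_overlap = FALSE) {
  stopifnot(inherits(image, "rgb_image"))
  if (!length(boxes) || is.null(names(boxes)))
    stop_data("boxes must be a named list of hsb_box")
  if (!allow_overlap && length(boxes) > 1) {
    nm <- names(boxes)
    for (i in seq_along(boxes)[-1]) for (j in seq_len(i - 1))
      if (boxes_overlap(boxes[[i]], boxes[[j]]))
        stop_data("classes overlap: ", nm[j], " and ", nm[i],
                  " (set allow_overlap = TRUE to permit)")
  }
  hsb <- rgb_to_hsb(image)
  tissue <- hsb$b <= tissue_b_max | hsb$s >= tissue_s_min
  tissue_px <- sum(tissue)
  if (tissue_px == 0) stop_data("zero tissue area: image is entirely background")
  areas <- vapply(boxes, function(bx) sum(in_hsb_box(hsb, bx) & tissue),
                  numeric(1))
  structure(
    list(class_fractions = areas / tissue_px,
         class_areas_px = areas,
         tissue_area_px = tissue_px),
    class = "stain_area_result")
}

#' @export
print.stain_area_result <- function(x, ...) {
  cat(sprintf("stain areas over %d tissue px:\n", x$tissue_area_px))
  for (nm in names(x$class_fractions))
    cat(sprintf("  %-8s %.4f (%d px)\n", nm, x$class_fractions[[nm]],
                x$class_areas_px[[nm]]))
  invisible(x)
}

## Ruifrok & Johnston H-DAB stain vectors (optical density space)
hdab_stain_matrix <- function() {
  m <- rbind(haematoxylin = c(0.650, 0.704, 0.286),
             dab = c(0.269, 0.568, 0.778),
             residual = c(0.633, -0.713, 0.302))
  m / sqrt(rowSums(m^2))
}

#' DAB-positive area fraction
#'
#' Fraction of tissue area positive for the DAB chromogen. Two methods:
#' `"hsb"` (default) thresholds a brown HSB box (see [stain_boxes()]);
#' `"deconvolution"` unmixes optical densities with the standard H-DAB
#' stain vectors and thresholds the DAB channel.
#'
#' @param image an [rgb_image()].
#' @param method `"hsb"` or `"deconvolution"`.
#' @param box HSB box for the hsb method (default `stain_boxes("dab")$dab`).
#' @param od_threshold DAB optical-density threshold for the
#'   deconvolution method (default 0.15).
#' @param tissue_b_max,tissue_s_min tissue-mask cutoffs as in
#'   [stain_area()].
#' @return A `stain_area_result` with a single `dab` class.
#' @export
dab_positive_area <- function(image, method = c("hsb", "deconvolution"),
                              box = stain_boxes("dab")$dab,
                              od_threshold = 0.15,
                              tissue_b_max = 230, tissue_s_min = 30) {
  method <- match.arg(method)
  stopifnot(inherits(image, "rgb_image"))
  if (method == "hsb")
    return(stain_area(image, boxes = list(dab = box),
                      tissue_b_max = tissue_b_max,
                      tissue_s_min = tissue_s_min))
  hsb <- rgb_to_hsb(image)
  tissue <- hsb$b <= tissue_b_max | hsb$s >= tissue_s_min
  tissue_px <- sum(tissue)
  if (tissue_px == 0) stop_data("zero tissue area: image is entirely background")
  arr <- image$pixels
  od <- -log10((cbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]),
                      as.vector(arr[, , 3])) + 1) / 256)
  conc <- od %*% solve(hdab_stain_matrix())
  dab_pos <- matrix(conc[, 2] > od_threshold, dim(arr)[1], dim(arr)[2])
  area <- sum(dab_pos & tissue)
  structure(
    list(class_fractions = c(dab = area / tissue_px),
         class_areas_px = c(dab = area),
         tissue_area_px = tissue_px),
    class = "stain_area_result")
}
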