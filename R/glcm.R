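## Grey-level co-occurrence texture: Haralick correlation as a function of
## pixel offset distance, in the four axis directions 0, 90, 180, 270 deg.
## Directional (asymmetric) GLCMs are kept: 0 and 180 deg are tabulated
## separately even though their Haralick correlation is identical (the
## count matrices are transposes) -- this identity is used as a self-check.

## quantise an 8-bit image to `levels` grey bins (0-based bin indices)
quantise_grey <- function(pixels, levels) {
  if (any(pixels < 0 | pixels > 255))
    stop_data("glcm expects 8-bit intensities in [0, 255]; see to_8bit()")
  pmin(floor(pixels * levels / 256), levels - 1)
}

#' Grey-level co-occurrence counts for one offset
#'
#' Tabulates ordered pixel pairs (value at p, value at p + offset) over
#' all positions p for which both pixels lie inside the image. Counts are
#' direction-specific (asymmetric): offset (0, 1) and (0, -1) give
#' transposed matrices.
#'
#' @param image8 a `calibrated_image` with 8-bit intensities (see
#'   [to_8bit()]), or a plain matrix with values in 0-255.
#' @param offset integer pair `(dy, dx)` in matrix row/col steps.
#' @param levels number of grey bins; 8-bit values are uniformly binned.
#' @return A `levels x levels` count matrix with attribute `n_pairs`.
#' @export
glcm_counts <- function(image8, offset, levels = 64) {
  m <- if (inherits(image8, "calibrated_image")) image8$pixels else image8
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  if (abs(dy) >= nrow(m) || abs(dx) >= ncol(m))
    stop_data("offset larger than image")
  q <- quantise_grey(m, levels)
  rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
  r1 <- rows[rows + dy >= 1 & rows + dy <= nrow(m)]
  c1 <- cols[cols + dx >= 1 & cols + dx <= ncol(m)]
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  counts <- matrix(tabulate(a * levels + b + 1L, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  attr(counts, "n_pairs") <- sum(counts)
  counts
}

#' Haralick correlation of a co-occurrence matrix
#'
#' Normalises counts to joint probabilities p(i, j) and returns
#' `sum_ij (i - mu_i)(j - mu_j) p(i, j) / (sigma_i sigma_j)` with marginal
#' means and standard deviations. Returns `NA` (the undefined flag) when
#' either marginal variance is zero, e.g. for a constant image.
#'
#' @param counts a square co-occurrence count matrix (see [glcm_counts()]).
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
haralick_correlation <- function(counts) {
  total <- sum(counts)
  if (!is.matrix(counts) || nrow(counts) != ncol(counts) || total == 0)
    stop_data("counts must be a non-empty square matrix")
  p <- counts / total
  lev <- seq_len(nrow(p)) - 1
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  var_i <- sum((lev - mu_i)^2 * pi_); var_j <- sum((lev - mu_j)^2 * pj_)
  if (var_i <= 0 || var_j <= 0) return(NA_real_)
  cov_ij <- sum(outer(lev - mu_i, lev - mu_j) * p)
  cov_ij / sqrt(var_i * var_j)
}

glcm_directions <- function() {
  ## (dy, dx) per direction; 0 deg = +x, anticlockwise positive (y up)
  list(`0` = c(0L, 1L), `90` = c(-1L, 0L),
       `180` = c(0L, -1L), `270` = c(1L, 0L))
}

#' GLCM correlation as a function of offset distance
#'
#' Computes the Haralick correlation at every offset distance d = 1..D in
#' the four axis directions (0, 90, 180, 270 degrees), the per-distance
#' direction mean, a normalised curve (each distance divided by the d = 1
#' mean) and the scalar summary `summary_mean_correlation` (average of the
#' direction-mean correlation over distances). Higher mean correlation
#' indicates a more organised fibre network. Undefined entries (zero
#' marginal variance) are excluded from means and counted.
#'
#' @param image a `calibrated_image`; converted with [to_8bit()] unless
#'   already 8-bit.
#' @param max_distance_px maximum offset distance D (default 50; must
#'   satisfy D < min(image dims) / 2).
#' @param levels grey bins for quantisation (default 64).
#' @return An object of class `glcm_curve`: list with `table` (data.frame
#'   distance, direction, correlation), `mean_correlation` (per distance),
#'   `normalised` (mean curve / value at d = 1), `summary_mean_correlation`,
#'   `n_undefined`, and the parameters used.
#' @export
glcm_correlation_curve <- function(image, max_distance_px = 50, levels = 64) {
  stopifnot(inherits(image, "calibrated_image"))
  D <- as.integer(max_distance_px)
  if (D < 1) stop_data("max_distance_px must be >= 1")
  if (D >= min(dim(image$pixels)) / 2)
    stop_data("max_distance_px must be < min(image dims)/2")
  img8 <- if (identical(image$bit_depth, 8L) && max(image$pixels) <= 255)
    image else to_8bit(image)
  dirs <- glcm_directions()
  tab <- expand.grid(distance = seq_len(D),
                     direction = as.numeric(names(dirs)),
                     KEEP.OUT.ATTRS = FALSE)
  tab$correlation <- mapply(function(d, dir) {
    off <- dirs[[as.character(dir)]] * d
    haralick_correlation(glcm_counts(img8, off, levels))
  }, tab$distance, tab$direction)
  mc <- tapply(tab$correlation, tab$distance, mean, na.rm = TRUE)
  mc[is.nan(mc)] <- NA_real_
  mean_correlation <- as.numeric(mc)
  if (all(is.na(mean_correlation)))
    stop_data("degenerate image: correlation undefined at every offset")
  normalised <- if (!is.na(mean_correlation[1]) && mean_correlation[1] != 0)
    mean_correlation / mean_correlation[1] else rep(NA_real_, D)
  structure(
    list(table = tab,
         mean_correlation = mean_correlation,
         normalised = normalised,
         summary_mean_correlation = mean(mean_correlation, na.rm = TRUE),
         n_undefined = sum(is.na(tab$correlation)),
         max_distance_px = D, levels = levels),
    class = "glcm_curve")
}

#' @export
print.glcm_curve <- function(x, ...) {
  cat(sprintf("glcm_curve: d = 1..%d, %d levels, summary mean correlation %.4f (%d undefined entries)\n",
              x$max_distance_px, x$levels, x$summary_mean_correlation,
              x$n_undefined))
  invisible(x)
}

#' @export
plot.glcm_curve <- function(x, ...) {
  plot(seq_along(x$mean_correlation), x$mean_correlation, type = "l",
       xlab = "offset distance (px)", ylab = "mean Haralick correlation", ...)
  invisible(x)
}
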