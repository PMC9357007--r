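## Structure-tensor orientation analysis. Spatial derivatives come from
## the cubic B-spline representation of the image (recursive prefilter,
## then the exact derivative of the spline at the sample points); tensor
## components are window-averaged with a Gaussian; the orientation
## histogram is summarised by its peak-to-baseline ratio.

## cubic B-spline prefilter along the rows of a matrix (one pole,
## z1 = sqrt(3) - 2; causal + anticausal recursive passes, Unser's scheme)
bspline_prefilter_rows <- function(m) {
  z1 <- sqrt(3) - 2
  n <- ncol(m)
  if (n < 3) return(m)
  gain <- 6
  out <- m * gain
  ## causal init by mirror-boundary horizon
  horizon <- min(n, ceiling(log(1e-10) / log(abs(z1))))
  zpow <- z1^(seq_len(horizon) - 1)
  out_t <- t(out)
  c0 <- as.numeric(crossprod(zpow, out_t[seq_len(horizon), , drop = FALSE]))
  cplus <- matrix(0, nrow(m), n)
  cplus[, 1] <- c0
  for (k in 2:n) cplus[, k] <- out[, k] + z1 * cplus[, k - 1]
  cminus <- matrix(0, nrow(m), n)
  cminus[, n] <- (z1 / (z1 * z1 - 1)) * (cplus[, n] + z1 * cplus[, n - 1])
  for (k in (n - 1):1) cminus[, k] <- z1 * (cminus[, k + 1] - cplus[, k])
  cminus
}

bspline_coefficients <- function(m) {
  t(bspline_prefilter_rows(t(bspline_prefilter_rows(m))))
}

## derivative of the spline along columns (x) / rows (y) at sample points:
## conv with [-1/2, 0, 1/2] in the derivative axis and the sampled cubic
## B-spline [1/6, 2/3, 1/6] in the other axis
conv3_rows <- function(m, k) {
  n <- ncol(m)
  left <- cbind(m[, 1], m[, -n]); right <- cbind(m[, -1], m[, n])
  k[1] * left + k[2] * m + k[3] * right
}
conv3_cols <- function(m, k) t(conv3_rows(t(m), k))

spline_gradients <- function(pixels) {
  c_ <- bspline_coefficients(pixels)
  bs <- c(1 / 6, 2 / 3, 1 / 6)
  dv <- c(-0.5, 0, 0.5)
  list(fx = conv3_cols(conv3_rows(c_, dv), bs),
       fy = conv3_rows(conv3_cols(c_, dv), bs))
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

#' Per-pixel orientation field by structure tensors
#'
#' Computes spatial derivatives from the cubic B-spline representation of
#' the image, forms the structure tensor (Jxx, Jyy, Jxy as Gaussian
#' window averages of the gradient products), and derives the local fibre
#' orientation and coherency. The reported angle is the fibre direction
#' (perpendicular to the intensity gradient), in degrees on (-90, 90]
#' with 0 along +x (columns) and anticlockwise positive.
#'
#' @param image a `calibrated_image` or plain numeric matrix.
#' @param smoothing_scale Gaussian window SD in pixels for tensor
#'   averaging (default 4).
#' @return An object of class `orientation_field`: list of matrices
#'   `theta` (degrees), `coherency` in \[0, 1\] (0 where energy is 0) and
#'   `energy` (tensor trace).
#' @export
structure_tensor <- function(image, smoothing_scale = 4) {
  m <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (!is.matrix(m)) stop_data("image must be a matrix or calibrated_image")
  if (smoothing_scale < 0) stop_data("smoothing_scale must be >= 0")
  g <- spline_gradients(m)
  ## y axis points up in the angle convention; matrix rows grow downward
  gx <- g$fx; gy <- -g$fy
  jxx <- gaussian_smooth(gx * gx, smoothing_scale)
  jyy <- gaussian_smooth(gy * gy, smoothing_scale)
  jxy <- gaussian_smooth(gx * gy, smoothing_scale)
  energy <- jxx + jyy
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi   # gradient direction
  theta <- wrap_axial(phi + 90)                       # fibre direction
  disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coherency <- ifelse(energy > 0, disc / energy, 0)
  coherency <- pmin(pmax(coherency, 0), 1)
  structure(list(theta = theta, coherency = coherency, energy = energy),
            class = "orientation_field")
}

#' Orientation histogram of a field
#'
#' Bins per-pixel orientations over the 180-degree axial range into a
#' normalised weighted histogram. The default weighting,
#' coherency x energy, suppresses background pixels; `"energy"` and
#' `"none"` are alternatives.
#'
#' @param field an `orientation_field` (see [structure_tensor()]).
#' @param n_bins number of uniform bins over 180 degrees (default 180).
#' @param weighting `"coherency_energy"` (default), `"energy"` or
#'   `"none"`.
#' @return An object of class `orientation_distribution`: list with
#'   `bin_centres` (degrees), `weights` (sum 1), `peak_angle` and
#'   `n_bins`.
#' @export
orientation_distribution <- function(field, n_bins = 180,
                                     weighting = c("coherency_energy",
                                                   "energy", "none")) {
  stopifnot(inherits(field, "orientation_field"))
  weighting <- match.arg(weighting)
  w <- switch(weighting,
              coherency_energy = field$coherency * field$energy,
              energy = field$energy,
              none = array(1, dim(field$theta)))
  if (sum(w) <= 0) stop_data("all-zero weights: no oriented signal")
  width <- 180 / n_bins
  ## bins cover (-90, 90]; bin i spans (-90 + (i-1)*width, -90 + i*width]
  idx <- ceiling((field$theta + 90) / width)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  weights <- as.numeric(tapply(as.vector(w), factor(idx, levels = seq_len(n_bins)),
                               sum, default = 0))
  weights <- weights / sum(weights)
  centres <- -90 + (seq_len(n_bins) - 0.5) * width
  structure(list(bin_centres = centres, weights = weights,
                 peak_angle = centres[which.max(weights)], n_bins = n_bins),
            class = "orientation_distribution")
}

#' Align orientation distributions and compute peak-to-baseline ratios
#'
#' Circularly shifts each distribution so its modal bin sits at 0 degrees
#' (so replicate curves can be averaged), then summarises alignment as
#' peak / baseline of the smoothed curve (moving average, window 3 bins).
#' The baseline is, by default, the mean of the lowest quartile of
#' smoothed weights; `"min"` and `"lowest_decile_mean"` are alternatives.
#' A zero baseline (e.g. a delta distribution) yields `Inf`.
#'
#' @param dists a single `orientation_distribution` or a list of them
#'   (equal bin counts).
#' @param baseline baseline rule: `"lowest_quartile_mean"` (default),
#'   `"min"`, or `"lowest_decile_mean"`.
#' @return An object of class `alignment_result`: list with `aligned`
#'   (matrix, one row per distribution, peak at the 0-degree bin),
#'   `bin_offsets_deg` (shift applied, i.e. the modal angle of each input),
#'   `peak_to_baseline` (per curve), `mean_curve` and `sem_curve`.
#' @export
align_and_ratio <- function(dists, baseline = c("lowest_quartile_mean",
                                                "min", "lowest_decile_mean")) {
  baseline <- match.arg(baseline)
  if (inherits(dists, "orientation_distribution")) dists <- list(dists)
  if (!length(dists) || !all(vapply(dists, inherits, TRUE,
                                    "orientation_distribution")))
    stop_data("dists must be orientation_distribution objects")
  nb <- dists[[1]]$n_bins
  if (any(vapply(dists, function(d) as.numeric(d$n_bins), numeric(1)) != nb))
    stop_data("all distributions must share the bin count")
  zero_bin <- which.min(abs(dists[[1]]$bin_centres))  # bin containing 0 deg
  aligned <- matrix(0, length(dists), nb)
  offs <- numeric(length(dists))
  ratios <- numeric(length(dists))
  for (i in seq_along(dists)) {
    w <- dists[[i]]$weights
    mode_bin <- which.max(circular_ma(w, 3L))
    shift <- (mode_bin - zero_bin) %% nb
    ws <- if (shift) c(w[(shift + 1):nb], w[1:shift]) else w
    aligned[i, ] <- ws
    offs[i] <- dists[[i]]$bin_centres[mode_bin]
    sm <- circular_ma(ws, 3L)
    peak <- max(sm)
    base <- switch(baseline,
      min = min(sm),
      lowest_quartile_mean = mean(sort(sm)[seq_len(max(1L, floor(nb / 4)))]),
      lowest_decile_mean = mean(sort(sm)[seq_len(max(1L, floor(nb / 10)))]))
    ratios[i] <- if (base > 0) peak / base else Inf
  }
  mean_curve <- colMeans(aligned)
  sem_curve <- if (nrow(aligned) > 1)
    apply(aligned, 2, stats::sd) / sqrt(nrow(aligned)) else rep(NA_real_, nb)
  structure(list(aligned = aligned, bin_offsets_deg = offs,
                 peak_to_baseline = ratios, mean_curve = mean_curve,
                 sem_curve = sem_curve,
                 bin_centres = dists[[1]]$bin_centres),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment of %d orientation curve(s): peak/baseline %s\n",
              nrow(x$aligned),
              paste(sprintf("%.3g", x$peak_to_baseline), collapse = ", ")))
  invisible(x)
}

#' HSB orientation map
#'
#' Renders the field as an RGB array with angle encoded as hue, coherency
#' as saturation and (rescaled) energy as brightness.
#'
#' @param field an `orientation_field`.
#' @return An h x w x 3 array in \[0, 1\], suitable for [png::writePNG()].
#' @export
orientation_hsb_map <- function(field) {
  stopifnot(inherits(field, "orientation_field"))
  h <- (field$theta + 90) / 180
  s <- field$coherency
  e <- field$energy
  v <- if (max(e) > 0) sqrt(e / max(e)) else e
  col <- grDevices::col2rgb(grDevices::hsv(pmin(h, 1), pmin(s, 1),
                                           pmin(v, 1))) / 255
  d <- dim(field$theta)
  arr <- array(0, c(d, 3))
  arr[, , 1] <- matrix(col[1, ], d[1], d[2])
  arr[, , 2] <- matrix(col[2, ], d[1], d[2])
  arr[, , 3] <- matrix(col[3, ], d[1], d[2])
  arr
}
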