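#' Peak SHG signal across a z-stack
#'
#' Computes a per-plane intensity statistic and reports the peak over
#' planes, i.e. the plane where the second-harmonic signal is strongest.
#'
#' @param stack a [z_stack()] (or single `calibrated_image`).
#' @param plane_stat `"mean"` (default) or `"p99"` (99th percentile).
#' @return An object of class `shg_peak_result`: list with
#'   `per_plane_stat`, `peak_value` and `plane_index`.
#' @export
shg_peak_signal <- function(stack, plane_stat = c("mean", "p99")) {
  plane_stat <- match.arg(plane_stat)
  planes <- if (inherits(stack, "z_stack")) stack$planes
            else if (inherits(stack, "calibrated_image")) list(stack)
            else stop_data("stack must be a z_stack or calibrated_image")
  if (!length(planes)) stop_data("empty stack")
  f <- switch(plane_stat,
              mean = function(p) mean(p$pixels),
              p99 = function(p) unname(stats::quantile(p$pixels, 0.99)))
  stats_ <- vapply(planes, f, numeric(1))
  structure(list(per_plane_stat = stats_,
                 peak_value = max(stats_),
                 plane_index = which.max(stats_),
                 plane_stat = plane_stat),
            class = "shg_peak_result")
}

#' @export
print.shg_peak_result <- function(x, ...) {
  cat(sprintf("SHG peak signal (%s): %.4g at plane %d of %d\n",
              x$plane_stat, x$peak_value, x$plane_index,
              length(x$per_plane_stat)))
  invisible(x)
}

## local maxima of a profile with prominence and full width at half
## prominence; crossings are linearly interpolated. Returns a data.frame.
profile_peaks <- function(y, step = 1, prominence_min = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), width = numeric()))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  out <- lapply(is_max, function(i) {
    ## prominence: drop to the highest minimum between the peak and the
    ## nearest higher ground (or profile end) on each side
    left_higher <- which(y[seq_len(i - 1)] > y[i])
    lbound <- if (length(left_higher)) max(left_higher) else 1L
    right_higher <- which(y[(i + 1):n] > y[i])
    rbound <- if (length(right_higher)) i + min(right_higher) else n
    base <- max(min(y[lbound:i]), min(y[i:rbound]))
    prom <- y[i] - base
    if (prom < prominence_min) return(NULL)
    half <- y[i] - prom / 2
    ## walk out to the half-prominence crossings
    li <- i
    while (li > 1 && y[li - 1] > half) li <- li - 1
    if (li == 1 && y[1] > half) return(NULL)  # truncated at border
    xl <- if (li == 1) 1 else (li - 1) + (half - y[li - 1]) / (y[li] - y[li - 1])
    ri <- i
    while (ri < n && y[ri + 1] > half) ri <- ri + 1
    if (ri == n && y[n] > half) return(NULL)
    xr <- if (ri == n) n else ri + (y[ri] - half) / (y[ri] - y[ri + 1])
    data.frame(index = i, width = (xr - xl) * step, prominence = prom)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(data.frame(index = integer(), width = numeric(),
                                      prominence = numeric()))
  do.call(rbind, out)
}

#' Fibre-bundle widths from intensity profiles
#'
#' Measures collagen fibre-bundle diameters from intensity profiles: the
#' image is tiled into a grid (default 3 x 3); in each tile, profile
#' lines are drawn perpendicular to the tile's dominant fibre orientation
#' (from the structure-tensor field), intensity is sampled along each
#' line by bilinear interpolation, and each detected peak's full width at
#' half prominence is converted to micrometres. Peaks narrower than 2 px,
#' touching a profile end, or with prominence below `prominence_frac`
#' times the tile's dynamic range are discarded.
#'
#' @param image a `calibrated_image`.
#' @param grid integer pair (rows, cols) for tiling (default `c(3, 3)`).
#' @param lines_per_tile profile lines per tile (default 5).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   tile dynamic range (default 0.3).
#' @param axis `"auto"` (perpendicular to the dominant orientation;
#'   default), `"horizontal"` or `"vertical"` for fixed-axis profiles.
#' @param step_px sampling step along profiles in pixels (default 0.25).
#' @return An object of class `bundle_width_result`: list with
#'   `widths_um` (all retained peak widths), `per_tile_mean_um` (matrix),
#'   `mean_width_um` and `n_peaks`. When no peak is found anywhere, the
#'   result is empty (`n_peaks = 0`, `mean_width_um = NA`).
#' @export
profile_peak_widths <- function(image, grid = c(3, 3), lines_per_tile = 5,
                                prominence_frac = 0.3,
                                axis = c("auto", "horizontal", "vertical"),
                                step_px = 0.25) {
  stopifnot(inherits(image, "calibrated_image"))
  axis <- match.arg(axis)
  tiles <- grid_rois(image, grid[1], grid[2])
  widths <- numeric(0)
  tile_means <- matrix(NA_real_, grid[1], grid[2])
  ti <- 0L
  for (tile in tiles) {
    ti <- ti + 1L
    m <- tile$pixels
    rng <- max(m) - min(m)
    tile_widths <- numeric(0)
    if (rng > 0) {
      prof_dir <- switch(axis,
        horizontal = 0,
        vertical = 90,
        auto = {
          fld <- structure_tensor(m, smoothing_scale = 2)
          od <- orientation_distribution(fld, n_bins = 36)
          wrap_axial(od$peak_angle + 90)  # perpendicular to fibres
        })
      th <- prof_dir * pi / 180
      ux <- cos(th); uy <- -sin(th)   # row/col step of the profile line
      nr <- nrow(m); nc <- ncol(m)
      half_len <- sqrt(nr^2 + nc^2) / 2
      ts <- seq(-half_len, half_len, by = step_px)
      ## line centres spread along the direction perpendicular to the
      ## profile (i.e. along the fibres), through the tile centre
      px <- sin(th); py <- cos(th)
      offs <- (seq_len(lines_per_tile) / (lines_per_tile + 1) - 0.5)
      for (o in offs) {
        cx <- (nc + 1) / 2 + o * nc * px
        cy <- (nr + 1) / 2 + o * nr * py
        rr <- cy + ts * uy; cc <- cx + ts * ux
        keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        if (sum(keep) < 5) next
        y <- bilinear(m, rr[keep], cc[keep])
        pk <- profile_peaks(y, step = step_px,
                            prominence_min = prominence_frac * rng)
        if (nrow(pk)) tile_widths <- c(tile_widths, pk$width[pk$width >= 2])
      }
    }
    if (length(tile_widths))
      tile_means[(ti - 1L) %/% grid[2] + 1L, (ti - 1L) %% grid[2] + 1L] <-
        mean(tile_widths) * image$pixel_size_um
    widths <- c(widths, tile_widths)
  }
  widths_um <- widths * image$pixel_size_um
  structure(list(widths_um = widths_um,
                 per_tile_mean_um = tile_means,
                 mean_width_um = if (length(widths_um)) mean(widths_um)
                                 else NA_real_,
                 n_peaks = length(widths_um)),
            class = "bundle_width_result")
}

#' @export
print.bundle_width_result <- function(x, ...) {
  if (!x$n_peaks) cat("bundle widths: no peaks detected\n")
  else cat(sprintf("bundle widths: %d peaks, mean %.3g um\n",
                   x$n_peaks, x$mean_width_um))
  invisible(x)
}
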