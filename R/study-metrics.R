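#' Classify cell depths into invading and non-invading counts
#'
#' Cells are scored against a depth threshold measured downward from the
#' upper surface of the organotypic matrix. A cell counts as invading only
#' when strictly deeper than the threshold (a cell sitting exactly at the
#' threshold is non-invading).
#'
#' @param cell_depths_um numeric vector of cell depths in micrometres,
#'   measured downward from the matrix upper surface (all >= 0).
#' @param threshold_um invasion depth threshold in micrometres (default 50).
#' @return An object of class `invasion_counts`: a list with `n_invading`,
#'   `n_non_invading` and `depth_threshold_um`.
#' @examples
#' classify_invading(c(10, 50, 51, 200))
#' @export
classify_invading <- function(cell_depths_um, threshold_um = 50) {
  if (length(cell_depths_um) && any(!is.finite(cell_depths_um) | cell_depths_um < 0))
    stop_data("cell depths must be finite and >= 0")
  assert_scalar_num(threshold_um, "threshold_um", lo = 0)
  n_inv <- sum(cell_depths_um > threshold_um)
  structure(
    list(n_invading = n_inv,
         n_non_invading = length(cell_depths_um) - n_inv,
         depth_threshold_um = threshold_um),
    class = "invasion_counts")
}

#' Invasive index
#'
#' Fraction of cancer cells that have invaded the organotypic matrix:
#' `n_invading / (n_invading + n_non_invading)`.
#'
#' @param counts an `invasion_counts` object (see [classify_invading()]),
#'   or a list with fields `n_invading` and `n_non_invading`.
#' @return The invasive index, a fraction in \[0, 1\].
#' @examples
#' invasive_index(classify_invading(c(10, 60, 70, 80)))
#' @export
invasive_index <- function(counts) {
  ni <- counts$n_invading; nn <- counts$n_non_invading
  if (!is.numeric(ni) || !is.numeric(nn) || ni < 0 || nn < 0)
    stop_data("counts must be non-negative")
  total <- ni + nn
  if (total == 0) stop_data("invasive index undefined: zero cells counted")
  ni / total
}

#' Tumour volume from calliper dimensions
#'
#' Volume in cubic millimetres from the two callipered dimensions:
#' `(max_dim^2 * min_dim) * 0.52`.
#'
#' @param max_dim_mm maximum tumour dimension (mm).
#' @param min_dim_mm minimum tumour dimension (mm). If the arguments arrive
#'   out of order they are swapped with a warning.
#' @return Tumour volume in mm^3.
#' @examples
#' tumour_volume(10, 10)  # 520 mm^3, the 1 cm x 1 cm endpoint volume
#' @export
tumour_volume <- function(max_dim_mm, min_dim_mm) {
  assert_scalar_num(max_dim_mm, "max_dim_mm", lo = 0)
  assert_scalar_num(min_dim_mm, "min_dim_mm", lo = 0)
  if (min_dim_mm > max_dim_mm) {
    warning("min_dim_mm > max_dim_mm; swapping", call. = FALSE)
    tmp <- max_dim_mm; max_dim_mm <- min_dim_mm; min_dim_mm <- tmp
  }
  (max_dim_mm^2 * min_dim_mm) * 0.52
}

#' Metastasis burden from segmented lung foci
#'
#' Counts metastatic foci strictly larger than the minimum area, and
#' normalises the count to the total lung cross-sectional area. A focus
#' whose area equals the threshold exactly is excluded.
#'
#' @param focus_areas_um2 numeric vector of per-focus areas (um^2).
#' @param lung_area_um2 total lung cross-sectional area (um^2, > 0).
#' @param min_focus_um2 minimum focus area (um^2); default 100.
#' @return A list with `n_mets`, `mets_per_unit_lung_area` (count per um^2)
#'   and `mean_focus_area` (um^2; `NA` when no focus is retained).
#' @examples
#' metastasis_burden(c(50, 150, 200), lung_area_um2 = 1e6)
#' @export
metastasis_burden <- function(focus_areas_um2, lung_area_um2,
                              min_focus_um2 = 100) {
  if (length(focus_areas_um2) && any(focus_areas_um2 <= 0))
    stop_data("focus areas must be > 0")
  assert_scalar_num(lung_area_um2, "lung_area_um2")
  if (lung_area_um2 <= 0) stop_data("lung area must be > 0")
  keep <- focus_areas_um2 > min_focus_um2
  n <- sum(keep)
  list(n_mets = n,
       mets_per_unit_lung_area = n / lung_area_um2,
       mean_focus_area = if (n) mean(focus_areas_um2[keep]) else NA_real_)
}

#' Focus areas from a labelled metastasis mask
#'
#' Helper converting a labelled mask image (integer labels, 0 = background)
#' into per-focus areas in um^2 using the pixel calibration.
#'
#' @param label_matrix integer matrix of focus labels (0 = background).
#' @param pixel_size_um micrometres per pixel.
#' @return numeric vector of focus areas (um^2), one per label.
#' @export
focus_areas_from_mask <- function(label_matrix, pixel_size_um) {
  assert_scalar_num(pixel_size_um, "pixel_size_um")
  if (pixel_size_um <= 0) stop_data("pixel_size_um must be > 0")
  labs <- label_matrix[label_matrix > 0]
  if (!length(labs)) return(numeric(0))
  as.numeric(table(labs)) * pixel_size_um^2
}

#' Compressive elastic modulus from an unconfined-compression curve
#'
#' Fits the slope of the linear viscoelastic region of a stress-strain
#' curve. A window of `window_frac` of the points slides across the
#' curve; the latest (highest-strain) window whose ordinary least-squares
#' fit reaches `R^2 >= min_r2` seeds the estimate (if no window
#' qualifies, the criterion is relaxed stepwise by 0.01 with a warning).
#' The seed fit is then refined by iteratively trimmed least squares over
#' the whole curve: points deviating by more than 2 residual-SEs from the
#' current line are dropped and the line refitted until membership
#' stabilises, which sheds the concave toe region while keeping every
#' linear point. The fitted region is reported so the selection is
#' auditable.
#'
#' @param strain numeric vector of strains (dimensionless fractions,
#'   non-decreasing, in \[0, 1)).
#' @param stress numeric vector of stresses (kPa), or forces if
#'   `contact_area_mm2` is supplied.
#' @param contact_area_mm2 optional contact area (mm^2); when given,
#'   `stress` is interpreted as force in mN and converted to kPa
#'   (mN / mm^2 = kPa).
#' @param window_frac fraction of points per fitting window (default 0.3).
#' @param min_r2 minimum R-squared for accepting a window (default 0.99).
#' @return An object of class `modulus_fit`: list with `modulus_kpa`,
#'   `intercept`, `r_squared`, `region` (index bounds), `strain_range`,
#'   and `relaxed_to` (the R^2 criterion actually used).
#' @examples
#' sc <- simulate_stress_strain(modulus = 10, toe_strain = 0.05,
#'                              noise_sd = 0, n_points = 80, seed = 1)
#' bulk_modulus(sc$strain, sc$stress)
#' @export
bulk_modulus <- function(strain, stress, contact_area_mm2 = NULL,
                         window_frac = 0.3, min_r2 = 0.99) {
  if (length(strain) != length(stress))
    stop_data("strain and stress must have equal length")
  n <- length(strain)
  if (n < 4) stop_data("insufficient data: at least 4 points required")
  if (any(diff(strain) < 0)) stop_data("strain must be non-decreasing")
  if (any(strain < 0 | strain >= 1)) stop_data("strains must lie in [0, 1)")
  if (!is.null(contact_area_mm2)) {
    assert_scalar_num(contact_area_mm2, "contact_area_mm2")
    if (contact_area_mm2 <= 0) stop_data("contact area must be > 0")
    stress <- stress / contact_area_mm2
  }
  w <- max(4L, as.integer(round(window_frac * n)))
  if (w > n) w <- n
  starts <- seq_len(n - w + 1L)
  fits <- vapply(starts, function(s) {
    idx <- s:(s + w - 1L)
    f <- stats::lm.fit(cbind(1, strain[idx]), stress[idx])
    ssr <- sum(f$residuals^2)
    sst <- sum((stress[idx] - mean(stress[idx]))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
    c(slope = unname(f$coefficients[2]), icpt = unname(f$coefficients[1]),
      r2 = r2)
  }, numeric(3))
  r2s <- fits["r2", ]
  crit <- min_r2
  repeat {
    ok <- which(!is.na(r2s) & r2s >= crit)
    if (length(ok)) break
    crit <- crit - 0.01
    if (crit < 0.5)
      stop_data("no window attains an acceptable linear fit (R^2 >= 0.5)")
  }
  if (crit < min_r2)
    warning(sprintf("linear-region criterion relaxed to R^2 >= %.2f", crit),
            call. = FALSE)
  ## reference window: the latest (highest-strain) window meeting the
  ## criterion. The linear viscoelastic region of a toe+linear
  ## compression curve sits at high strain, so the last acceptable
  ## window is free of toe curvature; max-R^2 selection can land on a
  ## toe-contaminated window when noise is comparable to the signal.
  best <- max(ok)
  region <- c(starts[best], starts[best] + w - 1L)
  ## refine by iteratively trimmed least squares over the whole curve,
  ## started from the window fit: points beyond 2 residual-SEs of the
  ## current line are dropped and the line refitted until membership is
  ## stable. Toe curvature is shed within a few iterations while the
  ## full linear region is retained, so the slope uses every point the
  ## data supports rather than one window.
  keep <- seq_len(n) %in% (region[1]:region[2])
  fit <- stats::lm.fit(cbind(1, strain[keep]), stress[keep])
  for (it in seq_len(30L)) {
    res <- stress - (fit$coefficients[1] + fit$coefficients[2] * strain)
    rse <- sqrt(sum(res[keep]^2) / max(1, sum(keep) - 2)) +
      1e-10 * max(abs(stress), 1)
    new_keep <- abs(res) <= 2 * rse
    if (sum(new_keep) < max(4L, w %/% 2L)) break  # keep the window fit
    if (identical(new_keep, keep)) break
    keep <- new_keep
    fit <- stats::lm.fit(cbind(1, strain[keep]), stress[keep])
  }
  region <- range(which(keep))
  final <- fit
  sst <- sum((stress[keep] - mean(stress[keep]))^2)
  final_r2 <- if (sst > 0) 1 - sum(final$residuals^2) / sst else NA_real_
  structure(
    list(modulus_kpa = unname(final$coefficients[2]),
         intercept = unname(final$coefficients[1]),
         r_squared = final_r2,
         region = region,
         strain_range = strain[region],
         relaxed_to = crit),
    class = "modulus_fit")
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf("Compressive elastic modulus: %.4g kPa\n", x$modulus_kpa))
  cat(sprintf("  linear region: points %d-%d (strain %.3f-%.3f), R^2 = %.4f\n",
              x$region[1], x$region[2],
              x$strain_range[1], x$strain_range[2], x$r_squared))
  invisible(x)
}

#' @export
print.invasion_counts <- function(x, ...) {
  cat(sprintf("Invasion counts (threshold > %g um): %d invading, %d non-invading\n",
              x$depth_threshold_um, x$n_invading, x$n_non_invading))
  invisible(x)
}
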