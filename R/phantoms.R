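## Synthetic-data generators: fibre-network image phantoms, stained-slide
## phantoms, abundance matrices with planted temporal clusters, and
## stress-strain curves. Every generator is deterministic under `seed` and
## returns its ground truth alongside the data.

## run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## von Mises sampler, Best & Fisher (1979) rejection method.
## kappa = 0 falls back to the uniform distribution on (-pi, pi].
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop_data("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa >= 1e6) return(rep(mu, n))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- (mu + sign(u3 - 0.5) * acos(f) + pi) %% (2 * pi) - pi
      i <- i + 1L
    }
  }
  out
}

## axial (period-180) von Mises angles in degrees on (-90, 90]:
## sample on the doubled angle, then halve (standard axial construction)
raxial_vonmises_deg <- function(n, mean_angle_deg, kappa) {
  psi <- rvonmises(n, 2 * mean_angle_deg * pi / 180, kappa)
  wrap_axial(psi / 2 * 180 / pi)
}

#' Generate a fibre-network image phantom
#'
#' Renders straight fibre segments with Gaussian cross-section onto a
#' calibrated grayscale canvas. Fibre orientations are axial (period 180
#' degrees), drawn from a von Mises distribution on the doubled angle with
#' concentration `kappa` (`kappa = 0` gives an isotropic network;
#' `kappa >= 1e6` is treated as the degenerate all-parallel limit). Fibre
#' centres are uniform over the image. Overlapping fibres combine by
#' maximum, not sum, so the width ground truth of each bundle remains
#' valid. Gaussian read noise and a constant background are added last.
#'
#' @param image_size integer pair (height, width) in pixels.
#' @param n_fibres number of fibres.
#' @param mean_angle mean fibre angle in degrees, in (-90, 90].
#' @param kappa von Mises concentration (>= 0; dimensionless).
#' @param fibre_fwhm_px full width at half maximum of the Gaussian fibre
#'   cross-section, in pixels (> 0).
#' @param fibre_length_px fibre length in pixels.
#' @param intensity peak intensity per fibre.
#' @param noise_sd additive Gaussian noise SD.
#' @param background baseline intensity.
#' @param pixel_size_um calibration attached to the result (default 1).
#' @param seed RNG seed; the same seed reproduces the image exactly.
#' @return A list with `image` (a [calibrated_image()]) and `fibres`
#'   (data.frame: centre_x, centre_y, angle_deg, fwhm_px, length_px).
#' @export
make_fibre_phantom <- function(image_size = c(256, 256), n_fibres = 100,
                               mean_angle = 0, kappa = 0,
                               fibre_fwhm_px = 6, fibre_length_px = 120,
                               intensity = 200, noise_sd = 5,
                               background = 10, pixel_size_um = 1,
                               seed = NULL) {
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (h <= 0 || w <= 0) stop_data("image dimensions must be positive")
  if (fibre_fwhm_px <= 0) stop_data("fibre_fwhm_px must be > 0")
  if (kappa < 0) stop_data("kappa must be >= 0")
  if (n_fibres < 0) stop_data("n_fibres must be >= 0")
  with_seed(seed, {
    sigma <- fibre_fwhm_px / (2 * sqrt(2 * log(2)))
    canvas <- matrix(0, h, w)
    angles <- if (n_fibres) raxial_vonmises_deg(n_fibres, mean_angle, kappa)
              else numeric(0)
    cx <- stats::runif(n_fibres, 1, w)
    cy <- stats::runif(n_fibres, 1, h)
    reach <- ceiling(3 * sigma)
    for (k in seq_len(n_fibres)) {
      th <- angles[k] * pi / 180
      ## x along columns; y up => row component of the direction is -sin
      ux <- cos(th); uy <- -sin(th)
      half <- fibre_length_px / 2
      x0 <- cx[k] - half * ux; y0 <- cy[k] - half * uy
      x1 <- cx[k] + half * ux; y1 <- cy[k] + half * uy
      rlo <- max(1L, floor(min(y0, y1)) - reach)
      rhi <- min(h, ceiling(max(y0, y1)) + reach)
      clo <- max(1L, floor(min(x0, x1)) - reach)
      chi <- min(w, ceiling(max(x0, x1)) + reach)
      if (rlo > rhi || clo > chi) next
      rr <- rlo:rhi; cc <- clo:chi
      px <- matrix(rep(cc, each = length(rr)), length(rr))
      py <- matrix(rep(rr, times = length(cc)), length(rr))
      ## distance from each pixel to the segment
      vx <- x1 - x0; vy <- y1 - y0
      len2 <- vx^2 + vy^2
      t_ <- if (len2 > 0) pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1)
            else 0
      dx <- px - (x0 + t_ * vx); dy <- py - (y0 + t_ * vy)
      contrib <- intensity * exp(-(dx^2 + dy^2) / (2 * sigma^2))
      canvas[rr, cc] <- pmax(canvas[rr, cc], contrib)
    }
    img <- canvas + background
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    img <- pmax(img, 0)
    list(image = calibrated_image(img, pixel_size_um),
         fibres = data.frame(centre_x = cx, centre_y = cy,
                             angle_deg = angles,
                             fwhm_px = rep(fibre_fwhm_px, n_fibres),
                             length_px = rep(fibre_length_px, n_fibres)))
  })
}

## tissue-background HSB box used for phantom pixels outside every class:
## pale bluish pseudo-tissue that passes the default tissue mask but falls
## in none of the shipped stain class boxes
phantom_background_box <- function() hsb_box(170, 190, 40, 100, 120, 200)

#' Generate a stained-slide phantom with known hue-class area fractions
#'
#' Builds an RGB image in which a known fraction of pixels falls inside
#' each stain class's HSB box. Class pixel counts are `round(fraction *
#' n_pixels)`, so planted fractions are exact up to integer rounding.
#' Pixels are drawn uniformly inside each class box, keeping a 2-step
#' margin from the box edges so the integer RGB round-trip cannot move a
#' pixel across a boundary. Remaining pixels are pale pseudo-tissue:
#' inside the default tissue mask but outside every class box, so planted
#' fractions are fractions of tissue area.
#'
#' @param area_fractions named numeric vector/list, class -> fraction;
#'   fractions >= 0 and summing to <= 1. Names must match `boxes`.
#' @param image_size integer pair (height, width).
#' @param boxes named list of [hsb_box()] class definitions (default: the
#'   birefringence red/yellow/green profile).
#' @param seed RNG seed.
#' @return A list with `image` (an [rgb_image()]), `true_fractions`
#'   (realised class pixel count / total pixels) and `n_pixels`.
#' @export
make_stain_phantom <- function(area_fractions, image_size = c(100, 100),
                               boxes = stain_boxes("birefringence"),
                               seed = NULL) {
  fr <- unlist(area_fractions)
  if (length(fr) && (is.null(names(fr)) || any(!nzchar(names(fr)))))
    stop_data("area_fractions must be named by stain class")
  if (any(fr < 0)) stop_data("fractions must be >= 0")
  if (sum(fr) > 1 + 1e-12) stop_data("fractions must sum to <= 1")
  missing_cls <- setdiff(names(fr), names(boxes))
  if (length(missing_cls))
    stop_data("no HSB box for class: ", paste(missing_cls, collapse = ", "))
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (h <= 0 || w <= 0) stop_data("image dimensions must be positive")
  npx <- h * w
  counts <- round(fr * npx)
  if (sum(counts) > npx) counts[which.max(counts)] <- counts[which.max(counts)] - (sum(counts) - npx)
  with_seed(seed, {
    idx <- sample.int(npx)
    H <- S <- B <- integer(npx)
    pos <- 1L
    draw_box <- function(box, n) {
      ## 3-step interior margin, and brightness floored at 80: at low
      ## brightness the integer RGB grid quantises hue coarsely enough to
      ## move a pixel across a box edge on round-trip
      margin <- 3L
      rng <- function(lo, hi) {
        lo2 <- min(lo + margin, hi); hi2 <- max(hi - margin, lo2)
        sample(seq(lo2, hi2), n, replace = TRUE)
      }
      if (isTRUE(box$wrap)) {
        ## wrapped hue interval: sample from the two arcs
        span1 <- box$h_hi + 1; span2 <- 256 - box$h_lo
        pick <- stats::runif(n) < span1 / (span1 + span2)
        hh <- integer(n)
        hh[pick] <- sample(seq(0, max(box$h_hi - margin, 0)), sum(pick), replace = TRUE)
        hh[!pick] <- sample(seq(min(box$h_lo + margin, 255), 255), sum(!pick), replace = TRUE)
      } else hh <- rng(box$h_lo, box$h_hi)
      list(h = hh, s = rng(box$s_lo, box$s_hi),
           b = pmax(rng(box$b_lo, box$b_hi), 80L))
    }
    for (cls in names(fr)) {
      n <- counts[[cls]]
      if (n == 0) next
      sel <- idx[pos:(pos + n - 1L)]; pos <- pos + n
      smp <- draw_box(boxes[[cls]], n)
      H[sel] <- smp$h; S[sel] <- smp$s; B[sel] <- smp$b
    }
    if (pos <= npx) {
      sel <- idx[pos:npx]
      smp <- draw_box(phantom_background_box(), length(sel))
      H[sel] <- smp$h; S[sel] <- smp$s; B[sel] <- smp$b
    }
    rgb <- hsb_to_rgb(H, S, B)
    arr <- array(0, c(h, w, 3))
    arr[, , 1] <- matrix(rgb[1, ], h, w)
    arr[, , 2] <- matrix(rgb[2, ], h, w)
    arr[, , 3] <- matrix(rgb[3, ], h, w)
    truef <- counts / npx
    list(image = rgb_image(arr), true_fractions = truef, n_pixels = npx)
  })
}

## the six condition labels in canonical order
condition_levels <- function()
  c("healthy.early", "healthy.mid", "healthy.late",
    "tumour.early", "tumour.mid", "tumour.late")

## planted log2 profiles over the six conditions, per temporal cluster:
## C1 rising in both tissues, higher and faster-rising in tumour;
## C2 uniformly elevated in tumour; C3 progressively downregulated in
## tumour; C4 down early/mid, up late.
cluster_profiles <- function(effect_size) {
  E <- effect_size
  rbind(
    C1 = c(0, 0.25, 0.5, 0.5, 1.0, 1.5) * E,
    C2 = c(0, 0, 0, 1, 1, 1) * E,
    C3 = c(0, 0, 0, 0, -0.5, -1) * E,
    C4 = c(0, 0, 0, -1, -1, 1) * E)
}

#' Simulate a protein-abundance matrix with planted temporal clusters
#'
#' Generates raw (linear-scale) intensities for a 2-tissue x 3-stage
#' design with `n_reps` replicates per group. Four planted clusters follow
#' distinct temporal shapes (rising-in-both-but-faster-in-tumour;
#' uniformly tumour-elevated; progressively downregulated; down early/mid
#' then up late); null proteins carry no group effect. Log-normal noise is
#' added in log2 space and entries go missing completely at random.
#'
#' @param n_per_cluster proteins per planted cluster (default 40).
#' @param n_null null (no-effect) proteins (default 100).
#' @param n_reps replicates per tissue-stage group (default 5).
#' @param effect_size planted effect in log2 units (default 2).
#' @param noise_sd residual SD in log2 units (default 0.5).
#' @param missing_rate MCAR missingness fraction in \[0, 0.3) by default;
#'   larger values are allowed but will defeat the presence filter.
#' @param seed RNG seed.
#' @return A list with `matrix` (proteins x samples, raw intensities, NA =
#'   missing), `design` (data.frame: sample_id, tissue, stage, replicate),
#'   `truth` (per-protein cluster label, "null" for the null set) and
#'   `annotation` (a synthetic matrisome annotation for the proteins).
#' @export
simulate_abundance <- function(n_per_cluster = 40, n_null = 100, n_reps = 5,
                               effect_size = 2, noise_sd = 0.5,
                               missing_rate = 0.1, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop_data("missing_rate must lie in [0, 1)")
  if (n_reps < 2) stop_data("n_reps must be >= 2")
  with_seed(seed, {
    conds <- condition_levels()
    design <- data.frame(
      sample_id = paste0(rep(conds, each = n_reps), "_r", seq_len(n_reps)),
      tissue = rep(sub("\\..*", "", conds), each = n_reps),
      stage = factor(rep(sub(".*\\.", "", conds), each = n_reps),
                     levels = c("early", "mid", "late")),
      replicate = rep(seq_len(n_reps), times = 6),
      stringsAsFactors = FALSE)
    prof <- cluster_profiles(effect_size)
    truth <- c(rep(rownames(prof), each = n_per_cluster),
               rep("null", n_null))
    n_prot <- length(truth)
    ids <- sprintf("P%04d", seq_len(n_prot))
    cond_idx <- match(paste(design$tissue, design$stage, sep = "."), conds)
    base <- stats::runif(n_prot, 18, 24)
    mu <- matrix(base, n_prot, nrow(design))
    planted <- truth != "null"
    mu[planted, ] <- mu[planted, ] + prof[truth[planted], cond_idx]
    log2v <- mu + matrix(stats::rnorm(n_prot * nrow(design), 0, noise_sd),
                         n_prot, nrow(design))
    vals <- 2^log2v
    if (missing_rate > 0)
      vals[matrix(stats::runif(length(vals)) < missing_rate,
                  n_prot, nrow(design))] <- NA
    dimnames(vals) <- list(ids, design$sample_id)
    list(matrix = vals, design = design,
         truth = stats::setNames(truth, ids),
         annotation = synthetic_matrisome_annotation(ids))
  })
}

#' Synthetic matrisome annotation table
#'
#' Assigns each protein a matrisome category (round-robin over the six
#' Naba-scheme categories) with the division implied by the category:
#' collagens, ECM glycoproteins and proteoglycans nest in the core
#' matrisome; ECM regulators, ECM-affiliated proteins and secreted factors
#' in the matrisome-associated division. Deterministic in the id order.
#'
#' @param protein_ids character vector of protein identifiers.
#' @return data.frame with columns `protein`, `division`, `category`.
#' @export
synthetic_matrisome_annotation <- function(protein_ids) {
  cats <- c("collagens", "ECM glycoproteins", "proteoglycans",
            "ECM regulators", "ECM-affiliated proteins", "secreted factors")
  core <- cats[1:3]
  category <- rep_len(cats, length(protein_ids))
  data.frame(protein = protein_ids,
             division = ifelse(category %in% core,
                               "core matrisome", "matrisome-associated"),
             category = category,
             stringsAsFactors = FALSE)
}

#' Simulate an unconfined-compression stress-strain curve
#'
#' Generates a curve with a concave toe region (stress = E s^2 / (2 t) for
#' strain s below the toe strain t, whose slope rises smoothly from 0 to
#' E) followed by a linear region of slope `modulus`, plus additive
#' Gaussian noise.
#'
#' @param modulus elastic modulus E (kPa, > 0): the slope of the linear
#'   region.
#' @param toe_strain strain at which the toe ends (fraction; 0 disables
#'   the toe).
#' @param noise_sd additive noise SD (kPa).
#' @param n_points number of strain samples.
#' @param max_strain largest strain sampled (default `toe_strain + 0.15`).
#' @param seed RNG seed.
#' @return A list with `strain`, `stress` (kPa), and the generating
#'   parameters.
#' @export
simulate_stress_strain <- function(modulus, toe_strain = 0.05,
                                   noise_sd = 0.01, n_points = 100,
                                   max_strain = toe_strain + 0.15,
                                   seed = NULL) {
  if (modulus <= 0) stop_data("modulus must be > 0")
  if (toe_strain < 0) stop_data("toe_strain must be >= 0")
  if (max_strain <= toe_strain) stop_data("max_strain must exceed toe_strain")
  with_seed(seed, {
    strain <- seq(0, max_strain, length.out = n_points)
    stress <- ifelse(strain < toe_strain & toe_strain > 0,
                     modulus * strain^2 / (2 * toe_strain),
                     modulus * (strain - toe_strain / 2))
    if (noise_sd > 0) stress <- stress + stats::rnorm(n_points, 0, noise_sd)
    list(strain = strain, stress = stress, modulus = modulus,
         toe_strain = toe_strain, noise_sd = noise_sd)
  })
}
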