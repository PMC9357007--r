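## Reproducible multi-stage runs: a flat YAML/list config selects stages
## and parameters; each output TSV carries a provenance header and the run
## directory gets a machine-readable manifest (inputs, parameters, seeds,
## checksums).

known_config_keys <- function() {
  list(
    run = c("seed", "out_dir", "stages"),
    fibre_phantom = c("image_size", "n_fibres", "mean_angle", "kappa",
                      "fibre_fwhm_px", "fibre_length_px", "intensity",
                      "noise_sd", "background", "pixel_size_um"),
    glcm = c("image", "max_distance_px", "levels"),
    orientation = c("image", "n_bins", "smoothing_scale", "weighting",
                    "hsb_map"),
    widths = c("image", "grid", "lines_per_tile", "prominence_frac", "axis"),
    stain = c("image", "profile", "fractions", "image_size"),
    modulus = c("curve", "modulus", "toe_strain", "noise_sd", "n_points",
                "window_frac", "min_r2"),
    matrisome = c("matrix", "design", "annotation", "n_per_cluster",
                  "n_null", "n_reps", "effect_size", "noise_sd",
                  "missing_rate", "min_frac", "fdr", "k", "linkage"))
}

validate_config <- function(config) {
  keys <- known_config_keys()
  unknown_top <- setdiff(names(config), names(keys))
  if (length(unknown_top))
    stop_data("unknown config section: ", paste(unknown_top, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), keys[[sec]])
    if (length(bad))
      stop_data("unknown key in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  invisible(config)
}

provenance_header <- function(stage, params, seed) {
  flat <- vapply(params, function(v) paste(format(v), collapse = ","),
                 character(1))
  c(sprintf("# fibrarch %s", as.character(utils::packageVersion("fibrarch"))),
    sprintf("# stage: %s", stage),
    sprintf("# seed: %s", format(seed)),
    sprintf("# %s: %s", names(flat), flat))
}

write_stage_tsv <- function(df, path, stage, params, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, params, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a stage TSV, skipping provenance headers
#'
#' @param path file written by [run_pipeline()].
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run a multi-stage analysis from a flat config
#'
#' Executes the selected stages in dependency order on synthetic or
#' user-supplied inputs and writes per-stage TSV outputs into a run
#' directory. Every output carries a provenance header (package version,
#' stage, seed, parameters) and the directory gets a `manifest.json`
#' listing stages, parameters, seeds and md5 checksums of the outputs.
#' Unknown config keys are rejected before any computation. With the same
#' config and seed, payloads are byte-identical across runs.
#'
#' Stage inputs: image stages (`glcm`, `orientation`, `widths`) analyse
#' the `image` path given in their section, or the fibre phantom
#' generated by the `fibre_phantom` section. `stain` analyses its `image`
#' or a generated stain phantom with `fractions`. `matrisome` uses
#' `matrix`/`design`/`annotation` TSV paths or a simulated dataset.
#' `modulus` fits the `curve` TSV (columns strain, stress) or a simulated
#' curve.
#'
#' @param config a named list, or path to a YAML file with sections
#'   `run` (seed, out_dir, stages) and one section per stage.
#' @return The run directory path, invisibly; stage outputs and
#'   `manifest.json` inside.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  run <- config$run %||% list()
  seed <- run$seed %||% 1L
  out_dir <- run$out_dir %||% stop_data("run.out_dir is required")
  stages <- run$stages %||% setdiff(names(config), "run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = as.character(utils::packageVersion("fibrarch")),
                   seed = seed, stages = list())
  outputs <- character(0)
  log_msg <- function(...) message(sprintf(...))

  phantom <- NULL
  get_image <- function(sec) {
    p <- config[[sec]][["image"]]
    if (!is.null(p)) return(read_image(p, pixel_size_um = 1))
    if (is.null(phantom)) {
      fp <- config$fibre_phantom %||% list()
      phantom <<- do.call(make_fibre_phantom, c(fp, list(seed = seed)))
      log_msg("fibre_phantom: %d fibres rendered", nrow(phantom$fibres))
    }
    phantom$image
  }

  for (stage in stages) {
    params <- config[[stage]] %||% list()
    out <- file.path(out_dir, paste0(stage, ".tsv"))
    switch(stage,
      fibre_phantom = {
        img <- get_image("fibre_phantom")
        write_image(img, file.path(out_dir, "fibre_phantom.tif"))
        write_stage_tsv(phantom$fibres, out, stage, params, seed)
      },
      glcm = {
        img <- get_image("glcm")
        cur <- glcm_correlation_curve(img,
          max_distance_px = params$max_distance_px %||% 50,
          levels = params$levels %||% 64)
        log_msg("glcm: summary mean correlation %.4f, %d undefined entries",
                cur$summary_mean_correlation, cur$n_undefined)
        write_stage_tsv(cur$table, out, stage, params, seed)
      },
      orientation = {
        img <- get_image("orientation")
        fld <- structure_tensor(img,
          smoothing_scale = params$smoothing_scale %||% 4)
        od <- orientation_distribution(fld,
          n_bins = params$n_bins %||% 180,
          weighting = params$weighting %||% "coherency_energy")
        ar <- align_and_ratio(od)
        log_msg("orientation: mode %.1f deg, peak/baseline %.3g",
                od$peak_angle, ar$peak_to_baseline[1])
        if (!is.null(params$hsb_map))
          png::writePNG(orientation_hsb_map(fld),
                        file.path(out_dir, params$hsb_map))
        write_stage_tsv(
          data.frame(angle_deg = od$bin_centres, weight = od$weights,
                     aligned_weight = ar$aligned[1, ],
                     peak_to_baseline = ar$peak_to_baseline[1]),
          out, stage, params, seed)
      },
      widths = {
        img <- get_image("widths")
        bw <- profile_peak_widths(img,
          grid = params$grid %||% c(3, 3),
          lines_per_tile = params$lines_per_tile %||% 5,
          prominence_frac = params$prominence_frac %||% 0.3,
          axis = params$axis %||% "auto")
        log_msg("widths: %d peaks, mean %.3g um", bw$n_peaks, bw$mean_width_um)
        write_stage_tsv(data.frame(width_um = bw$widths_um), out, stage,
                        params, seed)
      },
      stain = {
        profile <- params$profile %||% "birefringence"
        img <- if (!is.null(params[["image"]])) read_image(params[["image"]])
               else make_stain_phantom(params$fractions %||% list(red = 0.3),
                                       image_size = params$image_size %||% c(100, 100),
                                       boxes = stain_boxes(profile),
                                       seed = seed)$image
        sa <- if (profile == "dab") dab_positive_area(img)
              else stain_area(img, boxes = stain_boxes(profile))
        write_stage_tsv(
          data.frame(class = names(sa$class_fractions),
                     fraction = as.numeric(sa$class_fractions),
                     area_px = as.numeric(sa$class_areas_px),
                     tissue_px = sa$tissue_area_px),
          out, stage, params, seed)
      },
      modulus = {
        curve <- if (!is.null(params$curve)) read_stage_tsv(params$curve)
                 else simulate_stress_strain(params$modulus %||% 10,
                        toe_strain = params$toe_strain %||% 0.05,
                        noise_sd = params$noise_sd %||% 0.01,
                        n_points = params$n_points %||% 100, seed = seed)
        fit <- bulk_modulus(curve$strain, curve$stress,
                            window_frac = params$window_frac %||% 0.3,
                            min_r2 = params$min_r2 %||% 0.99)
        log_msg("modulus: %.4g kPa (R^2 %.4f)", fit$modulus_kpa, fit$r_squared)
        write_stage_tsv(
          data.frame(modulus_kpa = fit$modulus_kpa,
                     r_squared = fit$r_squared,
                     region_from = fit$region[1], region_to = fit$region[2]),
          out, stage, params, seed)
      },
      matrisome = {
        if (!is.null(params$matrix)) {
          mat <- as.matrix(read_stage_tsv(params$matrix)[, -1, drop = FALSE])
          rownames(mat) <- read_stage_tsv(params$matrix)[[1]]
          des <- read_stage_tsv(params$design)
          ann <- read_stage_tsv(params$annotation)
        } else {
          sim <- simulate_abundance(
            n_per_cluster = params$n_per_cluster %||% 40,
            n_null = params$n_null %||% 100,
            n_reps = params$n_reps %||% 5,
            effect_size = params$effect_size %||% 2,
            noise_sd = params$noise_sd %||% 0.5,
            missing_rate = params$missing_rate %||% 0.1,
            seed = seed)
          mat <- sim$matrix; des <- sim$design; ann <- sim$annotation
        }
        filt <- filter_presence(mat, params$min_frac %||% 0.70)
        log_msg("matrisome: %d proteins filtered out, %d retained",
                attr(filt, "n_removed"), nrow(filt))
        norm <- normalise_abundance(filt)
        aov_ <- multi_sample_anova(norm, des, fdr = params$fdr %||% 0.05)
        prof <- condition_profiles(norm, des)
        cl <- temporal_cluster(prof, k = params$k %||% 4,
                               linkage = params$linkage %||% "average")
        enr <- category_enrichment(cl, ann)
        res <- data.frame(protein = rownames(norm),
                          F = aov_$F, p = aov_$p, q = aov_$q,
                          significant = aov_$significant,
                          cluster = cl$labels[rownames(norm)])
        write_stage_tsv(res, out, stage, params, seed)
        write_stage_tsv(enr, file.path(out_dir, "matrisome_enrichment.tsv"),
                        "matrisome_enrichment", params, seed)
        outputs <- c(outputs, file.path(out_dir, "matrisome_enrichment.tsv"))
      },
      stop_data("unknown stage: ", stage))
    outputs <- c(outputs, out)
    manifest$stages[[stage]] <- list(params = params, output = basename(out))
  }
  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
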