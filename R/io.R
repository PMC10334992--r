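#' Write / read DoFP mosaic frames as TIFF with YAML sidecar metadata
#'
#' Frames are stored as 32-bit float TIFF (multi-page for frame stacks) with
#' pixel values in full-scale `[0, 1]` units. A `<path>.yaml` sidecar records
#' the analyzer layout and provenance metadata (mode, seeds, scene factors),
#' so a written file is fully self-describing.
#'
#' @param mosaic A `mosaic_image`, or a list of them (written as a
#'   multi-page stack; all frames must share the layout).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(mosaic, path) {
  frames <- if (inherits(mosaic, "mosaic_image")) list(mosaic) else mosaic
  if (!all(vapply(frames, inherits, logical(1), "mosaic_image"))) {
    stop("`mosaic` must be a mosaic_image or list of them", call. = FALSE)
  }
  layout <- frames[[1]]$layout
  tiff::writeTIFF(lapply(frames, `[[`, "pixels"), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(layout = as.vector(t(layout)),
               n_frames = length(frames),
               frames = lapply(frames, function(f) sanitize_meta(f$meta)))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

sanitize_meta <- function(m) {
  rapply(m, function(x) if (length(x) == 1L && is.na(x)) "NA" else x,
         how = "replace")
}

#' @rdname write_mosaic
#' @param layout Optional 2x2 analyzer-angle matrix (row-major vector of 4
#'   also accepted) overriding / replacing sidecar metadata. A TIFF without
#'   a sidecar and without this argument is a format error.
#' @return `read_mosaic()`: a `mosaic_image`, or a list of them for a
#'   multi-page stack (frames in file order).
#' @export
read_mosaic <- function(path, layout = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  }
  if (is.null(layout)) {
    if (is.null(meta$layout)) {
      stop(paste0("no analyzer layout for ", path, ": supply `layout = ` ",
                  "(2x2 matrix, row-major) or provide the ", sidecar_path(path),
                  " sidecar written by write_mosaic()"), call. = FALSE)
    }
    layout <- matrix(as.integer(meta$layout), 2, 2, byrow = TRUE)
  } else if (!is.matrix(layout)) {
    layout <- matrix(as.integer(layout), 2, 2, byrow = TRUE)
  }
  frames <- lapply(seq_along(pages), function(i) {
    fm <- if (!is.null(meta$frames) && length(meta$frames) >= i) meta$frames[[i]] else list()
    mosaic_image(pages[[i]], layout, meta = fm)
  })
  if (length(frames) == 1L) frames[[1]] else frames
}

#' Write / read Stokes images as multi-page float TIFF
#'
#' Pages, in order: S0, S1, S2, DoLP, AoP, valid mask. S1/S2 (signed) and
#' AoP (degrees) are affinely mapped into `[0, 1]` for storage; the mapping
#' is recorded in the YAML sidecar and undone on read.
#'
#' @param stokes A `stokes_image`.
#' @param path Output TIFF path.
#' @return `path` (write) or a `stokes_image` (read).
#' @export
write_stokes <- function(stokes, path) {
  if (!inherits(stokes, "stokes_image")) stop("`stokes` must be a stokes_image", call. = FALSE)
  s0max <- max(stokes$S0, 1e-12)
  pages <- list(stokes$S0 / s0max,
                (stokes$S1 / s0max + 1) / 2,
                (stokes$S2 / s0max + 1) / 2,
                stokes$DoLP,
                (stokes$AoP + 90) / 180,
                stokes$valid_mask * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(pages = c("S0", "S1", "S2", "DoLP", "AoP", "valid_mask"),
                        s0_max = s0max,
                        resolution_mode = stokes$resolution_mode),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_stokes
#' @export
read_stokes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!file.exists(sidecar_path(path))) {
    stop(sprintf("missing sidecar %s for Stokes image", sidecar_path(path)),
         call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar_path(path))
  p <- tiff::readTIFF(path, all = TRUE)
  s0max <- meta$s0_max
  structure(list(S0 = p[[1]] * s0max,
                 S1 = (2 * p[[2]] - 1) * s0max,
                 S2 = (2 * p[[3]] - 1) * s0max,
                 DoLP = p[[4]],
                 AoP = p[[5]] * 180 - 90,
                 valid_mask = p[[6]] > 0.5,
                 resolution_mode = meta$resolution_mode %||% "interpolated"),
            class = "stokes_image")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return Validated config list (see [run_pipeline()]).
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

pipeline_config_keys <- list(
  scene = c("alignment", "mode", "shape", "seed", "collagen_density",
            "riboflavin", "transmission_level", "mu_deg", "kappa",
            "retardance_rad", "depol_linear", "c_ret", "thickness_factor",
            "control_transmissivity", "base_intensity", "depol_transmission",
            "depol_reflectance", "retardance_jitter"),
  sensor = c("layout", "gain", "read_noise_sd", "bit_depth"),
  top = c("scene", "sensor", "input_handedness", "noise", "noise_seed",
          "demosaic", "estimator", "roi_margin", "roi_mask", "scale_max",
          "output_dir", "write_maps", "log")
)

validate_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_config_keys$top)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (blk in c("scene", "sensor")) {
    bad <- setdiff(names(config[[blk]]), pipeline_config_keys[[blk]])
    if (length(bad)) {
      stop(sprintf("unknown keys in `%s` block: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$scene$seed)) {
    stop("config must set scene$seed (no silent nondeterminism)", call. = FALSE)
  }
  if (isTRUE(config$noise %||% TRUE) && is.null(config$noise_seed)) {
    stop("config must set noise_seed when noise is enabled", call. = FALSE)
  }
  config
}

#' Run the simulate -> demosaic -> Stokes -> ROI-outcome pipeline
#'
#' Executes the full processing chain described by a config list (or YAML
#' path): generate the phantom scene, render the DoFP mosaic, demosaic,
#' compute Stokes/DoLP/AoP, and compute ROI outcomes. Outputs are written
#' under `output_dir`: `outcomes.csv` (with the producing configuration
#' echoed as `#`-prefixed header comments) and, if `write_maps` is true,
#' `dolp.png` / `aop.png` rendered maps. Fully deterministic given the
#' config (all seeds explicit).
#'
#' @param config Config list or path to a YAML file. Blocks: `scene`
#'   (passed to [generate_scene()]), `sensor` ([sensor_params()]), plus
#'   `input_handedness`, `noise`, `noise_seed`, `demosaic`
#'   (`"bilinear"`/`"superpixel"`), `estimator`, `roi_margin` or `roi_mask`
#'   (path to a mask image), `scale_max`, `output_dir`, `write_maps`.
#' @return The outcome `data.frame` (columns `sample_id`, `mode`, `roi_id`,
#'   `n_pixels`, `avg_dolp`, `std_aop_deg`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  log_on <- isTRUE(config$log)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    if (log_on) {
      message(sprintf("[%s] %.2fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    out
  }
  scn_args <- config$scene
  scn_args$shape <- as.numeric(scn_args$shape %||% c(64, 64))
  scene <- stage("scene", do.call(generate_scene, scn_args))
  sens_args <- config$sensor %||% list()
  if (!is.null(sens_args$layout)) {
    sens_args$layout <- matrix(as.integer(sens_args$layout), 2, 2, byrow = TRUE)
  }
  sensor <- do.call(sensor_params, sens_args)
  noise <- isTRUE(config$noise %||% TRUE)
  mosaic <- stage("render", render_mosaic(
    scene, sensor, config$input_handedness %||% "right",
    noise = noise, seed = if (noise) config$noise_seed else NULL))
  stokes <- stage("stokes", compute_stokes(
    demosaic(mosaic, config$demosaic %||% "bilinear")))
  mask <- stage("roi", {
    if (!is.null(config$roi_mask)) {
      if (!file.exists(config$roi_mask)) {
        stop(sprintf("ROI mask file not found: %s", config$roi_mask))
      }
      img <- tiff::readTIFF(config$roi_mask)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img > 0.5
    } else {
      roi_rect(dim(stokes$S0), config$roi_margin %||% 2L)
    }
  })
  outcomes <- stage("outcomes", {
    df <- roi_outcomes(stokes, list(roi1 = mask),
                       estimator = config$estimator %||% "recentred")
    cbind(data.frame(sample_id = sprintf("%s_seed%d", scene$alignment, scene$seed),
                     mode = scene$mode), df)
  })
  outdir <- config$output_dir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_outcomes_csv(outcomes, file.path(outdir, "outcomes.csv"), config)
  if (isTRUE(config$write_maps)) {
    png::writePNG(render_map(stokes$DoLP, "dolp",
                             scale_max = config$scale_max %||% 1),
                  file.path(outdir, "dolp.png"))
    png::writePNG(render_map(stokes$AoP, "aop"), file.path(outdir, "aop.png"))
  }
  invisible(outcomes)
}

#' Write an outcome table as CSV with provenance header comments
#'
#' The producing configuration is echoed as `#`-prefixed comment lines
#' before the CSV header, so every output file embeds its provenance.
#'
#' @param df Outcome `data.frame`.
#' @param path Output path.
#' @param config The producing config list (echoed in the header).
#' @export
write_outcomes_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    y <- strsplit(yaml::as.yaml(config), "\n")[[1]]
    writeLines(paste("#", y), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an outcomes CSV written by [write_outcomes_csv()]
#'
#' @param path CSV path.
#' @return `data.frame` (comment lines skipped).
#' @export
read_outcomes_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
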