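## end-to-end orchestration: image -> maps/HSB -> tensors/masks -> streamlines

default_run_config <- function() {
  list(
    prep = list(channel = "red", invert = TRUE, equalize = TRUE,
                clip_limit = 0.01, tile_grid = c(8L, 8L),
                out_range = c(0, 255), downsample_factor = 1L,
                invert_first = TRUE),
    st = list(sigma_window = 5, gradient_kernel = "cubic_spline",
              fa_denominator = "quadratic"),
    tensor = list(downsample_factor = 4L, track_convention = TRUE),
    mask = list(percentile = 95, close_radius = 5L),
    track = list(step_px = 2, curve_threshold_deg = 75, fa_min = 0.1,
                 iterations_per_seed = 10L, max_steps = 2000L,
                 min_points = 5L, bidirectional = TRUE),
    seed = 1L
  )
}

## deep-merge user config over defaults, rejecting unknown keys
resolve_run_config <- function(config = list()) {
  def <- default_run_config()
  merge_level <- function(base, user, path = "") {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
    }
    for (k in names(user)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
        merge_level(base[[k]], user[[k]], paste0(path, ".", k))
      } else user[[k]]
    }
    base
  }
  merge_level(def, config)
}

#' Read a run configuration from a YAML file
#'
#' Nested keys mirror [default_run_config()]: `prep.*`, `st.*`, `tensor.*`,
#' `mask.*`, `track.*`, `seed`. Unknown keys are rejected.
#'
#' @param path YAML file
#' @return resolved configuration list
#' @export
read_run_config <- function(path) {
  resolve_run_config(yaml::read_yaml(path))
}

as_input_image <- function(input) {
  if (inherits(input, "raster_image")) return(input)
  if (is.character(input)) return(read_image(input))
  if (is.list(input) && inherits(input$image, "raster_image")) return(input$image)
  stop("input must be a raster_image, a phantom, or an image path")
}

write_provenance <- function(out_dir, cfg, input, extra = list()) {
  prov <- list(config = cfg,
               package_version = as.character(utils::packageVersion("histotract")))
  if (is.character(input) && file.exists(input)) {
    prov$input <- list(path = input,
                       md5 = unname(tools::md5sum(input)))
  }
  jsonlite::write_json(c(prov, extra),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the orientation-analysis pipeline on a section image
#'
#' Preprocesses the image (grayscale + inversion by default - the HSB
#' dialect), computes the structure tensor field, and writes orientation,
#' coherency and FA maps (32-bit float NIfTI) plus the HSB orientation
#' render (8-bit RGB PNG) and a resolved-config snapshot.
#'
#' @param input image path, [raster_image()], or phantom list
#' @param out_dir output directory (created); NULL skips writing
#' @param config nested configuration list (see [default_run_config()]);
#'   missing keys take defaults
#' @param dialect preprocessing dialect, "hsb" (default) or "tract"
#' @return invisibly, a list with the preprocessed image, `st`, `eigen`,
#'   the three `scalar_map`s and the `hsb_render`
#' @export
run_analyze <- function(input, out_dir = NULL, config = list(),
                        dialect = "hsb") {
  cfg <- resolve_run_config(config)
  img <- as_input_image(input)
  pc <- prep_config(channel = if (dialect == "hsb") "luminance" else cfg$prep$channel,
                    invert = cfg$prep$invert,
                    equalize = dialect != "hsb" && cfg$prep$equalize,
                    clip_limit = cfg$prep$clip_limit,
                    tile_grid = cfg$prep$tile_grid,
                    out_range = cfg$prep$out_range,
                    downsample_factor = cfg$prep$downsample_factor)
  pre <- prep_image(img, dialect = dialect, cfg = pc,
                    invert_first = cfg$prep$invert_first)
  st <- compute_structure_tensor(pre, sigma_window = cfg$st$sigma_window,
                                 gradient_kernel = cfg$st$gradient_kernel)
  ef <- eigen_decompose(st)
  coh <- coherency(ef)
  fa <- fa2d(ef, denominator = cfg$st$fa_denominator)
  orient <- new_scalar_map(ef$theta_fiber, "orientation")
  hsb <- render_hsb(ef, pre, coherency_map = coh)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scalar_map(orient, file.path(out_dir, "orientation.nii.gz"))
    write_scalar_map(coh, file.path(out_dir, "coherency.nii.gz"))
    write_scalar_map(fa, file.path(out_dir, "fa2d.nii.gz"))
    write_hsb_png(hsb, file.path(out_dir, "hsb.png"))
    write_provenance(out_dir, cfg, input, list(dialect = dialect))
  }
  invisible(list(pre = pre, st = st, eigen = ef, orientation = orient,
                 coherency = coh, fa = fa, hsb = hsb, config = cfg))
}

#' Run the histology-based tractography pipeline
#'
#' The full tracking chain: tract-dialect preprocessing (red channel,
#' inversion, CLAHE, normalization), structure tensors, pseudo-3D tensor
#' embedding, brain mask (Otsu + closing + fill + largest component) at
#' full resolution, tensor down-sampling (factor 4 by default) with FA
#' recomputed from the averaged tensors, seed mask from the top FA
#' percentile inside the coarse brain mask, deterministic RK4 streamline
#' tracking, and export of the 4D NIfTI tensor volume, masks, VTK
#' streamlines and a JSON run summary.
#'
#' Alternatively `input` may be a pre-built tensor NIfTI (path ending in
#' .nii/.nii.gz); preprocessing and masking from intensity are then
#' replaced by a positive-trace brain mask on the tensor grid.
#'
#' @param input image path, [raster_image()], phantom list, or tensor
#'   NIfTI path
#' @param out_dir output directory (created); NULL skips writing
#' @param config nested configuration list; `config$seed` is the master
#'   RNG seed of the run
#' @return invisibly, a list with the coarse `tv`, `fa`, `brain`, `seeds`,
#'   the `streamline_set` and the run `summary`
#' @export
run_track <- function(input, out_dir = NULL, config = list()) {
  cfg <- resolve_run_config(config)
  is_nifti <- is.character(input) && grepl("\\.nii(\\.gz)?$", input)
  if (is_nifti) {
    tv0 <- read_nifti_tensor(input)
    ds <- downsample_tensor(tv0, cfg$tensor$downsample_factor,
                            fa_denominator = cfg$st$fa_denominator)
    tvc <- ds$tv; fac <- ds$fa
    trace <- tvc$d[, , 1] + tvc$d[, , 4] + tvc$d[, , 6]
    brain_c <- new_mask(trace > 0, "brain")
  } else {
    img <- as_input_image(input)
    pc <- prep_config(channel = cfg$prep$channel, invert = cfg$prep$invert,
                      equalize = cfg$prep$equalize,
                      clip_limit = cfg$prep$clip_limit,
                      tile_grid = cfg$prep$tile_grid,
                      out_range = cfg$prep$out_range,
                      downsample_factor = cfg$prep$downsample_factor)
    pre <- prep_image(img, dialect = "tract", cfg = pc,
                      invert_first = cfg$prep$invert_first)
    st <- compute_structure_tensor(pre, sigma_window = cfg$st$sigma_window,
                                   gradient_kernel = cfg$st$gradient_kernel)
    tv0 <- embed_pseudo_tensor(st, track_convention = cfg$tensor$track_convention,
                               voxel_size = pre$pixel_size_um)
    brain_f <- build_brain_mask(pre, close_radius = cfg$mask$close_radius)
    ds <- downsample_tensor(tv0, cfg$tensor$downsample_factor,
                            fa_denominator = cfg$st$fa_denominator)
    tvc <- ds$tv; fac <- ds$fa
    brain_c <- downsample_mask(brain_f, cfg$tensor$downsample_factor)
  }
  seeds <- build_seed_mask(fac, brain_c, percentile = cfg$mask$percentile)
  tcfg <- tracking_config(step_px = cfg$track$step_px,
                          curve_threshold_deg = cfg$track$curve_threshold_deg,
                          fa_min = cfg$track$fa_min,
                          iterations_per_seed = cfg$track$iterations_per_seed,
                          max_steps = cfg$track$max_steps,
                          min_points = cfg$track$min_points,
                          bidirectional = cfg$track$bidirectional)
  ss <- track_streamlines(tvc, fac, brain_c, seeds, tcfg,
                          run_seed = cfg$seed)
  summ <- streamline_summary(ss)
  summ$seed_mask_threshold <- attr(seeds, "threshold")
  summ$n_seed_voxels <- sum(seeds$values)
  summ$n_brain_voxels <- sum(brain_c$values)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nifti_tensor(tvc, file.path(out_dir, "tensor.nii.gz"))
    write_mask_png(brain_c, file.path(out_dir, "brain_mask.png"))
    write_mask_png(seeds, file.path(out_dir, "seed_mask.png"))
    write_float_map(fac$values, file.path(out_dir, "fa2d_coarse.nii.gz"))
    write_vtk(ss, file.path(out_dir, "streamlines.vtk"))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    write_provenance(out_dir, cfg, input)
  }
  invisible(list(tv = tvc, fa = fac, brain = brain_c, seeds = seeds,
                 streamlines = ss, summary = summ, config = cfg))
}

#' Run analysis and tractography together
#'
#' Convenience wrapper: [run_analyze()] (HSB dialect) and [run_track()]
#' on the same input, writing into `analyze/` and `track/` subdirectories.
#'
#' @inheritParams run_track
#' @return invisibly, list(analyze, track)
#' @export
run_pipeline <- function(input, out_dir = NULL, config = list()) {
  a <- run_analyze(input, if (is.null(out_dir)) NULL
                   else file.path(out_dir, "analyze"), config)
  t <- run_track(input, if (is.null(out_dir)) NULL
                 else file.path(out_dir, "track"), config)
  invisible(list(analyze = a, track = t))
}
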