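#' Read a time-lapse stack from a multi-page TIFF with sidecar metadata
#'
#' The sidecar JSON supplies the calibration that TIFF alone does not
#' carry (`frame_interval`, optional `pixel_size`, `channel`, and the
#' `intensity_scale` used at write time).  A missing sidecar is an error,
#' never a silent default.
#'
#' @param path Path to a single-channel multi-page TIFF.
#' @param sidecar Path to the sidecar JSON; defaults to `path` with a
#'   `.json` extension appended.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  if (!file.exists(sidecar))
    stop("missing sidecar metadata (", sidecar, "): frame_interval is ",
         "required and is never defaulted")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$frame_interval))
    stop("sidecar lacks frame_interval")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("TIFF read error in ", path, ": ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (k in seq_along(pages)) {
    if (length(dim(pages[[k]])) > 2)
      stop("page ", k, " has multiple samples per pixel; ",
           "single-channel TIFFs only")
  }
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
  image_stack(arr, meta$frame_interval,
              pixel_size = meta$pixel_size,
              channel = if (is.null(meta$channel)) "" else meta$channel)
}

#' Write a stack as multi-page 32-bit TIFF plus sidecar JSON
#'
#' Intensities are scaled into `[0, 1]` for storage; the scale factor is
#' recorded in the sidecar so [read_image_stack()] restores the original
#' values (to 32-bit float precision).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param sidecar Sidecar JSON path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path,
                              sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  tt <- dim(stack$data)[3]
  pages <- lapply(seq_len(tt), function(k) stack$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(list(frame_interval = stack$frame_interval,
                            pixel_size = stack$pixel_size,
                            channel = stack$channel,
                            intensity_scale = scale),
                       sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Trace CSV round trip
#'
#' @param trace An [activity_trace()].
#' @param path CSV path.
#' @return `path` invisibly (write) / an [activity_trace()] (read).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "activity_trace"))
  # full double precision so the round trip is exact
  utils::write.csv(data.frame(time_min = sprintf("%.17g", trace$times),
                              value = sprintf("%.17g", trace$values),
                              label = trace$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  activity_trace(as.numeric(df$time_min), as.numeric(df$value),
                 label = if ("label" %in% names(df) && nrow(df) > 0)
                   as.character(df$label[1]) else "")
}

# md5 of the canonical JSON rendering of a config list
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Write analysis artifacts and a run manifest
#'
#' Writes event tables, traces and kymographs as CSV under `out_dir` and
#' a `manifest.json` listing every artifact together with the config
#' hash, seed and package version, so any run can be reconstructed.
#'
#' @param events Named list of event data frames (may be empty).
#' @param traces Named list of [activity_trace()]s.
#' @param kymographs Named list of `perimeter_kymograph`s.
#' @param out_dir Output directory (created if absent).
#' @param config The run configuration (hashed into the manifest).
#' @param seed The seed used.
#' @param force Overwrite an existing manifest (default `FALSE`).
#' @return The manifest, invisibly.
#' @export
write_results <- function(events = list(), traces = list(),
                          kymographs = list(), out_dir, config = list(),
                          seed = NA, force = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("refusing to overwrite existing results in ", out_dir,
         " (use force = TRUE)")
  artifacts <- character(0)
  for (nm in names(events)) {
    p <- file.path(out_dir, paste0("events_", nm, ".csv"))
    utils::write.csv(events[[nm]], p, row.names = FALSE)
    artifacts <- c(artifacts, basename(p))
  }
  for (nm in names(traces)) {
    p <- file.path(out_dir, paste0("trace_", nm, ".csv"))
    write_trace_csv(traces[[nm]], p)
    artifacts <- c(artifacts, basename(p))
  }
  for (nm in names(kymographs)) {
    p <- file.path(out_dir, paste0("kymo_", nm, ".csv"))
    utils::write.csv(as.data.frame(kymographs[[nm]]$values), p,
                     row.names = FALSE)
    artifacts <- c(artifacts, basename(p))
  }
  manifest <- list(artifacts = artifacts,
                   config_hash = config_hash(config),
                   seed = seed,
                   package_version =
                     as.character(utils::packageVersion("pulsecoupler")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# defaults equal to the published analysis thresholds
default_run_config <- function() {
  list(
    mode = "synth",
    seed = NULL,
    out_dir = NULL,
    fdm = list(interval_minutes = 6, avg_window = 3,
               protrusion_threshold_pct = 100, flash_threshold_pct = 10,
               min_duration_min = 5, min_area_px = 25, kymo_bins = 120),
    quantify = list(pulse_threshold = 0.20, max_lag_min = 30,
                    pairing_window_min = 15, smoothing_window = 3),
    simulate = list(preset = "high_threshold", duration = 240,
                    sample_every = 25, stimulus = "none", erk = TRUE),
    synth = list(duration = 120, n_protrusions = 4, noise_sigma = 0,
                 erk_delay = 5, erk_gain = 0.1)
  )
}

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML or JSON (by extension).  Unknown keys are rejected;
#' every analysis threshold has a default equal to the published value
#' (100% and 10% FDM thresholds over 6 min, 5-min minimum duration,
#' 20% pulse rule).  Stochastic runs require an explicit seed.
#'
#' @param path Config file path.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml/.yml or .json"))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A raw config list.
#' @export
validate_run_config <- function(cfg) {
  def <- default_run_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in c("fdm", "quantify", "simulate", "synth")) {
    if (!is.null(cfg[[blk]])) {
      badk <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
      if (length(badk))
        stop("unknown keys in ", blk, ": ", paste(badk, collapse = ", "))
    }
  }
  out <- utils::modifyList(def, cfg)
  if (!out$mode %in% c("synth", "simulate"))
    stop("mode must be 'synth' or 'simulate'")
  if (is.null(out$seed))
    stop("seed is required for stochastic subcommands")
  if (out$fdm$interval_minutes %% 1 != 0 ||
      out$fdm$interval_minutes < out$fdm$avg_window)
    stop("validation error: fdm interval must be a whole number of ",
         "minutes and at least avg_window frames")
  structure(out, class = "run_config")
}
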