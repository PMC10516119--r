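# Frame and results I/O. Frames travel as grayscale TIFF (multi-page per
# epoch) or PNG sequences with a CSV schedule sidecar; results are plain CSVs
# plus a JSON run manifest. The device sensor is monochrome, so RGB inputs
# are rejected rather than silently converted.

frame_sidecar_name <- "frames.csv"

#' Write hologram frames to disk
#'
#' Writes a multi-page grayscale TIFF (or a PNG sequence) together with a
#' `frames.csv` schedule sidecar (columns `frame`, `timestamp_s`,
#' `epoch_id`). Pixel values are stored at the noise model's bit depth and
#' round-trip exactly through [read_frames()].
#'
#' @param frames List of [hologram_frame] objects.
#' @param path Output file (`.tif`) or directory (PNG sequence).
#' @param bit_depth 8 or 16.
#' @param format `"tiff"` or `"png"`.
#' @return The path, invisibly.
#' @export
write_frames <- function(frames, path, bit_depth = 8L,
                         format = c("tiff", "png")) {
  format <- match.arg(format)
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  full <- 2^bit_depth - 1
  mats <- lapply(frames, function(f) {
    m <- f$intensity / full
    if (any(m < 0 | m > 1)) stopf("frame counts exceed the %d-bit range", bit_depth)
    m
  })
  sched <- data.frame(
    frame = seq_along(frames),
    timestamp_s = vapply(frames, function(f) f$timestamp_s, numeric(1)),
    epoch_id = vapply(frames, function(f) f$epoch_id, integer(1)))
  if (format == "tiff") {
    tiff::writeTIFF(mats, path, bits.per.sample = bit_depth,
                    compression = "none")
    sidecar <- file.path(dirname(path), frame_sidecar_name)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(mats))
      png::writePNG(mats[[i]], file.path(path, sprintf("frame_%04d.png", i)))
    sidecar <- file.path(path, frame_sidecar_name)
  }
  write.csv(cbind(sched, bit_depth = bit_depth, pitch_um =
                    vapply(frames, function(f) f$pitch_um, numeric(1))),
            sidecar, row.names = FALSE)
  invisible(path)
}

#' Read hologram frames from disk
#'
#' Reads a multi-page TIFF or a directory of PNG/TIFF frames, ordered by the
#' schedule sidecar's timestamps (or file order when no sidecar exists).
#' Bit depth is preserved: pixel values come back as floating detector
#' counts. Mixed shapes or bit depths, and RGB images, are rejected.
#'
#' @param path A TIFF file or a directory of frames.
#' @return List of [hologram_frame] objects.
#' @export
read_frames <- function(path) {
  read_one_tiff <- function(f) {
    pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    lapply(pages, function(p) {
      if (length(dim(p)) == 3L) stopf("RGB frames are not supported: %s", f)
      storage.mode(p) <- "double"
      p
    })
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stopf("no frames found in %s", path)
    mats <- unlist(lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        p <- png::readPNG(f, info = TRUE)
        if (length(dim(p)) == 3L) stopf("RGB frames are not supported: %s", f)
        bits <- attr(p, "info")$bit.depth
        if (is.null(bits)) bits <- 8L
        m <- p * (2^bits - 1)
        attributes(m) <- list(dim = dim(p))
        list(m)
      } else read_one_tiff(f)
    }), recursive = FALSE)
    sidecar <- file.path(path, frame_sidecar_name)
  } else {
    if (!file.exists(path)) stopf("no such file: %s", path)
    mats <- read_one_tiff(path)
    sidecar <- file.path(dirname(path), frame_sidecar_name)
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames have mixed shapes")
  n <- length(mats)
  sched <- if (file.exists(sidecar)) read.csv(sidecar) else {
    warnf("no %s sidecar; assuming 1 s spacing, epoch 0", frame_sidecar_name)
    data.frame(frame = seq_len(n), timestamp_s = seq_len(n) - 1,
               epoch_id = 0L, pitch_um = 1.67)
  }
  if (nrow(sched) != n)
    stopf("sidecar lists %d frames but %d were read", nrow(sched), n)
  ord <- order(sched$timestamp_s)
  lapply(ord, function(i) {
    hologram_frame(mats[[i]],
                   if ("pitch_um" %in% names(sched)) sched$pitch_um[i] else 1.67,
                   sched$timestamp_s[i], sched$epoch_id[i])
  })
}

#' Read an hourly reference PM2.5 series
#'
#' CSV with columns `hour_start_iso` (ISO-8601 UTC) and `pm25_ugm3_int`
#' (nonnegative integers, as county monitors report whole numbers; the
#' +/- 0.5 rounding error is carried as `rounding_error_ugm3`).
#'
#' @param path CSV file path.
#' @return Data frame with `hour_start` (POSIXct, UTC), `pm25_ugm3`, and
#'   `rounding_error_ugm3`.
#' @export
read_reference_series <- function(path) {
  df <- read.csv(path)
  if (!all(c("hour_start_iso", "pm25_ugm3_int") %in% names(df)))
    stopf("reference CSV needs columns hour_start_iso, pm25_ugm3_int")
  v <- df$pm25_ugm3_int
  if (any(v < 0) || any(v != floor(v)))
    stopf("reference PM2.5 values must be nonnegative integers")
  data.frame(hour_start = as.POSIXct(df$hour_start_iso, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%SZ"),
             pm25_ugm3 = as.numeric(v), rounding_error_ugm3 = 0.5)
}

iso_utc <- function(t0, offset_s) {
  format(t0 + offset_s, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Write pipeline results
#'
#' Writes `detections.csv`, `histogram.csv` (long format), `pm_hourly.csv`
#' and a `run_manifest.json` recording the configuration, seed and package
#' version. Outputs are deterministic: equal inputs give byte-identical CSV
#' bodies.
#'
#' @param detections Detection table (may be empty).
#' @param histograms Long-format histogram table (may be `NULL`).
#' @param pm_series Hourly PM table (may be `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list stored in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(detections, histograms, pm_series, out_dir,
                          config = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(detections = file.path(out_dir, "detections.csv"),
             histogram = file.path(out_dir, "histogram.csv"),
             pm_hourly = file.path(out_dir, "pm_hourly.csv"),
             manifest = file.path(out_dir, "run_manifest.json"))
  det_cols <- c("epoch_id", "x_um", "y_um", "peak_phase_rad", "pass_index",
                "diameter_nm", "clamped")
  det <- as.data.frame(detections)
  for (cn in det_cols) if (!cn %in% names(det))
    det[[cn]] <- if (nrow(det)) NA else logical(0)
  write.csv(det[det_cols], paths[["detections"]], row.names = FALSE)
  if (is.null(histograms))
    histograms <- data.frame(epoch_id = integer(0), bin_lo_nm = numeric(0),
                             bin_hi_nm = numeric(0), count = integer(0))
  write.csv(histograms, paths[["histogram"]], row.names = FALSE)
  if (is.null(pm_series))
    pm_series <- data.frame(hour = integer(0), pm_cap_ugm3 = numeric(0),
                            pm_ugm3 = numeric(0))
  write.csv(pm_series, paths[["pm_hourly"]], row.names = FALSE)
  cfg_txt <- if (is.null(config)) "" else yaml::as.yaml(config)
  tf <- tempfile(); writeLines(cfg_txt, tf)
  manifest <- list(package = "holopm",
                   version = as.character(packageVersion("holopm")),
                   seed = seed, config_hash = unname(tools::md5sum(tf)),
                   config = config)
  unlink(tf)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
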