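#' Average repeated exposures of one acquisition epoch
#'
#' The device records 20 frames per 10-minute epoch and averages them to beat
#' down sensor noise before reconstruction. All frames must share the same
#' shape and epoch; the averaged frame carries the mean timestamp.
#'
#' @param frames List of [hologram_frame] objects.
#' @return A single averaged [hologram_frame].
#' @export
average_frames <- function(frames) {
  if (length(frames) < 1L) stopf("need at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "hologram_frame")))
    stopf("all elements must be hologram_frame objects")
  dims <- vapply(frames, function(f) dim(f$intensity), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames have mismatched shapes")
  epochs <- vapply(frames, function(f) f$epoch_id, integer(1))
  if (length(unique(epochs)) != 1L)
    stopf("frames belong to different epochs: %s",
          paste(unique(epochs), collapse = ", "))
  acc <- Reduce(`+`, lapply(frames, function(f) f$intensity))
  hologram_frame(acc / length(frames), frames[[1]]$pitch_um,
                 mean(vapply(frames, function(f) f$timestamp_s, numeric(1))),
                 epochs[1])
}

#' Normalize a hologram against its particle-free background
#'
#' Divides the frame by the scalar mean intensity of a background region so
#' the unscattered background sits at 1, as required before taking the square
#' root of intensity as field amplitude. The region is either a user rectangle
#' (mirroring the device workflow, where the user selects a particle-free
#' portion of the lensfree image) or `"auto"`, which picks the tile of minimal
#' local variance.
#'
#' @param frame A [hologram_frame].
#' @param background_roi Either `"auto"` or an integer vector
#'   `c(row0, row1, col0, col1)` (1-based, inclusive).
#' @param tile_px Tile size used by the `"auto"` search.
#' @return The normalized [hologram_frame] (background mean ~ 1).
#' @export
normalize_background <- function(frame, background_roi = "auto",
                                 tile_px = 16L) {
  if (!inherits(frame, "hologram_frame")) stopf("frame must be a hologram_frame")
  I <- frame$intensity
  if (identical(background_roi, "auto")) {
    nr <- nrow(I); nc <- ncol(I)
    tile_px <- min(tile_px, nr, nc)
    r_starts <- seq(1L, nr - tile_px + 1L, by = tile_px)
    c_starts <- seq(1L, nc - tile_px + 1L, by = tile_px)
    best <- NULL; best_var <- Inf
    for (r in r_starts) for (cc in c_starts) {
      tile <- I[r:(r + tile_px - 1L), cc:(cc + tile_px - 1L)]
      v <- var(as.vector(tile))
      if (v < best_var) { best_var <- v; best <- tile }
    }
    bg <- mean(best)
  } else {
    r <- as.integer(background_roi)
    if (length(r) != 4L || r[1] < 1 || r[3] < 1 || r[2] > nrow(I) ||
        r[4] > ncol(I) || r[1] > r[2] || r[3] > r[4])
      stopf("background_roi must be c(row0, row1, col0, col1) within the frame")
    bg <- mean(I[r[1]:r[2], r[3]:r[4]])
  }
  if (bg <= 0) stopf("background mean is <= 0; cannot normalize")
  frame$intensity <- I / bg
  frame
}
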