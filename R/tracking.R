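#' Optical-flow parameters
#'
#' Parameters of the pyramidal Lucas-Kanade tracker used to propagate the
#' end-diastolic endocardial trace through the cycle. Defaults follow common
#' practice for speckle tracking at typical apical acquisition resolution:
#' 3 pyramid levels and a 15 px window.
#'
#' @param pyramid_levels coarse-to-fine pyramid depth.
#' @param window_px square tracking window side in pixels (odd).
#' @param max_iterations Newton iterations per pyramid level.
#' @param eps convergence threshold on the per-iteration update (pixels).
#' @return A named list of class `flow_params`.
#' @export
flow_params <- function(pyramid_levels = 3L, window_px = 15L,
                        max_iterations = 20L, eps = 0.01) {
  window_px <- as.integer(window_px)
  if (window_px %% 2L == 0L) window_px <- window_px + 1L
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 window_px = window_px,
                 max_iterations = as.integer(max_iterations),
                 eps = as.double(eps)),
            class = "flow_params")
}

#' Track a contour through a cardiac cycle
#'
#' Propagates the end-diastolic contour frame-to-frame over `[ed_frame,
#' end_frame]` by pyramidal Lucas-Kanade optical flow estimated at each
#' contour point (speckle tracking with a translation model per point).
#' Displacement accumulates across frames; the spurious drift this produces is
#' removed later by the strain module's drift correction. Tracking is
#' deterministic given frames and parameters.
#'
#' @param frames list of image matrices (values in `[0, 1]`), indexed so that
#'   `frames[[k + 1]]` is frame `k` (0-based).
#' @param ed_contour the [contour()] at `cycle$ed_frame` (typically already
#'   resampled to the canonical tracking resolution).
#' @param cycle a [cardiac_cycle()]; `ed_contour$frame_index` must equal
#'   `cycle$ed_frame` and the frames must cover the cycle.
#' @param params a [flow_params()].
#' @return Object of class `tracked_sequence`: `points` (n_points x 2 x
#'   n_frames array of tracked positions), `frames` (0-based frame indices),
#'   `source` (the ED contour), `pixel_spacing`, `residuals` (per-frame median
#'   patch dissimilarity, mean absolute intensity difference), `flagged`
#'   (per-frame count of clamped out-of-image points) and
#'   `stabilization_weight` (0 until [stabilize()] is applied).
#' @export
track_contour <- function(frames, ed_contour, cycle, params = flow_params()) {
  stopifnot(inherits(ed_contour, "echo_contour"), inherits(cycle, "cardiac_cycle"))
  if (ed_contour$frame_index != cycle$ed_frame)
    abort("invalid_cycle", "ED contour frame (%d) does not match cycle ED (%d)",
          ed_contour$frame_index, cycle$ed_frame)
  if (length(frames) < cycle$end_frame + 1L)
    abort("invalid_cycle", "frames do not cover the cycle (need %d, got %d)",
          cycle$end_frame + 1L, length(frames))
  idx <- cycle$ed_frame:cycle$end_frame
  nf <- length(idx)
  npt <- nrow(ed_contour$points)
  pts <- ed_contour$points
  out <- array(NA_real_, dim = c(npt, 2L, nf))
  out[, , 1L] <- pts
  residuals <- numeric(nf)
  flagged <- integer(nf)
  for (k in seq_len(nf - 1L)) {
    f0 <- frames[[idx[k] + 1L]]
    f1 <- frames[[idx[k + 1L] + 1L]]
    r <- lk_track_cpp(f0, f1, pts, params$pyramid_levels, params$window_px,
                      params$max_iterations, params$eps)
    pts <- r$points
    out[, , k + 1L] <- pts
    residuals[k + 1L] <- median(r$residual)
    flagged[k + 1L] <- sum(r$flagged)
    if (flagged[k + 1L] > 0.2 * npt)
      abort("tracking_failed",
            "more than 20%% of points left the image at frame %d", idx[k + 1L])
  }
  structure(
    list(points = out, frames = idx, source = ed_contour,
         pixel_spacing = ed_contour$pixel_spacing, residuals = residuals,
         flagged = flagged, stabilization_weight = 0,
         unstabilized_frames = integer(0)),
    class = "tracked_sequence"
  )
}

# align annotation orientation to a reference point set (annulus A to annulus
# A): reverse the annotation if its endpoints match the reference better
# reversed than direct
align_orientation <- function(ann_pts, ref_pts) {
  n <- nrow(ann_pts)
  direct <- sum((ann_pts[1L, ] - ref_pts[1L, ])^2) +
    sum((ann_pts[n, ] - ref_pts[nrow(ref_pts), ])^2)
  reversed <- sum((ann_pts[n, ] - ref_pts[1L, ])^2) +
    sum((ann_pts[1L, ] - ref_pts[nrow(ref_pts), ])^2)
  if (reversed < direct) ann_pts[n:1L, , drop = FALSE] else ann_pts
}

#' Stabilize a tracked sequence with per-frame annotations
#'
#' Blends every tracked point with the corresponding point of that frame's
#' annotation: `w * annotation + (1 - w) * tracked`. Correspondence is by arc
#' fraction after orientation alignment (annulus A to annulus A), not nearest
#' neighbor, which prevents points sliding along the contour. `w = 0` is a
#' no-op and `w = 1` replaces the track by the annotations. Frames without an
#' annotation are left unstabilized and flagged.
#'
#' @param tracked a [track_contour()] result.
#' @param annotations list of [contour()] objects (or `NULL` for missing
#'   frames), indexed so `annotations[[k + 1]]` is frame `k`.
#' @param w blend weight in `[0, 1]` (default 0.5).
#' @return The stabilized `tracked_sequence`.
#' @export
stabilize <- function(tracked, annotations, w = 0.5) {
  stopifnot(inherits(tracked, "tracked_sequence"))
  if (w < 0 || w > 1) abort("config_error", "stabilization weight must be in [0, 1]")
  if (w == 0) return(tracked)
  npt <- dim(tracked$points)[1L]
  missing_frames <- integer(0)
  for (k in seq_along(tracked$frames)) {
    f <- tracked$frames[k]
    ann <- if (f + 1L <= length(annotations)) annotations[[f + 1L]] else NULL
    if (is.null(ann)) {
      missing_frames <- c(missing_frames, f)
      next
    }
    ann_pts <- resample(as_points(ann), npt)
    ann_pts <- align_orientation(ann_pts, tracked$points[, , k])
    tracked$points[, , k] <- w * ann_pts + (1 - w) * tracked$points[, , k]
  }
  tracked$stabilization_weight <- w
  tracked$unstabilized_frames <- missing_frames
  tracked
}

# per-frame contour arc lengths (mm) of a tracked sequence
tracked_lengths <- function(tracked) {
  vapply(seq_along(tracked$frames), function(k)
    arc_length(tracked$points[, , k], pixel_spacing = tracked$pixel_spacing),
    numeric(1))
}
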