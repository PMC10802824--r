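#' Raw longitudinal strain curve from contour lengths
#'
#' Longitudinal strain at frame `k` of a cycle is the percentage change of the
#' traced endocardial length relative to end-diastole:
#' `e(k) = 100 * (L(k) - L(ED)) / L(ED)`, so `e(ED) = 0` and shortening is
#' negative.
#'
#' @param lengths per-frame contour lengths in mm. Either a full-video vector
#'   indexed from frame 0 or a vector covering exactly
#'   `ed_frame:end_frame`.
#' @param cycle a [cardiac_cycle()].
#' @return Numeric vector of strain (%) for frames `ed_frame:end_frame`, with
#'   the first element 0.
#' @export
strain_curve <- function(lengths, cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  nf <- cycle$end_frame - cycle$ed_frame + 1L
  if (length(lengths) == nf) {
    L <- as.double(lengths)
  } else if (length(lengths) >= cycle$end_frame + 1L) {
    L <- as.double(lengths[(cycle$ed_frame + 1L):(cycle$end_frame + 1L)])
  } else {
    abort("invalid_length", "lengths do not cover the cycle")
  }
  if (any(!is.finite(L)) || any(L <= 0))
    abort("invalid_length", "contour lengths must be positive and finite")
  100 * (L - L[1L]) / L[1L]
}

#' Drift-correct a strain curve
#'
#' Frame-to-frame tracking accumulates drift, so the raw strain does not
#' return to zero at the next end-diastole. The correction subtracts the
#' linear ramp in frame index that vanishes at ED and equals the residual
#' strain at the cycle end: `corrected(k) = raw(k) - raw(end) * (k - ed) /
#' (end - ed)`. The corrected curve is exactly 0 at both EDs, and the
#' operation is idempotent (curves already ending at 0 are unchanged).
#'
#' @param raw strain (%) per frame over `ed_frame:end_frame`, with
#'   `raw[1] == 0`.
#' @param cycle a [cardiac_cycle()].
#' @return Corrected strain (%) per frame.
#' @export
drift_correct <- function(raw, cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  nf <- cycle$end_frame - cycle$ed_frame + 1L
  if (nf < 2L) abort("invalid_cycle", "cycle has fewer than two frames")
  if (length(raw) != nf)
    abort("invalid_length", "strain curve length does not match the cycle")
  if (abs(raw[1L]) > 1e-9)
    abort("invalid_length", "raw strain must be 0 at end-diastole")
  k <- seq_len(nf) - 1L
  out <- raw - raw[nf] * k / (nf - 1L)
  out[1L] <- 0
  out[nf] <- 0
  out
}

#' Strain curve object for one cycle
#'
#' Bundles the drift-corrected global strain curve of a cycle with the six
#' per-segment curves (A4C/A2C only) and the cycle itself.
#'
#' @param global_values drift-corrected global strain (%) per frame.
#' @param cycle a [cardiac_cycle()].
#' @param segment_values optional 6-row matrix of per-segment strain curves
#'   (rows named by segment).
#' @param drift_corrected logical.
#' @return Object of class `strain_curve_set`.
#' @export
strain_curve_set <- function(global_values, cycle, segment_values = NULL,
                             drift_corrected = TRUE) {
  nf <- cycle$end_frame - cycle$ed_frame + 1L
  if (length(global_values) != nf)
    abort("invalid_length", "global strain curve length does not match the cycle")
  if (abs(global_values[1L]) > 1e-9)
    abort("invalid_length", "strain at end-diastole must be 0")
  if (!is.null(segment_values) &&
      (nrow(segment_values) != 6L || ncol(segment_values) != nf))
    abort("invalid_length", "segment_values must be a 6 x n_frames matrix")
  structure(list(global_values = global_values, segment_values = segment_values,
                 drift_corrected = isTRUE(drift_corrected), cycle = cycle),
            class = "strain_curve_set")
}

#' Global longitudinal strain of one video
#'
#' The video's GLS is the average over its accepted cycles of the
#' drift-corrected strain at end-systole (per-video cycle averaging).
#'
#' @param curves list of [strain_curve_set()] objects, one per accepted cycle.
#' @return GLS in strain %.
#' @export
gls_for_video <- function(curves) {
  if (!length(curves)) abort("no_measurement", "no accepted cycles for this video")
  mean(vapply(curves, function(cu) {
    es_pos <- cu$cycle$es_frame - cu$cycle$ed_frame + 1L
    cu$global_values[es_pos]
  }, numeric(1)))
}

#' Total GLS from the three apical views
#'
#' The total left-ventricular GLS is the arithmetic mean of the A4C, A2C and
#' A3C per-view values. By default all three views are required (a study that
#' fails any view is excluded upstream); with `allow_partial = TRUE` the mean
#' of the available views is returned and flagged by the caller.
#'
#' @param per_view named numeric vector of per-view GLS (names among
#'   `"A4C"`, `"A2C"`, `"A3C"`; `NA` marks a missing view).
#' @param allow_partial permit 1-2 view averages.
#' @return Total GLS (strain %).
#' @export
total_gls <- function(per_view, allow_partial = FALSE) {
  required <- c("A4C", "A2C", "A3C")
  vals <- per_view[match(required, names(per_view))]
  if (anyNA(vals)) {
    if (!allow_partial) {
      missing <- required[is.na(vals)]
      abort("missing_view", "missing view(s): %s", paste(missing, collapse = ", "))
    }
    vals <- vals[!is.na(vals)]
    if (!length(vals)) abort("missing_view", "no views available")
  }
  mean(vals)
}

# per-segment length curves of a tracked sequence: boundaries fixed at the ED
# arc fractions (fractional point indices) and carried by point correspondence
segment_length_curves <- function(tracked, scheme) {
  ed_pts <- tracked$points[, , 1L]
  fidx <- boundary_positions(ed_pts, scheme$boundaries)
  nf <- length(tracked$frames)
  out <- matrix(NA_real_, nrow = 6L, ncol = nf,
                dimnames = list(scheme$names, NULL))
  for (k in seq_len(nf)) {
    pts <- tracked$points[, , k]
    cum <- cum_arc(pts)
    at <- function(f) {
      i <- min(max(floor(f), 1), nrow(pts) - 1L)
      cum[i] + (f - i) * (cum[i + 1L] - cum[i])
    }
    pos <- vapply(fidx, at, numeric(1))
    out[, k] <- diff(pos) * tracked$pixel_spacing
  }
  out
}

#' Regional (segmental) peak strain
#'
#' Computes the per-frame length strain of each of the six wall segments of a
#' tracked A4C or A2C sequence. Segment boundaries are fixed at the
#' end-diastolic arc fractions and carried through the cycle by point
#' correspondence; each segment curve is drift-corrected with its own linear
#' ramp (which preserves the exact additivity of segment lengths). The peak
#' is the most negative corrected value within the systolic interval
#' `[ED, ES]`; the most negative value over the whole cycle is reported
#' separately as the post-systolic peak.
#'
#' @param tracked a [track_contour()] (optionally [stabilize()]d) sequence.
#' @param scheme a [segment_scheme()] matching the view.
#' @param cycle the [cardiac_cycle()] the sequence covers.
#' @return List with `peaks` (named per-segment systolic peak strain, %),
#'   `curves` (6 x n_frames corrected strain matrix), `raw_curves`,
#'   `ed_lengths` (named, mm) and `whole_cycle_peaks`.
#' @export
regional_strain <- function(tracked, scheme, cycle) {
  stopifnot(inherits(tracked, "tracked_sequence"), inherits(scheme, "segment_scheme"),
            inherits(cycle, "cardiac_cycle"))
  if (tracked$source$view == "A3C")
    abort("unsupported_view", "regional strain is defined for A4C and A2C views only")
  if (tracked$source$view != scheme$view)
    abort("unsupported_view", "tracked view %s does not match scheme view %s",
          tracked$source$view, scheme$view)
  len <- segment_length_curves(tracked, scheme)
  nf <- ncol(len)
  raw <- 100 * sweep(len, 1L, len[, 1L], "-") / len[, 1L]
  corr <- t(apply(raw, 1L, drift_correct, cycle = cycle))
  es_pos <- cycle$es_frame - cycle$ed_frame + 1L
  peaks <- apply(corr[, seq_len(es_pos), drop = FALSE], 1L, min)
  whole <- apply(corr, 1L, min)
  list(peaks = peaks, curves = corr, raw_curves = raw,
       ed_lengths = stats::setNames(len[, 1L], scheme$names),
       whole_cycle_peaks = whole)
}

#' Classify impaired GLS
#'
#' A GLS value is "impaired" when it is strictly less negative than the
#' threshold (default -16%); a value exactly at the threshold is classed not
#' impaired.
#'
#' @param gls GLS in strain % (negative for contracting ventricles).
#' @param threshold impairment threshold in strain %.
#' @return Logical.
#' @export
classify_impaired <- function(gls, threshold = -16) {
  if (any(!is.finite(gls))) abort("invalid_length", "GLS must be finite")
  gls > threshold
}
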