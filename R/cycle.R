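#' Cavity-size curve
#'
#' Per-frame cavity size (mm^2) of a video, the signal from which cardiac
#' cycles are detected. Frames are 0-based; frame `k` is `values[k + 1]`.
#'
#' @param values numeric vector of cavity sizes, one per frame, length >= 8.
#' @param frame_rate acquisition frame rate in frames/s. Values outside the
#'   plausible echo range 20-150 fps trigger a warning (typical apical
#'   acquisitions run at 60-80 fps) but are not rejected.
#' @return Object of class `size_curve` with `values`, `frame_rate` and
#'   derived `frame_times` (s).
#' @export
size_curve <- function(values, frame_rate) {
  values <- as.double(values)
  if (length(values) < 8L) abort("invalid_curve", "size curve needs >= 8 frames")
  if (anyNA(values)) abort("invalid_curve", "size curve contains missing values")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    abort("invalid_curve", "frame_rate must be a positive scalar")
  if (frame_rate < 20 || frame_rate > 150)
    warning(sprintf("frame rate %.1f fps outside the plausible echo range [20, 150]",
                    frame_rate))
  structure(
    list(values = values, frame_rate = as.double(frame_rate),
         frame_times = (seq_along(values) - 1) / frame_rate),
    class = "size_curve"
  )
}

#' Cardiac cycle
#'
#' One complete beat: end-diastole (maximal cavity size) to end-systole
#' (minimal cavity size) to the next end-diastole. Frame indices are 0-based.
#'
#' @param ed_frame,es_frame,end_frame 0-based frame indices with
#'   `ed_frame < es_frame < end_frame`; `end_frame` is the next end-diastole.
#' @param frame_rate frames/s, used to derive the heart rate.
#' @return Object of class `cardiac_cycle` with the three frames,
#'   `frame_rate` and derived `heart_rate_bpm = 60 * frame_rate /
#'   (end_frame - ed_frame)`.
#' @export
cardiac_cycle <- function(ed_frame, es_frame, end_frame, frame_rate) {
  ed_frame <- as.integer(ed_frame); es_frame <- as.integer(es_frame)
  end_frame <- as.integer(end_frame)
  if (!(ed_frame < es_frame && es_frame < end_frame))
    abort("invalid_cycle", "need ed_frame < es_frame < end_frame")
  if (frame_rate <= 0) abort("invalid_cycle", "frame_rate must be positive")
  structure(
    list(ed_frame = ed_frame, es_frame = es_frame, end_frame = end_frame,
         frame_rate = as.double(frame_rate),
         heart_rate_bpm = 60 * frame_rate / (end_frame - ed_frame)),
    class = "cardiac_cycle"
  )
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("<cardiac_cycle> ED %d -> ES %d -> ED %d (%.0f bpm at %.1f fps)\n",
              x$ed_frame, x$es_frame, x$end_frame, x$heart_rate_bpm, x$frame_rate))
  invisible(x)
}

#' ECG trace
#'
#' @param samples amplitude samples (may be `NULL` when only R-peak indices
#'   are supplied precomputed).
#' @param sample_rate Hz.
#' @param r_peaks strictly increasing 0-based sample indices of R peaks.
#' @return Object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples = NULL, sample_rate, r_peaks) {
  r_peaks <- as.double(r_peaks)
  if (length(r_peaks) > 1L && any(diff(r_peaks) <= 0))
    abort("invalid_curve", "r_peaks must be strictly increasing")
  if (sample_rate <= 0) abort("invalid_curve", "sample_rate must be positive")
  structure(list(samples = samples, sample_rate = as.double(sample_rate),
                 r_peaks = r_peaks),
            class = "ecg_trace")
}

# centered moving average with window shrinking symmetrically at the edges,
# so extrema of symmetric pulses are not shifted
smooth_ma <- function(v, window) {
  window <- max(1L, as.integer(window))
  if (window <= 1L) return(v)
  hw <- window %/% 2L
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(hw, i - 1L, n - i)
    out[i] <- mean(v[(i - h):(i + h)])
  }
  out
}

# local maxima of a vector (first index of plateaus; endpoints eligible),
# filtered by topographic prominence
find_peaks <- function(v, min_prominence) {
  n <- length(v)
  # collapse equal-value runs
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  vals <- runs$values
  m <- length(vals)
  cand <- integer(0)
  for (k in seq_len(m)) {
    left_ok <- k == 1L || vals[k] > vals[k - 1L]
    right_ok <- k == m || vals[k] > vals[k + 1L]
    if (left_ok && right_ok) cand <- c(cand, starts[k])
  }
  if (!length(cand)) return(integer(0))
  # prominence: on each side, the minimum between the peak and the nearest
  # strictly higher point (or the series end); drop to the higher of the two
  keep <- vapply(cand, function(p) {
    h <- v[p]
    hl <- if (p > 1L) which(v[seq_len(p - 1L)] > h) else integer(0)
    base_l <- if (length(hl)) min(v[max(hl):p])
      else if (p > 1L) min(v[seq_len(p - 1L)]) else -Inf
    hr <- if (p < n) p + which(v[(p + 1L):n] > h) else integer(0)
    base_r <- if (length(hr)) min(v[p:min(hr)])
      else if (p < n) min(v[(p + 1L):n]) else -Inf
    (h - max(base_l, base_r)) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Detect cardiac cycles from the cavity-size curve
#'
#' End-diastolic frames are prominent local maxima of the smoothed cavity-size
#' curve; end-systole is the minimum strictly between consecutive
#' end-diastoles. Only complete ED-to-ED spans are returned, in temporal
#' order. Ties are broken toward the earlier frame.
#'
#' @param curve a [size_curve()].
#' @param smoothing_window centered moving-average window in frames; default
#'   `round(frame_rate / 10)`, suppressing trace jitter before peak picking.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   smoothed curve's dynamic range (default 0.05).
#' @return List of [cardiac_cycle()] objects.
#' @export
detect_cycles <- function(curve, smoothing_window = NULL, prominence_frac = 0.05) {
  stopifnot(inherits(curve, "size_curve"))
  if (is.null(smoothing_window))
    smoothing_window <- max(1L, as.integer(round(curve$frame_rate / 10)))
  s <- smooth_ma(curve$values, smoothing_window)
  rng <- diff(range(s))
  if (rng <= 0) abort("no_cycle", "cavity-size curve is constant; no cycles detected")
  peaks <- find_peaks(s, min_prominence = prominence_frac * rng)
  if (length(peaks) < 2L)
    abort("no_cycle", "fewer than two end-diastolic maxima found")
  cycles <- vector("list", length(peaks) - 1L)
  for (k in seq_len(length(peaks) - 1L)) {
    ed <- peaks[k]; nxt <- peaks[k + 1L]
    if (nxt - ed < 2L) next
    inner <- (ed + 1L):(nxt - 1L)
    es <- inner[which.min(s[inner])]
    cycles[[k]] <- cardiac_cycle(ed - 1L, es - 1L, nxt - 1L, curve$frame_rate)
  }
  cycles <- Filter(Negate(is.null), cycles)
  if (!length(cycles)) abort("no_cycle", "no complete ED-to-ED span found")
  cycles
}

#' ECG congruence of detected cycles
#'
#' A cycle is congruent with the ECG when an R peak lies within `tolerance`
#' seconds of its end-diastolic time. Without an ECG the check is "not
#' assessed", which is distinct from a failure (the ECG check is applied only
#' if a trace is available).
#'
#' @param cycles list of [cardiac_cycle()].
#' @param ecg an [ecg_trace()] or `NULL`.
#' @param tolerance seconds (default 0.1).
#' @return Character vector per cycle: `"congruent"`, `"incongruent"` or
#'   `"not_assessed"`.
#' @export
ecg_congruence <- function(cycles, ecg, tolerance = 0.1) {
  if (is.null(ecg))
    return(rep("not_assessed", length(cycles)))
  stopifnot(inherits(ecg, "ecg_trace"))
  r_times <- ecg$r_peaks / ecg$sample_rate
  vapply(cycles, function(cy) {
    t_ed <- cy$ed_frame / cy$frame_rate
    if (!length(r_times)) return("not_assessed")
    if (min(abs(r_times - t_ed)) <= tolerance) "congruent" else "incongruent"
  }, character(1))
}
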