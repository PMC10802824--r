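#' Select the best video for a view
#'
#' Picks the candidate with the highest view-classifier confidence; ties are
#' broken toward the earliest acquisition order. Mirrors the workflow's rule
#' of measuring on the single highest-quality loop per view rather than
#' averaging all available videos.
#'
#' @param candidates list of videos, each with a `confidence` field in
#'   `[0, 1]` (or a bare numeric vector of confidences).
#' @return The index of the selected candidate.
#' @export
select_best_video <- function(candidates) {
  conf <- if (is.numeric(candidates)) candidates
  else vapply(candidates, function(v) as.double(v$confidence), numeric(1))
  if (!length(conf)) abort("view_not_found", "no candidate videos for this view")
  if (any(conf < 0 | conf > 1))
    abort("config_error", "view confidences must be in [0, 1]")
  which.max(conf)  # which.max takes the first maximum: earliest acquisition
}

#' Heart-rate confidence check
#'
#' A cycle passes when its implied heart rate lies inside the closed
#' plausibility interval (default 30-180 bpm; the boundary passes).
#'
#' @param cycle a [cardiac_cycle()].
#' @param bounds closed bpm interval.
#' @return `"pass"` or `"fail"`.
#' @export
heart_rate_check <- function(cycle, bounds = c(30, 180)) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  hr <- cycle$heart_rate_bpm
  if (hr >= bounds[1L] && hr <= bounds[2L]) "pass" else "fail"
}

#' Displacement (ROI-mismatch) check
#'
#' Measures the mean point-wise distance between the tracked contour at the
#' cycle end (the next end-diastole) and the end-diastolic annotation, with
#' arc-fraction point correspondence. The check passes when the distance is
#' at most `tau` times the end-diastolic arc length; a large mismatch means
#' the trace drifted off the wall during tracking.
#'
#' @param tracked a [track_contour()] sequence covering the full cycle.
#' @param ed_annotation the end-diastolic [contour()] annotation.
#' @param tau threshold as a fraction of the ED arc length (default 0.05).
#' @return List with `status` (`"pass"`/`"fail"`), `distance_mm` and
#'   `limit_mm`.
#' @export
displacement_check <- function(tracked, ed_annotation, tau = 0.05) {
  stopifnot(inherits(tracked, "tracked_sequence"))
  npt <- dim(tracked$points)[1L]
  ann <- resample(as_points(ed_annotation), npt)
  ann <- align_orientation(ann, tracked$points[, , 1L])
  end_pts <- tracked$points[, , dim(tracked$points)[3L]]
  dist_mm <- mean(sqrt(rowSums((end_pts - ann)^2))) * tracked$pixel_spacing
  L <- arc_length(ed_annotation)
  list(status = if (dist_mm <= tau * L) "pass" else "fail",
       distance_mm = dist_mm, limit_mm = tau * L)
}

qa_check_names <- c("view_identification", "measurement_confidence",
                    "heart_rate", "displacement", "systole_diastole_ecg")

# assemble the fixed-order check ledger for one video; `done` is a named list
# of list(status, detail) for the checks that ran; everything after the first
# fail (or not run) is reported not_assessed
qa_ledger <- function(done) {
  status <- rep("not_assessed", length(qa_check_names))
  detail <- rep("", length(qa_check_names))
  failed <- FALSE
  for (i in seq_along(qa_check_names)) {
    nm <- qa_check_names[i]
    if (!failed && !is.null(done[[nm]])) {
      status[i] <- done[[nm]]$status
      detail[i] <- done[[nm]]$detail %||% ""
      if (identical(status[i], "fail")) failed <- TRUE
    }
  }
  data.frame(check = qa_check_names, status = status, detail = detail,
             stringsAsFactors = FALSE)
}

# first failing check of a ledger, or NA
first_fail <- function(ledger) {
  i <- which(ledger$status == "fail")
  if (length(i)) ledger$check[min(i)] else NA_character_
}

#' Run the sequential quality checks on a study
#'
#' Executes the full per-view pipeline (view identification, tracking-based
#' measurement confidence, heart rate, trace displacement, ECG congruence)
#' with short-circuit semantics — a failing check stops later checks for that
#' video — and returns the quality-assurance report. The study-level
#' exclusion reason is the earliest failing check (ties broken by view
#' order), so excluded + analysed always equals the total and every excluded
#' study carries exactly one primary reason code.
#'
#' @param bundle a study bundle (see [analyze_study()]).
#' @param config a [strain_config()].
#' @return The `qa` element of the [analyze_study()] report: `study_id`,
#'   `per_video` (named list of check ledgers), `final_status`
#'   (`"analysed"`/`"excluded"`) and `reason_code`.
#' @export
run_sequential_qa <- function(bundle, config = strain_config()) {
  analyze_study(bundle, config)$qa
}
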