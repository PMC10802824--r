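#' Pipeline configuration
#'
#' All tunable parameters of the strain pipeline with their defaults. The
#' thresholds of the quality gates are configuration values: heart-rate
#' plausibility 30-180 bpm (closed interval), displacement threshold
#' `tau = 0.05` of the ED arc length, tracking-residual cap 0.2 (intensity
#' units in `[0, 1]`), ECG congruence tolerance 100 ms (advisory unless
#' `ecg_strict`), minimum view confidence 0.5.
#'
#' @param n_points canonical contour resolution used for tracking and strain.
#' @param stabilization_weight blend weight toward the per-frame annotations.
#' @param flow a [flow_params()].
#' @param smoothing_window cavity-curve smoothing window in frames (`NULL`:
#'   `round(frame_rate / 10)`).
#' @param prominence_frac peak prominence threshold for cycle detection as a
#'   fraction of dynamic range.
#' @param hr_bounds closed heart-rate plausibility interval, bpm.
#' @param displacement_tau displacement threshold as a fraction of the ED
#'   arc length.
#' @param residual_cap maximum mean tracking residual ("measurement
#'   confidence").
#' @param ecg_tolerance ECG congruence tolerance, s.
#' @param ecg_strict when `TRUE`, incongruent cycles are dropped and the ECG
#'   check can exclude a video; by default it is advisory (applied only "if
#'   available", never excluding).
#' @param min_view_confidence minimum view-classifier confidence.
#' @param allow_partial permit total GLS from fewer than three views
#'   (flagged).
#' @param required_views views required for a complete study.
#' @param gls_threshold impaired-GLS threshold, strain %.
#' @param segment_boundaries arc fractions passed to [segment_scheme()].
#' @return Object of class `strain_config`.
#' @export
strain_config <- function(n_points = 64L, stabilization_weight = 0.5,
                          flow = flow_params(), smoothing_window = NULL,
                          prominence_frac = 0.05, hr_bounds = c(30, 180),
                          displacement_tau = 0.05, residual_cap = 0.2,
                          ecg_tolerance = 0.1, ecg_strict = FALSE,
                          min_view_confidence = 0.5, allow_partial = FALSE,
                          required_views = c("A4C", "A2C", "A3C"),
                          gls_threshold = -16,
                          segment_boundaries = seq(0, 1, length.out = 7)) {
  structure(
    list(n_points = as.integer(n_points),
         stabilization_weight = stabilization_weight, flow = flow,
         smoothing_window = smoothing_window, prominence_frac = prominence_frac,
         hr_bounds = hr_bounds, displacement_tau = displacement_tau,
         residual_cap = residual_cap, ecg_tolerance = ecg_tolerance,
         ecg_strict = isTRUE(ecg_strict),
         min_view_confidence = min_view_confidence,
         allow_partial = isTRUE(allow_partial), required_views = required_views,
         gls_threshold = gls_threshold, segment_boundaries = segment_boundaries),
    class = "strain_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [strain_config()] (flow parameters under a `flow:` block). Keys absent
#' from the file keep their defaults; `overrides` (e.g. from CLI flags) take
#' precedence over the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied last.
#' @return A [strain_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, overrides)
  flow_args <- vals$flow %||% list()
  vals$flow <- NULL
  args <- vals[names(vals) %in% names(formals(strain_config))]
  cfg <- do.call(strain_config, args)
  if (length(flow_args))
    cfg$flow <- do.call(flow_params, flow_args[names(flow_args) %in%
                                                 names(formals(flow_params))])
  cfg
}

# analyze one selected video; returns gls, segment peaks, check ledger, ...
analyze_view <- function(video, config) {
  done <- list(view_identification = list(status = "pass",
                                          detail = sprintf("confidence %.2f", video$confidence)))
  fail_out <- function(done, extra = list()) {
    c(list(view = video$view, analysed = FALSE, gls = NA_real_, n_cycles = 0L,
           segment_peaks = NULL, checks = qa_ledger(done)), extra)
  }
  sizes <- vapply(video$annotations, cavity_size, numeric(1))
  curve <- size_curve(sizes, video$frame_rate)
  cycles <- tryCatch(
    detect_cycles(curve, config$smoothing_window, config$prominence_frac),
    echostrain_no_cycle = function(e) e)
  if (inherits(cycles, "condition")) {
    done$measurement_confidence <- list(status = "not_assessed",
                                        detail = "no cycles to track")
    done$heart_rate <- list(status = "fail",
                            detail = paste("no cardiac cycle detected:",
                                           conditionMessage(cycles)))
    return(fail_out(done))
  }

  tracked <- vector("list", length(cycles))
  track_err <- NULL
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    ed_ann <- video$annotations[[cy$ed_frame + 1L]]
    ed64 <- resample(ed_ann, config$n_points)
    tr <- tryCatch(track_contour(video$frames, ed64, cy, config$flow),
                   echostrain_tracking_failed = function(e) e)
    if (inherits(tr, "condition")) { track_err <- tr; break }
    tracked[[i]] <- stabilize(tr, video$annotations, config$stabilization_weight)
  }
  if (!is.null(track_err)) {
    done$measurement_confidence <- list(status = "fail",
                                        detail = conditionMessage(track_err))
    return(fail_out(done))
  }
  resid <- mean(vapply(tracked, function(tr) mean(tr$residuals[-1L]), numeric(1)))
  if (resid <= config$residual_cap) {
    done$measurement_confidence <- list(status = "pass",
                                        detail = sprintf("mean residual %.4f", resid))
  } else {
    done$measurement_confidence <- list(status = "fail",
                                        detail = sprintf("mean residual %.4f > cap %.4f",
                                                         resid, config$residual_cap))
    return(fail_out(done))
  }

  hr_ok <- vapply(cycles, function(cy)
    heart_rate_check(cy, config$hr_bounds) == "pass", logical(1))
  if (!any(hr_ok)) {
    hrs <- vapply(cycles, function(cy) cy$heart_rate_bpm, numeric(1))
    done$heart_rate <- list(status = "fail",
                            detail = sprintf("heart rate(s) %s bpm outside [%g, %g]",
                                             paste(round(hrs), collapse = "/"),
                                             config$hr_bounds[1L], config$hr_bounds[2L]))
    return(fail_out(done))
  }
  done$heart_rate <- list(status = "pass",
                          detail = sprintf("%d/%d cycles in bounds",
                                           sum(hr_ok), length(cycles)))
  cycles <- cycles[hr_ok]; tracked <- tracked[hr_ok]

  disp <- lapply(seq_along(cycles), function(i)
    displacement_check(tracked[[i]],
                       video$annotations[[cycles[[i]]$ed_frame + 1L]],
                       config$displacement_tau))
  disp_ok <- vapply(disp, function(d) d$status == "pass", logical(1))
  if (!any(disp_ok)) {
    done$displacement <- list(status = "fail",
                              detail = sprintf("trace displacement %s mm over limit",
                                               paste(sprintf("%.1f", vapply(disp, `[[`, numeric(1), "distance_mm")),
                                                     collapse = "/")))
    return(fail_out(done))
  }
  done$displacement <- list(status = "pass",
                            detail = sprintf("%d/%d cycles within tau",
                                             sum(disp_ok), length(cycles)))
  cycles <- cycles[disp_ok]; tracked <- tracked[disp_ok]

  cong <- ecg_congruence(cycles, video$ecg, config$ecg_tolerance)
  if (all(cong == "not_assessed")) {
    done$systole_diastole_ecg <- list(status = "not_assessed", detail = "no ECG")
  } else {
    detail <- sprintf("%d/%d cycles congruent", sum(cong == "congruent"), length(cong))
    if (config$ecg_strict) {
      keep <- cong == "congruent"
      if (!any(keep)) {
        done$systole_diastole_ecg <- list(status = "fail", detail = detail)
        return(fail_out(done))
      }
      done$systole_diastole_ecg <- list(status = "pass", detail = detail)
      cycles <- cycles[keep]; tracked <- tracked[keep]
    } else {
      # advisory: incongruence is recorded but never excludes the video
      done$systole_diastole_ecg <- list(
        status = if (any(cong == "incongruent")) "fail" else "pass",
        detail = if (any(cong == "incongruent")) paste(detail, "(advisory)") else detail)
    }
  }

  scheme <- if (video$view != "A3C")
    segment_scheme(video$view, config$segment_boundaries) else NULL
  curve_sets <- vector("list", length(cycles))
  seg_mat <- NULL
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    lens <- tracked_lengths(tracked[[i]])
    corr <- drift_correct(strain_curve(lens, cy), cy)
    seg <- NULL
    if (!is.null(scheme)) {
      reg <- regional_strain(tracked[[i]], scheme, cy)
      seg <- reg$peaks
      seg_mat <- rbind(seg_mat, reg$peaks)
    }
    curve_sets[[i]] <- strain_curve_set(corr, cy)
  }
  list(view = video$view, analysed = TRUE, gls = gls_for_video(curve_sets),
       n_cycles = length(cycles),
       segment_peaks = if (!is.null(seg_mat)) colMeans(seg_mat) else NULL,
       checks = qa_ledger(done), mean_residual = resid,
       heart_rate_bpm = mean(vapply(cycles, `[[`, numeric(1), "heart_rate_bpm")))
}

#' Analyse one study
#'
#' Runs the full post-segmentation strain workflow on a study bundle: for
#' each required view, select the highest-confidence video, detect cardiac
#' cycles from the annotation cavity-size curve, track the end-diastolic
#' trace by optical flow with annotation stabilization, apply the sequential
#' quality gates, and compute drift-corrected strain. Per-view GLS is the
#' cycle average of the selected video, total GLS the mean over the three
#' apical views, and regional peak strain is reported for the twelve A4C/A2C
#' segments. A failing check never crashes the run; it becomes the study's
#' exclusion reason code.
#'
#' @param bundle a study bundle: `list(study_id, videos, seed)` where each
#'   video has `view`, `confidence`, `frames` (list of matrices in `[0, 1]`),
#'   `frame_rate`, `pixel_spacing`, `annotations` (list of [contour()] per
#'   frame) and optional `ecg` ([ecg_trace()]). Built by [generate_study()],
#'   [load_study()], or by hand.
#' @param config a [strain_config()].
#' @return A report list: `study_id`, `status` (`"analysed"`/`"excluded"`),
#'   `reason_code` (e.g. `"view_identification:A2C"`, `NA` when analysed),
#'   `per_view`, `total_gls`, `impaired`, `segments` (data frame `view`,
#'   `label`, `peak_strain`), `flags`, `qa`, `seed`.
#' @export
analyze_study <- function(bundle, config = strain_config()) {
  stopifnot(is.list(bundle), !is.null(bundle$videos))
  flags <- character(0)
  per_view <- list()
  for (vw in config$required_views) {
    cand <- which(vapply(bundle$videos, function(v)
      identical(v$view, vw) && v$confidence >= config$min_view_confidence,
      logical(1)))
    if (!length(cand)) {
      done <- list(view_identification = list(
        status = "fail",
        detail = sprintf("no %s video with confidence >= %.2f", vw,
                         config$min_view_confidence)))
      per_view[[vw]] <- list(view = vw, analysed = FALSE, gls = NA_real_,
                             n_cycles = 0L, segment_peaks = NULL,
                             checks = qa_ledger(done))
      next
    }
    best <- cand[select_best_video(bundle$videos[cand])]
    per_view[[vw]] <- analyze_view(bundle$videos[[best]], config)
  }

  analysed_views <- vapply(per_view, `[[`, logical(1), "analysed")
  # study-level reason: earliest failing check in the fixed order, view order
  # breaking ties
  reason <- NA_character_
  if (!all(analysed_views)) {
    best_rank <- Inf
    for (vw in names(per_view)) {
      f <- first_fail(per_view[[vw]]$checks)
      if (!is.na(f)) {
        r <- match(f, qa_check_names)
        if (r < best_rank) {
          best_rank <- r
          reason <- paste0(f, ":", vw)
        }
      }
    }
  }
  complete <- all(analysed_views)
  usable <- complete || (config$allow_partial && any(analysed_views))
  gls_views <- vapply(per_view, `[[`, numeric(1), "gls")
  total <- if (usable)
    total_gls(gls_views, allow_partial = config$allow_partial) else NA_real_
  if (usable && !complete) flags <- c(flags, "partial_views")

  segments <- NULL
  for (vw in intersect(c("A4C", "A2C"), names(per_view))) {
    sp <- per_view[[vw]]$segment_peaks
    if (!is.null(sp))
      segments <- rbind(segments,
                        data.frame(view = vw, label = names(sp),
                                   peak_strain = as.double(sp),
                                   stringsAsFactors = FALSE))
  }
  status <- if (usable) "analysed" else "excluded"
  qa <- list(study_id = bundle$study_id,
             per_video = lapply(per_view, `[[`, "checks"),
             final_status = status, reason_code = reason)
  list(study_id = bundle$study_id, status = status,
       reason_code = if (status == "excluded") reason else NA_character_,
       per_view = per_view, total_gls = total,
       impaired = if (usable) classify_impaired(total, config$gls_threshold) else NA,
       segments = segments, flags = flags, qa = qa, seed = bundle$seed %||% NA)
}

#' Write a study report as JSON
#'
#' @param report an [analyze_study()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

seg_col_name <- function(view, label) {
  paste0("seg_", view, "_", gsub("-", "_", label))
}

#' Run the pipeline over a cohort
#'
#' Analyses every study, assembles one row per study (status, reason, total
#' and per-view GLS, the twelve segment peaks) and the exclusion table by
#' reason code. Analysed plus excluded always equals the total.
#'
#' @param studies list of study bundles, or the path of a manifest CSV with a
#'   `path` column naming study directories (read with [load_study()]).
#' @param config a [strain_config()].
#' @param out_dir optional directory; when given, `cohort.csv` and
#'   `exclusions.csv` are written there.
#' @return List with `results` (data frame) and `exclusions` (data frame
#'   `reason_code`, `n`, `percent`).
#' @export
run_cohort <- function(studies, config = strain_config(), out_dir = NULL) {
  if (is.character(studies)) {
    manifest <- read.csv(studies, stringsAsFactors = FALSE)
    if (is.null(manifest$path)) abort("config_error", "manifest needs a 'path' column")
    studies <- lapply(manifest$path, load_study)
  }
  seg_cols <- c(vapply(a4c_segments, seg_col_name, "", view = "A4C"),
                vapply(a2c_segments, seg_col_name, "", view = "A2C"))
  rows <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    rep_i <- analyze_study(build_study(studies[[i]]), config)
    row <- data.frame(study_id = rep_i$study_id, status = rep_i$status,
                      reason_code = rep_i$reason_code,
                      total_gls = rep_i$total_gls,
                      gls_A4C = rep_i$per_view$A4C$gls %||% NA_real_,
                      gls_A2C = rep_i$per_view$A2C$gls %||% NA_real_,
                      gls_A3C = rep_i$per_view$A3C$gls %||% NA_real_,
                      stringsAsFactors = FALSE)
    for (cc in seg_cols) row[[cc]] <- NA_real_
    if (!is.null(rep_i$segments)) {
      for (k in seq_len(nrow(rep_i$segments)))
        row[[seg_col_name(rep_i$segments$view[k], rep_i$segments$label[k])]] <-
          rep_i$segments$peak_strain[k]
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  excluded <- results[results$status == "excluded", , drop = FALSE]
  if (nrow(excluded)) {
    tab <- table(excluded$reason_code)
    exclusions <- data.frame(reason_code = names(tab), n = as.integer(tab),
                             percent = 100 * as.integer(tab) / nrow(results),
                             stringsAsFactors = FALSE)
  } else {
    exclusions <- data.frame(reason_code = character(0), n = integer(0),
                             percent = numeric(0))
  }
  stopifnot(sum(results$status == "analysed") + nrow(excluded) == nrow(results))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    write.csv(exclusions, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  }
  list(results = results, exclusions = exclusions)
}
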