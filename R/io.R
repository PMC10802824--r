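#' Write a study bundle to disk
#'
#' Serializes a study in the package's array-stack dialect: a `study.json`
#' sidecar (study id, per-video view, confidence, frame rate, pixel spacing,
#' ECG R-peak samples), one directory of 8-bit grayscale PNG frames per
#' video, and one annotation JSON per video in the documented dialect
#' `{study_id, view, pixel_spacing_mm, frames: [{frame_index, points,
#' apex_index}]}`. [load_study()] round-trips this exactly (frames are
#' quantized to 8 bits at render time).
#'
#' @param bundle a study bundle (see [analyze_study()]).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_videos <- vector("list", length(bundle$videos))
  for (i in seq_along(bundle$videos)) {
    v <- bundle$videos[[i]]
    vdir <- sprintf("video_%02d_%s", i, v$view)
    dir.create(file.path(dir, vdir), showWarnings = FALSE)
    for (k in seq_along(v$frames))
      png::writePNG(v$frames[[k]],
                    file.path(dir, vdir, sprintf("frame_%04d.png", k - 1L)))
    ann_file <- sprintf("annotations_%02d_%s.json", i, v$view)
    if (!is.null(v$annotations)) {
      ann <- list(
        study_id = bundle$study_id, view = v$view,
        pixel_spacing_mm = v$pixel_spacing,
        frames = lapply(seq_along(v$annotations), function(k) {
          ct <- v$annotations[[k]]
          list(frame_index = k - 1L,
               points = lapply(seq_len(nrow(ct$points)),
                               function(r) unname(ct$points[r, ])),
               apex_index = ct$apex_index - 1L)  # 0-based on disk
        })
      )
      jsonlite::write_json(ann, file.path(dir, ann_file), auto_unbox = TRUE,
                           digits = NA)
    }
    meta_videos[[i]] <- list(
      view = v$view, confidence = v$confidence, frame_rate = v$frame_rate,
      pixel_spacing_mm = v$pixel_spacing, n_frames = length(v$frames),
      frames_dir = vdir,
      annotations_file = if (!is.null(v$annotations)) ann_file else NULL,
      ecg = if (!is.null(v$ecg))
        list(sample_rate = v$ecg$sample_rate, r_peaks = v$ecg$r_peaks) else NULL
    )
  }
  meta <- list(study_id = bundle$study_id, seed = bundle$seed %||% NA,
               videos = meta_videos)
  jsonlite::write_json(meta, file.path(dir, "study.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Load a study bundle from disk
#'
#' Reads the array-stack + JSON sidecar dialect written by [write_study()].
#' Malformed videos are skipped with a warning; a study without any readable
#' video is an error. Missing pixel spacing or frame rate, and annotation
#' frame indices beyond the video length, are rejected with messages naming
#' the field.
#'
#' @param dir study directory containing `study.json`.
#' @return A study bundle as consumed by [analyze_study()].
#' @export
load_study <- function(dir) {
  meta_path <- file.path(dir, "study.json")
  if (!file.exists(meta_path)) abort("empty_study", "no study.json in %s", dir)
  meta <- jsonlite::read_json(meta_path)
  videos <- list()
  for (m in meta$videos) {
    # missing required metadata is a hard error naming the field
    if (is.null(m$pixel_spacing_mm))
      abort("config_error", "video %s: missing field pixel_spacing_mm",
            m$frames_dir %||% "?")
    if (is.null(m$frame_rate))
      abort("config_error", "video %s: missing field frame_rate",
            m$frames_dir %||% "?")
    v <- tryCatch({
      files <- sort(list.files(file.path(dir, m$frames_dir),
                               pattern = "^frame_\\d+\\.png$", full.names = TRUE))
      if (!length(files)) abort("config_error", "video %s: no frames", m$frames_dir)
      frames <- lapply(files, function(f) {
        img <- png::readPNG(f)
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        img
      })
      annotations <- NULL
      if (!is.null(m$annotations_file)) {
        ann <- jsonlite::read_json(file.path(dir, m$annotations_file))
        annotations <- vector("list", length(frames))
        for (fr in ann$frames) {
          fi <- fr$frame_index
          if (fi + 1L > length(frames))
            abort("config_error",
                  "annotation frame_index %d beyond video length %d", fi,
                  length(frames))
          pts <- do.call(rbind, lapply(fr$points, function(p) c(p[[1L]], p[[2L]])))
          annotations[[fi + 1L]] <-
            contour(pts, frame_index = fi,
                    pixel_spacing = ann$pixel_spacing_mm %||%
                      stop("missing field pixel_spacing_mm in annotations"),
                    apex_index = fr$apex_index + 1L, view = ann$view)
        }
      }
      ecg <- if (!is.null(m$ecg))
        ecg_trace(sample_rate = m$ecg$sample_rate,
                  r_peaks = unlist(m$ecg$r_peaks)) else NULL
      list(view = m$view, confidence = m$confidence, frames = frames,
           frame_rate = m$frame_rate, pixel_spacing = m$pixel_spacing_mm,
           annotations = annotations, ecg = ecg)
    }, echostrain_config_error = function(e) {
      warning(sprintf("skipping video: %s", conditionMessage(e)))
      NULL
    })
    if (!is.null(v)) videos[[length(videos) + 1L]] <- v
  }
  if (!length(videos)) abort("empty_study", "no readable video in %s", dir)
  structure(list(study_id = meta$study_id, videos = videos,
                 seed = meta$seed %||% NA),
            class = "study_bundle")
}
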