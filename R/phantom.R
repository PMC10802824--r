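#' Phantom configuration
#'
#' Parameters of the kinematic contracting-ventricle phantom. The endocardium
#' is a truncated ellipse; contraction is a smooth systolic activation pulse
#' that shortens the trace so the programmed global and per-segment strains
#' hold exactly by construction. Defaults emulate the acquisition envelope of
#' routine apical imaging: frame rates drawn uniformly in 60-80 fps, resting
#' heart rate, a ventricle of typical adult dimensions, and a GLS of -20%
#' (healthy contraction).
#'
#' @param view apical view label.
#' @param ed_long_axis end-diastolic apex-to-base length, mm.
#' @param ed_short_axis end-diastolic cavity width, mm.
#' @param target_gls programmed global longitudinal strain, % in `(-35, 0]`.
#' @param per_segment_modifiers 6 multipliers in `[0, 1]` of the local
#'   shortening, ordered from basal landmark A to basal landmark B
#'   (0 = akinetic segment, 1 = full contraction).
#' @param heart_rate beats/min.
#' @param frame_rate frames/s; `NULL` draws uniformly in `[60, 80]` under the
#'   seed.
#' @param n_beats number of complete beats in the video.
#' @param pixel_spacing mm/pixel (isotropic).
#' @param speckle_noise_sd SD of the per-pixel multiplicative speckle noise,
#'   as a fraction of intensity.
#' @param ecg_jitter_sd SD (s) of the jitter applied to the ECG impulse times
#'   around true end-diastole.
#' @param seed integer seed; all phantom randomness derives from it.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(view = c("A4C", "A2C", "A3C"), ed_long_axis = 75,
                           ed_short_axis = 45, target_gls = -20,
                           per_segment_modifiers = rep(1, 6), heart_rate = 75,
                           frame_rate = NULL, n_beats = 3, pixel_spacing = 0.5,
                           speckle_noise_sd = 0.1, ecg_jitter_sd = 0, seed = 1L) {
  view <- match.arg(view)
  if (!(target_gls > -35 && target_gls <= 0))
    abort("config_error", "target_gls must be in (-35, 0]")
  if (length(per_segment_modifiers) != 6L ||
      any(per_segment_modifiers < 0 | per_segment_modifiers > 1))
    abort("config_error", "per_segment_modifiers must be 6 values in [0, 1]")
  if (heart_rate <= 0 || (!is.null(frame_rate) && frame_rate <= 0))
    abort("config_error", "heart_rate and frame_rate must be positive")
  if (n_beats < 1) abort("config_error", "need at least one beat")
  if (pixel_spacing <= 0) abort("config_error", "pixel_spacing must be positive")
  structure(
    list(view = view, ed_long_axis = ed_long_axis, ed_short_axis = ed_short_axis,
         target_gls = target_gls, per_segment_modifiers = as.double(per_segment_modifiers),
         heart_rate = heart_rate, frame_rate = frame_rate, n_beats = as.integer(n_beats),
         pixel_spacing = pixel_spacing, speckle_noise_sd = speckle_noise_sd,
         ecg_jitter_sd = ecg_jitter_sd, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# number of truth contour points: 6 segments x 20 edges + 1, so the default
# equal-sixths segment boundaries fall exactly on vertices
PHANTOM_POINTS <- 121L
EDGES_PER_SEGMENT <- 20L

# smooth activation pulse in [0, 1]: 0 at both end-diastoles, 1 at
# end-systole, zero slope at the extremes (sin^2 ramps)
activation <- function(phase, frac_sys) {
  ifelse(phase <= frac_sys,
         sin(pi * phase / (2 * frac_sys))^2,
         sin(pi * (1 - phase) / (2 * (1 - frac_sys)))^2)
}

#' Generate ground-truth phantom contours
#'
#' Builds the end-diastolic truncated-ellipse endocardium and deforms it over
#' time by scaling each polyline edge with its segment's shortening factor
#' `1 + gls * m_j * s(t) / 100` while keeping edge directions and anchoring
#' the base midpoint. Because every edge of segment `j` scales by exactly the
#' same factor, the programmed global and per-segment strains are reproduced
#' by the generated contours to floating precision.
#'
#' @param config a [phantom_config()].
#' @return Object of class `phantom_truth`: `contours` (one [contour()] per
#'   frame), `ed_frames`, `es_frames`, `end_frames` (0-based, per beat),
#'   `strain_global` (per-frame true strain %), `segment_strain` (6 x
#'   n_frames), `segment_peaks` (named, % — `NULL` for A3C where no segment
#'   scheme is defined), `ecg` (an [ecg_trace()] with impulses at true ED
#'   times), `frame_rate`, and the resolved `config`.
#' @export
generate_contours <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  if (is.null(cfg$frame_rate))
    cfg$frame_rate <- with_seed(derive_seed(cfg$seed, 1L), runif(1, 60, 80))
  sp <- cfg$pixel_spacing
  margin <- 22  # px head-room for the speckle band and tracking window

  # truncated ellipse in mm, apex toward larger row (image bottom)
  a <- cfg$ed_long_axis / 1.35
  b <- cfg$ed_short_axis / 2
  phi_b <- asin(0.35)
  phi <- seq(pi - phi_b, 2 * pi + phi_b, length.out = 4001L)
  dense <- cbind(b * cos(phi), -a * sin(phi))  # base at top, apex at bottom row
  dense <- sweep(dense, 2L, apply(dense, 2L, min), "-")
  ed_pts <- resample(dense / sp, PHANTOM_POINTS)  # px
  ed_pts <- sweep(ed_pts, 2L, margin - apply(ed_pts, 2L, min), "+")
  apex_index <- which.max(ed_pts[, 2L])

  T_frames <- max(8L, as.integer(round(cfg$frame_rate * 60 / cfg$heart_rate)))
  es_off <- max(2L, as.integer(round(0.35 * T_frames)))
  n_frames <- cfg$n_beats * T_frames + 1L
  k <- seq_len(n_frames) - 1L
  phase <- (k %% T_frames) / T_frames
  s_t <- activation(phase, es_off / T_frames)
  s_t[phase == 0] <- 0

  seg_of_edge <- rep(seq_len(6L), each = EDGES_PER_SEGMENT)
  edges <- ed_pts[-1L, ] - ed_pts[-PHANTOM_POINTS, ]
  rho_es <- 1 + cfg$target_gls * cfg$per_segment_modifiers / 100
  if (any(rho_es > 1.1))
    abort("config_error", "modifiers would lengthen a segment by more than 10%")

  base_mid <- (ed_pts[1L, ] + ed_pts[PHANTOM_POINTS, ]) / 2
  contours <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    rho <- 1 + cfg$target_gls * cfg$per_segment_modifiers * s_t[i] / 100
    scaled <- edges * rho[seg_of_edge]
    q <- rbind(c(0, 0), cbind(cumsum(scaled[, 1L]), cumsum(scaled[, 2L])))
    q <- sweep(q, 2L, ed_pts[1L, ], "+")
    shift <- base_mid - (q[1L, ] + q[PHANTOM_POINTS, ]) / 2
    q <- sweep(q, 2L, shift, "+")
    contours[[i]] <- contour(q, frame_index = i - 1L, pixel_spacing = sp,
                             apex_index = apex_index, view = cfg$view)
  }

  lengths <- vapply(contours, arc_length, numeric(1))
  strain_global <- 100 * (lengths - lengths[1L]) / lengths[1L]
  seg_len <- vapply(contours, function(ct) {
    e <- ct$points[-1L, ] - ct$points[-PHANTOM_POINTS, ]
    el <- sqrt(rowSums(e^2))
    as.double(tapply(el, seg_of_edge, sum)) * sp
  }, numeric(6L))
  segment_strain <- 100 * sweep(seg_len, 1L, seg_len[, 1L], "-") / seg_len[, 1L]
  scheme_names <- if (cfg$view == "A4C") a4c_segments else
    if (cfg$view == "A2C") a2c_segments else NULL
  if (!is.null(scheme_names)) rownames(segment_strain) <- scheme_names

  ed_frames <- seq(0L, cfg$n_beats * T_frames, by = T_frames)
  es_frames <- ed_frames[-length(ed_frames)] + es_off
  segment_peaks <- if (!is.null(scheme_names))
    stats::setNames(apply(segment_strain[, seq_len(es_off + 1L), drop = FALSE], 1L, min),
                    scheme_names) else NULL

  sr <- 250
  ed_times <- ed_frames / cfg$frame_rate
  jit <- if (cfg$ecg_jitter_sd > 0)
    with_seed(derive_seed(cfg$seed, 2L), rnorm(length(ed_times), 0, cfg$ecg_jitter_sd))
  else rep(0, length(ed_times))
  r_samples <- sort(round(pmax(ed_times + jit, 0) * sr))
  samples <- numeric(ceiling((n_frames - 1L) / cfg$frame_rate * sr) + 1L)
  samples[pmin(r_samples + 1L, length(samples))] <- 1
  ecg <- ecg_trace(samples = samples, sample_rate = sr, r_peaks = r_samples)

  cfg_out <- cfg
  structure(
    list(contours = contours, ed_frames = ed_frames, es_frames = es_frames,
         end_frames = ed_frames[-1L], strain_global = strain_global,
         segment_strain = segment_strain, segment_peaks = segment_peaks,
         ecg = ecg, frame_rate = cfg$frame_rate, config = cfg_out),
    class = "phantom_truth"
  )
}

# position and unit inward-normal offset point at fractional vertex indices
band_points <- function(pts, fidx, v) {
  i <- pmin(pmax(floor(fidx), 1), nrow(pts) - 1L)
  t <- fidx - i
  p <- pts[i, , drop = FALSE] + t * (pts[i + 1L, , drop = FALSE] - pts[i, , drop = FALSE])
  e <- pts[i + 1L, , drop = FALSE] - pts[i, , drop = FALSE]
  el <- sqrt(rowSums(e^2))
  nx <- -e[, 2L] / el; ny <- e[, 1L] / el
  cbind(p[, 1L] + v * nx, p[, 2L] + v * ny)
}

#' Render a speckle-textured phantom sequence
#'
#' Renders the phantom as B-mode-like frames: a band of Gaussian speckle
#' particles is laid down around the end-diastolic contour in material band
#' coordinates (arc position, normal offset) and advected each frame by the
#' analytic contour motion, so the texture deforms exactly with the tissue.
#' Per-pixel multiplicative noise of SD `speckle_noise_sd` and a noisy
#' background floor are added, values are clamped to `[0, 1]` and quantized
#' to 8 bits (matching the on-disk PNG representation exactly).
#'
#' @param truth a [generate_contours()] result.
#' @param config the same [phantom_config()] (defaults to `truth$config`).
#' @param band_halfwidth_px half-width of the myocardial speckle band.
#' @param blob_density particles per band pixel^2.
#' @param blob_sigma particle Gaussian SD in pixels.
#' @param band_end_margin fraction of the arc length by which the textured
#'   band extends past the annulus points (tissue does not terminate at the
#'   trace ends; without the margin the end points sit on a texture edge).
#' @return List with `frames` (list of matrices in `[0, 1]`), `nrow`, `ncol`,
#'   and the band mask of frame 0 (`band_mask`, logical matrix).
#' @export
render_sequence <- function(truth, config = truth$config, band_halfwidth_px = 6,
                            blob_density = 0.15, blob_sigma = 1.2,
                            band_end_margin = 0.04, return_mask = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  ed <- truth$contours[[1L]]$points
  n_frames <- length(truth$contours)
  pad <- band_halfwidth_px + 10
  nc <- as.integer(ceiling(max(ed[, 1L]) + pad))
  nr <- as.integer(ceiling(max(ed[, 2L]) + pad))
  if (min(ed) - pad < 0)
    abort("config_error", "image too small to contain the contour and band")

  L_px <- arc_length(ed)
  n_blobs <- max(50L, as.integer(round(blob_density * L_px *
                                         (1 + 2 * band_end_margin) *
                                         2 * band_halfwidth_px)))
  sd_n <- config$speckle_noise_sd

  with_seed(derive_seed(config$seed, 3L), {
    # material arc fraction (ED); fractions outside [0, 1] extrapolate the
    # band past the annulus points along the end tangents
    u <- runif(n_blobs, -band_end_margin, 1 + band_end_margin)
    v <- runif(n_blobs, -band_halfwidth_px, band_halfwidth_px)
    amp <- runif(n_blobs, 0.1, 0.5)
    fidx <- 1 + u * (PHANTOM_POINTS - 1L)     # ED vertices are equal-chord
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      pos <- band_points(truth$contours[[i]]$points, fidx, v)
      img <- splat_gaussians_cpp(nr, nc, pos, amp, blob_sigma)
      if (sd_n > 0) {
        img <- img * (1 + sd_n * matrix(rnorm(nr * nc), nr, nc))
        img <- img + 0.06 * (1 + sd_n * matrix(rnorm(nr * nc), nr, nc))
      } else {
        img <- img + 0.06
      }
      img[img < 0] <- 0
      img[img > 1] <- 1
      frames[[i]] <- round(img * 255) / 255
    }
  })

  band_mask <- NULL
  if (return_mask) {
    # band mask of frame 0 (for masking diagnostics)
    gx <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    gy <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
    dmin <- matrix(Inf, nr, nc)
    for (j in seq(1L, PHANTOM_POINTS, by = 2L)) {
      d <- sqrt((gx - ed[j, 1L])^2 + (gy - ed[j, 2L])^2)
      dmin <- pmin(dmin, d)
    }
    band_mask <- dmin <= band_halfwidth_px
  }
  list(frames = frames, nrow = nr, ncol = nc, band_mask = band_mask)
}

#' Generate one phantom study (all three apical views)
#'
#' Builds a complete study bundle — A4C, A2C and A3C videos with rendered
#' frames, per-frame ground-truth annotations (standing in for the CNN
#' traces), ECG, and view confidence 1.0 — together with its ground truth.
#'
#' @param study_id identifier string.
#' @param seed integer seed for all randomness in this study.
#' @param target_gls programmed GLS (%) shared by the three views.
#' @param abnormal_view `NA`, `"A4C"` or `"A2C"`: the view carrying a
#'   wall-motion abnormality.
#' @param abnormal_segment segment index 1-6 within the abnormal view.
#' @param abnormal_modifier local shortening multiplier of the abnormal
#'   segment (0 = akinetic, intermediate = hypokinetic).
#' @param heart_rate,frame_rate,n_beats,speckle_noise_sd,pixel_spacing see
#'   [phantom_config()].
#' @param views which views to generate (dropping one produces an incomplete
#'   study for exercising view-identification exclusion).
#' @return List with `study` (a study bundle as consumed by
#'   [analyze_study()]) and `truth` (per-view programmed GLS, total GLS,
#'   per-segment truth peaks, abnormal labels).
#' @export
generate_study <- function(study_id, seed, target_gls = -20,
                           abnormal_view = NA_character_, abnormal_segment = NA_integer_,
                           abnormal_modifier = 0, heart_rate = 75, frame_rate = NULL,
                           n_beats = 3, speckle_noise_sd = 0.1, pixel_spacing = 0.5,
                           views = c("A4C", "A2C", "A3C")) {
  videos <- list()
  seg_truth <- list()
  per_view_gls <- c(A4C = NA_real_, A2C = NA_real_, A3C = NA_real_)
  for (vi in seq_along(views)) {
    vw <- views[vi]
    mods <- rep(1, 6)
    if (!is.na(abnormal_view) && vw == abnormal_view)
      mods[abnormal_segment] <- abnormal_modifier
    cfg <- phantom_config(view = vw, target_gls = target_gls,
                          per_segment_modifiers = mods, heart_rate = heart_rate,
                          frame_rate = frame_rate, n_beats = n_beats,
                          pixel_spacing = pixel_spacing,
                          speckle_noise_sd = speckle_noise_sd,
                          seed = derive_seed(seed, vi))
    truth <- generate_contours(cfg)
    rend <- render_sequence(truth)
    videos[[vi]] <- list(
      view = vw, confidence = 1.0, frames = rend$frames,
      frame_rate = truth$frame_rate, pixel_spacing = pixel_spacing,
      annotations = truth$contours, ecg = truth$ecg, truth = truth
    )
    es1 <- truth$es_frames[1L] + 1L
    per_view_gls[vw] <- truth$strain_global[es1]
    if (!is.null(truth$segment_peaks)) seg_truth[[vw]] <- truth$segment_peaks
  }
  study <- structure(list(study_id = study_id, videos = videos, seed = seed),
                     class = "study_bundle")
  truth_row <- list(
    study_id = study_id,
    per_view_gls = per_view_gls,
    true_gls = mean(per_view_gls[views], na.rm = TRUE),
    segment_peaks = seg_truth,
    abnormal_view = abnormal_view,
    abnormal_segment_label =
      if (!is.na(abnormal_view))
        (if (abnormal_view == "A4C") a4c_segments else a2c_segments)[abnormal_segment]
      else NA_character_
  )
  list(study = study, truth = truth_row)
}

#' Generate a phantom cohort
#'
#' Draws `n` phantom studies with per-study GLS from a normal distribution
#' (truncated to the valid `(-35, 0]` range), heart rates uniform in 55-95
#' bpm and frame rates uniform in 60-80 fps. A fraction of studies receives
#' one akinetic (or hypokinetic) segment in a randomly chosen A4C or A2C
#' view. All randomness derives from `seed`; identical seeds reproduce the
#' cohort exactly.
#'
#' @param n number of studies (>= 2).
#' @param gls_mean,gls_sd GLS distribution, strain %.
#' @param abnormal_fraction fraction of studies given a wall-motion
#'   abnormality.
#' @param seed integer master seed.
#' @param speckle_noise_sd,n_beats,pixel_spacing forwarded to the phantom.
#' @param abnormal_modifier local shortening multiplier for the induced
#'   abnormality (default 0 = akinetic).
#' @param materialize render every study up front (`TRUE`), or return lazy
#'   study handles built on demand by [build_study()] (`FALSE`). The default
#'   materializes small cohorts and keeps large ones lazy so that a 50-study
#'   cohort (hundreds of rendered frames per study) never has to reside in
#'   memory at once; [run_cohort()] builds and discards one study at a time.
#' @return List with `studies` (study bundles or lazy handles) and `truth`
#'   (data frame: study_id, true_gls, abnormal, abnormal_view,
#'   abnormal_segment, heart_rate, frame_rate). True GLS is exact by
#'   construction: the programmed GLS scaled by the mean segment modifier,
#'   averaged over the three views.
#' @export
generate_cohort <- function(n, gls_mean = -18, gls_sd = 4, abnormal_fraction = 0,
                            seed = 1L, speckle_noise_sd = 0.1, n_beats = 3,
                            pixel_spacing = 0.5, abnormal_modifier = 0,
                            materialize = NULL) {
  if (n < 2) abort("config_error", "cohort needs at least 2 studies")
  draws <- with_seed(seed, {
    gls <- rnorm(n, gls_mean, gls_sd)
    for (i in seq_len(n))  # truncate to the valid phantom range
      while (gls[i] <= -34.5 || gls[i] > 0) gls[i] <- rnorm(1, gls_mean, gls_sd)
    hr <- runif(n, 55, 95)
    fps <- runif(n, 60, 80)
    n_ab <- round(abnormal_fraction * n)
    ab <- rep(FALSE, n)
    if (n_ab > 0) ab[sample.int(n, n_ab)] <- TRUE
    ab_view <- ifelse(ab, sample(c("A4C", "A2C"), n, replace = TRUE), NA_character_)
    ab_seg <- ifelse(ab, sample.int(6L, n, replace = TRUE), NA_integer_)
    list(gls = gls, hr = hr, fps = fps, ab = ab, ab_view = ab_view, ab_seg = ab_seg)
  })
  if (is.null(materialize)) materialize <- n <= 10
  studies <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    args <- list(
      study_id = sprintf("phantom-%03d", i), seed = derive_seed(seed, 100L + i),
      target_gls = draws$gls[i], abnormal_view = draws$ab_view[i],
      abnormal_segment = draws$ab_seg[i], abnormal_modifier = abnormal_modifier,
      heart_rate = draws$hr[i], frame_rate = draws$fps[i], n_beats = n_beats,
      speckle_noise_sd = speckle_noise_sd, pixel_spacing = pixel_spacing
    )
    studies[[i]] <- if (materialize) do.call(generate_study, args)$study
    else structure(list(args = args), class = "lazy_study")
    # exact by construction: each view's GLS is the programmed value scaled
    # by the mean segment modifier (segments have equal ED length)
    view_gls <- rep(draws$gls[i], 3)
    if (draws$ab[i]) {
      hit <- match(draws$ab_view[i], c("A4C", "A2C", "A3C"))
      view_gls[hit] <- draws$gls[i] * (5 + abnormal_modifier) / 6
    }
    seg_label <- if (draws$ab[i])
      (if (draws$ab_view[i] == "A4C") a4c_segments else
         a2c_segments)[draws$ab_seg[i]] else NA_character_
    rows[[i]] <- data.frame(
      study_id = args$study_id, true_gls = mean(view_gls),
      abnormal = draws$ab[i], abnormal_view = draws$ab_view[i],
      abnormal_segment = seg_label,
      heart_rate = draws$hr[i], frame_rate = draws$fps[i],
      stringsAsFactors = FALSE
    )
  }
  list(studies = studies, truth = do.call(rbind, rows))
}

#' Materialize a study handle
#'
#' Lazy cohort entries from [generate_cohort()] carry only their generating
#' parameters; this builds the full study bundle (contours, rendered frames,
#' ECG). Already-materialized bundles pass through unchanged.
#'
#' @param x a study bundle or a lazy study handle.
#' @return A study bundle.
#' @export
build_study <- function(x) {
  if (inherits(x, "lazy_study")) do.call(generate_study, x$args)$study else x
}
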