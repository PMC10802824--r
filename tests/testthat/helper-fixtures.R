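# Programmatic fixtures shared across test files. Everything is generated in
# code under fixed seeds; expensive objects are memoized for the run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# random smooth open contour (apex-down arc with low-frequency radius
# perturbations), n points, centered near (cx, cy)
smooth_contour <- function(n = 200, seed = 1, cx = 80, cy = 40, r0 = 50,
                           wiggle = 0.08) {
  set.seed(seed)
  th <- seq(0.15 * pi, 0.85 * pi, length.out = n)
  a <- runif(3, -wiggle, wiggle)
  r <- r0 * (1 + a[1] * sin(2 * th) + a[2] * cos(3 * th) + a[3] * sin(5 * th))
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# speckle texture image built from random Gaussian particles
speckle_texture <- function(nr = 160, nc = 160, n_blobs = 2500, seed = 5,
                            sigma = 1.3) {
  set.seed(seed)
  pts <- cbind(runif(n_blobs, 3, nc - 3), runif(n_blobs, 3, nr - 3))
  amp <- runif(n_blobs, 0.1, 0.5)
  img <- echostrain:::splat_gaussians_cpp(nr, nc, pts, amp, sigma) + 0.05
  img[img > 1] <- 1
  list(img = img, pts = pts, amp = amp, sigma = sigma, nr = nr, nc = nc)
}

# frames of the texture rigidly shifted by (k, 0) px per frame
shifted_frames <- function(tex, n_frames) {
  lapply(seq_len(n_frames) - 1L, function(k) {
    ptsk <- sweep(tex$pts, 2L, c(k, 0), "+")
    img <- echostrain:::splat_gaussians_cpp(tex$nr, tex$nc, ptsk, tex$amp,
                                            tex$sigma) + 0.05
    img[img > 1] <- 1
    img
  })
}

# frames of the texture scaled about `center` by factors `svals`
scaled_frames <- function(tex, center, svals) {
  lapply(svals, function(s) {
    ptsk <- sweep(sweep(tex$pts, 2L, center, "-") * s, 2L, center, "+")
    img <- echostrain:::splat_gaussians_cpp(tex$nr, tex$nc, ptsk, tex$amp,
                                            tex$sigma) + 0.05
    img[img > 1] <- 1
    img
  })
}

# tracked sequence with exact material point correspondence, built from
# phantom truth contours (the ground-truth oracle for regional strain)
truth_tracked <- function(truth, n_points = 64L) {
  ed <- resample(truth$contours[[1L]], n_points)
  npts <- nrow(truth$contours[[1L]]$points)
  fid <- 1 + seq(0, 1, length.out = n_points) * (npts - 1L)
  end <- truth$end_frames[1L]
  nf <- end + 1L
  arr <- array(NA_real_, dim = c(n_points, 2L, nf))
  for (k in seq_len(nf))
    arr[, , k] <- echostrain:::point_at_index(truth$contours[[k]]$points, fid)
  structure(
    list(points = arr, frames = 0L:end, source = ed,
         pixel_spacing = ed$pixel_spacing, residuals = numeric(nf),
         flagged = integer(nf), stabilization_weight = 0,
         unstabilized_frames = integer(0)),
    class = "tracked_sequence"
  )
}

# the fixed zero-noise phantom study used by several files
zero_noise_study <- function() {
  memo("zero_noise_study",
       generate_study("phantom-zero", seed = 11L, target_gls = -20,
                      heart_rate = 75, frame_rate = 70, n_beats = 3,
                      speckle_noise_sd = 0))
}

zero_noise_report <- function() {
  memo("zero_noise_report", analyze_study(zero_noise_study()$study))
}
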