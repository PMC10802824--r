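test_that("strain curve is the percentage length change from end-diastole", {
  cy <- cardiac_cycle(0, 2, 4, 60)
  expect_equal(strain_curve(c(100, 90, 80, 90, 100), cy),
               c(0, -10, -20, -10, 0))
  expect_equal(strain_curve(rep(82.5, 5), cy), rep(0, 5))
  expect_error(strain_curve(c(100, 90, 0, 90, 100), cy),
               class = "echostrain_invalid_length")
})

test_that("strain on ground-truth phantom contours recovers the programmed value", {
  truth <- generate_contours(phantom_config(target_gls = -20, frame_rate = 70,
                                            heart_rate = 75, n_beats = 1,
                                            speckle_noise_sd = 0, seed = 4))
  lens <- vapply(truth$contours, arc_length, numeric(1))
  cy <- cardiac_cycle(truth$ed_frames[1], truth$es_frames[1],
                      truth$end_frames[1], truth$frame_rate)
  eps <- strain_curve(lens, cy)
  expect_lt(abs(eps[cy$es_frame + 1] - (-20)), 1e-6)
  expect_true(all(eps <= 1e-9))  # shortening is negative throughout
})

test_that("drift correction subtracts the linear ramp vanishing at ED", {
  cy <- cardiac_cycle(0, 2, 4, 60)
  expect_equal(drift_correct(c(0, -10, -20, -9, 2), cy),
               c(0, -10.5, -21, -10.5, 0))
  ends_at_zero <- c(0, -8, -16, -7, 0)
  expect_equal(drift_correct(ends_at_zero, cy), ends_at_zero)
  expect_equal(drift_correct(drift_correct(c(0, -10, -20, -9, 2), cy), cy),
               drift_correct(c(0, -10, -20, -9, 2), cy))
  expect_error(drift_correct(c(1, -10, -20, -9, 2), cy),
               class = "echostrain_invalid_length")
})

test_that("drift correction equals the direct ramp construction on random curves", {
  set.seed(42)
  for (i in 1:200) {
    nf <- sample(10:60, 1)
    cy <- cardiac_cycle(0, sample(2:(nf - 2), 1), nf - 1, 60)
    raw <- c(0, cumsum(rnorm(nf - 1, -0.3, 1)))
    # independent oracle: the unique linear function vanishing at ED and
    # equal to raw[end] at the end
    ramp <- raw[nf] * (seq_len(nf) - 1) / (nf - 1)
    corrected <- drift_correct(raw, cy)
    expect_lt(max(abs(corrected - (raw - ramp))), 1e-12)
    expect_identical(corrected[1], 0)
    expect_identical(corrected[nf], 0)
  }
})

test_that("video GLS averages the drift-corrected ES strain over cycles", {
  mk <- function(es_val) {
    cy <- cardiac_cycle(0, 2, 4, 60)
    strain_curve_set(c(0, es_val / 2, es_val, es_val / 2, 0), cy)
  }
  expect_equal(gls_for_video(list(mk(-20), mk(-22))), -21)
  expect_equal(gls_for_video(list(mk(-17.3))), -17.3)
  expect_error(gls_for_video(list()), class = "echostrain_no_measurement")
})

test_that("identical phantom beats give identical video and cycle GLS", {
  truth <- zero_noise_study()$study$videos[[1]]$truth
  lens <- vapply(truth$contours, arc_length, numeric(1))
  sets <- lapply(seq_along(truth$es_frames), function(b) {
    cy <- cardiac_cycle(truth$ed_frames[b], truth$es_frames[b],
                        truth$end_frames[b], truth$frame_rate)
    strain_curve_set(drift_correct(strain_curve(lens, cy), cy), cy)
  })
  expect_lt(abs(gls_for_video(sets) - gls_for_video(sets[1])), 1e-6)
})

test_that("total GLS is the mean of the three views", {
  expect_equal(total_gls(c(A4C = -20, A2C = -18, A3C = -19)), -19)
  expect_equal(total_gls(c(A4C = -15.4, A2C = -15.4, A3C = -15.4)), -15.4)
  set.seed(1)
  for (i in 1:50) {
    v <- stats::setNames(rnorm(3, -18, 4), c("A4C", "A2C", "A3C"))
    expect_equal(total_gls(v), sum(v) / 3)
  }
  expect_error(total_gls(c(A4C = -20, A2C = -18, A3C = NA)),
               class = "echostrain_missing_view")
  expect_equal(total_gls(c(A4C = -20, A2C = -18, A3C = NA),
                         allow_partial = TRUE), -19)
})

test_that("regional strain on material correspondences recovers segment truth", {
  uni <- generate_contours(phantom_config(view = "A4C", target_gls = -20,
                                          frame_rate = 70, heart_rate = 75,
                                          n_beats = 1, speckle_noise_sd = 0,
                                          seed = 6))
  cy <- cardiac_cycle(uni$ed_frames[1], uni$es_frames[1], uni$end_frames[1],
                      uni$frame_rate)
  reg <- regional_strain(truth_tracked(uni), segment_scheme("A4C"), cy)
  expect_true(all(abs(reg$peaks - (-20)) < 0.5))

  aki <- generate_contours(phantom_config(view = "A4C", target_gls = -20,
                                          per_segment_modifiers = c(0, 1, 1, 1, 1, 1),
                                          frame_rate = 70, heart_rate = 75,
                                          n_beats = 1, speckle_noise_sd = 0,
                                          seed = 6))
  reg2 <- regional_strain(truth_tracked(aki), segment_scheme("A4C"), cy)
  expect_lt(abs(reg2$peaks[["basal-inferoseptal"]]), 2)
  expect_true(all(reg2$peaks[-1] < -15))
})

test_that("global curve equals the ED-length-weighted mean of segment curves", {
  truth <- generate_contours(phantom_config(view = "A4C", target_gls = -18,
                                            per_segment_modifiers = c(1, .6, 1, 0, 1, .8),
                                            frame_rate = 70, heart_rate = 75,
                                            n_beats = 1, speckle_noise_sd = 0,
                                            seed = 8))
  cy <- cardiac_cycle(truth$ed_frames[1], truth$es_frames[1],
                      truth$end_frames[1], truth$frame_rate)
  tk <- truth_tracked(truth)
  reg <- regional_strain(tk, segment_scheme("A4C"), cy)
  w <- reg$ed_lengths / sum(reg$ed_lengths)
  lens <- echostrain:::tracked_lengths(tk)
  global_raw <- strain_curve(lens, cy)
  expect_lt(max(abs(colSums(reg$raw_curves * w) - global_raw)), 1e-9)
  global_corr <- drift_correct(global_raw, cy)
  expect_lt(max(abs(colSums(reg$curves * w) - global_corr)), 1e-9)
})

test_that("regional strain rejects unsupported or mismatched views", {
  truth <- generate_contours(phantom_config(view = "A3C", target_gls = -18,
                                            frame_rate = 70, heart_rate = 75,
                                            n_beats = 1, speckle_noise_sd = 0,
                                            seed = 9))
  cy <- cardiac_cycle(truth$ed_frames[1], truth$es_frames[1],
                      truth$end_frames[1], truth$frame_rate)
  expect_error(regional_strain(truth_tracked(truth), segment_scheme("A4C"), cy),
               class = "echostrain_unsupported_view")
})

test_that("impaired GLS is strictly less negative than the threshold", {
  expect_true(classify_impaired(-15, -16))
  expect_false(classify_impaired(-18, -16))
  expect_false(classify_impaired(-16, -16))  # boundary: not impaired
  expect_error(classify_impaired(NaN), class = "echostrain_invalid_length")
})
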