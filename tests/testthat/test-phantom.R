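test_that("programmed strain is reproduced exactly by the generated contours", {
  truth <- generate_contours(phantom_config(target_gls = -20, frame_rate = 70,
                                            heart_rate = 75, n_beats = 2,
                                            speckle_noise_sd = 0, seed = 1))
  es1 <- truth$es_frames[1] + 1
  expect_lt(abs(truth$strain_global[es1] - (-20)), 1e-6)
  expect_true(all(abs(truth$strain_global[truth$ed_frames + 1]) < 1e-9))
  expect_true(all(abs(truth$segment_peaks - (-20)) < 1e-6))
})

test_that("an akinetic segment has exactly zero truth strain", {
  truth <- generate_contours(phantom_config(view = "A4C", target_gls = -20,
                                            per_segment_modifiers = c(0, 1, 1, 1, 1, 1),
                                            frame_rate = 70, heart_rate = 75,
                                            n_beats = 1, speckle_noise_sd = 0,
                                            seed = 2))
  expect_lt(abs(truth$segment_peaks[["basal-inferoseptal"]]), 1e-6)
  es1 <- truth$es_frames[1] + 1
  expect_gt(truth$strain_global[es1], -20)   # less negative than programmed
  expect_lt(truth$strain_global[es1], -15)
})

test_that("truth strains are self-consistent with re-measured contour lengths", {
  truth <- generate_contours(phantom_config(target_gls = -17.5, frame_rate = 65,
                                            heart_rate = 80, n_beats = 2,
                                            per_segment_modifiers = c(1, .5, 1, .8, 1, 1),
                                            speckle_noise_sd = 0.1, seed = 3))
  lens <- vapply(truth$contours, arc_length, numeric(1))
  eps <- 100 * (lens - lens[1]) / lens[1]
  expect_lt(max(abs(eps - truth$strain_global)), 1e-6)
  # ED-length-weighted segment strains average to the global strain
  seg_of_edge <- rep(1:6, each = 20)
  ed_seg_len <- tapply(sqrt(rowSums(diff(truth$contours[[1]]$points)^2)),
                       seg_of_edge, sum)
  w <- as.numeric(ed_seg_len / sum(ed_seg_len))
  expect_lt(max(abs(colSums(truth$segment_strain * w) - truth$strain_global)),
            1e-9)
})

test_that("phantom generation is deterministic under the seed", {
  cfg <- phantom_config(target_gls = -19, n_beats = 1, speckle_noise_sd = 0.1,
                        seed = 12)
  t1 <- generate_contours(cfg)
  t2 <- generate_contours(cfg)
  expect_identical(t1$strain_global, t2$strain_global)
  expect_identical(t1$contours[[5]]$points, t2$contours[[5]]$points)
  r1 <- render_sequence(t1)
  r2 <- render_sequence(t2)
  expect_identical(r1$frames, r2$frames)
})

test_that("a NULL frame rate is drawn reproducibly in the 60-80 fps envelope", {
  cfg <- phantom_config(target_gls = -19, n_beats = 1, frame_rate = NULL, seed = 13)
  t1 <- generate_contours(cfg)
  t2 <- generate_contours(cfg)
  expect_identical(t1$frame_rate, t2$frame_rate)
  expect_gte(t1$frame_rate, 60)
  expect_lte(t1$frame_rate, 80)
})

test_that("rendering puts speckle inside the myocardial band", {
  truth <- generate_contours(phantom_config(target_gls = -18, frame_rate = 70,
                                            heart_rate = 75, n_beats = 1,
                                            speckle_noise_sd = 0.1, seed = 14))
  rend <- render_sequence(truth, return_mask = TRUE)
  f0 <- rend$frames[[1]]
  expect_gt(mean(f0[rend$band_mask]), mean(f0[!rend$band_mask]))
  expect_true(all(f0 >= 0 & f0 <= 1))
})

test_that("zero-noise rendering is periodic: the next-beat ED frame repeats frame 0", {
  truth <- zero_noise_study()$study$videos[[1]]$truth
  rend <- zero_noise_study()$study$videos[[1]]$frames
  t_beat <- truth$end_frames[1]
  expect_identical(rend[[1]], rend[[t_beat + 1]])
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(target_gls = 3), class = "echostrain_config_error")
  expect_error(phantom_config(target_gls = -40), class = "echostrain_config_error")
  expect_error(phantom_config(per_segment_modifiers = rep(2, 6)),
               class = "echostrain_config_error")
  expect_error(phantom_config(heart_rate = -5), class = "echostrain_config_error")
})

test_that("cohorts are reproducible and respect the abnormal fraction", {
  c1 <- generate_cohort(4, seed = 50, abnormal_fraction = 0.5, n_beats = 1,
                        speckle_noise_sd = 0.05)
  c2 <- generate_cohort(4, seed = 50, abnormal_fraction = 0.5, n_beats = 1,
                        speckle_noise_sd = 0.05)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$studies[[2]]$videos[[1]]$frames,
                   c2$studies[[2]]$videos[[1]]$frames)
  expect_equal(sum(c1$truth$abnormal), 2)
  expect_true(all(is.na(c1$truth$abnormal_segment[!c1$truth$abnormal])))
  expect_true(all(!is.na(c1$truth$abnormal_segment[c1$truth$abnormal])))

  c0 <- generate_cohort(3, seed = 51, abnormal_fraction = 0, n_beats = 1,
                        speckle_noise_sd = 0.05)
  expect_true(all(!c0$truth$abnormal))
  expect_true(all(c0$truth$true_gls > -35 & c0$truth$true_gls < 0))
})

test_that("phantom ECG impulses coincide with true end-diastoles", {
  truth <- generate_contours(phantom_config(target_gls = -18, frame_rate = 70,
                                            heart_rate = 75, n_beats = 3,
                                            speckle_noise_sd = 0, seed = 15))
  r_times <- truth$ecg$r_peaks / truth$ecg$sample_rate
  ed_times <- truth$ed_frames / truth$frame_rate
  expect_equal(length(r_times), length(ed_times))
  expect_lt(max(abs(r_times - ed_times)), 1 / truth$ecg$sample_rate + 1e-9)
})
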