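test_that("best-video selection maximizes confidence with first-wins ties", {
  expect_equal(select_best_video(c(0.70, 0.95, 0.85)), 2)
  expect_equal(select_best_video(0.5), 1)
  expect_equal(select_best_video(c(0.9, 0.9)), 1)
  expect_error(select_best_video(numeric(0)), class = "echostrain_view_not_found")
})

test_that("heart-rate check uses a closed plausibility interval", {
  mk <- function(bpm) cardiac_cycle(0, 10, round(60 * 60 / bpm), 60)
  expect_equal(heart_rate_check(mk(72)), "pass")
  expect_equal(heart_rate_check(mk(25)), "fail")
  expect_equal(heart_rate_check(cardiac_cycle(0, 10, 20, 60)), "pass")  # 180 bpm
})

offset_tracked <- function(offset_frac) {
  # straight-line "track" whose end frame is rigidly offset by a fraction of
  # the trace length
  n <- 32L
  line <- cbind(seq(0, 100, length.out = n), 10)
  L <- 100
  arr <- array(NA_real_, dim = c(n, 2L, 4L))
  for (k in 1:4) arr[, , k] <- line
  arr[, 2, 4] <- line[, 2] + offset_frac * L
  structure(list(points = arr, frames = 0:3,
                 source = contour(line, pixel_spacing = 1, apex_index = 16L),
                 pixel_spacing = 1, residuals = numeric(4), flagged = integer(4),
                 stabilization_weight = 0, unstabilized_frames = integer(0)),
            class = "tracked_sequence")
}

test_that("displacement check compares end-of-cycle mismatch to tau", {
  ann <- contour(cbind(seq(0, 100, length.out = 32), 10), pixel_spacing = 1,
                 apex_index = 16L)
  d0 <- displacement_check(offset_tracked(0), ann, tau = 0.05)
  expect_equal(d0$status, "pass")
  expect_equal(d0$distance_mm, 0)
  d10 <- displacement_check(offset_tracked(0.10), ann, tau = 0.05)
  expect_equal(d10$status, "fail")
  expect_equal(d10$distance_mm, 10, tolerance = 1e-9)
})

test_that("raising tau never decreases the displacement pass rate", {
  offsets <- seq(0, 0.12, by = 0.015)
  ann <- contour(cbind(seq(0, 100, length.out = 32), 10), pixel_spacing = 1,
                 apex_index = 16L)
  taus <- seq(0.01, 0.15, by = 0.01)
  rates <- vapply(taus, function(tau)
    mean(vapply(offsets, function(o)
      displacement_check(offset_tracked(o), ann, tau)$status == "pass",
      logical(1))), numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("displacement passes on noisy phantoms in nearly all seeded runs", {
  n_runs <- 30
  pass <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- phantom_config(view = "A4C", target_gls = -18, heart_rate = 75,
                          frame_rate = 70, n_beats = 1, speckle_noise_sd = 0.1,
                          seed = 5000L + i)
    truth <- generate_contours(cfg)
    rend <- render_sequence(truth)
    cy <- cardiac_cycle(truth$ed_frames[1], truth$es_frames[1],
                        truth$end_frames[1], truth$frame_rate)
    ed64 <- resample(truth$contours[[1]], 64)
    tk <- stabilize(track_contour(rend$frames, ed64, cy), truth$contours, 0.5)
    pass[i] <- displacement_check(tk, truth$contours[[1]])$status == "pass"
  }
  expect_gte(mean(pass), 0.95)
})

test_that("a study with no video of a required view is excluded for view identification", {
  g <- generate_study("qa-miss", seed = 31, n_beats = 1, speckle_noise_sd = 0,
                      views = c("A4C", "A3C"))
  rep <- analyze_study(g$study)
  expect_equal(rep$status, "excluded")
  expect_equal(rep$reason_code, "view_identification:A2C")
  qa <- run_sequential_qa(g$study)
  expect_equal(qa$final_status, "excluded")
  checks <- qa$per_video$A2C
  expect_equal(checks$status[checks$check == "view_identification"], "fail")
  expect_true(all(checks$status[-1] == "not_assessed"))
})

test_that("a failing check short-circuits later checks", {
  g <- generate_study("qa-hr", seed = 32, heart_rate = 75, frame_rate = 70,
                      n_beats = 1, speckle_noise_sd = 0)
  cfg <- strain_config(hr_bounds = c(110, 180))  # phantom beats at ~75 bpm
  rep <- analyze_study(g$study, cfg)
  expect_equal(rep$status, "excluded")
  expect_match(rep$reason_code, "^heart_rate:")
  for (vw in names(rep$per_view)) {
    checks <- rep$per_view[[vw]]$checks
    i_fail <- which(checks$status == "fail")
    expect_length(i_fail, 1)
    after <- checks$status[seq_len(nrow(checks)) > i_fail]
    expect_true(all(after == "not_assessed"))
  }
})

test_that("cohort accounting conserves studies and assigns one reason each", {
  studies <- c(
    lapply(1:2, function(i)
      generate_study(sprintf("full-%d", i), seed = 40L + i, n_beats = 1,
                     speckle_noise_sd = 0)$study),
    lapply(3:4, function(i)
      generate_study(sprintf("miss-%d", i), seed = 40L + i, n_beats = 1,
                     speckle_noise_sd = 0, views = c("A4C", "A2C"))$study)
  )
  rc <- run_cohort(studies)
  expect_equal(nrow(rc$results), 4)
  expect_equal(sum(rc$results$status == "analysed"), 2)
  expect_equal(sum(rc$results$status == "excluded"), 2)
  expect_equal(sum(rc$exclusions$n), 2)
  expect_true(all(rc$exclusions$reason_code == "view_identification:A3C"))
  excluded <- rc$results[rc$results$status == "excluded", ]
  expect_true(all(!is.na(excluded$reason_code)))
  expect_true(all(is.na(rc$results$reason_code[rc$results$status == "analysed"])))
})

test_that("the ECG check is advisory and reported not assessed without a trace", {
  g <- generate_study("qa-necg", seed = 33, n_beats = 1, speckle_noise_sd = 0)
  g$study$videos <- lapply(g$study$videos, function(v) { v$ecg <- NULL; v })
  rep <- analyze_study(g$study)
  expect_equal(rep$status, "analysed")
  for (vw in names(rep$per_view)) {
    checks <- rep$per_view[[vw]]$checks
    expect_equal(checks$status[checks$check == "systole_diastole_ecg"],
                 "not_assessed")
  }
})
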