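test_that("arc length sums Euclidean segments scaled by pixel spacing", {
  expect_equal(arc_length(rbind(c(0, 0), c(3, 0), c(3, 4))), 7)
  expect_equal(arc_length(rbind(c(0, 0), c(1, 0)), pixel_spacing = 0.5), 0.5)
  expect_error(arc_length(matrix(c(1, 1), 1, 2)), class = "echostrain_invalid_contour")
})

test_that("arc length matches quadrature on a half-ellipse", {
  a <- 40; b <- 25
  th <- seq(0, pi, length.out = 1000)
  pts <- cbind(a * cos(th), b * sin(th))
  # independent oracle: numerical quadrature of the arc-length integral
  oracle <- integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                      0, pi, rel.tol = 1e-12)$value
  expect_lt(abs(arc_length(pts) - oracle) / oracle, 0.001)
})

test_that("contour constructor enforces its invariants", {
  th <- seq(0, pi, length.out = 25)
  pts <- cbind(40 * cos(th) + 50, 60 * sin(th) + 10)
  ct <- contour(pts, pixel_spacing = 0.5)
  expect_s3_class(ct, "echo_contour")
  expect_gt(ct$apex_index, 1)
  expect_lt(ct$apex_index, nrow(pts))
  expect_error(contour(pts[1:5, ]), class = "echostrain_invalid_contour")
  expect_error(contour(rbind(pts, pts[1, ])), class = "echostrain_invalid_contour")
  expect_error(contour(pts[c(1, 1:24), ]), class = "echostrain_invalid_contour")
  expect_error(contour(pts, pixel_spacing = c(0.3, 0.4)),
               class = "echostrain_invalid_contour")
  expect_error(contour(pts, apex_index = 1), class = "echostrain_invalid_contour")
  # equal length-2 spacing collapses to the scalar
  expect_equal(contour(pts, pixel_spacing = c(0.5, 0.5))$pixel_spacing, 0.5)
})

test_that("resample places equally spaced points, keeps endpoints, is idempotent", {
  line <- resample(rbind(c(0, 0), c(10, 0)), 5)
  expect_equal(line[, 1], c(0, 2.5, 5, 7.5, 10))
  expect_equal(line[, 2], rep(0, 5))

  c0 <- smooth_contour(200, seed = 2)
  r1 <- resample(c0, 64)
  r2 <- resample(r1, 64)
  expect_lt(max(abs(r1 - r2)), 1e-9)
  expect_equal(r1[1, ], c0[1, ])
  expect_equal(r1[64, ], c0[200, ])
  # chords equal to numerical tolerance
  ch <- sqrt(rowSums(diff(r1)^2))
  expect_lt(diff(range(ch)) / mean(ch), 1e-9)
  # arc length preserved within 0.5%
  expect_lt(abs(arc_length(r1) - arc_length(c0)) / arc_length(c0), 0.005)
})

test_that("resample re-assigns the apex landmark by arc fraction", {
  th <- seq(0, pi, length.out = 101)
  ct <- contour(cbind(40 * cos(th), 60 * sin(th)), pixel_spacing = 1)
  r <- resample(ct, 65)
  frac_old <- echostrain:::cum_arc(ct$points)[ct$apex_index] /
    arc_length(ct)
  frac_new <- (r$apex_index - 1) / 64
  expect_lt(abs(frac_new - frac_old), 1 / 64)
})

test_that("cavity size is the chord-closed shoelace area", {
  expect_equal(cavity_size(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))), 1)
  expect_equal(cavity_size(cbind(0:4, 0:4)), 0)  # collinear
  a <- 40; b <- 25
  th <- seq(0, pi, length.out = 500)
  he <- cbind(a * cos(th), b * sin(th))
  expect_lt(abs(cavity_size(he) - pi * a * b / 2) / (pi * a * b / 2), 0.001)
  # self-intersecting closure warns and returns |area|
  zig <- rbind(c(0, 0), c(3, 2), c(5, -2), c(7, 2), c(10, 0))
  expect_warning(val <- cavity_size(zig), "intersects")
  expect_gte(val, 0)
})

test_that("lengths and areas scale as spacing^1 and spacing^2", {
  c0 <- smooth_contour(120, seed = 9)
  expect_equal(arc_length(c0, pixel_spacing = 2), 2 * arc_length(c0))
  expect_equal(cavity_size(c0, pixel_spacing = 2), 4 * cavity_size(c0))
})

test_that("segment schemes carry the named wall segments in order", {
  s4 <- segment_scheme("A4C")
  expect_identical(s4$names, c("basal-inferoseptal", "mid-inferoseptal",
                               "apical-septal", "apical-lateral",
                               "mid-anterolateral", "basal-anterolateral"))
  s2 <- segment_scheme("A2C")
  expect_identical(s2$names, c("basal-inferior", "mid-inferior",
                               "apical-inferior", "apical-anterior",
                               "mid-anterior", "basal-anterior"))
  expect_error(segment_scheme("A4C", c(0, .5, .4, .6, .7, .8, 1)),
               class = "echostrain_config_error")
})

test_that("partition splits at exact arc fractions", {
  line60 <- cbind(seq(0, 60, length.out = 61), 0)
  p <- partition_segments(line60, segment_scheme("A4C"))
  expect_equal(vapply(p, `[[`, numeric(1), "length"), rep(10, 6))

  line100 <- cbind(seq(0, 100, length.out = 101), 0)
  p2 <- partition_segments(line100,
                           segment_scheme("A4C", c(0, .2, .35, .5, .65, .8, 1)))
  expect_equal(vapply(p2, `[[`, numeric(1), "length"),
               c(20, 15, 15, 15, 15, 20))
})

test_that("partition is a partition: segment lengths sum to the whole", {
  for (seed in 1:100) {
    c0 <- smooth_contour(80, seed = seed)
    p <- partition_segments(c0, segment_scheme("A4C"))
    total <- sum(vapply(p, `[[`, numeric(1), "length"))
    expect_lt(abs(total - arc_length(c0)) / arc_length(c0), 1e-9)
  }
  # order follows point order A -> B
  c0 <- smooth_contour(80, seed = 1)
  p <- partition_segments(c0, segment_scheme("A4C"))
  expect_equal(p[[1]]$points[1, ], c0[1, ])
  expect_equal(p[[6]]$points[nrow(p[[6]]$points), ], c0[80, ])
})

test_that("regional partitioning rejects the A3C view", {
  th <- seq(0, pi, length.out = 25)
  ct <- contour(cbind(40 * cos(th), 60 * sin(th)), view = "A3C")
  expect_error(partition_segments(ct, segment_scheme("A4C")),
               class = "echostrain_unsupported_view")
})
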