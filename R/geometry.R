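#' Endocardial contour
#'
#' An ordered open polyline tracing the left-ventricular endocardium from one
#' mitral-annulus point, around the apex, to the other annulus point.
#' Coordinates are image coordinates `(x, y)` = (column, row) with the origin
#' at the top-left pixel center; positions are sub-pixel real values.
#'
#' @param points numeric matrix with two columns `(x, y)`, at least 7 rows,
#'   open (first point differs from the last), no two consecutive points equal.
#' @param frame_index 0-based frame the contour belongs to.
#' @param pixel_spacing isotropic pixel spacing in mm/pixel (scalar > 0). A
#'   length-2 spacing is accepted only when both entries are equal; anisotropic
#'   input is rejected.
#' @param apex_index index of the apex landmark, strictly between the first and
#'   last point. Defaults to the point farthest from the base midpoint.
#' @param view apical view label, one of `"A4C"`, `"A2C"`, `"A3C"`.
#' @return An object of class `echo_contour`: a list with elements `points`,
#'   `frame_index`, `pixel_spacing`, `apex_index`, `view`. Basal landmark A is
#'   the first point and basal landmark B the last.
#' @examples
#' th <- seq(0, pi, length.out = 25)
#' c0 <- contour(cbind(40 * cos(th) + 50, 60 * sin(th) + 10), pixel_spacing = 0.5)
#' arc_length(c0)
#' @export
contour <- function(points, frame_index = 0L, pixel_spacing = 1,
                    apex_index = NULL, view = c("A4C", "A2C", "A3C")) {
  view <- match.arg(view)
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  if (ncol(pts) != 2L) abort("invalid_contour", "contour points must have 2 columns")
  n <- nrow(pts)
  if (n < 7L) abort("invalid_contour", "contour needs at least 7 points, got %d", n)
  if (anyNA(pts)) abort("invalid_contour", "contour points contain missing values")
  if (all(pts[1L, ] == pts[n, ]))
    abort("invalid_contour", "contour must be an open polyline (first point equals last)")
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (any(d == 0))
    abort("invalid_contour", "contour has identical consecutive points")
  if (length(pixel_spacing) == 2L) {
    if (pixel_spacing[1L] != pixel_spacing[2L])
      abort("invalid_contour", "anisotropic pixel spacing is not supported")
    pixel_spacing <- pixel_spacing[1L]
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L || pixel_spacing <= 0)
    abort("invalid_contour", "pixel_spacing must be a positive scalar (mm/pixel)")
  if (is.null(apex_index)) {
    base_mid <- (pts[1L, ] + pts[n, ]) / 2
    apex_index <- which.max((pts[, 1L] - base_mid[1L])^2 + (pts[, 2L] - base_mid[2L])^2)
  }
  apex_index <- as.integer(apex_index)
  if (apex_index <= 1L || apex_index >= n)
    abort("invalid_contour", "apex index must be strictly interior")
  structure(
    list(points = pts, frame_index = as.integer(frame_index),
         pixel_spacing = as.double(pixel_spacing), apex_index = apex_index,
         view = view),
    class = "echo_contour"
  )
}

#' @export
print.echo_contour <- function(x, ...) {
  cat(sprintf("<echo_contour> %s, frame %d, %d points, %.3f mm/px, length %.2f mm\n",
              x$view, x$frame_index, nrow(x$points), x$pixel_spacing, arc_length(x)))
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "echo_contour")) return(x$points)
  pts <- as.matrix(x)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  if (ncol(pts) != 2L) abort("invalid_contour", "points must have 2 columns")
  pts
}

spacing_of <- function(x, pixel_spacing = NULL) {
  if (!is.null(pixel_spacing)) return(pixel_spacing)
  if (inherits(x, "echo_contour")) x$pixel_spacing else 1
}

# cumulative arc length (pixel units) along a polyline, starting at 0
cum_arc <- function(pts) {
  n <- nrow(pts)
  c(0, cumsum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))))
}

#' Arc length of a contour
#'
#' Sum of Euclidean segment lengths scaled by the pixel spacing: the
#' "circumferential" length of the traced endocardium used as the basis of
#' longitudinal strain.
#'
#' @param x an [contour()] object or a plain two-column point matrix.
#' @param pixel_spacing optional spacing override in mm/pixel (default: the
#'   contour's own spacing, or 1 for a plain matrix).
#' @return Length in mm (strictly positive).
#' @export
arc_length <- function(x, pixel_spacing = NULL) {
  pts <- as_points(x)
  if (nrow(pts) < 2L) abort("invalid_contour", "need at least 2 points for arc length")
  sp <- spacing_of(x, pixel_spacing)
  n <- nrow(pts)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))) * sp
}

# place points on a polyline at given cumulative-arc positions (pixel units)
interp_at_arc <- function(pts, cum, s) {
  m <- nrow(pts)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > m - 1L] <- m - 1L
  den <- cum[idx + 1L] - cum[idx]
  t <- ifelse(den > 0, (s - cum[idx]) / den, 0)
  pts[idx, , drop = FALSE] + t * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])
}

#' Resample a contour to equally spaced points
#'
#' Places `n` points along the polyline so that consecutive points are
#' separated by equal chord length, with both endpoints preserved exactly. The
#' equal-chord parametrization is computed by a fixed-point reparametrization
#' iteration, which makes the operation idempotent: resampling an already
#' equal-chord polyline returns it unchanged (to floating precision). The apex
#' landmark is re-assigned to the resampled point nearest the original apex
#' arc fraction.
#'
#' @param x an [contour()] object or a plain two-column point matrix.
#' @param n number of output points (at least 7 for a contour object).
#' @param tol convergence tolerance of the reparametrization iteration,
#'   relative to the polyline length.
#' @return Object of the same kind as `x` with `n` points.
#' @export
resample <- function(x, n, tol = 1e-12) {
  pts <- as_points(x)
  is_contour <- inherits(x, "echo_contour")
  n <- as.integer(n)
  if (is_contour && n < 7L) abort("invalid_contour", "resample needs n >= 7 for a contour")
  if (n < 2L) abort("invalid_contour", "resample needs n >= 2")
  # drop duplicate consecutive points defensively (plain-matrix input)
  m <- nrow(pts)
  keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] - pts[-m, , drop = FALSE])^2) > 0)
  pts <- pts[keep, , drop = FALSE]
  m <- nrow(pts)
  if (m < 2L) abort("invalid_contour", "degenerate polyline")
  cum <- cum_arc(pts)
  L <- cum[m]
  if (L <= 0) abort("invalid_contour", "zero-length polyline")
  s <- seq(0, L, length.out = n)
  out <- interp_at_arc(pts, cum, s)
  for (it in seq_len(50L)) {
    ch <- c(0, cumsum(sqrt(rowSums((out[-1L, , drop = FALSE] - out[-n, , drop = FALSE])^2))))
    target <- seq(0, ch[n], length.out = n)
    dev <- max(abs(ch - target))
    if (dev <= tol * L) break
    # move arc positions so cumulative chord length becomes uniform
    s_new <- approx(ch, s, xout = target, rule = 2)$y
    s_new[1L] <- 0; s_new[n] <- L
    s <- s_new
    out <- interp_at_arc(pts, cum, s)
  }
  out[1L, ] <- pts[1L, ]
  out[n, ] <- pts[m, ]
  if (!is_contour) return(out)
  apex_frac <- cum_arc(as_points(x))[x$apex_index] / L
  new_apex <- which.min(abs(seq(0, 1, length.out = n) - apex_frac))
  new_apex <- min(max(new_apex, 2L), n - 1L)
  contour(out, frame_index = x$frame_index, pixel_spacing = x$pixel_spacing,
          apex_index = new_apex, view = x$view)
}

# do segments p1-p2 and p3-p4 properly intersect?
segs_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  c1 <- cross(p1, p2, q1); c2 <- cross(p1, p2, q2)
  c3 <- cross(q1, q2, p1); c4 <- cross(q1, q2, p2)
  (c1 * c2 < 0) && (c3 * c4 < 0)
}

#' Cavity-size surrogate of a contour
#'
#' Shoelace area of the polygon obtained by closing the open endocardial
#' polyline with the chord from its last point back to the first (the mitral
#' base chord), scaled by the squared pixel spacing. Used as the per-frame
#' cavity-size signal from which cardiac cycles are detected: it is monotone
#' in ventricular size and available from the contour alone.
#'
#' @inheritParams arc_length
#' @return Area in mm^2 (non-negative). If the closing chord crosses the
#'   polyline a warning is emitted and the absolute area is returned.
#' @export
cavity_size <- function(x, pixel_spacing = NULL) {
  pts <- as_points(x)
  sp <- spacing_of(x, pixel_spacing)
  n <- nrow(pts)
  if (n < 3L) return(0)
  xs <- pts[, 1L]; ys <- pts[, 2L]
  j <- c(2:n, 1L)
  a <- 0.5 * sum(xs * ys[j] - xs[j] * ys)
  # self-intersection of the closing chord with interior edges
  if (n > 3L) {
    for (k in seq_len(n - 3L) + 1L) {
      if (segs_intersect(pts[n, ], pts[1L, ], pts[k, ], pts[k + 1L, ])) {
        warning("closing chord intersects the contour; returning absolute area")
        break
      }
    }
  }
  abs(a) * sp^2
}

a4c_segments <- c("basal-inferoseptal", "mid-inferoseptal", "apical-septal",
                  "apical-lateral", "mid-anterolateral", "basal-anterolateral")
a2c_segments <- c("basal-inferior", "mid-inferior", "apical-inferior",
                  "apical-anterior", "mid-anterior", "basal-anterior")

#' Segment scheme for regional strain
#'
#' The six wall segments of an apical view, ordered from basal landmark A to
#' basal landmark B along the endocardial trace, with the apical cap excluded
#' (it is never reported as a segment). Boundaries are arc-length fractions of
#' the contour; the default splits the trace into equal sixths, placing the
#' apex at fraction 0.5 between the two apical segments.
#'
#' @param view `"A4C"` or `"A2C"` (regional strain is not defined for A3C
#'   here).
#' @param boundaries 7 strictly increasing arc fractions, first 0 and last 1.
#' @return Object of class `segment_scheme` with fields `view`, `names`,
#'   `boundaries`.
#' @export
segment_scheme <- function(view = c("A4C", "A2C"),
                           boundaries = seq(0, 1, length.out = 7)) {
  view <- match.arg(view)
  boundaries <- as.double(boundaries)
  if (length(boundaries) != 7L || boundaries[1L] != 0 || boundaries[7L] != 1 ||
      any(diff(boundaries) <= 0))
    abort("config_error",
          "boundaries must be 7 strictly increasing fractions from 0 to 1")
  structure(
    list(view = view,
         names = if (view == "A4C") a4c_segments else a2c_segments,
         boundaries = boundaries),
    class = "segment_scheme"
  )
}

# fractional point indices at given cumulative-arc fractions
boundary_positions <- function(pts, fractions) {
  cum <- cum_arc(pts)
  L <- cum[length(cum)]
  s <- fractions * L
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(pts) - 1L] <- nrow(pts) - 1L
  den <- cum[idx + 1L] - cum[idx]
  idx + ifelse(den > 0, (s - cum[idx]) / den, 0)
}

# point at a fractional index (linear between vertices)
point_at_index <- function(pts, fidx) {
  i <- pmin(pmax(floor(fidx), 1), nrow(pts) - 1L)
  t <- fidx - i
  pts[i, , drop = FALSE] + t * (pts[i + 1L, , drop = FALSE] - pts[i, , drop = FALSE])
}

# polyline length (pixels) between two fractional indices of the same polyline
length_between <- function(pts, f0, f1) {
  cum <- cum_arc(pts)
  at <- function(f) {
    i <- min(max(floor(f), 1), nrow(pts) - 1L)
    cum[i] + (f - i) * (cum[i + 1L] - cum[i])
  }
  at(f1) - at(f0)
}

#' Partition a contour into wall segments
#'
#' Splits the endocardial polyline into the six segments of a
#' [segment_scheme()] at exact arc-length fractions, inserting interpolated
#' boundary points so that the six sub-polylines cover the contour without
#' overlap and their lengths sum exactly to the total arc length.
#'
#' @param x an [contour()] object or plain point matrix (A4C/A2C only for
#'   contour input).
#' @param scheme a [segment_scheme()]; its view must match the contour's.
#' @return A list of six elements, each `list(label, points, length)` with
#'   `length` in mm, ordered from basal landmark A to basal landmark B.
#' @export
partition_segments <- function(x, scheme = segment_scheme("A4C")) {
  pts <- as_points(x)
  sp <- spacing_of(x)
  if (inherits(x, "echo_contour")) {
    if (x$view == "A3C")
      abort("unsupported_view", "regional strain is defined for A4C and A2C views only")
    if (x$view != scheme$view)
      abort("unsupported_view", "contour view %s does not match scheme view %s",
            x$view, scheme$view)
  }
  fidx <- boundary_positions(pts, scheme$boundaries)
  out <- vector("list", 6L)
  for (k in seq_len(6L)) {
    f0 <- fidx[k]; f1 <- fidx[k + 1L]
    first <- ceiling(f0 + 1e-12); last <- floor(f1 - 1e-12)
    inner <- if (last >= first) pts[seq(first, last), , drop = FALSE] else
      matrix(numeric(0), 0, 2)
    seg_pts <- rbind(point_at_index(pts, f0), inner, point_at_index(pts, f1))
    # drop duplicated endpoints when a boundary falls exactly on a vertex
    m <- nrow(seg_pts)
    keep <- c(TRUE, rowSums((seg_pts[-1L, , drop = FALSE] -
                             seg_pts[-m, , drop = FALSE])^2) > 0)
    seg_pts <- seg_pts[keep, , drop = FALSE]
    out[[k]] <- list(label = scheme$names[k], points = seg_pts,
                     length = arc_length(seg_pts) * sp)
  }
  out
}
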