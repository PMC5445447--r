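# Shared planar-geometry helpers. Polygons are n x 2 matrices of (x, y)
# vertices, implicitly closed (last vertex connects back to the first).

#' Signed polygon area (shoelace, raw image coordinates)
#'
#' Positive for a traversal that appears clockwise on screen when y points
#' down (which is mathematically counterclockwise).
#' @param poly n x 2 matrix of vertices.
#' @return Signed area in px^2.
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  0.5 * sum(x * y2 - x2 * y)
}

#' Polygon area (absolute value)
#' @inheritParams polygon_area_signed
#' @return Area in px^2.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon centroid
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Normalize traversal so the shoelace sign is positive (clockwise on screen).
ensure_clockwise <- function(poly) {
  if (polygon_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

#' Wrap angles to (-180, 180] degrees
#' @param a Numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrap180 <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Absolute angular difference in [0, 180] degrees
#' @param a,b Angles in degrees.
#' @return Nonnegative difference, wrap-around aware.
#' @export
angle_diff <- function(a, b) abs(wrap180(a - b))

# atan2 in degrees
atan2d <- function(y, x) atan2(y, x) * 180 / pi

# Convert an angle measured in raw image coordinates (y down) to the
# reporting convention (degrees CCW from +x, y up), and back. The two are
# the same operation (negation) so one helper suffices.
flip_angle_y <- function(a) wrap180(-a)

# --- similarity transforms -------------------------------------------------
# Represented as list(ar, ai, tx, ty): p -> A p + t with
# A = [[ar, -ai], [ai, ar]] (complex multiplication by ar + i*ai).

fit_similarity <- function(src, dst) {
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  ms <- mean(zs); md <- mean(zd)
  zs0 <- zs - ms; zd0 <- zd - md
  denom <- sum(Mod(zs0)^2)
  a <- if (denom < 1e-12) complex(real = 1, imaginary = 0) else sum(Conj(zs0) * zd0) / denom
  t0 <- md - a * ms
  list(ar = Re(a), ai = Im(a), tx = Re(t0), ty = Im(t0))
}

apply_similarity <- function(tr, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  cbind(tr$ar * x - tr$ai * y + tr$tx,
        tr$ai * x + tr$ar * y + tr$ty)
}

invert_similarity <- function(tr) {
  a <- complex(real = tr$ar, imaginary = tr$ai)
  ai <- 1 / a
  t0 <- -ai * complex(real = tr$tx, imaginary = tr$ty)
  list(ar = Re(ai), ai = Im(ai), tx = Re(t0), ty = Im(t0))
}

identity_similarity <- function() list(ar = 1, ai = 0, tx = 0, ty = 0)

# --- rasterized polygon overlap --------------------------------------------

#' Overlap area of two polygons
#'
#' Rasterizes both polygons on a common integer pixel grid and counts pixels
#' covered by both. Accurate to pixel resolution, which matches the blob
#' segmentation the polygons come from.
#' @param a,b Polygons (n x 2 matrices).
#' @return Overlap area in px^2.
#' @export
polygon_overlap_area <- function(a, b) {
  xr <- range(a[, 1], b[, 1]); yr <- range(a[, 2], b[, 2])
  # disjoint bounding boxes: no overlap
  if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) return(0)
  ox <- floor(xr[1]) - 1; oy <- floor(yr[1]) - 1
  W <- ceiling(xr[2]) - ox + 1; H <- ceiling(yr[2]) - oy + 1
  sa <- cbind(a[, 1] - ox, a[, 2] - oy)
  sb <- cbind(b[, 1] - ox, b[, 2] - oy)
  ma <- fill_polygon_cpp(sa, H, W)
  mb <- fill_polygon_cpp(sb, H, W)
  sum(ma & mb)
}

# shape vector packing: n x 2 contour <-> (x1, y1, ..., xn, yn)
contour_to_vec <- function(contour) as.vector(t(contour))
vec_to_contour <- function(v) matrix(v, ncol = 2, byrow = TRUE)

# seeded evaluation without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}
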