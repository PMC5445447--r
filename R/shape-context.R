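# Contour resampling and inner-distance shape-context descriptors.
#
# Shapes are closed polygons stored as n x 2 matrices of (x, y) points.
# Descriptors use the inner distance (shortest path inside the silhouette)
# and the inner angle (direction of that path relative to the local boundary
# tangent), which makes them insensitive to spine articulation and in-plane
# rotation -- both essential for matching bent mouse silhouettes against a
# straight reference.

#' Resample a closed boundary to n equidistant points
#'
#' Points are placed at equal arc-length spacing along the closed chain,
#' preserving the input starting point.
#'
#' @param boundary m x 2 matrix, closed pixel chain (closure implicit).
#' @param n Number of output points (at least 8).
#' @return n x 2 matrix of resampled points.
#' @export
resample_contour <- function(boundary, n = 100) {
  if (n < 8) stop("n must be at least 8")
  m <- nrow(boundary)
  if (is.null(m) || m < 3) stop("boundary must have at least 3 points")
  closed <- rbind(boundary, boundary[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[m + 1]
  if (L <= 0) stop("degenerate boundary with zero length")
  targets <- (seq_len(n) - 1) * L / n
  xs <- approx(cum, closed[, 1], xout = targets, rule = 2)$y
  ys <- approx(cum, closed[, 2], xout = targets, rule = 2)$y
  cbind(xs, ys, deparse.level = 0)
}

#' Inner distances and inner angles of a simple polygon
#'
#' The inner distance between two boundary points is the length of the
#' shortest path connecting them that stays inside the silhouette, computed
#' over the visibility graph of the polygon vertices with Floyd-Warshall.
#' The inner angle at point i towards j is the angle between the boundary
#' tangent at i and the initial direction of that shortest path, wrapped to
#' (-180, 180] degrees.
#'
#' @param contour n x 2 simple polygon (e.g. from [resample_contour()]).
#' @return List with `dist` (n x n, symmetric, zero diagonal) and `angle`
#'   (n x n degrees; diagonal 0 by convention).
#' @export
inner_geometry <- function(contour) {
  n <- nrow(contour)
  if (!is_simple_polygon_cpp(contour)) stop("polygon is self-intersecting")
  ig <- inner_geometry_cpp(contour)
  d <- ig$dist
  nxt <- ig$`next`
  if (any(!is.finite(d))) stop("polygon interior is disconnected (degenerate contour)")
  # tangent at each vertex: central difference along the closed contour
  nb_prev <- c(n, seq_len(n - 1))
  nb_next <- c(2:n, 1)
  tx <- contour[nb_next, 1] - contour[nb_prev, 1]
  ty <- contour[nb_next, 2] - contour[nb_prev, 2]
  tang <- atan2d(ty, tx)                      # raw image coords; consistent
  # first-step direction of shortest path i -> j
  step_x <- matrix(contour[nxt, 1], n, n) - contour[, 1]
  step_y <- matrix(contour[nxt, 2], n, n) - contour[, 2]
  ang <- wrap180(atan2d(step_y, step_x) - tang)
  diag(ang) <- 0
  list(dist = d, angle = ang)
}

#' Log-polar inner-distance shape context
#'
#' For each contour point, a 2-D histogram of all other points over
#' `n_r` log-spaced radial bins (inner distance, normalized by the mean
#' inner distance for scale invariance) times `n_theta` angular bins (inner
#' angle relative to the tangent, for rotation invariance). Radial values
#' outside the bin range are clamped into the end bins so every histogram
#' sums to n - 1.
#'
#' @param contour n x 2 simple polygon.
#' @param n_r,n_theta Number of radial / angular bins (defaults 5 and 12).
#' @param r_inner,r_outer Radial bin range as multiples of the mean inner
#'   distance.
#' @param geom Optional precomputed [inner_geometry()] result.
#' @return Object of class `shape_descriptor`: list with `hist`
#'   (n x (n_r * n_theta) integer matrix), the bin edges, `dist`, `angle`
#'   and the contour.
#' @export
shape_context <- function(contour, n_r = 5, n_theta = 12,
                          r_inner = 0.125, r_outer = 2, geom = NULL) {
  n <- nrow(contour)
  if (is.null(geom)) geom <- inner_geometry(contour)
  mean_d <- mean(geom$dist[upper.tri(geom$dist)])
  r_edges <- exp(seq(log(r_inner), log(r_outer), length.out = n_r + 1))
  rnorm_d <- geom$dist / mean_d
  # radial bin with clamping into end bins
  rbin <- matrix(findInterval(rnorm_d, r_edges), n, n)
  rbin[rbin < 1] <- 1L
  rbin[rbin > n_r] <- n_r
  # angular bin over (-180, 180]
  tbin <- ceiling((geom$angle + 180) / (360 / n_theta))
  tbin[tbin < 1] <- 1L
  tbin[tbin > n_theta] <- n_theta
  k <- (rbin - 1L) * n_theta + tbin          # combined bin index, 1..n_r*n_theta
  K <- n_r * n_theta
  h <- matrix(0L, n, K)
  off_diag <- !diag(TRUE, n)
  for (i in seq_len(n)) {
    h[i, ] <- tabulate(k[i, ][off_diag[i, ]], nbins = K)
  }
  structure(list(hist = h, n = n, n_r = n_r, n_theta = n_theta,
                 r_edges = r_edges, mean_dist = mean_d,
                 dist = geom$dist, angle = geom$angle, contour = contour),
            class = "shape_descriptor")
}

#' Chi-squared matching cost between two histograms
#'
#' `C = 1/2 * sum_k (h_i(k) - h_j(k))^2 / (h_i(k) + h_j(k))`, empty bins
#' contributing zero. Symmetric, nonnegative, zero iff the histograms agree.
#'
#' @param h_i,h_j Integer histogram vectors of equal length.
#' @return Scalar cost.
#' @export
chi2_cost <- function(h_i, h_j) {
  stopifnot(length(h_i) == length(h_j))
  s <- h_i + h_j
  nz <- s > 0
  0.5 * sum((h_i[nz] - h_j[nz])^2 / s[nz])
}

# full pairwise cost matrix between two descriptors (rows of A vs rows of B)
chi2_cost_matrix <- function(A, B) {
  ha <- A$hist; hb <- B$hist
  stopifnot(ncol(ha) == ncol(hb))
  n <- nrow(ha); m <- nrow(hb)
  C <- matrix(0, n, m)
  for (k in seq_len(ncol(ha))) {
    ak <- ha[, k]; bk <- hb[, k]
    S <- outer(ak, bk, "+")
    D <- outer(ak, bk, "-")
    term <- D^2 / S
    term[S == 0] <- 0
    C <- C + term
  }
  0.5 * C
}

#' Optimal correspondence between two shape descriptors
#'
#' Minimizes the total chi-squared cost over all bijections between the two
#' point sets (dense linear assignment, solved exactly by a shortest
#' augmenting path algorithm).
#'
#' @param A,B `shape_descriptor` objects with the same point count.
#' @return Object of class `shape_match`: list with `perm` (point i of A
#'   corresponds to point `perm[i]` of B), total cost `H`, and the per-pair
#'   costs `pair_costs`.
#' @export
match_shapes <- function(A, B) {
  if (A$n != B$n) stop("descriptors have different point counts")
  C <- chi2_cost_matrix(A, B)
  perm <- assignment_cpp(C)
  pc <- C[cbind(seq_len(A$n), perm)]
  structure(list(perm = perm, H = sum(pc), pair_costs = pc),
            class = "shape_match")
}
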