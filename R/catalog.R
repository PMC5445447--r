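# Runtime shape catalog: matching blob contours to the reference, landmark
# transfer with nose/tail disambiguation, viewing direction, the rho_max
# acceptance gate, and vertical alignment for shape-model training.

#' Match a contour to the reference shape and transfer landmarks
#'
#' Computes the optimal correspondence between a resampled blob contour and
#' the reference, then reads off nose, tail-base and ear positions. Because
#' a mouse silhouette is nearly fore-aft symmetric, nose and tail base are
#' easily swapped; the match is therefore disambiguated against the tail
#' base found by tail morphology (`tail_hint`) or, when the tail is not
#' localizable, against the body-axis orientation of the previous frame.
#'
#' @param contour n x 2 resampled blob contour (tail removed).
#' @param ref [reference_shape()].
#' @param tail_hint Length-2 (x, y) tail-base estimate, or `NULL`.
#' @param prev_orientation Previous body-axis angle (tail to nose, degrees in
#'   the reporting convention), or `NULL`. One of the two hints is required.
#' @return List: `landmarks` (named list of (x, y) points), `corresponded`
#'   (the contour re-ordered into reference indexing), `H` (total match
#'   cost), `perm`, `flipped` (whether the reversed-traversal match was
#'   chosen), `phi` (viewing direction, degrees).
#' @export
match_to_reference <- function(contour, ref, tail_hint = NULL,
                               prev_orientation = NULL) {
  if (is.null(tail_hint) && is.null(prev_orientation))
    stop("need a tail hint or a previous orientation to disambiguate nose and tail")
  primary <- match_one(contour, ref)
  pick_reversed <- FALSE
  if (!is.null(tail_hint)) {
    d_tail <- sqrt(sum((primary$landmarks$tail_base - tail_hint)^2))
    d_nose <- sqrt(sum((primary$landmarks$nose - tail_hint)^2))
    if (d_tail > d_nose) pick_reversed <- TRUE
  } else {
    a1 <- body_axis_angle(primary$landmarks)
    if (angle_diff(a1, prev_orientation) > 90) pick_reversed <- TRUE
  }
  res <- primary
  if (pick_reversed) {
    n <- nrow(contour)
    rev_contour <- contour[c(1L, rev(seq_len(n))[-n]), , drop = FALSE]
    reversed <- match_one(rev_contour, ref)
    # keep whichever orientation actually satisfies the hint
    if (!is.null(tail_hint)) {
      d_tail_r <- sqrt(sum((reversed$landmarks$tail_base - tail_hint)^2))
      d_nose_r <- sqrt(sum((reversed$landmarks$nose - tail_hint)^2))
      if (d_tail_r <= d_nose_r) res <- c(reversed, flipped = TRUE)
    } else {
      a2 <- body_axis_angle(reversed$landmarks)
      if (angle_diff(a2, prev_orientation) <
          angle_diff(body_axis_angle(primary$landmarks), prev_orientation))
        res <- c(reversed, flipped = TRUE)
    }
  }
  if (is.null(res$flipped)) res$flipped <- FALSE
  res$phi <- viewing_direction(res$landmarks$nose, res$landmarks$ear_left,
                               res$landmarks$ear_right, y_down = TRUE)
  res
}

# single unconstrained match of a contour against the reference
match_one <- function(contour, ref) {
  desc <- shape_context(contour, n_r = ref$n_r, n_theta = ref$n_theta)
  m <- match_shapes(ref$descriptor, desc)
  sm <- smooth_correspondence(m$perm, window = 8)
  corresponded <- contour[sm, , drop = FALSE]
  lm <- lapply(ref$landmarks, function(i) unname(corresponded[i, ]))
  list(landmarks = lm, corresponded = corresponded, H = m$H, perm = m$perm,
       perm_smooth = sm)
}

#' Smooth an optimal assignment into an order-consistent correspondence
#'
#' The unrestricted optimal assignment occasionally sends individual points
#' of featureless boundary stretches (e.g. the blunt rear of the body) far
#' from their neighbours. Because a plausible contour correspondence is a
#' slowly varying cyclic shift, the per-point index shifts are smoothed by a
#' windowed circular mean, which suppresses such outliers while leaving a
#' globally shifted (rigidly transformed) match exactly unchanged.
#'
#' @param perm Permutation from [match_shapes()].
#' @param window Half-width of the circular smoothing window (in contour
#'   positions).
#' @return Integer vector: smoothed corresponding index for every point.
#' @export
smooth_correspondence <- function(perm, window = 8) {
  n <- length(perm)
  sh <- (perm - seq_len(n)) %% n
  z <- exp(2i * pi * sh / n)
  out <- integer(n)
  for (i in seq_len(n)) {
    idx <- ((i - 1 + (-window:window)) %% n) + 1
    s <- Arg(mean(z[idx])) * n / (2 * pi)
    out[i] <- ((i - 1 + round(s)) %% n) + 1
  }
  out
}

# body-axis angle tail -> nose in the reporting convention (y up)
body_axis_angle <- function(landmarks) {
  v <- landmarks$nose - landmarks$tail_base
  flip_angle_y(atan2d(v[2], v[1]))
}

#' Viewing direction from head landmarks
#'
#' Direction of the vector from the midpoint between the two ears to the
#' nose, in degrees CCW from +x. With `y_down = TRUE` the inputs are taken
#' as image coordinates (y down) and the angle is reported in the package's
#' y-up convention.
#'
#' @param nose,ear_left,ear_right Length-2 (x, y) points.
#' @param y_down Whether inputs are in image (y-down) coordinates.
#' @return Angle phi in degrees, in [0, 360).
#' @export
viewing_direction <- function(nose, ear_left, ear_right, y_down = FALSE) {
  if (all(ear_left == ear_right)) stop("ear positions must be distinct")
  mid <- (ear_left + ear_right) / 2
  v <- nose - mid
  if (sqrt(sum(v^2)) < 1e-9) stop("nose coincides with the ear midpoint")
  dy <- if (y_down) -v[2] else v[2]
  unname(atan2d(dy, v[1]) %% 360)
}

#' Gate a matched shape and align it vertically
#'
#' A matched contour enters the catalog only if its total matching cost is
#' strictly below `rho_max` (mismatches tend to have high costs). Accepted
#' contours are rotated about their centroid so the tail-to-nose axis lies
#' on the vertical image axis with the nose pointing downwards, then
#' translated so the nose/tail midpoint sits at the origin. This removes
#' whole-body rotation from the learned shape variation.
#'
#' @param corresponded n x 2 contour in reference indexing.
#' @param landmark_idx Named list of landmark indices (from the reference).
#' @param H Total matching cost of this contour.
#' @param rho_max Acceptance threshold.
#' @return The aligned n x 2 contour, or `NULL` when rejected.
#' @export
gate_and_align <- function(corresponded, landmark_idx, H, rho_max) {
  if (!(H < rho_max)) return(NULL)
  align_vertical(corresponded, landmark_idx)
}

# rotate about centroid so tail -> nose points along +y (down in image),
# then translate the nose/tail midpoint to the origin
align_vertical <- function(contour, landmark_idx) {
  nose <- contour[landmark_idx$nose, ]
  tail <- contour[landmark_idx$tail_base, ]
  v <- nose - tail
  rot <- (pi / 2) - atan2(v[2], v[1])          # raw coords; +y is image-down
  ctr <- polygon_centroid(contour)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  out <- sweep(contour, 2, ctr) %*% t(R)
  out <- sweep(out, 2, ctr, FUN = "+")
  mid <- (out[landmark_idx$nose, ] + out[landmark_idx$tail_base, ]) / 2
  sweep(out, 2, mid)
}

#' Calibrate the acceptance threshold from a warm-up cost sample
#'
#' Chooses `rho_max` so that a fraction `c_v` of the observed matching costs
#' falls strictly below it (the catalog acceptance ratio). A ratio around
#' 0.5 trades shape-variability coverage against correspondence
#' plausibility.
#'
#' @param costs Numeric vector of total matching costs (at least 10).
#' @param c_v Target acceptance ratio in (0, 1).
#' @return The threshold `rho_max`.
#' @export
calibrate_rho <- function(costs, c_v) {
  stopifnot(length(costs) >= 10, c_v > 0, c_v < 1)
  s <- sort(costs)
  N <- length(s)
  k <- round(c_v * N)
  if (k <= 0) return(s[1])                       # nothing strictly below
  if (k >= N) return(s[N] + max(1e-9, abs(s[N]) * 1e-9))
  (s[k] + s[k + 1]) / 2
}

# --- catalog container ------------------------------------------------------

#' Create an empty shape catalog
#'
#' Stores vertically aligned, landmark-corresponded contours accepted under
#' `rho_max`, each paired with its source frame index and an image patch for
#' grey-profile training. Capped at `max_entries` with seeded reservoir
#' thinning to bound model-training cost on long videos.
#'
#' @param ref [reference_shape()] whose indexing the entries share.
#' @param max_entries Catalog size cap.
#' @return Object of class `shape_catalog`.
#' @export
new_catalog <- function(ref, max_entries = 3000) {
  structure(list(ref = ref, entries = list(), n_seen = 0L,
                 max_entries = max_entries),
            class = "shape_catalog")
}

#' Add an accepted shape to the catalog
#'
#' @param catalog `shape_catalog`.
#' @param aligned Vertically aligned contour (from [gate_and_align()]).
#' @param corresponded Contour in image coordinates, reference indexing.
#' @param H Matching cost.
#' @param frame Source frame index.
#' @param patch List with `img` (numeric matrix) and `offset` (x, y offset
#'   such that image coordinates = patch coordinates + offset), or `NULL`.
#' @return Updated catalog.
#' @export
catalog_add <- function(catalog, aligned, corresponded, H, frame, patch = NULL) {
  entry <- list(aligned = aligned, corresponded = corresponded,
                H = H, frame = frame, patch = patch)
  catalog$n_seen <- catalog$n_seen + 1L
  if (length(catalog$entries) < catalog$max_entries) {
    catalog$entries[[length(catalog$entries) + 1L]] <- entry
  } else {
    # reservoir replacement keeps a uniform subsample of everything seen
    j <- sample.int(catalog$n_seen, 1L)
    if (j <= catalog$max_entries) catalog$entries[[j]] <- entry
  }
  catalog
}

#' @export
length.shape_catalog <- function(x) length(x$entries)

#' @export
print.shape_catalog <- function(x, ...) {
  cat(sprintf("<shape_catalog> %d entries (of %d accepted), n = %d points\n",
              length(x$entries), x$n_seen, x$ref$n))
  invisible(x)
}
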