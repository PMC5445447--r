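# The one-time user-annotated reference shape: a resampled contour with
# nose, tail-base and ear landmark indices. All runtime shapes are put into
# correspondence with this reference, which freezes landmark indices across
# the whole catalog.

#' Create a reference shape
#'
#' The contour is cyclically re-indexed so that the nose is point 1; all
#' landmark indices are adjusted accordingly. Landmark correspondence of
#' every later catalog entry is expressed in this fixed indexing.
#'
#' @param contour n x 2 closed polygon (resampled blob boundary).
#' @param nose,tail_base,ear_left,ear_right Landmark indices into the
#'   contour (1-based, distinct).
#' @param n_r,n_theta Shape-context bin counts used when matching against
#'   this reference.
#' @return Object of class `reference_shape`.
#' @export
reference_shape <- function(contour, nose, tail_base, ear_left, ear_right,
                            n_r = 5, n_theta = 12) {
  n <- nrow(contour)
  idx <- c(nose = nose, tail_base = tail_base,
           ear_left = ear_left, ear_right = ear_right)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > n))
    stop("landmark indices must be distinct and within [1, n]")
  shift <- nose - 1L
  ord <- ((seq_len(n) - 1L + shift) %% n) + 1L      # new i <- old ord[i]
  contour <- contour[ord, , drop = FALSE]
  idx <- ((idx - 1L - shift) %% n) + 1L
  desc <- shape_context(contour, n_r = n_r, n_theta = n_theta)
  structure(list(contour = contour, landmarks = as.list(idx),
                 n = n, n_r = n_r, n_theta = n_theta, descriptor = desc),
            class = "reference_shape")
}

#' Build a reference shape from clicked landmark positions
#'
#' Convenience for annotation front-ends: maps user-clicked pixel positions
#' to the nearest contour points.
#'
#' @param contour n x 2 polygon.
#' @param nose_xy,tail_xy,ear_left_xy,ear_right_xy Length-2 (x, y) positions.
#' @inheritParams reference_shape
#' @return `reference_shape` object.
#' @export
reference_from_points <- function(contour, nose_xy, tail_xy,
                                  ear_left_xy, ear_right_xy,
                                  n_r = 5, n_theta = 12) {
  nearest <- function(p) {
    which.min((contour[, 1] - p[1])^2 + (contour[, 2] - p[2])^2)
  }
  reference_shape(contour, nearest(nose_xy), nearest(tail_xy),
                  nearest(ear_left_xy), nearest(ear_right_xy),
                  n_r = n_r, n_theta = n_theta)
}

#' Write / read a reference shape as JSON
#' @param ref `reference_shape` object.
#' @param path File path.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns the `reference_shape`.
#' @export
write_reference <- function(ref, path) {
  obj <- list(contour = unname(ref$contour),
              landmarks = ref$landmarks,
              n_r = ref$n_r, n_theta = ref$n_theta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_shape(as.matrix(obj$contour),
                  nose = obj$landmarks$nose,
                  tail_base = obj$landmarks$tail_base,
                  ear_left = obj$landmarks$ear_left,
                  ear_right = obj$landmarks$ear_right,
                  n_r = obj$n_r, n_theta = obj$n_theta)
}
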