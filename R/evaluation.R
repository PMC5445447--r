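# Validation metrics against ground truth: landmark distances, angular
# deviation, the mean tracking error, and precision curves.

# per-frame identity resolution: map predicted animals onto true animals by
# minimal total nose distance (identity switches are corrected before
# precision evaluation)
resolve_identities <- function(track, truth) {
  frames <- sort(intersect(unique(track$frame), unique(truth$frame)))
  skipped <- 0L
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    tr <- track[track$frame == f, ]
    gt <- truth[truth$frame == f, ]
    if (nrow(tr) != 2 || nrow(gt) != 2 ||
        any(!is.finite(c(tr$nose_x, tr$nose_y)))) {
      skipped <- skipped + 1L
      next
    }
    d <- function(a, b) sqrt((tr$nose_x[a] - gt$nose_x[b])^2 +
                               (tr$nose_y[a] - gt$nose_y[b])^2)
    map <- if (d(1, 1) + d(2, 2) <= d(1, 2) + d(2, 1)) c(1L, 2L) else c(2L, 1L)
    out[[i]] <- tibble::tibble(frame = f, animal_id = gt$animal_id, tr_i = map)
  }
  list(map = dplyr::bind_rows(out), skipped = skipped)
}

#' Per-frame landmark and angle errors against ground truth
#'
#' Euclidean nose and tail-base distances and the wrapped absolute viewing
#' angle deviation, per labeled frame per animal, after per-frame identity
#' resolution. Frames missing from either table are skipped (count reported
#' via a message).
#'
#' @param track Track tibble from [track_video()].
#' @param truth Ground-truth tibble (`frame`, `animal_id`, `nose_x/y`,
#'   `tail_x/y`, `phi_deg`).
#' @return Tibble: `frame`, `animal_id` (ground-truth identity), `d_nose`,
#'   `d_tail`, `d_phi`.
#' @export
landmark_errors <- function(track, truth) {
  res <- resolve_identities(track, truth)
  if (res$skipped > 0)
    message(res$skipped, " frame(s) skipped (missing or incomplete)")
  map <- res$map
  out <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    f <- map$frame[i]
    tr <- track[track$frame == f, ][map$tr_i[i], ]
    gt <- truth[truth$frame == f & truth$animal_id == map$animal_id[i], ]
    out[[i]] <- tibble::tibble(
      frame = f, animal_id = map$animal_id[i],
      d_nose = sqrt((tr$nose_x - gt$nose_x)^2 + (tr$nose_y - gt$nose_y)^2),
      d_tail = sqrt((tr$tail_x - gt$tail_x)^2 + (tr$tail_y - gt$tail_y)^2),
      d_phi = angle_diff(tr$phi_deg, gt$phi_deg))
  }
  dplyr::bind_rows(out)
}

#' Absolute angular deviation, wrap-around aware
#'
#' @param phi_est,phi_gt Angles in degrees.
#' @return Deviation in `[0, 180]` degrees.
#' @export
angle_error <- function(phi_est, phi_gt) angle_diff(phi_est, phi_gt)

#' Mean tracking error over nose and tail landmarks
#'
#' The per-frame average of nose and tail deviations, averaged over frames:
#' `epsilon = mean over f of (d_nose_f + d_tail_f) / 2`. With
#' `literal_sum = TRUE` the per-frame contributions are summed instead of
#' averaged (no 1/N), which grows with the number of frames and is kept
#' only for comparison.
#'
#' @param d_nose,d_tail Per-frame landmark distances (same length).
#' @param literal_sum Use the unnormalized sum.
#' @return Scalar error (px).
#' @export
mean_error <- function(d_nose, d_tail, literal_sum = FALSE) {
  stopifnot(length(d_nose) == length(d_tail))
  if (!length(d_nose)) stop("no errors supplied")
  if (literal_sum) return(0.5 * sum(d_nose + d_tail))
  mean((d_nose + d_tail) / 2)
}

#' Precision curve: fraction of frames below each error threshold
#'
#' @param errors Per-frame error values.
#' @param thresholds Threshold grid.
#' @return Tibble of class `precision_curve`: `threshold`, `fraction`
#'   (monotone non-decreasing, 1 at +Inf).
#' @export
precision_curve <- function(errors, thresholds) {
  errors <- errors[is.finite(errors)]
  frac <- vapply(thresholds, function(t) mean(errors <= t), numeric(1))
  structure(tibble::tibble(threshold = thresholds, fraction = frac),
            class = c("precision_curve", class(tibble::tibble())))
}

#' Summarize tracking accuracy against ground truth
#'
#' @param track Track tibble.
#' @param truth Ground-truth tibble.
#' @param literal_sum Passed to [mean_error()].
#' @return One-row tibble: `epsilon`, `mean_d_nose`, `mean_d_tail`,
#'   `mean_d_phi`, `n_frames`, `identity_switches`.
#' @export
evaluate_tracking <- function(track, truth, literal_sum = FALSE) {
  err <- landmark_errors(track, truth)
  tibble::tibble(
    epsilon = mean_error(err$d_nose, err$d_tail, literal_sum),
    mean_d_nose = mean(err$d_nose),
    mean_d_tail = mean(err$d_tail),
    mean_d_phi = mean(err$d_phi, na.rm = TRUE),
    n_frames = length(unique(err$frame)),
    identity_switches = count_identity_switches(track, truth))
}
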