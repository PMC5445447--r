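# Behavior classification: social conditions C1-C5 from positional/angular
# trajectories, self-grooming C6 from shape-model coefficients, and
# aggregation of per-frame flags into events.

# spread the long track tibble into one row per frame with _A/_B columns
track_wide <- function(track) {
  stopifnot(all(c("frame", "animal_id") %in% names(track)))
  a <- track[track$animal_id == "A", ]
  b <- track[track$animal_id == "B", ]
  keep <- c("frame", "regime", "nose_x", "nose_y", "tail_x", "tail_y",
            "phi_deg", "overlap_frac")
  keep_a <- intersect(keep, names(a))
  out <- dplyr::inner_join(
    dplyr::select(a, dplyr::all_of(keep_a)),
    dplyr::select(b, dplyr::all_of(setdiff(keep_a, "regime"))),
    by = "frame", suffix = c("_A", "_B"))
  out
}

#' Classify social conditions C1-C5 per frame
#'
#' Predicates on the two trajectories, with distances in body-length units
#' (body length = median nose-to-tail distance over separated frames):
#' C1 nose-nose contact; C2 nose-to-anogenital contact (directional);
#' C3 side-by-side (close body centers, parallel or antiparallel headings);
#' C4 following (nose behind the other's tail base with aligned headings,
#' sustained); C5 mating posture (large silhouette overlap with aligned
#' headings, mounting animal behind). Conditions are not mutually exclusive;
#' lost frames assert nothing.
#'
#' @param track Track tibble from [track_video()] or a ground-truth table
#'   with the same columns (`frame`, `animal_id`, `nose_x/y`, `tail_x/y`,
#'   `phi_deg`, optionally `overlap_frac`, `regime`).
#' @param config Configuration list ([default_config()]); uses the
#'   `behavior` section and `fps`.
#' @return Tibble, one row per frame: logical columns `c1`, `c2_A`, `c2_B`,
#'   `c3`, `c4_A`, `c4_B`, `c5_A`, `c5_B` (suffix = acting animal: `c2_A`
#'   means A's nose at B's anogenital region, `c4_A` means A follows B,
#'   `c5_A` means A mounts B).
#' @export
classify_social <- function(track, config = default_config()) {
  bh <- config$behavior
  w <- track_wide(track)
  sep <- if ("regime" %in% names(w)) w$regime == "separated" else rep(TRUE, nrow(w))
  bl_frames <- c(
    sqrt((w$nose_x_A - w$tail_x_A)^2 + (w$nose_y_A - w$tail_y_A)^2)[sep],
    sqrt((w$nose_x_B - w$tail_x_B)^2 + (w$nose_y_B - w$tail_y_B)^2)[sep])
  BL <- median(bl_frames, na.rm = TRUE)
  if (!is.finite(BL) || BL <= 0) stop("cannot estimate body length from the track")

  d <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
  cAx <- (w$nose_x_A + w$tail_x_A) / 2; cAy <- (w$nose_y_A + w$tail_y_A) / 2
  cBx <- (w$nose_x_B + w$tail_x_B) / 2; cBy <- (w$nose_y_B + w$tail_y_B) / 2
  dh <- angle_diff(w$phi_deg_A, w$phi_deg_B)
  ok <- is.finite(w$nose_x_A) & is.finite(w$nose_x_B) & is.finite(dh)
  if ("regime" %in% names(w)) ok <- ok & w$regime != "lost"

  c1 <- ok & d(w$nose_x_A, w$nose_y_A, w$nose_x_B, w$nose_y_B) < bh$c1_dist * BL
  c2_A <- ok & d(w$nose_x_A, w$nose_y_A, w$tail_x_B, w$tail_y_B) < bh$c2_dist * BL
  c2_B <- ok & d(w$nose_x_B, w$nose_y_B, w$tail_x_A, w$tail_y_A) < bh$c2_dist * BL
  c3 <- ok & d(cAx, cAy, cBx, cBy) < bh$c3_dist * BL &
    (dh < bh$c3_angle | dh > 180 - bh$c3_angle)
  sustain <- max(1L, round(bh$c4_sustain_s * config$fps))
  c4_A_raw <- ok & d(w$nose_x_A, w$nose_y_A, w$tail_x_B, w$tail_y_B) <
    bh$c4_dist * BL & dh < bh$c4_angle
  c4_B_raw <- ok & d(w$nose_x_B, w$nose_y_B, w$tail_x_A, w$tail_y_A) <
    bh$c4_dist * BL & dh < bh$c4_angle
  c4_A <- keep_sustained(c4_A_raw, sustain)
  c4_B <- keep_sustained(c4_B_raw, sustain)
  ovf <- if ("overlap_frac" %in% names(track)) {
    track$overlap_frac[track$animal_id == "A"][match(w$frame,
      track$frame[track$animal_id == "A"])]
  } else rep(0, nrow(w))
  c5_core <- ok & is.finite(ovf) & ovf > bh$c5_overlap & dh < bh$c5_angle
  # the mounting animal sits behind the other relative to its heading
  hB <- w$phi_deg_B * pi / 180
  behindB <- ((cAx - cBx) * cos(hB) + (cAy - cBy) * -sin(hB)) < 0
  hA <- w$phi_deg_A * pi / 180
  behindA <- ((cBx - cAx) * cos(hA) + (cBy - cAy) * -sin(hA)) < 0
  c5_A <- c5_core & behindB
  c5_B <- c5_core & behindA

  tibble::tibble(frame = w$frame, c1 = c1, c2_A = c2_A, c2_B = c2_B,
                 c3 = c3, c4_A = c4_A, c4_B = c4_B,
                 c5_A = c5_A, c5_B = c5_B, body_length = BL)
}

# keep only frames belonging to runs of at least `sustain` consecutive TRUEs
keep_sustained <- function(flags, sustain) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  r$values <- r$values & r$lengths >= sustain
  inverse.rle(r)
}

#' Aggregate per-frame flags into behavior events
#'
#' Majority-vote smoothing over a sliding window, then maximal runs of
#' active frames; runs shorter than the minimum duration are dropped.
#' Idempotent on its own output flags.
#'
#' @param flags Logical vector, one entry per frame.
#' @param fps Frames per second (converts durations to seconds).
#' @param min_duration_s Minimum event duration in seconds.
#' @param smooth_window Odd window length in frames for the majority vote
#'   (1 disables smoothing).
#' @param condition,animal Labels copied into the output.
#' @param frames Optional frame numbers (defaults to `seq_along(flags)`).
#' @return Tibble of events: `condition`, `animal`, `start_frame`,
#'   `end_frame`, `duration_s`.
#' @export
frames_to_events <- function(flags, fps = 25, min_duration_s = 0,
                             smooth_window = 1L, condition = NA_character_,
                             animal = NA_character_, frames = NULL) {
  flags[is.na(flags)] <- FALSE
  n <- length(flags)
  if (is.null(frames)) frames <- seq_len(n)
  if (smooth_window > 1) {
    half <- smooth_window %/% 2
    padded <- c(rep(flags[1], half), flags, rep(flags[n], half))
    sm <- vapply(seq_len(n), function(i) {
      sum(padded[i:(i + 2 * half)]) > half
    }, logical(1))
    flags <- sm
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths / fps >= min_duration_s)
  tibble::tibble(
    condition = condition, animal = animal,
    start_frame = frames[starts[keep]], end_frame = frames[ends[keep]],
    duration_s = r$lengths[keep] / fps)
}

#' All behavior events of a session
#'
#' Runs [classify_social()] and [frames_to_events()] for every condition
#' and acting animal.
#'
#' @inheritParams classify_social
#' @return Tibble of events across conditions.
#' @export
behavior_events <- function(track, config = default_config()) {
  fl <- classify_social(track, config)
  bh <- config$behavior
  specs <- list(
    list("C1", "A+B", fl$c1), list("C2", "A", fl$c2_A), list("C2", "B", fl$c2_B),
    list("C3", "A+B", fl$c3), list("C4", "A", fl$c4_A), list("C4", "B", fl$c4_B),
    list("C5", "A", fl$c5_A), list("C5", "B", fl$c5_B))
  dplyr::bind_rows(lapply(specs, function(s) {
    frames_to_events(s[[3]], fps = config$fps,
                     min_duration_s = bh$min_duration_s,
                     smooth_window = bh$smooth_window,
                     condition = s[[1]], animal = s[[2]], frames = fl$frame)
  }))
}

#' Relative duration estimation error
#'
#' `E = |T_est - T_gt| / T_gt`. A condition that truly occurred but was
#' never detected gives E = 1. A detection with zero true duration is
#' undefined and returned as `NA` with a warning (reported separately by
#' callers).
#'
#' @param T_est,T_gt Estimated and ground-truth durations (same units).
#' @return Relative absolute error.
#' @export
duration_error <- function(T_est, T_gt) {
  stopifnot(T_gt >= 0, T_est >= 0)
  if (T_gt == 0) {
    if (T_est == 0) return(0)
    warning("true duration is zero with a nonzero estimate; error undefined")
    return(NA_real_)
  }
  abs(T_est - T_gt) / T_gt
}

#' Detect self-grooming from shape-model coefficients
#'
#' Class-weighted RBF-kernel support-vector machine on the ASM coefficient
#' vectors (a stooped grooming posture compresses the body, which shows up
#' in the low-order modes). Validation is interval-wise: each time interval
#' is predicted by a model trained on all remaining intervals.
#'
#' @param features Numeric matrix, one row per frame (ASM coefficients).
#' @param labels Logical vector: grooming or not.
#' @param intervals Integer/factor vector assigning each frame to a
#'   validation interval.
#' @param seed Seed (SVM training is deterministic; kept for interface
#'   symmetry).
#' @return Tibble: `row`, `interval`, `label`, `pred`.
#' @export
detect_grooming <- function(features, labels, intervals, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            length(intervals) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("grooming labels must contain both classes")
  ok <- stats::complete.cases(features) & !is.na(labels)
  preds <- rep(NA, length(labels))
  with_seed(seed, {
    for (iv in unique(intervals)) {
      test <- ok & intervals == iv
      train <- ok & intervals != iv
      if (!any(test)) next
      ytr <- factor(labels[train], levels = c(FALSE, TRUE))
      if (length(unique(ytr[!is.na(ytr)])) < 2)
        stop("training split for interval ", iv, " contains a single class")
      freq <- table(ytr)
      cw <- as.numeric(sum(freq) / (2 * freq))
      names(cw) <- names(freq)
      fit <- e1071::svm(x = features[train, , drop = FALSE], y = ytr,
                        kernel = "radial", class.weights = cw, scale = TRUE)
      preds[test] <- as.logical(predict(fit, features[test, , drop = FALSE]))
    }
  })
  tibble::tibble(row = seq_along(labels), interval = intervals,
                 label = labels, pred = preds)
}

#' Balanced accuracy of a binary prediction
#' @param pred,truth Logical vectors.
#' @return Mean of sensitivity and specificity.
#' @export
balanced_accuracy <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  (sens + spec) / 2
}
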