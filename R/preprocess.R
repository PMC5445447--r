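# Frame preprocessing: illumination normalization, temporal-median background,
# foreground segmentation, blob extraction and tail localization.

#' Normalize frame illumination
#'
#' Removes temporal illumination inhomogeneities by dividing every pixel by
#' the frame's mean intensity and rescaling to a common target mean, so that
#' global lighting drift cancels out before background subtraction.
#'
#' @param frame Numeric matrix (grayscale image, `img[y, x]`).
#' @param target_mean Intensity every frame is rescaled to (default 128 on a
#'   0--255 scale).
#' @return Matrix with `mean(out) == target_mean` and the spatial pattern
#'   preserved up to a global scale factor.
#' @export
normalize_illumination <- function(frame, target_mean = 128) {
  m <- mean(frame)
  if (!is.finite(m) || m <= 0) stop("degenerate frame: mean intensity is not positive")
  frame * (target_mean / m)
}

#' Build the static background model
#'
#' Pixel-wise temporal median over a sequence of frames. With a static
#' background and animals that occupy each pixel less than half the time,
#' the median recovers the empty arena exactly.
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @return Object of class `background_model`: list with `median_image` and
#'   `n_frames_used`.
#' @export
build_background <- function(frames) {
  if (length(frames) == 0) stop("empty frame sequence")
  if (length(frames) < 3) stop("need at least 3 frames to build a background")
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), dims)) stop("frames must share dimensions")
  }
  arr <- array(unlist(frames, use.names = FALSE), dim = c(dims, length(frames)))
  med <- apply(arr, c(1, 2), median)
  structure(list(median_image = med, n_frames_used = length(frames)),
            class = "background_model")
}

#' Segment foreground blobs from a frame
#'
#' Thresholds the absolute difference between frame and background. The
#' threshold is found automatically by between-class variance maximization
#' (Otsu) on the difference image, or set to a fixed user value when the
#' automatic setting fails for a scene. Working on the absolute difference
#' makes the segmentation polarity-agnostic (dark animals on a bright floor
#' or the reverse).
#'
#' @param frame Normalized frame (numeric matrix).
#' @param bg `background_model` from [build_background()].
#' @param threshold `"auto"` or a fixed numeric intensity threshold.
#' @return Logical matrix, `TRUE` on foreground.
#' @export
segment_foreground <- function(frame, bg, threshold = "auto") {
  d <- abs(frame - bg$median_image)
  if (identical(threshold, "auto")) {
    rng <- range(d)
    if (diff(rng) < 1e-9) return(matrix(FALSE, nrow(d), ncol(d)))
    thr <- EBImage::otsu(EBImage::Image(d / rng[2]), range = c(0, 1), levels = 256) * rng[2]
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
    thr <- threshold
  }
  d > thr
}

#' Extract blobs from a binary mask
#'
#' 8-connected components with area at least `b_min`, sorted by area
#' (largest first). Each blob carries its outer boundary as a closed pixel
#' chain traced clockwise in image coordinates.
#'
#' @param mask Logical matrix.
#' @param b_min Minimum blob area in px^2; smaller components are dropped as
#'   segmentation artifacts.
#' @return List of `blob` objects: `area`, `centroid` (x, y), `boundary`
#'   (m x 2 matrix), `label`, and the label image as attribute-free fields.
#' @export
extract_blobs <- function(mask, b_min = 1) {
  stopifnot(is.logical(mask), b_min >= 1)
  if (!any(mask)) return(list())
  lab <- label_blobs_cpp(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= b_min)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)  # (row, col) = (y, x)
    boundary <- ensure_clockwise(trace_boundary_cpp(lab, k))
    structure(list(
      label = k,
      area = areas[k],
      centroid = c(mean(idx[, 2]), mean(idx[, 1])),
      boundary = boundary,
      mask = lab == k
    ), class = "blob")
  })
}

#' Locate the tail and remove it from a single-animal mask
#'
#' The body is the morphological opening of the mask with a disc of radius
#' `r_S` (chosen to exceed the tail half-width), so the thin tail vanishes.
#' The tail is the set difference mask minus body; the tail base is the
#' center of the intersection between the dilated tail and the body. An
#' absent tail base is a normal outcome (e.g. tail hidden under the body).
#'
#' @param mask Logical matrix containing one blob.
#' @param r_S Disc radius in px of the structural element.
#' @param min_tail_area Minimum tail-component area (px^2) to count as a tail
#'   rather than boundary speckle.
#' @return List with `body_mask` (logical matrix) and `tail_base`
#'   (length-2 numeric (x, y), or `NULL` when no tail is found).
#' @export
locate_tail <- function(mask, r_S = 4, min_tail_area = 10) {
  stopifnot(is.logical(mask), r_S >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(r_S) + 1L, shape = "disc")
  m <- mask * 1
  body <- EBImage::opening(m, brush) > 0.5
  tail <- mask & !body
  if (!any(body)) return(list(body_mask = body, tail_base = NULL))
  if (!any(tail)) return(list(body_mask = body, tail_base = NULL))
  # keep the largest tail component only
  tl <- label_blobs_cpp(tail)
  ta <- tabulate(tl[tl > 0L])
  best <- which.max(ta)
  if (ta[best] < min_tail_area) return(list(body_mask = body, tail_base = NULL))
  tail1 <- tl == best
  dil <- EBImage::dilate(tail1 * 1, brush) > 0.5
  inter <- dil & body
  if (!any(inter)) return(list(body_mask = body, tail_base = NULL))
  idx <- which(inter, arr.ind = TRUE)
  list(body_mask = body, tail_base = c(mean(idx[, 2]), mean(idx[, 1])))
}
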