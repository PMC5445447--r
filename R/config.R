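# Nested pipeline configuration with validated YAML round-tripping.

#' Default pipeline configuration
#'
#' All tunables of the pipeline in one nested list. Sections:
#' \describe{
#'   \item{preprocess}{`b_min` minimum blob area (px^2); `r_S` tail-removal
#'     disc radius (px); `threshold` `"auto"` or fixed intensity;
#'     `target_mean` illumination normalization target.}
#'   \item{match}{`n_points` contour sample count; `n_r`, `n_theta`
#'     log-polar bin counts; `smooth_window` correspondence smoothing.}
#'   \item{catalog}{`rho_max` `"auto"` or a fixed acceptance threshold;
#'     `c_v` target acceptance ratio for auto-calibration; `warmup_n`
#'     number of warm-up match costs; `max_entries` catalog cap.}
#'   \item{asm}{`m` clamp multiplier; `f_v` variance fraction; `N_max`
#'     fit iterations per frame; `profile_k` profile half-length;
#'     `search_l` search half-range; `profile_max` entries used for
#'     profile statistics.}
#'   \item{tracker}{`bg_frames` frames sampled for the background median;
#'     `floor_frac`/`merged_frac` regime-area factors relative to the
#'     median single-animal area; `min_catalog` entries required before
#'     ASM training; `refresh_every` accepted shapes between retrains.}
#'   \item{behavior}{distance thresholds in body-length units and angle
#'     windows for conditions C1--C5; `min_duration_s`, `smooth_window`
#'     (frames), `interval_s` for grooming cross-validation.}
#'   \item{evaluation}{`literal_sum` use the literal (unnormalized) sum in
#'     the mean tracking error instead of mean semantics.}
#' }
#' Plus global `fps` and `seed`.
#'
#' @return Nested configuration list of class `shapetrack_config`.
#' @export
default_config <- function() {
  structure(list(
    fps = 25,
    seed = 1L,
    preprocess = list(b_min = 400, r_S = 4, threshold = "auto",
                      target_mean = 128),
    match = list(n_points = 100L, n_r = 5L, n_theta = 12L, smooth_window = 8L),
    catalog = list(rho_max = "auto", c_v = 0.5, warmup_n = 60L,
                   max_entries = 3000L),
    asm = list(m = 3, f_v = 0.98, N_max = 60L, profile_k = 5L, search_l = 7L,
               profile_max = 300L),
    tracker = list(bg_frames = 61L, floor_frac = 0.4, merged_frac = 1.3,
                   min_catalog = 50L, refresh_every = 500L),
    behavior = list(c1_dist = 0.25, c2_dist = 0.25, c3_dist = 0.6,
                    c3_angle = 30, c4_dist = 0.5, c4_angle = 45,
                    c4_sustain_s = 0.5, c5_overlap = 0.4, c5_angle = 45,
                    min_duration_s = 0.2, smooth_window = 5L,
                    interval_s = 60),
    evaluation = list(literal_sum = FALSE)
  ), class = "shapetrack_config")
}

# recursive merge + validation against the defaults
merge_validate <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    dv <- defaults[[key]]; uv <- user[[key]]
    if (is.list(dv)) {
      if (!is.list(uv)) stop("configuration section ", full, " must be a mapping")
      defaults[[key]] <- merge_validate(dv, uv, c(path, key))
    } else {
      # "auto"-able keys accept a string or a number
      if (is.character(dv) || identical(dv, "auto")) {
        if (!(is.character(uv) || is.numeric(uv)))
          stop("configuration key ", full, " must be a string or number")
      } else if (is.numeric(dv) && !is.numeric(uv)) {
        stop("configuration key ", full, " must be numeric, got ",
             class(uv)[1])
      }
      defaults[[key]] <- uv
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$preprocess$b_min <= 0) stop("preprocess.b_min must be positive")
  if (cfg$preprocess$r_S < 1) stop("preprocess.r_S must be at least 1")
  if (cfg$match$n_points < 8) stop("match.n_points must be at least 8")
  if (!identical(cfg$catalog$rho_max, "auto") && !is.numeric(cfg$catalog$rho_max))
    stop("catalog.rho_max must be 'auto' or numeric")
  if (identical(cfg$catalog$rho_max, "auto") &&
      (cfg$catalog$c_v <= 0 || cfg$catalog$c_v >= 1))
    stop("catalog.c_v must lie in (0, 1)")
  if (is.numeric(cfg$catalog$rho_max) && !is.null(cfg$catalog$c_v_user))
    stop("set either catalog.rho_max or catalog.c_v, not both")
  bh <- cfg$behavior
  if (any(c(bh$c1_dist, bh$c2_dist, bh$c3_dist, bh$c4_dist) <= 0))
    stop("behavior distance thresholds must be positive")
  if (any(c(bh$c3_angle, bh$c4_angle, bh$c5_angle) < 0) ||
      any(c(bh$c3_angle, bh$c4_angle, bh$c5_angle) > 180))
    stop("behavior angle windows must lie in [0, 180] degrees")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML configuration, applies defaults for every missing key,
#' rejects unknown keys and validates values. An empty file yields the full
#' default configuration. Setting both a fixed `catalog.rho_max` and
#' `catalog.c_v` is rejected as conflicting.
#'
#' @param path YAML file path.
#' @return `shapetrack_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$catalog) &&
      !is.null(user$catalog$rho_max) && is.numeric(user$catalog$rho_max) &&
      !is.null(user$catalog$c_v))
    stop("set either catalog.rho_max or catalog.c_v, not both")
  cfg <- merge_validate(unclass(default_config()), user)
  class(cfg) <- "shapetrack_config"
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param cfg `shapetrack_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
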