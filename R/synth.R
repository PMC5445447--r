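# Synthetic arena videos with two articulated mouse silhouettes and full
# ground truth. The generator emulates what the tracking pipeline must cope
# with -- body bend and squash/stretch (the dominant shape modes), a head
# with ear bumps, a thin tail, illumination drift, sensor noise and scripted
# contact events -- while every landmark and identity stays known exactly.

#' Mouse silhouette parameters
#'
#' @param body_length Spine length tail base to nose, px (default 80, at a
#'   25 fps top-view scale).
#' @param body_width Maximum body width, px.
#' @param bend Total spine bend angle in degrees (+ = left turn); must be
#'   within [-120, 120].
#' @param stretch Length scale factor (squash < 1 < stretch).
#' @param head_scale Relative head size.
#' @param ear_size Ear bump amplitude, px.
#' @param tail_length,tail_width Tail dimensions, px (the tail is rendered
#'   2--3 px wide so tail-removal morphology is exercised realistically).
#' @param tail_curl Tail curvature, degrees over the tail length.
#' @return List of class `mouse_shape_params`.
#' @export
mouse_shape_params <- function(body_length = 80, body_width = 28, bend = 0,
                               stretch = 1, head_scale = 1, ear_size = 4,
                               tail_length = 55, tail_width = 2.6,
                               tail_curl = 25) {
  stopifnot(body_length > 0, body_width > 0, stretch > 0, head_scale > 0,
            ear_size >= 0, tail_length >= 0, tail_width > 0)
  if (abs(bend) > 120) stop("bend angle outside [-120, 120] degrees")
  structure(list(body_length = body_length, body_width = body_width,
                 bend = bend, stretch = stretch, head_scale = head_scale,
                 ear_size = ear_size, tail_length = tail_length,
                 tail_width = tail_width, tail_curl = tail_curl),
            class = "mouse_shape_params")
}

# spine sample of the bent body: s in [0,1] from tail base to nose
mouse_spine <- function(params, pose, s) {
  L <- params$body_length * params$stretch
  # heading of the spine tangent in reporting convention (deg, y up)
  th <- pose$heading + params$bend * (s - 0.5)
  th_rad <- th * pi / 180
  dirx <- cos(th_rad); diry <- -sin(th_rad)      # image coords (y down)
  ns <- length(s)
  dx <- c(0, cumsum((s[-1] - s[-ns]) * L * (dirx[-1] + dirx[-ns]) / 2))
  dy <- c(0, cumsum((s[-1] - s[-ns]) * L * (diry[-1] + diry[-ns]) / 2))
  # center the spine midpoint on the pose position
  mid <- ceiling(ns / 2)
  cbind(x = pose$x + dx - dx[mid], y = pose$y + dy - dy[mid])
}

#' Render one mouse silhouette
#'
#' Builds a simple polygon: a bent body along a circular-arc spine with a
#' smooth width profile, an elliptical head with two ear bumps tapering to a
#' sharp nose, plus a thin tapering tail polygon, and returns ground-truth
#' landmarks.
#'
#' @param params [mouse_shape_params()].
#' @param pose List with `x`, `y` (body center, image px) and `heading`
#'   (degrees, reporting convention).
#' @return List: `body` (polygon), `tail` (polygon), `landmarks` (nose,
#'   tail_base, ear_left, ear_right as (x, y)), `phi` (true viewing
#'   direction, degrees).
#' @export
render_mouse <- function(params, pose) {
  ns <- 81
  s <- seq(0, 1, length.out = ns)
  spine <- mouse_spine(params, pose, s)
  # spine direction d = (cos th, -sin th) in image coords; lateral unit
  # normal n = (sin th, cos th) points to the animal's right
  th <- (pose$heading + params$bend * (s - 0.5)) * pi / 180
  nx <- sin(th)
  ny <- cos(th)
  W2 <- params$body_width / 2
  u <- s
  wb <- W2 * sqrt(pmax(0, 1 - ((u - 0.34) / 0.40)^2))
  wh <- 0.60 * W2 * params$head_scale * sqrt(pmax(0, 1 - ((u - 0.80) / 0.20)^2))
  we <- params$ear_size * exp(-((u - 0.74) / 0.035)^2)
  w <- pmax(wb, wh) + we
  right <- cbind(spine[, 1] + nx * w, spine[, 2] + ny * w)
  left <- cbind(spine[, 1] - nx * w, spine[, 2] - ny * w)
  # rear cap: semicircle of radius w(0) behind the spine start
  w0 <- w[1]
  back <- c(-cos(th[1]), sin(th[1]))             # backwards direction, image
  n0 <- c(nx[1], ny[1])
  cap_a <- seq(-90, 90, length.out = 9) * pi / 180
  cap <- t(vapply(cap_a, function(a) {
    as.numeric(spine[1, ]) + w0 * (cos(a) * back + sin(a) * n0)
  }, numeric(2)))
  # polygon: right side tailward -> nose, left side back, then the rear cap
  # (cap runs from the left corner through the apex to the right corner)
  body <- rbind(right[-c(1, ns), , drop = FALSE],
                spine[ns, ],
                left[rev(seq_len(ns))[-c(1, ns)], , drop = FALSE],
                cap)
  if (!is_simple_polygon_cpp(body))
    stop("silhouette self-intersects at this bend/stretch combination")
  tail_base <- as.numeric(spine[1, ]) + w0 * as.numeric(back)
  nose <- as.numeric(spine[ns, ])
  iu <- which.min(abs(u - 0.74))
  ear_left <- c(spine[iu, 1] - nx[iu] * w[iu], spine[iu, 2] - ny[iu] * w[iu])
  ear_right <- c(spine[iu, 1] + nx[iu] * w[iu], spine[iu, 2] + ny[iu] * w[iu])
  phi <- viewing_direction(nose, ear_left, ear_right, y_down = TRUE)
  # tail: tapering strip curling from the rear apex
  tail <- NULL
  if (params$tail_length > 0) {
    nt <- 25
    ts <- seq(0, 1, length.out = nt)
    ang0 <- atan2(back[2], back[1])
    ang <- ang0 + (params$tail_curl * pi / 180) * ts
    step <- params$tail_length / (nt - 1)
    cx <- tail_base[1] + c(0, cumsum(step * cos(ang[-1])))
    cy <- tail_base[2] + c(0, cumsum(step * sin(ang[-1])))
    # anchor the first segment slightly inside the body so the union connects
    cx[1] <- tail_base[1] - 2 * back[1]; cy[1] <- tail_base[2] - 2 * back[2]
    tw <- (params$tail_width / 2) * (1 - 0.6 * ts)
    tnx <- -sin(ang); tny <- cos(ang)
    tail <- rbind(cbind(cx + tnx * tw, cy + tny * tw),
                  cbind(rev(cx - tnx * tw), rev(cy - tny * tw)))
  }
  list(body = unname(body), tail = tail,
       landmarks = list(nose = nose, tail_base = tail_base,
                        ear_left = ear_left, ear_right = ear_right),
       phi = phi)
}

# --- session scripts --------------------------------------------------------

new_session_script <- function(poses, labels, arena = c(480, 480),
                               bg_grey = 200, mouse_grey = 40, noise_sd = 3,
                               drift_amp = 0.04, drift_period = 200,
                               fps = 25, params = mouse_shape_params(),
                               name = "custom") {
  structure(list(poses = poses, labels = labels, arena = arena,
                 bg_grey = bg_grey, mouse_grey = mouse_grey,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_period = drift_period, fps = fps, params = params,
                 name = name),
            class = "session_script")
}

#' @export
print.session_script <- function(x, ...) {
  cat(sprintf("<session_script> '%s': %d frames, %d x %d px, fps %g\n",
              x$name, max(x$poses$frame), x$arena[1], x$arena[2], x$fps))
  invisible(x)
}

# pose rows for one animal following a circular orbit
orbit_poses <- function(frames, animal, cx, cy, r, omega, phase = 0,
                        bend_amp = 12, bend_period = 40, stretch_amp = 0.04,
                        stretch_period = 57) {
  th <- phase + omega * (frames - 1)
  # position on the circle (image coords); heading = motion tangent (y up)
  x <- cx + r * cos(th)
  y <- cy + r * sin(th)
  heading <- flip_angle_y(atan2d(cos(th) * sign(omega), -sin(th) * sign(omega))) %% 360
  tibble::tibble(
    frame = frames, animal = animal, x = x, y = y, heading = heading,
    bend = bend_amp * sin(2 * pi * frames / bend_period + phase),
    stretch = 1 + stretch_amp * sin(2 * pi * frames / stretch_period + phase)
  )
}

#' Canned session scripts
#'
#' Named generators covering every pipeline stage: `"separated_only"`
#' (two orbiting animals that never meet), `"crossings_k"` (k scripted
#' contact events with partial overlap; pass `k`), `"following"`,
#' `"nose_nose"`, `"nose_anogenital"`, `"mating_posture"` (high-overlap,
#' aligned headings), `"grooming"` (compressed-body episodes for one
#' animal) and `"low_contrast"` (reduced figure-ground contrast).
#'
#' @param name Script name.
#' @param n_frames Number of frames (each script has a sensible default).
#' @param k Number of crossing events (`"crossings_k"` only).
#' @param ... Overrides passed to the script meta (e.g. `noise_sd`).
#' @return `session_script`.
#' @export
script_library <- function(name, n_frames = NULL, k = 3, ...) {
  builders <- list(
    separated_only = build_separated_only,
    crossings_k = function(n) build_crossings(n, k = k),
    following = build_following,
    side_by_side = build_side_by_side,
    nose_nose = build_nose_nose,
    nose_anogenital = build_nose_anogenital,
    mating_posture = build_mating,
    grooming = build_grooming,
    low_contrast = function(n) {
      sc <- build_separated_only(n); sc$mouse_grey <- 120
      sc$name <- "low_contrast"; sc
    }
  )
  if (!name %in% names(builders))
    stop("unknown script '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  sc <- builders[[name]](n_frames)
  extra <- list(...)
  for (key in names(extra)) sc[[key]] <- extra[[key]]
  sc
}

build_separated_only <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 150 else n_frames
  f <- seq_len(n)
  poses <- dplyr::bind_rows(
    orbit_poses(f, "A", 140, 140, 55, 0.045, phase = 0),
    orbit_poses(f, "B", 340, 340, 55, -0.045, phase = pi)
  )
  new_session_script(poses, labels = tibble::tibble(
    condition = character(), animal = character(),
    start = integer(), end = integer()
  ), name = "separated_only")
}

build_crossings <- function(n_frames = NULL, k = 3) {
  warmup <- 60; half <- 45
  n <- if (is.null(n_frames)) warmup + half * k + 60 else n_frames
  f <- seq_len(n)
  # A mows two lanes: rightward passes on y = 228, leftward returns on
  # y = 196; the split keeps every pixel dark well under half the time so
  # the temporal-median background stays clean
  lane_hi <- 228; lane_lo <- 196
  xA <- numeric(n); yA <- numeric(n); hA <- numeric(n)
  for (i in f) {
    p <- (i - (warmup + 1)) %% (2 * half)
    if (p < half) {                       # rightward on lane_hi
      xA[i] <- 120 + 4 * p
      yA[i] <- lane_lo + (lane_hi - lane_lo) * min(1, p / 8)
      hA[i] <- 0
    } else {                              # leftward on lane_lo
      q <- p - half
      xA[i] <- 300 - 4 * q
      yA[i] <- lane_hi - (lane_hi - lane_lo) * min(1, q / 8)
      hA[i] <- 180
    }
  }
  A <- tibble::tibble(frame = f, animal = "A", x = xA, y = yA, heading = hA,
                      bend = 12 * sin(2 * pi * f / 40),
                      stretch = 1 + 0.04 * sin(2 * pi * f / 57))
  # B: warm-up shuttle above the lanes, then k sweeps, each meeting A
  # head-on with a partial (lane offset 24 px) overlap: leftward sweeps on
  # y = 252 against A's rightward passes, rightward sweeps on y = 172
  # against A's leftward returns; afterwards it leaves the lanes and idles
  xr <- 330; xl <- 120
  lane_dn <- 249; lane_up <- 175
  sweep_end <- warmup + half * k
  park_left <- k %% 2 == 1
  park_x <- if (park_left) xl else xr
  y_out <- if (park_left) 320 else 104
  park_lane <- if (park_left) lane_dn else lane_up
  xB <- numeric(n); yB <- numeric(n); hB <- numeric(n)
  for (i in f) {
    if (i <= warmup - 16) {               # idle shuttle, off the lanes
      xB[i] <- 345 - 15 * cos(2 * pi * (i - (warmup - 15)) / 40)
      yB[i] <- 320
      hB[i] <- if (sin(2 * pi * (i - (warmup - 15)) / 40) >= 0) 180 else 0
    } else if (i <= warmup) {             # descend onto the first lane
      xB[i] <- xr
      yB[i] <- 320 - (320 - lane_dn) * (i - (warmup - 16)) / 16
      hB[i] <- 180
    } else if (i <= sweep_end) {
      tphase <- (i - warmup - 1) / half
      hh <- floor(tphase); frac <- tphase - hh
      lane <- if (hh %% 2 == 0) lane_dn else lane_up
      prev_lane <- if (hh == 0) lane_dn else if (hh %% 2 == 0) lane_up else lane_dn
      if (hh %% 2 == 0) { xB[i] <- xr - (xr - xl) * frac; hB[i] <- 180 }
      else { xB[i] <- xl + (xr - xl) * frac; hB[i] <- 0 }
      yB[i] <- prev_lane + (lane - prev_lane) * min(1, frac * half / 14)
    } else if (i <= sweep_end + 16) {     # leave the lanes again
      xB[i] <- park_x
      yB[i] <- park_lane + (y_out - park_lane) * (i - sweep_end) / 16
      hB[i] <- if (park_left) 180 else 0
    } else {
      xB[i] <- park_x + (if (park_left) 1 else -1) *
        (30 - 30 * cos(2 * pi * (i - sweep_end - 16) / 40))
      yB[i] <- y_out
      hB[i] <- if (sin(2 * pi * (i - sweep_end - 16) / 40) >= 0)
        (if (park_left) 0 else 180) else (if (park_left) 180 else 0)
    }
  }
  B <- tibble::tibble(frame = f, animal = "B", x = xB, y = yB, heading = hB,
                      bend = 6 * sin(2 * pi * f / 50), stretch = 1)
  poses <- dplyr::bind_rows(A, B)
  new_session_script(poses, labels = tibble::tibble(
    condition = character(), animal = character(),
    start = integer(), end = integer()
  ), name = sprintf("crossings_%d", k))
}

# analytic per-frame ground truth (landmarks and viewing direction) computed
# straight from the script geometry, without rasterization; used to derive
# behavior labels from explicit pixel rules independent of the classifier
analytic_truth <- function(poses, params, keep_polys = FALSE) {
  n <- max(poses$frame)
  animals <- sort(unique(poses$animal))
  rows <- vector("list", n * 2)
  polys <- if (keep_polys) vector("list", n) else NULL
  for (fi in seq_len(n)) {
    pf <- poses[poses$frame == fi, ]
    pl <- list()
    for (ai in seq_along(animals)) {
      r <- pf[pf$animal == animals[ai], ]
      p <- params; p$bend <- r$bend; p$stretch <- r$stretch
      m <- render_mouse(p, list(x = r$x, y = r$y, heading = r$heading))
      lm <- m$landmarks
      rows[[(fi - 1) * 2 + ai]] <- tibble::tibble(
        frame = fi, animal_id = animals[ai],
        nose_x = lm$nose[1], nose_y = lm$nose[2],
        tail_x = lm$tail_base[1], tail_y = lm$tail_base[2],
        phi_deg = m$phi)
      pl[[ai]] <- m$body
    }
    if (keep_polys) polys[[fi]] <- pl
  }
  list(truth = dplyr::bind_rows(rows), polys = polys)
}

runs_to_labels <- function(flag, condition, animal) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(condition = condition, animal = animal,
                 start = starts[keep], end = ends[keep])
}

# distance between two landmark columns of the wide analytic truth
lm_dist <- function(at, a, b, la, lb) {
  A <- at[at$animal_id == a, ]; B <- at[at$animal_id == b, ]
  sqrt((A[[paste0(la, "_x")]] - B[[paste0(lb, "_x")]])^2 +
         (A[[paste0(la, "_y")]] - B[[paste0(lb, "_y")]])^2)
}

build_following <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 120 else n_frames
  f <- seq_len(n)
  r <- 200; cx <- 240; cy <- 250
  omega <- 2.8 / r                        # ~2.8 px/frame along the circle
  thA <- -pi / 2 + omega * (f - 1)
  # B closes from a 150 px gap down to 96 px, then follows
  gap <- pmax(96, 150 - 1.6 * (f - 1))
  thB <- thA - gap / r
  mk <- function(th, animal) tibble::tibble(
    frame = f, animal = animal,
    x = cx + r * cos(th), y = cy + r * sin(th),
    heading = flip_angle_y(atan2d(cos(th), -sin(th))) %% 360,
    bend = 0, stretch = 1
  )
  poses <- dplyr::bind_rows(mk(thA, "A"), mk(thB, "B"))
  params <- mouse_shape_params()
  at <- analytic_truth(poses, params)$truth
  # label rule: B's nose within 40 px of A's tail base, headings within
  # 40 degrees, for at least 13 consecutive frames
  raw <- lm_dist(at, "B", "A", "nose", "tail") < 40 &
    angle_diff(at$phi_deg[at$animal_id == "B"],
               at$phi_deg[at$animal_id == "A"]) < 40
  lab <- runs_to_labels(keep_sustained(raw, 13), "C4", "B")
  new_session_script(poses, labels = lab, params = params, name = "following")
}

# approach -> hold -> retreat gap profile with crisp transitions
approach_hold <- function(n, gap_far, gap_near, hold = c(0.15, 0.85)) {
  f <- seq_len(n)
  h1 <- floor(hold[1] * n); h2 <- ceiling(hold[2] * n)
  gap <- numeric(n)
  gap[f <= h1] <- gap_far - (gap_far - gap_near) * (f[f <= h1] - 1) / max(h1 - 1, 1)
  gap[f > h1 & f <= h2] <- gap_near
  idx <- f > h2
  gap[idx] <- gap_near + (gap_far - gap_near) * (f[idx] - h2) / max(n - h2, 1)
  list(gap = gap, hold = c(h1 + 1, h2))
}

build_nose_nose <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 100 else n_frames
  ah <- approach_hold(n, gap_far = 150, gap_near = 90)  # center-to-center
  f <- seq_len(n)
  poses <- dplyr::bind_rows(
    tibble::tibble(frame = f, animal = "A", x = 275 - ah$gap / 2,
                   y = 240, heading = 0, bend = 0, stretch = 1),
    tibble::tibble(frame = f, animal = "B", x = 275 + ah$gap / 2,
                   y = 240, heading = 180, bend = 0, stretch = 1)
  )
  params <- mouse_shape_params()
  at <- analytic_truth(poses, params)$truth
  lab <- runs_to_labels(lm_dist(at, "A", "B", "nose", "nose") < 20,
                        "C1", "A+B")
  new_session_script(poses, labels = lab, params = params, name = "nose_nose")
}

build_nose_anogenital <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 100 else n_frames
  # A fixed, facing right; B approaches from behind until its nose reaches
  # A's tail base
  ah <- approach_hold(n, gap_far = 160, gap_near = 99)  # center-to-center
  f <- seq_len(n)
  poses <- dplyr::bind_rows(
    tibble::tibble(frame = f, animal = "A", x = 330, y = 200,
                   heading = 0, bend = 0, stretch = 1),
    tibble::tibble(frame = f, animal = "B", x = 330 - ah$gap, y = 200,
                   heading = 0, bend = 0, stretch = 1)
  )
  params <- mouse_shape_params()
  at <- analytic_truth(poses, params)$truth
  lab <- runs_to_labels(lm_dist(at, "B", "A", "nose", "tail") < 20, "C2", "B")
  new_session_script(poses, labels = lab, params = params,
                     name = "nose_anogenital")
}

build_side_by_side <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 100 else n_frames
  ah <- approach_hold(n, gap_far = 110, gap_near = 35)  # lateral gap
  f <- seq_len(n)
  poses <- dplyr::bind_rows(
    tibble::tibble(frame = f, animal = "A", x = 240, y = 220,
                   heading = 0, bend = 0, stretch = 1),
    tibble::tibble(frame = f, animal = "B", x = 240, y = 220 + ah$gap,
                   heading = 0, bend = 0, stretch = 1)
  )
  params <- mouse_shape_params()
  at <- analytic_truth(poses, params)$truth
  A <- at[at$animal_id == "A", ]; B <- at[at$animal_id == "B", ]
  cdist <- sqrt(((A$nose_x + A$tail_x) / 2 - (B$nose_x + B$tail_x) / 2)^2 +
                  ((A$nose_y + A$tail_y) / 2 - (B$nose_y + B$tail_y) / 2)^2)
  lab <- runs_to_labels(cdist < 50 & angle_diff(A$phi_deg, B$phi_deg) < 25,
                        "C3", "A+B")
  new_session_script(poses, labels = lab, params = params,
                     name = "side_by_side")
}

build_mating <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 80 else n_frames
  ah <- approach_hold(n, gap_far = 80, gap_near = 10)
  f <- seq_len(n)
  poses <- dplyr::bind_rows(
    tibble::tibble(frame = f, animal = "A", x = 240, y = 240,
                   heading = 0, bend = 0, stretch = 1),
    tibble::tibble(frame = f, animal = "B", x = 240 - 8, y = 240 + ah$gap,
                   heading = 0, bend = 0, stretch = 1)
  )
  params <- mouse_shape_params()
  atp <- analytic_truth(poses, params, keep_polys = TRUE)
  ovf <- vapply(atp$polys, function(pl) {
    polygon_overlap_area(pl[[1]], pl[[2]]) /
      min(polygon_area(pl[[1]]), polygon_area(pl[[2]]))
  }, numeric(1))
  at <- atp$truth
  # the mounting animal is behind: here B approaches from behind/below
  lab <- runs_to_labels(ovf > 0.42 &
                          angle_diff(at$phi_deg[at$animal_id == "A"],
                                     at$phi_deg[at$animal_id == "B"]) < 40,
                        "C5", "B")
  new_session_script(poses, labels = lab, params = params,
                     name = "mating_posture")
}

build_grooming <- function(n_frames = NULL) {
  n <- if (is.null(n_frames)) 240 else n_frames
  f <- seq_len(n)
  A <- orbit_poses(f, "A", 160, 160, 55, 0.04, bend_amp = 10)
  # grooming episodes: stooped posture = compressed body, stronger bend
  n_ep <- max(1L, n %/% 80)
  starts <- round(seq(30, n - 40, length.out = n_ep))
  labels <- tibble::tibble(condition = "C6", animal = "A",
                           start = starts, end = starts + 29)
  groom <- rep(FALSE, n)
  for (j in seq_len(nrow(labels))) groom[labels$start[j]:labels$end[j]] <- TRUE
  A$stretch[groom] <- 0.68
  A$bend[groom] <- 35 * sin(2 * pi * f[groom] / 25)
  B <- orbit_poses(f, "B", 350, 350, 55, -0.04)
  new_session_script(dplyr::bind_rows(A, B), labels = labels,
                     name = "grooming")
}

# --- rendering --------------------------------------------------------------

#' Render a scripted session into frames plus ground truth
#'
#' Produces grayscale frames (bright static background with multiplicative
#' illumination drift, dark silhouettes, Gaussian pixel noise) and tidy
#' ground-truth tables in the evaluation module's format. Deterministic
#' given `seed`.
#'
#' @param script `session_script` from [script_library()].
#' @param seed Integer seed for the pixel noise.
#' @return List of class `synthetic_session`: `frames` (list of integer
#'   matrices), `truth` (tibble: frame, animal_id, landmark positions,
#'   phi_deg, overlap_frac), `labels` (behavior intervals), `polys`
#'   (per-frame true body polygons) and the script.
#' @export
render_session <- function(script, seed = 1) {
  H <- script$arena[1]; W <- script$arena[2]
  n <- max(script$poses$frame)
  animals <- sort(unique(script$poses$animal))
  stopifnot(length(animals) == 2)
  poses <- dplyr::arrange(script$poses, .data$frame, .data$animal)
  frames <- vector("list", n)
  truth <- vector("list", n)
  polys <- vector("list", n)
  with_seed(seed, {
    for (fi in seq_len(n)) {
      rows <- poses[poses$frame == fi, ]
      drift <- 1 + script$drift_amp * sin(2 * pi * fi / script$drift_period)
      img <- matrix(script$bg_grey * drift, H, W)
      mice <- list()
      for (ai in seq_len(2)) {
        r <- rows[rows$animal == animals[ai], ]
        p <- script$params
        p$bend <- r$bend; p$stretch <- r$stretch
        mouse <- render_mouse(p, list(x = r$x, y = r$y, heading = r$heading))
        lo <- min(mouse$body[, 1], mouse$tail[, 1])
        hi <- max(mouse$body[, 1], mouse$tail[, 1])
        lo2 <- min(mouse$body[, 2], mouse$tail[, 2])
        hi2 <- max(mouse$body[, 2], mouse$tail[, 2])
        if (lo < 2 || lo2 < 2 || hi > W - 1 || hi2 > H - 1)
          stop("animal pose overlaps the arena boundary at frame ", fi)
        mask <- fill_polygon_cpp(mouse$body, H, W)
        if (!is.null(mouse$tail)) mask <- mask | fill_polygon_cpp(mouse$tail, H, W)
        img[mask] <- script$mouse_grey * drift
        mice[[ai]] <- mouse
      }
      if (script$noise_sd > 0)
        img <- img + matrix(rnorm(H * W, sd = script$noise_sd), H, W)
      img[img < 0] <- 0; img[img > 255] <- 255
      frames[[fi]] <- matrix(as.integer(round(img)), H, W)
      ov <- polygon_overlap_area(mice[[1]]$body, mice[[2]]$body)
      ovf <- ov / min(polygon_area(mice[[1]]$body), polygon_area(mice[[2]]$body))
      truth[[fi]] <- dplyr::bind_rows(lapply(seq_len(2), function(ai) {
        lm <- mice[[ai]]$landmarks
        tibble::tibble(frame = fi, animal_id = animals[ai],
                       nose_x = lm$nose[1], nose_y = lm$nose[2],
                       tail_x = lm$tail_base[1], tail_y = lm$tail_base[2],
                       ear_left_x = lm$ear_left[1], ear_left_y = lm$ear_left[2],
                       ear_right_x = lm$ear_right[1], ear_right_y = lm$ear_right[2],
                       phi_deg = mice[[ai]]$phi, overlap_frac = ovf)
      }))
      polys[[fi]] <- list(mice[[1]]$body, mice[[2]]$body)
    }
  })
  structure(list(frames = frames, truth = dplyr::bind_rows(truth),
                 labels = script$labels, polys = polys, script = script),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> '%s': %d frames of %d x %d px\n",
              x$script$name, length(x$frames),
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' Annotate a reference shape from a synthetic session
#'
#' Stands in for the one-time manual annotation: picks a separated frame
#' with a nearly straight body, segments it with the same preprocessing the
#' tracker uses, and places the four landmarks at the ground-truth
#' positions.
#'
#' @param session `synthetic_session`.
#' @param animal Which animal to annotate.
#' @param frame_idx Frame to annotate (default: the early frame where the
#'   animal is straightest).
#' @param config Configuration list.
#' @return `reference_shape`.
#' @export
reference_from_session <- function(session, animal = "A", frame_idx = NULL,
                                   config = default_config()) {
  poses <- session$script$poses
  if (is.null(frame_idx)) {
    early <- poses[poses$animal == animal &
                     poses$frame <= min(40, max(poses$frame)), ]
    frame_idx <- early$frame[which.min(abs(early$bend))]
  }
  pp <- config$preprocess
  n <- length(session$frames)
  bg_idx <- unique(round(seq(1, n, length.out = min(n, config$tracker$bg_frames))))
  bg <- build_background(lapply(session$frames[bg_idx], normalize_illumination,
                                target_mean = pp$target_mean))
  img <- normalize_illumination(session$frames[[frame_idx]], pp$target_mean)
  blobs <- extract_blobs(segment_foreground(img, bg, pp$threshold), pp$b_min)
  gt <- session$truth[session$truth$frame == frame_idx &
                        session$truth$animal_id == animal, ]
  ctr_d <- vapply(blobs, function(b) {
    sum((b$centroid - c((gt$nose_x + gt$tail_x) / 2,
                        (gt$nose_y + gt$tail_y) / 2))^2)
  }, numeric(1))
  blob <- blobs[[which.min(ctr_d)]]
  lt <- locate_tail(blob$mask, pp$r_S)
  body <- extract_blobs(lt$body_mask, pp$b_min)[[1]]
  contour <- resample_contour(body$boundary, config$match$n_points)
  reference_from_points(contour,
                        nose_xy = c(gt$nose_x, gt$nose_y),
                        tail_xy = c(gt$tail_x, gt$tail_y),
                        ear_left_xy = c(gt$ear_left_x, gt$ear_left_y),
                        ear_right_xy = c(gt$ear_right_x, gt$ear_right_y),
                        n_r = config$match$n_r, n_theta = config$match$n_theta)
}
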