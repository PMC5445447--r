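# Per-frame tracking state machine: separated-regime shape matching vs
# crossing-regime alternating ASM fitting, with identity preservation by
# maximum shape overlap between successive frames.

#' Classify the per-frame regime from segmented blobs
#'
#' Two or more blobs whose two largest areas both exceed the single-animal
#' floor mean the animals are separated; a single qualifying blob of
#' roughly double area is a crossing; anything else is a lost frame (the
#' previous state is carried forward).
#'
#' @param blobs List of blobs from [extract_blobs()] (area-sorted).
#' @param single_floor Minimum area (px^2) for a blob to count as one animal.
#' @param merged_min Minimum area for a lone blob to count as two animals in
#'   contact.
#' @return One of `"separated"`, `"crossing"`, `"lost"`.
#' @export
classify_regime <- function(blobs, single_floor, merged_min) {
  areas <- vapply(blobs, function(b) b$area, numeric(1))
  big <- sum(areas >= single_floor)
  if (big >= 2) return("separated")
  if (big == 1 && areas[1] >= merged_min) return("crossing")
  "lost"
}

#' Assign identities by maximum overlap with the previous frame
#'
#' Evaluates both pairings of the two new contours against the two previous
#' contours and keeps the one with the larger total overlap area; ties keep
#' the incoming order (previous labels preserved).
#'
#' @param prev,new Lists of two polygons each.
#' @return Integer vector `map` such that new contour `map[i]` belongs to
#'   the animal of `prev[[i]]`.
#' @export
assign_identities <- function(prev, new) {
  straight <- polygon_overlap_area(prev[[1]], new[[1]]) +
    polygon_overlap_area(prev[[2]], new[[2]])
  swapped <- polygon_overlap_area(prev[[1]], new[[2]]) +
    polygon_overlap_area(prev[[2]], new[[1]])
  if (swapped > straight) c(2L, 1L) else c(1L, 2L)
}

#' Count identity switches against ground truth
#'
#' At every evaluated frame the predicted animals are mapped to the true
#' animals by minimal total nose distance; a switch is counted whenever that
#' mapping flips relative to the previous evaluated frame.
#'
#' @param track Track tibble (see [track_video()]).
#' @param truth Ground-truth tibble (same column convention).
#' @return Number of identity switches.
#' @export
count_identity_switches <- function(track, truth) {
  frames <- intersect(unique(track$frame), unique(truth$frame))
  prev_map <- NULL
  switches <- 0L
  for (f in sort(frames)) {
    tr <- track[track$frame == f, ]
    gt <- truth[truth$frame == f, ]
    if (nrow(tr) != 2 || nrow(gt) != 2) next
    if (any(!is.finite(c(tr$nose_x, tr$nose_y)))) next
    d <- function(i, j) sqrt((tr$nose_x[i] - gt$nose_x[j])^2 +
                               (tr$nose_y[i] - gt$nose_y[j])^2)
    map <- if (d(1, 1) + d(2, 2) <= d(1, 2) + d(2, 1)) c(1L, 2L) else c(2L, 1L)
    if (!is.null(prev_map) && !identical(map, prev_map)) switches <- switches + 1L
    prev_map <- map
  }
  switches
}

# crop a patch around a contour (margin in px); offset maps patch -> image
crop_patch <- function(img, contour, margin) {
  x0 <- max(1L, floor(min(contour[, 1])) - margin)
  x1 <- min(ncol(img), ceiling(max(contour[, 1])) + margin)
  y0 <- max(1L, floor(min(contour[, 2])) - margin)
  y1 <- min(nrow(img), ceiling(max(contour[, 2])) + margin)
  list(img = img[y0:y1, x0:x1, drop = FALSE], offset = c(x0 - 1L, y0 - 1L))
}

# landmarks of a contour in reference indexing, as a per-animal state list
state_from_contour <- function(contour, ref, H = NA_real_) {
  lm <- lapply(ref$landmarks, function(i) unname(contour[i, ]))
  phi <- tryCatch(
    viewing_direction(lm$nose, lm$ear_left, lm$ear_right, y_down = TRUE),
    error = function(e) NA_real_)
  list(contour = contour, landmarks = lm, phi = phi,
       orientation = body_axis_angle(lm), H = H)
}

#' Track a two-animal video
#'
#' Runs the full pipeline: illumination normalization, temporal-median
#' background, blob segmentation, tail removal, reference matching with
#' runtime catalog growth while the animals are separated, and alternating
#' occlusion-aware ASM fitting through contact events. The acceptance
#' threshold `rho_max` is either fixed in the configuration or calibrated
#' from a warm-up cost sample to hit the target acceptance ratio `c_v`.
#'
#' @param frames List of grayscale matrices, or a `synthetic_session`.
#' @param ref [reference_shape()] annotated on one frame.
#' @param config Configuration list (see [default_config()]).
#' @param seed Integer seed (catalog reservoir thinning; all core geometry
#'   is deterministic).
#' @return Object of class `shapetrack_result`: list with `track` (tibble:
#'   frame, animal_id, regime, nose/tail positions, `phi_deg`, `match_cost`,
#'   `overlap_frac`, shape coefficients `b` as a list column), `catalog`,
#'   `model`, `rho_max` and the configuration.
#' @export
track_video <- function(frames, ref, config = default_config(), seed = 1L) {
  if (inherits(frames, "synthetic_session")) frames <- frames$frames
  cfg <- config
  pp <- cfg$preprocess; ct <- cfg$catalog; av <- cfg$asm; tk <- cfg$tracker
  n <- length(frames)
  stopifnot(n >= 3)
  ids <- c("A", "B")

  bg_idx <- unique(round(seq(1, n, length.out = min(n, tk$bg_frames))))
  bg <- build_background(lapply(frames[bg_idx], normalize_illumination,
                                target_mean = pp$target_mean))

  catalog <- new_catalog(ref, ct$max_entries)
  rho_max <- if (identical(ct$rho_max, "auto")) NULL else ct$rho_max
  costs <- numeric(0)
  pending <- list()
  model <- NULL
  accepted_since_train <- 0L
  single_areas <- numeric(0)
  aligned_store <- rep(list(list()), n)   # aligned shapes per separated frame
  state <- NULL                     # list(A = ..., B = ...)
  instances <- NULL                 # crossing-regime ASM instances
  regime_prev <- "separated"
  rows <- vector("list", n)

  gate_entry <- function(cand) {
    aligned <- gate_and_align(cand$corresponded, ref$landmarks, cand$H, rho_max)
    if (is.null(aligned)) return(FALSE)
    catalog <<- catalog_add(catalog, aligned, cand$corresponded, cand$H,
                            cand$frame, cand$patch)
    accepted_since_train <<- accepted_since_train + 1L
    TRUE
  }
  train_model <- function() {
    if (length(catalog) < tk$min_catalog)
      stop(sprintf(paste0("shape catalog too small to train the ASM ",
                          "(%d entries, need at least %d separated-frame shapes)"),
                   length(catalog), tk$min_catalog))
    mdl <- build_shape_model(catalog, f_v = av$f_v, m = av$m)
    attach_profile_model(mdl, build_profile_model(catalog, k = av$profile_k,
                                                  max_entries = av$profile_max))
  }

  with_seed(seed, {
    for (f in seq_len(n)) {
      img <- normalize_illumination(frames[[f]], pp$target_mean)
      mask <- segment_foreground(img, bg, pp$threshold)
      blobs <- extract_blobs(mask, pp$b_min)
      med_single <- if (length(single_areas)) median(single_areas) else
        if (length(blobs) >= 2) mean(vapply(blobs[1:2], `[[`, numeric(1), "area")) else NA
      regime <- if (!length(blobs) || !is.finite(med_single)) "lost" else
        classify_regime(blobs, tk$floor_frac * med_single,
                        tk$merged_frac * med_single)

      if (regime == "separated") {
        areas2 <- vapply(blobs[1:2], `[[`, numeric(1), "area")
        single_areas <- c(single_areas, areas2)
        cand <- vector("list", 2)
        ok <- TRUE
        for (bi in 1:2) {
          res <- tryCatch({
            lt <- locate_tail(blobs[[bi]]$mask, pp$r_S)
            body <- extract_blobs(lt$body_mask, pp$b_min)
            if (!length(body)) stop("body vanished under opening")
            contour <- resample_contour(body[[1]]$boundary, cfg$match$n_points)
            hint_or <- if (!is.null(state)) {
              ctr <- polygon_centroid(contour)
              dA <- sum((polygon_centroid(state$A$contour) - ctr)^2)
              dB <- sum((polygon_centroid(state$B$contour) - ctr)^2)
              if (dA <= dB) state$A$orientation else state$B$orientation
            } else NULL
            m <- match_to_reference(contour, ref, tail_hint = lt$tail_base,
                                    prev_orientation = hint_or)
            m$patch <- crop_patch(img, m$corresponded,
                                  av$profile_k + av$search_l + 4L)
            m
          }, error = function(e) NULL)
          if (is.null(res)) ok <- FALSE
          cand[[bi]] <- res
        }
        if (!ok) {
          regime <- "lost"
        } else {
          if (is.null(state)) {
            map <- c(1L, 2L)
          } else {
            map <- assign_identities(list(state$A$contour, state$B$contour),
                                     list(cand[[1]]$corresponded,
                                          cand[[2]]$corresponded))
          }
          state <- list(A = state_from_contour(cand[[map[1]]]$corresponded, ref,
                                               cand[[map[1]]]$H),
                        B = state_from_contour(cand[[map[2]]]$corresponded, ref,
                                               cand[[map[2]]]$H))
          instances <- NULL
          # catalog bookkeeping
          for (bi in 1:2) {
            cc <- cand[[bi]]
            cc$frame <- f
            costs <- c(costs, cc$H)
            if (is.null(rho_max)) {
              pending[[length(pending) + 1L]] <- cc
              if (length(costs) >= ct$warmup_n) {
                rho_max <- calibrate_rho(costs, ct$c_v)
                for (p in pending) gate_entry(p)
                pending <- list()
              }
            } else {
              gate_entry(cc)
            }
          }
          # periodic model refresh while the catalog keeps growing
          if (!is.null(model) && accepted_since_train >= tk$refresh_every) {
            model <- train_model()
            accepted_since_train <- 0L
          }
        }
      } else if (regime == "crossing") {
        if (is.null(state)) {
          regime <- "lost"
        } else {
          if (is.null(model)) {
            if (is.null(rho_max)) {
              if (length(costs) >= 10) {
                rho_max <- calibrate_rho(costs, ct$c_v)
                for (p in pending) gate_entry(p)
                pending <- list()
              }
            }
            model <- train_model()
            accepted_since_train <- 0L
          }
          if (is.null(instances)) {
            instances <- list(A = instance_from_contour(model, state$A$contour),
                              B = instance_from_contour(model, state$B$contour))
          }
          order_ab <- if (f %% 2 == 0) c("A", "B") else c("B", "A")
          for (iter in seq_len(av$N_max)) {
            for (a in order_ab) {
              other <- setdiff(c("A", "B"), a)
              frozen <- which(
                point_in_polygon_cpp(instances[[a]]$contour,
                                     instances[[other]]$contour) |
                  dist_to_polygon_cpp(instances[[a]]$contour,
                                      instances[[other]]$contour) <= 2)
              instances[[a]] <- asm_fit_iteration(model, img, instances[[a]],
                                                  frozen, av$search_l)
            }
          }
          state <- list(A = state_from_contour(instances$A$contour, ref),
                        B = state_from_contour(instances$B$contour, ref))
          state$A$b <- instances$A$b
          state$B$b <- instances$B$b
        }
      }

      if (regime == "lost" && is.null(state)) {
        rows[[f]] <- tibble::tibble(
          frame = f, animal_id = ids, regime = "lost",
          nose_x = NA_real_, nose_y = NA_real_,
          tail_x = NA_real_, tail_y = NA_real_, phi_deg = NA_real_,
          match_cost = NA_real_, overlap_frac = NA_real_, b = list(NULL, NULL))
        next
      }

      # shape coefficients on separated frames: projection of the aligned shape
      if (regime == "separated") {
        for (a in ids) {
          aligned <- align_vertical(state[[a]]$contour, ref$landmarks)
          aligned_store[[f]][[a]] <- aligned
          if (!is.null(model))
            state[[a]]$b <- asm_clamp(asm_project(model, aligned), model)
        }
      }
      ovf <- if (regime == "crossing") {
        polygon_overlap_area(state$A$contour, state$B$contour) /
          min(polygon_area(state$A$contour), polygon_area(state$B$contour))
      } else 0
      rows[[f]] <- dplyr::bind_rows(lapply(ids, function(a) {
        s <- state[[a]]
        tibble::tibble(
          frame = f, animal_id = a, regime = regime,
          nose_x = s$landmarks$nose[1], nose_y = s$landmarks$nose[2],
          tail_x = s$landmarks$tail_base[1], tail_y = s$landmarks$tail_base[2],
          phi_deg = s$phi,
          match_cost = if (regime == "separated") s$H else NA_real_,
          overlap_frac = ovf,
          b = list(if (is.null(s$b)) NULL else s$b))
      }))
      regime_prev <- regime
    }
  })

  # a session without contact events never triggered training: train at the
  # end (if possible) and back-fill the shape coefficients
  if (is.null(model) && length(catalog) >= tk$min_catalog) {
    model <- with_seed(seed, train_model())
  }
  track <- dplyr::bind_rows(rows)
  if (!is.null(model)) {
    for (i in seq_len(nrow(track))) {
      if (!is.null(track$b[[i]])) next
      al <- aligned_store[[track$frame[i]]][[track$animal_id[i]]]
      if (!is.null(al))
        track$b[[i]] <- asm_clamp(asm_project(model, al), model)
    }
  }
  structure(list(track = track, catalog = catalog,
                 model = model, rho_max = rho_max, ref = ref,
                 config = cfg, n_frames = n),
            class = "shapetrack_result")
}

#' @export
print.shapetrack_result <- function(x, ...) {
  reg <- table(x$track$regime[x$track$animal_id == "A"])
  cat(sprintf(paste0("<shapetrack_result> %d frames (%s), catalog %d shapes,",
                     " rho_max = %s\n"),
              x$n_frames,
              paste(sprintf("%s %d", names(reg), as.integer(reg)), collapse = ", "),
              length(x$catalog),
              if (is.null(x$rho_max)) "uncalibrated" else sprintf("%.1f", x$rho_max)))
  invisible(x)
}
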