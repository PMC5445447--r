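# File I/O glue: frame directories, track/truth/event CSVs, provenance.

#' Read a directory of grayscale image frames
#'
#' PNG frames in lexicographic order; the codec-free input path. Images are
#' converted to grayscale matrices on a 0--255 scale.
#'
#' @param dir Directory containing `.png` files.
#' @return List of numeric matrices.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no .png frames found in ", dir)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) a <- a[, , 1] * 0.299 + a[, , 2] * 0.587 + a[, , 3] * 0.114
    a * 255
  })
}

#' Write frames as a numbered PNG sequence
#' @param frames List of matrices (0--255 scale).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(pmin(pmax(frames[[i]] / 255, 0), 1),
                  file.path(dir, sprintf("frame_%05d.png", i)))
  }
  invisible(dir)
}

# flatten the b list column into b_1 ... b_t for CSV round-tripping
flatten_track <- function(track) {
  if (!"b" %in% names(track)) return(track)
  t_max <- max(c(0L, vapply(track$b, length, integer(1))))
  flat <- track[setdiff(names(track), "b")]
  if (t_max > 0) {
    bm <- t(vapply(track$b, function(b) {
      out <- rep(NA_real_, t_max)
      if (length(b)) out[seq_along(b)] <- b
      out
    }, numeric(t_max)))
    colnames(bm) <- paste0("b_", seq_len(t_max))
    flat <- dplyr::bind_cols(flat, tibble::as_tibble(bm))
  }
  flat
}

#' Write / read a track record CSV
#'
#' Columns: frame, animal_id, regime, nose_x, nose_y, tail_x, tail_y,
#' phi_deg, match_cost, overlap_frac, b_1 ... b_t.
#'
#' @param track Track tibble (possibly with a `b` list column).
#' @param path CSV path.
#' @return `read_track` returns a tibble (with the `b` list column
#'   reassembled); `write_track` returns `path` invisibly.
#' @export
write_track <- function(track, path) {
  readr::write_csv(flatten_track(track), path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  bcols <- grep("^b_\\d+$", names(df), value = TRUE)
  if (length(bcols)) {
    bm <- as.matrix(df[bcols])
    df <- df[setdiff(names(df), bcols)]
    df$b <- lapply(seq_len(nrow(bm)), function(i) {
      v <- bm[i, ]
      if (all(is.na(v))) NULL else v[!is.na(v)]
    })
  }
  df
}

#' Write / read ground truth CSV
#' @param truth Tibble (`frame`, `animal_id`, `nose_x/y`, `tail_x/y`,
#'   `phi_deg`, ...).
#' @param path CSV path.
#' @return Tibble for the reader; `path` invisibly for the writer.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' Write behavior events CSV
#' @param events Tibble from [behavior_events()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Tracks a video (a frame directory or an in-memory frame list /
#' `synthetic_session`), writes the track CSV, the trained model archive, a
#' behavior event CSV and a machine-readable provenance record (config
#' hash, seed, package version).
#'
#' @param input Frame directory path, list of frames or `synthetic_session`.
#' @param reference `reference_shape` or path to a reference JSON.
#' @param config `shapetrack_config` or path to a YAML configuration.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return The `shapetrack_result`, invisibly.
#' @export
run_pipeline <- function(input, reference, config = default_config(),
                         out_dir, seed = 1L) {
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference annotation not found: ", reference)
    reference <- read_reference(reference)
  }
  if (is.character(config)) config <- load_config(config)
  frames <- if (is.character(input)) read_frames(input) else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- track_video(frames, reference, config, seed = seed)
  write_track(res$track, file.path(out_dir, "track.csv"))
  if (!is.null(res$model)) write_model(res$model, file.path(out_dir, "model.rds"))
  ev <- tryCatch(behavior_events(res$track, config), error = function(e) NULL)
  if (!is.null(ev)) write_events(ev, file.path(out_dir, "events.csv"))
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  prov <- list(
    package = "shapetrack",
    version = as.character(utils::packageVersion("shapetrack")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    rho_max = res$rho_max,
    n_frames = res$n_frames,
    catalog_size = length(res$catalog),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
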