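# ggplot2 visualizations and broom-style summaries.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the mode spectrum of an active shape model
#'
#' @param x `active_shape_model`.
#' @param ... Unused.
#' @return Tibble: `mode`, `eigenvalue`, `var_frac`, `cum_var_frac`,
#'   `retained`.
#' @export
tidy.active_shape_model <- function(x, ...) {
  lam <- x$lambda_all
  total <- sum(lam)
  tibble::tibble(
    mode = seq_along(lam), eigenvalue = lam,
    var_frac = if (total > 0) lam / total else 0,
    cum_var_frac = if (total > 0) cumsum(lam) / total else 0,
    retained = seq_along(lam) <= x$t)
}

#' @rdname tidy.active_shape_model
#' @export
glance.active_shape_model <- function(x, ...) {
  tibble::tibble(n_landmarks = x$n, n_shapes = x$s, t = x$t, f_v = x$f_v,
                 m = x$m, total_variance = sum(x$lambda_all),
                 has_profiles = !is.null(x$profile))
}

#' Summarize a tracking result
#' @param x `shapetrack_result`.
#' @param ... Unused.
#' @return One-row tibble with regime counts, catalog size and `rho_max`.
#' @export
glance.shapetrack_result <- function(x, ...) {
  tr <- x$track[x$track$animal_id == "A", ]
  tibble::tibble(
    n_frames = x$n_frames,
    n_separated = sum(tr$regime == "separated"),
    n_crossing = sum(tr$regime == "crossing"),
    n_lost = sum(tr$regime == "lost"),
    catalog_size = length(x$catalog),
    rho_max = if (is.null(x$rho_max)) NA_real_ else x$rho_max,
    t_modes = if (is.null(x$model)) NA_integer_ else x$model$t,
    mean_match_cost = mean(x$track$match_cost, na.rm = TRUE))
}

#' Plot tracked trajectories
#'
#' Nose trajectories of both animals in image coordinates (y axis flipped
#' so the plot matches the video orientation).
#'
#' @param track Track tibble.
#' @return ggplot object.
#' @export
plot_trajectories <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$nose_x, y = .data$nose_y,
                                      color = .data$animal_id)) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "animal",
                  title = "Nose trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a precision curve
#' @param object `precision_curve` tibble.
#' @param ... Unused.
#' @return ggplot object.
#' @export
autoplot.precision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "error threshold", y = "fraction of frames below",
                  title = "Tracking precision") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the leading shape modes of a model
#'
#' Mean shape plus/minus `m` standard deviations along each of the first
#' `n_modes` eigenvectors (the bend and squash/stretch modes dominate for
#' mouse silhouettes).
#'
#' @param model `active_shape_model`.
#' @param n_modes Number of modes to show.
#' @param m Mode excursion in standard deviations.
#' @return ggplot object.
#' @export
plot_eigenmodes <- function(model, n_modes = 3, m = 2) {
  n_modes <- min(n_modes, model$t)
  dfs <- list()
  for (k in seq_len(n_modes)) {
    for (s in c(-m, 0, m)) {
      b <- rep(0, model$t)
      b[k] <- s * sqrt(model$lambda[k])
      ct <- asm_reconstruct(model, b)
      ct <- rbind(ct, ct[1, ])
      dfs[[length(dfs) + 1]] <- tibble::tibble(
        mode = paste("mode", k), excursion = factor(s),
        x = ct[, 1], y = ct[, 2], step = seq_len(nrow(ct)))
    }
  }
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$excursion,
                                   color = .data$excursion)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(color = "sd", title = "Leading shape modes") +
    ggplot2::theme_minimal()
}
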