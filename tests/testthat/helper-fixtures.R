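# Shared fixtures, all generated in code.

# star-shaped polygon with random radii: always simple
random_simple_polygon <- function(n, r_min = 20, r_max = 60, center = c(0, 0)) {
  ang <- sort(runif(n, 0, 2 * pi))
  # enforce distinct angles
  while (any(diff(ang) < 1e-4)) ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_min, r_max)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

random_convex_polygon <- function(n, r = 40, center = c(0, 0)) {
  ang <- sort(runif(n, 0, 2 * pi))
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# U-shaped polygon: inner distance between prong tips must round the bend
u_polygon <- function() {
  rbind(
    c(0, 0), c(50, 0), c(50, 40), c(40, 40), c(40, 10),
    c(10, 10), c(10, 40), c(0, 40))
}

rotate_polygon <- function(poly, deg, center = colMeans(poly)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(poly, 2, center) %*% t(R), 2, center, FUN = "+")
}

# independent visibility-graph + Dijkstra oracle for inner distances,
# written against igraph (separate code path from the package's C++)
inner_distance_oracle <- function(poly) {
  n <- nrow(poly)
  seg_int <- function(p1, p2, p3, p4) {
    o <- function(a, b, c) (b[1]-a[1])*(c[2]-a[2]) - (b[2]-a[2])*(c[1]-a[1])
    o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
    o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
    (o1 * o2 < 0) && (o3 * o4 < 0)
  }
  pip <- function(p) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly[i,2] > p[2]) != (poly[j,2] > p[2]) &&
          p[1] < (poly[j,1]-poly[i,1]) * (p[2]-poly[i,2]) /
            (poly[j,2]-poly[i,2]) + poly[i,1]) inside <- !inside
      j <- i
    }
    inside
  }
  edges <- NULL; weights <- NULL
  for (i in 1:(n-1)) for (j in (i+1):n) {
    adj <- (j == i + 1) || (i == 1 && j == n)
    visible <- TRUE
    if (!adj) {
      for (a in seq_len(n)) {
        b <- if (a == n) 1 else a + 1
        if (a %in% c(i, j) || b %in% c(i, j)) next
        if (seg_int(poly[i,], poly[j,], poly[a,], poly[b,])) { visible <- FALSE; break }
      }
      if (visible && !pip((poly[i,] + poly[j,]) / 2)) visible <- FALSE
    }
    if (visible) {
      edges <- rbind(edges, c(i, j))
      weights <- c(weights, sqrt(sum((poly[i,] - poly[j,])^2)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::distances(g, weights = weights)
}

# rasterize one mouse and extract its tail-free resampled body contour,
# mirroring the separated-regime preprocessing
rasterized_mouse_contour <- function(bend = 0, stretch = 1, heading = 0,
                                     x = 240, y = 240, n = 100, size = 480) {
  m <- render_mouse(mouse_shape_params(bend = bend, stretch = stretch),
                    list(x = x, y = y, heading = heading))
  img <- matrix(200, size, size)
  mask <- shapetrack:::fill_polygon_cpp(m$body, size, size) |
    shapetrack:::fill_polygon_cpp(m$tail, size, size)
  img[mask] <- 40
  bg <- build_background(rep(list(matrix(200, size, size)), 3))
  blobs <- extract_blobs(segment_foreground(img, bg), 400)
  lt <- locate_tail(blobs[[1]]$mask, 4)
  body <- extract_blobs(lt$body_mask, 400)[[1]]
  list(contour = resample_contour(body$boundary, n), mouse = m,
       tail_hint = lt$tail_base, img = img)
}

# reference built from a straight rasterized mouse
make_test_reference <- function(n = 100) {
  rc <- rasterized_mouse_contour()
  lm <- rc$mouse$landmarks
  reference_from_points(rc$contour, lm$nose, lm$tail_base,
                        lm$ear_left, lm$ear_right)
}

# cache expensive fixtures across tests within a session
fixture_env <- new.env()
cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

# one-frame track/truth pair with hand-computable errors:
# nose offset (3,4) -> 5, tail offset (5,12) -> 13, phi 10 vs 350 -> 20
mk_metric_pair <- function() {
  truth <- tibble::tibble(
    frame = 1, animal_id = c("A", "B"),
    nose_x = c(0, 500), nose_y = 0, tail_x = c(50, 550), tail_y = 0,
    phi_deg = 350)
  track <- tibble::tibble(
    frame = 1, animal_id = c("A", "B"),
    nose_x = c(3, 503), nose_y = 4, tail_x = c(55, 555), tail_y = 12,
    phi_deg = 10)
  list(track = track, truth = truth)
}

# smooth star-shaped Fourier contour: strictly curved boundary, so no
# collinear point triples (numerically stable visibility graphs)
random_smooth_contour <- function(n, base = 40) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- base + 0 * th
  for (k in 2:4) {
    r <- r + runif(1, 2, base / 8) * cos(k * th + runif(1, 0, 2 * pi))
  }
  cbind(r * cos(th), r * sin(th))
}
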