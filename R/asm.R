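# Active shape model: point-distribution model (PCA over the vertically
# aligned catalog) plus per-landmark grey-level profile statistics, fitted
# to images by iterative Mahalanobis search along contour normals with
# coefficient clamping.

#' Build the point-distribution (shape) part of an ASM
#'
#' Stacks the aligned catalog contours as shape vectors
#' (x1, y1, ..., xn, yn), computes mean and covariance (1/(s-1)
#' normalization) and its eigendecomposition, and retains the smallest
#' number of modes t whose eigenvalues sum to at least `f_v` of the total
#' variance (bounded below at one mode).
#'
#' @param shapes A `shape_catalog` or an s x 2n numeric matrix of shape
#'   vectors (one row per shape).
#' @param f_v Fraction of shape variance the retained modes must explain.
#' @param m Coefficient clamp multiplier: |b_i| <= m * sqrt(lambda_i).
#' @return Object of class `active_shape_model` (shape part only; see
#'   [build_profile_model()] for the grey-profile part).
#' @export
build_shape_model <- function(shapes, f_v = 0.98, m = 3) {
  X <- if (inherits(shapes, "shape_catalog")) {
    do.call(rbind, lapply(shapes$entries, function(e) contour_to_vec(e$aligned)))
  } else {
    as.matrix(shapes)
  }
  s <- nrow(X)
  if (is.null(s) || s < 3) stop("need at least 3 catalog shapes to train the model")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  S <- crossprod(Xc) / (s - 1)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  total <- sum(lambda)
  t_keep <- if (total <= 0) 1L else {
    which(cumsum(lambda) >= f_v * total)[1]
  }
  t_keep <- max(1L, t_keep)
  structure(list(
    mean = xbar, P = eg$vectors[, seq_len(t_keep), drop = FALSE],
    lambda = lambda[seq_len(t_keep)], lambda_all = lambda,
    t = t_keep, f_v = f_v, m = m, s = s, n = length(xbar) / 2,
    profile = NULL
  ), class = "active_shape_model")
}

#' @export
print.active_shape_model <- function(x, ...) {
  cat(sprintf(
    "<active_shape_model> n = %d landmarks, %d training shapes, t = %d modes (f_v = %.2f)%s\n",
    x$n, x$s, x$t, x$f_v,
    if (is.null(x$profile)) "" else sprintf(", grey profiles k = %d", x$profile$k)))
  invisible(x)
}

# outward unit normals of a closed contour (positive-shoelace traversal)
contour_normals <- function(contour) {
  n <- nrow(contour)
  nb_prev <- c(n, seq_len(n - 1)); nb_next <- c(2:n, 1)
  tx <- contour[nb_next, 1] - contour[nb_prev, 1]
  ty <- contour[nb_next, 2] - contour[nb_prev, 2]
  len <- sqrt(tx^2 + ty^2); len[len < 1e-12] <- 1
  sgn <- if (polygon_area_signed(contour) >= 0) 1 else -1
  cbind(sgn * ty / len, -sgn * tx / len)
}

# sample, differentiate and normalize one set of profiles:
# points n x 2, normals n x 2, offsets length q -> list of n x (2k) rows?
# Returns an n x q x ... helper; here: matrix (n*q) x samples handled by caller.
sample_profiles <- function(img, points, normals, k, offsets = 0) {
  n <- nrow(points); q <- length(offsets); w <- 2 * k + 1
  rel <- -k:k
  # sample positions: landmark-major blocks of q offsets, w profile samples
  base_x <- rep(points[, 1], each = q) + rep(normals[, 1], each = q) * offsets
  base_y <- rep(points[, 2], each = q) + rep(normals[, 2], each = q) * offsets
  nx <- rep(normals[, 1], each = q); ny <- rep(normals[, 2], each = q)
  xs <- matrix(base_x, n * q, w) + outer(nx, rel)
  ys <- matrix(base_y, n * q, w) + outer(ny, rel)
  vals <- bilinear_cpp(img, as.vector(xs), as.vector(ys))
  V <- matrix(vals, nrow = n * q, ncol = w)
  G <- V[, -1, drop = FALSE] - V[, -w, drop = FALSE]   # first differences
  nrm <- rowSums(abs(G))
  G / ifelse(nrm < 1e-9, 1, nrm)                       # flat profiles -> zeros
}

#' Build the grey-level profile part of an ASM
#'
#' For every landmark, samples `2k + 1` intensities along the contour
#' normal in each catalog entry's source image, takes first differences and
#' normalizes by the sum of absolute values, then accumulates the mean
#' profile and its covariance. Covariances are regularized by adding
#' `1e-6 * trace / dim` to the diagonal so the Mahalanobis inverse exists
#' even for near-degenerate catalogs.
#'
#' @param catalog `shape_catalog` whose entries carry image patches.
#' @param k Profile half-length in samples (profile length is 2k).
#' @param max_entries Use at most this many (evenly spaced) entries.
#' @return List of per-landmark statistics to attach to a model (see
#'   [attach_profile_model()]).
#' @export
build_profile_model <- function(catalog, k = 5, max_entries = 300) {
  entries <- Filter(function(e) !is.null(e$patch), catalog$entries)
  if (length(entries) < 2) stop("need at least 2 catalog entries with image patches")
  if (length(entries) > max_entries) {
    sel <- unique(round(seq(1, length(entries), length.out = max_entries)))
    entries <- entries[sel]
  }
  n <- catalog$ref$n
  gs <- vector("list", length(entries))
  for (ei in seq_along(entries)) {
    e <- entries[[ei]]
    pts <- cbind(e$corresponded[, 1] - e$patch$offset[1],
                 e$corresponded[, 2] - e$patch$offset[2])
    nrm <- contour_normals(e$corresponded)
    gs[[ei]] <- sample_profiles(e$patch$img, pts, nrm, k)   # n x 2k
  }
  dim_g <- 2 * k
  mean_g <- matrix(0, n, dim_g)
  for (g in gs) mean_g <- mean_g + g
  mean_g <- mean_g / length(gs)
  Sinv <- array(0, dim = c(dim_g, dim_g, n))
  for (i in seq_len(n)) {
    Gi <- do.call(rbind, lapply(gs, function(g) g[i, ]))
    Si <- cov(Gi)
    reg <- 1e-6 * max(sum(diag(Si)), 1e-12) / dim_g
    Si <- Si + diag(reg, dim_g)
    Sinv[, , i] <- solve(Si)
  }
  list(mean_g = mean_g, Sinv = Sinv, k = k, n_entries = length(gs))
}

#' Attach grey-profile statistics to a shape model
#' @param model `active_shape_model`.
#' @param profile Result of [build_profile_model()].
#' @return The model with profiles attached.
#' @export
attach_profile_model <- function(model, profile) {
  model$profile <- profile
  model
}

#' Project a shape onto the model modes / reconstruct from coefficients
#'
#' `asm_project` computes `b = P^T (x - mean)`; `asm_reconstruct` computes
#' `mean + P b`. With all modes retained the round trip is exact; otherwise
#' it is the orthogonal projection onto the model subspace.
#'
#' @param model `active_shape_model`.
#' @param x Shape vector (length 2n) or n x 2 contour.
#' @param b Coefficient vector (length t).
#' @return `asm_project`: numeric vector b. `asm_reconstruct`: n x 2 contour
#'   in the model (aligned) frame.
#' @export
asm_project <- function(model, x) {
  if (is.matrix(x) && ncol(x) == 2) x <- contour_to_vec(x)
  if (length(x) != length(model$mean)) stop("shape dimension mismatch")
  as.vector(crossprod(model$P, x - model$mean))
}

#' @rdname asm_project
#' @export
asm_reconstruct <- function(model, b) {
  stopifnot(length(b) == model$t)
  vec_to_contour(model$mean + as.vector(model$P %*% b))
}

#' Clamp model coefficients to the plausible range
#'
#' Per-coordinate clipping to `[-m sqrt(lambda_i), m sqrt(lambda_i)]`;
#' idempotent.
#'
#' @param b Coefficient vector.
#' @param model `active_shape_model`.
#' @param m Clamp multiplier (defaults to the model's).
#' @return Clamped coefficient vector.
#' @export
asm_clamp <- function(b, model, m = model$m) {
  lim <- m * sqrt(model$lambda)
  pmin(pmax(b, -lim), lim)
}

#' Mahalanobis profile quality
#'
#' `d_M(g) = (g - mean_g)^T S_g^{-1} (g - mean_g)` with the regularized
#' inverse; zero at the mean profile.
#'
#' @param g Profile vector (length 2k).
#' @param mean_g Mean profile.
#' @param Sinv Regularized inverse covariance.
#' @return Scalar distance.
#' @export
profile_quality <- function(g, mean_g, Sinv) {
  d <- g - mean_g
  as.numeric(d %*% Sinv %*% d)
}

# --- fitting ----------------------------------------------------------------

#' Create a shape instance
#'
#' @param pose Similarity transform (list `ar`, `ai`, `tx`, `ty`) mapping
#'   the model frame into image coordinates.
#' @param b Coefficient vector.
#' @param model `active_shape_model`.
#' @return Object of class `shape_instance` with the realized contour.
#' @export
shape_instance <- function(pose, b, model) {
  contour <- apply_similarity(pose, asm_reconstruct(model, b))
  structure(list(pose = pose, b = b, contour = contour), class = "shape_instance")
}

#' Initialize a shape instance from an image-space contour
#'
#' Least-squares similarity alignment of the model mean to the contour,
#' followed by projection and clamping of the residual shape.
#'
#' @param model `active_shape_model`.
#' @param contour n x 2 contour in image coordinates, reference indexing.
#' @return `shape_instance`.
#' @export
instance_from_contour <- function(model, contour) {
  mu <- vec_to_contour(model$mean)
  pose <- fit_similarity(mu, contour)
  aligned <- apply_similarity(invert_similarity(pose), contour)
  b <- asm_clamp(asm_project(model, aligned), model)
  shape_instance(pose, b, model)
}

#' Fit an ASM instance to an image
#'
#' Runs `n_iter` iterations of the classic ASM loop: (a) for every
#' non-frozen landmark, evaluate the Mahalanobis profile distance at
#' `2l + 1` unit-spaced offsets along the contour normal and move to the
#' argmin (frozen landmarks -- e.g. inside an occlusion overlap -- stay in
#' place until the model constraints are applied); (b) fit the optimal
#' similarity pose to the suggested points; (c) project to coefficients,
#' clamp, reconstruct.
#'
#' @param model `active_shape_model` with profile statistics attached.
#' @param img Image (numeric matrix) to fit to.
#' @param init `shape_instance` initialization.
#' @param frozen Integer vector of landmark indices to freeze.
#' @param n_iter Number of iterations (the per-frame budget N_max).
#' @param search_l Search half-range l in px along the normal.
#' @return Fitted `shape_instance`.
#' @export
asm_fit <- function(model, img, init, frozen = integer(0),
                    n_iter = 60, search_l = 7) {
  if (is.null(model$profile)) stop("model has no grey-profile statistics; build them first")
  inst <- init
  for (iter in seq_len(n_iter)) {
    inst <- asm_fit_iteration(model, img, inst, frozen, search_l)
  }
  inst
}

# one ASM iteration (exposed internally for alternating two-animal fitting)
asm_fit_iteration <- function(model, img, inst, frozen, search_l) {
  k <- model$profile$k
  n <- model$n
  Y <- inst$contour
  normals <- contour_normals(Y)
  offsets <- -search_l:search_l
  q <- length(offsets)
  G <- sample_profiles(img, Y, normals, k, offsets)   # (n*q) x 2k
  best_off <- numeric(n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * q + 1):(i * q)
    D <- sweep(G[rows, , drop = FALSE], 2, model$profile$mean_g[i, ])
    dm <- rowSums((D %*% model$profile$Sinv[, , i]) * D)
    best_off[i] <- offsets[which.min(dm)]
  }
  if (length(frozen)) best_off[frozen] <- 0
  suggested <- Y + normals * best_off
  # pose update: optimal similarity from the model-frame shape to suggestions
  model_shape <- asm_reconstruct(model, inst$b)
  pose <- fit_similarity(model_shape, suggested)
  back <- apply_similarity(invert_similarity(pose), suggested)
  b <- asm_clamp(asm_project(model, back), model)
  shape_instance(pose, b, model)
}

# --- persistence ------------------------------------------------------------

#' Save / load a trained model archive
#' @param model `active_shape_model`.
#' @param path File path (`.rds`).
#' @return `read_model` returns the model; `write_model` the path, invisibly.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
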