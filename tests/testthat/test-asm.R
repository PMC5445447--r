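# a small synthetic point-distribution model: mean ellipse + two known
# orthonormal variation modes
make_linear_shapes <- function(s, n = 50, sd1 = 6, sd2 = 2.5, seed = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  mean_shape <- cbind(40 * cos(th), 18 * sin(th))
  v1 <- cbind(cos(th) * sin(2 * th), sin(th) * cos(th))   # arbitrary smooth modes
  v2 <- cbind(sin(3 * th), cos(2 * th))
  p1 <- shapetrack:::contour_to_vec(v1); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- shapetrack:::contour_to_vec(v2)
  p2 <- p2 - sum(p2 * p1) * p1; p2 <- p2 / sqrt(sum(p2^2))
  mu <- shapetrack:::contour_to_vec(mean_shape)
  set.seed(seed)
  # scores scaled to exact generator variances so the oracle is noise-free
  b1 <- as.numeric(scale(rnorm(s))) * sd1
  b2 <- as.numeric(scale(rnorm(s))) * sd2
  X <- t(vapply(seq_len(s), function(i) mu + b1[i] * p1 + b2[i] * p2,
                numeric(2 * n)))
  list(X = X, mu = mu, p1 = p1, p2 = p2, sd1 = sd1, sd2 = sd2,
       b1 = b1, b2 = b2)
}

test_that("shape model recovers a known two-mode linear model", {
  g <- make_linear_shapes(200, n = 100)
  model <- build_shape_model(g$X, f_v = 0.98, m = 3)
  expect_equal(model$t, 2)
  expect_equal(as.numeric(model$mean), g$mu, tolerance = 0.5)
  # principal angles between true and learned 2-D subspaces < 5 degrees
  Vt <- cbind(g$p1, g$p2)
  Vl <- model$P
  sv <- svd(crossprod(Vt, Vl))$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 5)
  # eigenvalue ratios within 10% of the generator variances
  expect_lt(abs(model$lambda[1] / g$sd1^2 - 1), 0.1)
  expect_lt(abs(model$lambda[2] / g$sd2^2 - 1), 0.1)
  # leading mode tracks the dominant generator coefficient
  b_fit <- apply(g$X, 1, function(x) asm_project(model, x)[1])
  expect_gt(abs(cor(b_fit, g$b1)), 0.99)
})

test_that("degenerate and hand-checked retained-mode counts", {
  same <- matrix(rep(c(0, 0, 1, 0, 1, 1, 0, 1), each = 5), nrow = 5)
  m0 <- build_shape_model(same, f_v = 0.98)
  expect_equal(m0$t, 1)                        # bounded below at one mode
  expect_lt(sum(m0$lambda_all), 1e-18)
  expect_equal(as.numeric(m0$mean), c(0, 0, 1, 0, 1, 1, 0, 1))

  # variances ~ (4, 3, 2, 1) with f_v = 0.5 -> t = 2 (0.4 < 0.5 <= 0.7)
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  Z <- scale(matrix(rnorm(4000 * 4), ncol = 4))  # unit-variance scores
  X <- Z %*% diag(c(2, sqrt(3), sqrt(2), 1)) %*% t(Q[, 1:4])
  mdl <- build_shape_model(X, f_v = 0.5)
  expect_equal(mdl$t, 2)
  # retained count matches a brute-force scan over all prefixes
  t_brute <- min(which(cumsum(mdl$lambda_all) >= 0.5 * sum(mdl$lambda_all)))
  expect_equal(mdl$t, t_brute)

  expect_error(build_shape_model(same[1:2, ]), "at least 3")
})

test_that("eigenvectors are orthonormal and projection round-trips", {
  g <- make_linear_shapes(50, n = 30, seed = 4)
  model <- build_shape_model(g$X, f_v = 1)     # full rank retained
  P <- model$P
  expect_lt(max(abs(crossprod(P) - diag(ncol(P)))), 1e-8)

  expect_equal(asm_project(model, as.numeric(model$mean)),
               rep(0, model$t))
  b <- rep(0, model$t)
  b[1] <- 2 * sqrt(model$lambda[1])
  x <- model$mean + as.numeric(model$P %*% b)
  expect_equal(asm_project(model, x), b, tolerance = 1e-9)

  x_rand <- g$X[7, ]
  expect_lt(sqrt(sum((shapetrack:::contour_to_vec(
    asm_reconstruct(model, asm_project(model, x_rand))) - x_rand)^2)), 1e-9)
  expect_error(asm_project(model, rnorm(10)), "mismatch")
})

test_that("coefficient clamping clips to the mode box and is idempotent", {
  g <- make_linear_shapes(50, n = 20, seed = 6)
  model <- build_shape_model(g$X)
  b <- 5 * sqrt(model$lambda)
  b_cl <- asm_clamp(b, model, m = 3)
  expect_equal(b_cl, 3 * sqrt(model$lambda))
  inside <- 0.5 * sqrt(model$lambda)
  expect_equal(asm_clamp(inside, model, 3), inside)
  set.seed(8)
  for (i in 1:5) {
    br <- rnorm(model$t, 0, 10)
    expect_equal(asm_clamp(asm_clamp(br, model), model),
                 asm_clamp(br, model))
  }
})

test_that("profile statistics and Mahalanobis quality", {
  expect_equal(profile_quality(c(1, 2), c(1, 2), diag(2)), 0)
  g <- c(1, 3); mu <- c(0, 1)
  expect_equal(profile_quality(g, mu, diag(2)), sum((g - mu)^2))
  set.seed(10)
  sig <- runif(6, 0.5, 3)
  gg <- rnorm(6); mm <- rnorm(6)
  expect_equal(profile_quality(gg, mm, diag(1 / sig)),
               sum((gg - mm)^2 / sig), tolerance = 1e-12)
})

test_that("profile model learns a step edge and guards flat profiles", {
  ref <- cached("ref", make_test_reference())
  rc <- cached("rc_straight", rasterized_mouse_contour())
  cat0 <- new_catalog(ref)
  for (i in 1:3) {
    res <- match_to_reference(rc$contour, ref, tail_hint = rc$tail_hint)
    aligned <- gate_and_align(res$corresponded, ref$landmarks, res$H, Inf)
    patch <- shapetrack:::crop_patch(rc$img, res$corresponded, 16L)
    cat0 <- catalog_add(cat0, aligned, res$corresponded, res$H, i, patch)
  }
  prof <- build_profile_model(cat0, k = 5)
  expect_equal(prof$n_entries, 3)
  # identical entries: mean profile is the normalized step derivative and it
  # peaks at the boundary crossing
  expect_true(all(is.finite(prof$mean_g)))
  peak <- apply(abs(prof$mean_g), 1, which.max)
  expect_true(mean(peak %in% 4:7) > 0.9)

  # flat image: normalization guard returns zeros, not NaN
  flat <- matrix(100, 60, 60)
  pts <- cbind(rep(30, 5), 26:30)
  nrm <- cbind(rep(1, 5), rep(0, 5))
  G <- shapetrack:::sample_profiles(flat, pts, nrm, k = 5)
  expect_true(all(G == 0))

  expect_error(build_profile_model(new_catalog(ref), 5), "at least 2")
})

test_that("profile covariance tracks i.i.d. noise variance", {
  # noisy step profiles: diagonal of S_g approx derivative-propagated noise
  set.seed(12)
  k <- 5; sigma <- 2
  n_entries <- 500
  base <- c(rep(200, k), rep(40, k + 1))
  G <- t(vapply(seq_len(n_entries), function(i) {
    v <- base + rnorm(2 * k + 1, 0, sigma)
    d <- diff(v)
    d / sum(abs(d))
  }, numeric(2 * k)))
  S <- cov(G)
  # expected: derivative doubles the variance, normalization divides by
  # ~(step height)^2; check within 20%
  nrm <- 160 + 2 * 2 * k * sigma * sqrt(2 / pi) / 2   # approximate |.| sum
  expected <- 2 * sigma^2 / nrm^2
  off_step <- setdiff(seq_len(2 * k), c(k, k + 1))
  expect_lt(abs(mean(diag(S)[off_step]) / expected - 1), 0.2)
})

test_that("ASM fitting is a fixed point on its own rendering and recovers shifts", {
  sim <- cached("asm_fit_sim", {
    ref <- make_test_reference()
    # small catalog of rasterized mice with varied bend
    cat0 <- new_catalog(ref)
    set.seed(16)
    rcs <- lapply(c(-25, -15, -5, 0, 5, 15, 25, -20, 10, 20),
                  function(b) rasterized_mouse_contour(bend = b,
                                                       heading = runif(1, 0, 360)))
    for (rc in rcs) {
      res <- match_to_reference(rc$contour, ref, tail_hint = rc$tail_hint)
      aligned <- gate_and_align(res$corresponded, ref$landmarks, res$H, Inf)
      patch <- shapetrack:::crop_patch(rc$img, res$corresponded, 16L)
      cat0 <- catalog_add(cat0, aligned, res$corresponded, res$H, 1, patch)
    }
    model <- build_shape_model(cat0)
    model <- attach_profile_model(model, build_profile_model(cat0, k = 5))
    target <- rasterized_mouse_contour(bend = 8, heading = 120)
    res_t <- match_to_reference(target$contour, ref, tail_hint = target$tail_hint)
    init <- instance_from_contour(model, res_t$corresponded)
    list(model = model, target = target, init = init)
  })
  model <- sim$model; init <- sim$init; img <- sim$target$img
  ref <- cached("ref", make_test_reference())

  # profiles trained at the instance's own realized contour make it an
  # exact fixed point of the search: all argmins sit at offset zero
  cat_fp <- new_catalog(ref)
  al <- shapetrack:::align_vertical(init$contour, ref$landmarks)
  for (i in 1:3) {
    cat_fp <- catalog_add(cat_fp, al, init$contour, 0, i,
                          shapetrack:::crop_patch(img, init$contour, 16L))
  }
  model_fp <- attach_profile_model(model, build_profile_model(cat_fp, k = 5))
  fit_fp <- asm_fit(model_fp, img, init, n_iter = 5)
  expect_lt(max(abs(fit_fp$contour - init$contour)), 1e-6)

  # on a realistically trained profile model, fitting stays near the match
  fit0 <- asm_fit(model, img, init, n_iter = 60)
  expect_lt(sqrt(mean((fit0$contour - init$contour)^2)), 1.5)

  # 3 px offset init converges back onto the target (< 0.5 px RMS from the
  # unshifted fit, i.e. the shift is fully recovered)
  off <- init
  off$pose$tx <- off$pose$tx + 3
  off <- shape_instance(off$pose, off$b, model)
  fit <- asm_fit(model, img, off, n_iter = 60)
  expect_lt(sqrt(mean((fit$contour - fit0$contour)^2)), 0.5)
  # clamp constraint holds exactly after fitting
  expect_true(all(abs(fit$b) <= model$m * sqrt(model$lambda) + 1e-12))

  # all landmarks frozen: no profile motion, shape unchanged up to clamping
  fit_frozen <- asm_fit(model, img, init, frozen = seq_len(model$n), n_iter = 3)
  expect_lt(max(abs(fit_frozen$contour - init$contour)), 1e-6)
})
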