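test_that("contour resampling places points at equal arc length", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(resample_contour(square, 8)[c(1, 3, 5, 7), ], square)

  # circle: consecutive gaps equal within 1%
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(50 * cos(th), 50 * sin(th))
  rs <- resample_contour(circle, 100)
  gaps <- sqrt(rowSums((rs - rbind(rs[-1, ], rs[1, ]))^2))
  expect_lt((max(gaps) - min(gaps)) / mean(gaps), 0.01)

  # idempotence on a smooth contour
  rs2 <- resample_contour(rs, 100)
  expect_lt(max(abs(rs2 - rs)), 0.01 * mean(gaps))

  expect_error(resample_contour(square, 4), "at least 8")
})

test_that("inner geometry matches Euclid on convex shapes and exceeds it generally", {
  set.seed(101)
  poly <- random_convex_polygon(15)
  ig <- inner_geometry(poly)
  expect_equal(ig$dist, unname(as.matrix(dist(poly))), tolerance = 1e-12)
  expect_true(all(diag(ig$dist) == 0))

  u <- u_polygon()
  igu <- inner_geometry(u)
  # prong tips (vertices 3 and 7): path must round the bend
  d_euclid <- sqrt(sum((u[3, ] - u[7, ])^2))
  expect_gt(igu$dist[3, 7], d_euclid + 10)
  expect_equal(igu$dist, inner_distance_oracle(u), tolerance = 1e-9)

  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(inner_geometry(bowtie), "self-intersecting")
})

test_that("inner distance >= Euclidean with equality on convex polygons", {
  set.seed(7)
  for (i in 1:5) {
    poly <- random_simple_polygon(30)
    ig <- inner_geometry(poly)
    expect_true(all(ig$dist - as.matrix(dist(poly)) > -1e-9))
    expect_true(isSymmetric(unname(ig$dist)))
  }
})

test_that("shape context histograms count all other points", {
  set.seed(11)
  poly <- random_simple_polygon(40)
  sc <- shape_context(poly)
  expect_true(all(rowSums(sc$hist) == 39))
  expect_true(all(sc$hist >= 0))

  # scale invariance through mean-distance normalization
  sc2 <- shape_context(poly * 2)
  expect_equal(sc$hist, sc2$hist)
})

test_that("shape context equals a brute-force bin assignment", {
  poly <- random_convex_polygon(9, r = 30)
  n_r <- 3; n_theta <- 4
  sc <- shape_context(poly, n_r = n_r, n_theta = n_theta)
  # oracle: recompute bins directly from the definition
  g <- inner_geometry(poly)
  mean_d <- mean(g$dist[upper.tri(g$dist)])
  edges <- exp(seq(log(0.125), log(2), length.out = n_r + 1))
  for (i in seq_len(nrow(poly))) {
    h <- numeric(n_r * n_theta)
    for (j in seq_len(nrow(poly))) {
      if (j == i) next
      r <- g$dist[i, j] / mean_d
      rb <- min(max(findInterval(r, edges), 1), n_r)
      tb <- min(max(ceiling((g$angle[i, j] + 180) / (360 / n_theta)), 1), n_theta)
      k <- (rb - 1) * n_theta + tb
      h[k] <- h[k] + 1
    }
    expect_equal(unname(sc$hist[i, ]), h)
  }
})

test_that("chi-squared cost behaves per definition", {
  expect_equal(chi2_cost(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(chi2_cost(c(1, 0), c(0, 1)), 1)
  expect_equal(chi2_cost(c(0, 0), c(0, 0)), 0)   # empty bins contribute 0
  set.seed(5)
  for (i in 1:10) {
    a <- rpois(12, 3); b <- rpois(12, 3)
    expect_equal(chi2_cost(a, b), chi2_cost(b, a))
    expect_gte(chi2_cost(a, b), 0)
  }
})

test_that("optimal matching solves the assignment exactly", {
  set.seed(21)
  poly <- random_simple_polygon(20)
  sc <- shape_context(poly)
  m_self <- match_shapes(sc, sc)
  expect_equal(m_self$perm, 1:20)
  expect_equal(m_self$H, 0)

  # cyclic shift recovered with zero cost
  s <- 7
  shifted <- poly[c((s + 1):20, 1:s), ]
  m_shift <- match_shapes(sc, shape_context(shifted))
  expect_equal(m_shift$H, 0, tolerance = 1e-12)
  expect_equal(m_shift$perm, ((1:20 - 1 - s) %% 20) + 1)

  expect_error(match_shapes(sc, shape_context(random_simple_polygon(15))),
               "different point counts")
})

test_that("assignment equals brute force and igraph on random costs", {
  perms6 <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms6 <- perms6[apply(perms6, 1, function(p) !anyDuplicated(p)), ]
  set.seed(33)
  for (i in 1:50) {
    C <- matrix(runif(36), 6, 6)
    perm <- shapetrack:::assignment_cpp(C)
    H <- sum(C[cbind(1:6, perm)])
    brute <- min(apply(perms6, 1, function(p) sum(C[cbind(1:6, p)])))
    expect_equal(H, brute, tolerance = 1e-12)
  }
  # independent cross-check on a larger instance via igraph
  C <- matrix(runif(30 * 30), 30, 30)
  perm <- shapetrack:::assignment_cpp(C)
  W <- max(C) + 1 - C
  g <- igraph::graph_from_biadjacency_matrix(W, weighted = TRUE)
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  perm_ig <- as.integer(sub("V", "", mm$matching[1:30])) - 30L
  expect_equal(sum(C[cbind(1:30, perm)]), sum(C[cbind(1:30, perm_ig)]),
               tolerance = 1e-9)
})

test_that("descriptors are invariant to rigid motion of the contour", {
  set.seed(55)
  poly <- random_simple_polygon(30)
  sc <- shape_context(poly)
  moved <- rotate_polygon(poly, 73) + 11.5
  m <- match_shapes(sc, shape_context(moved))
  other <- match_shapes(sc, shape_context(random_simple_polygon(30)))
  expect_lt(m$H, 1e-6 * other$H + 1e-9)
})
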