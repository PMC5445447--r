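test_that("illumination normalization rescales to the target mean", {
  u <- matrix(100, 10, 10)
  expect_equal(normalize_illumination(u, 128), matrix(128, 10, 10))

  half <- matrix(c(rep(50, 50), rep(150, 50)), 10, 10)
  out <- normalize_illumination(half, 128)
  expect_equal(mean(out), 128)
  # direct per-pixel arithmetic: mean 100 scaled by 1.28
  expect_equal(sort(unique(as.vector(out))), c(64, 192))

  at_target <- matrix(runif(100, 50, 200), 10, 10)
  at_target <- normalize_illumination(at_target, 128)
  expect_equal(normalize_illumination(at_target, 128), at_target)

  expect_error(normalize_illumination(matrix(0, 5, 5)), "degenerate")
})

test_that("background is the pixel-wise temporal median", {
  static <- matrix(runif(400, 0, 255), 20, 20)
  bg <- build_background(list(static, static, static))
  expect_equal(bg$median_image, static)

  f1 <- matrix(10, 4, 4); f2 <- matrix(20, 4, 4); f3 <- matrix(200, 4, 4)
  expect_equal(build_background(list(f1, f2, f3))$median_image[2, 2], 20)

  # moving dark object covering each pixel in < 50% of frames
  frames <- lapply(1:101, function(i) {
    f <- matrix(200, 40, 120)
    x0 <- 1 + ((i - 1) %% 92)
    f[16:25, x0:(x0 + 9)] <- 30
    f
  })
  bg2 <- build_background(frames)
  expect_equal(bg2$median_image, matrix(200, 40, 120))

  expect_error(build_background(list()), "empty")
  expect_error(build_background(list(f1, f2)), "at least 3")
  expect_error(build_background(list(f1, matrix(1, 5, 5), f2)), "dimensions")
})

test_that("foreground segmentation thresholds the difference image", {
  bg <- build_background(rep(list(matrix(200, 60, 60)), 3))
  expect_false(any(segment_foreground(matrix(200, 60, 60), bg)))

  frame <- matrix(200, 60, 60)
  frame[21:40, 21:40] <- 40
  m_fixed <- segment_foreground(frame, bg, threshold = 80)
  expect_equal(which(m_fixed), which(frame == 40))

  # automatic mode against an exhaustive between-class-variance search
  m_auto <- segment_foreground(frame, bg, threshold = "auto")
  expect_equal(which(m_auto), which(frame == 40))
  d <- abs(frame - bg$median_image)
  bcv <- vapply(1:254, function(t) {
    g <- d > t
    w1 <- mean(g); w0 <- 1 - w1
    if (w1 == 0 || w0 == 0) return(0)
    w0 * w1 * (mean(d[g]) - mean(d[!g]))^2
  }, numeric(1))
  t_star <- which.max(bcv)
  expect_equal(which(d > t_star), which(m_auto))
})

test_that("blob extraction keeps 8-connected components above b_min", {
  m <- matrix(FALSE, 40, 40)
  m[2:3, 2:6] <- TRUE                      # area 10
  m[11:30, 11:20] <- TRUE                  # area 200
  blobs <- extract_blobs(m, b_min = 50)
  expect_length(blobs, 1)
  expect_equal(blobs[[1]]$area, 200)

  expect_length(extract_blobs(matrix(FALSE, 5, 5), 1), 0)

  # touching at a corner: one blob under 8-connectivity (flood-fill oracle)
  corner <- matrix(FALSE, 10, 10)
  corner[2:4, 2:4] <- TRUE
  corner[5:7, 5:7] <- TRUE
  expect_length(extract_blobs(corner, 1), 1)

  # partition property: blob areas sum to the mask area when b_min = 1
  set.seed(42)
  rnd <- matrix(runif(900) < 0.3, 30, 30)
  blobs_all <- extract_blobs(rnd, 1)
  expect_equal(sum(vapply(blobs_all, `[[`, numeric(1), "area")), sum(rnd))
  blobs_min <- extract_blobs(rnd, 5)
  expect_lte(sum(vapply(blobs_min, `[[`, numeric(1), "area")), sum(rnd))

  # boundaries are closed clockwise chains
  b <- blobs[[1]]$boundary
  expect_true(all(abs(diff(rbind(b, b[1, ]))) <= 1))
  expect_gt(shapetrack:::polygon_area_signed(b), 0)
})

test_that("tail localization by morphological opening", {
  # solid ellipse, no appendage
  yy <- row(matrix(0, 60, 80)); xx <- col(matrix(0, 60, 80))
  ell <- ((xx - 40) / 30)^2 + ((yy - 30) / 15)^2 <= 1
  lt <- locate_tail(ell, r_S = 4)
  expect_null(lt$tail_base)
  expect_gt(sum(lt$body_mask), 0.8 * sum(ell))

  # ellipse with a thin attached strip: tail base near the junction
  strip <- matrix(FALSE, 60, 120)
  strip[, 1:80][ell] <- TRUE
  strip[29:31, 70:110] <- TRUE
  lt2 <- locate_tail(strip, r_S = 4)
  expect_false(is.null(lt2$tail_base))
  junction <- c(69, 30)                    # strip meets the ellipse boundary
  expect_lt(sqrt(sum((lt2$tail_base - junction)^2)), 4)

  # strip only: no body after opening
  only <- matrix(FALSE, 20, 60)
  only[10:12, 5:55] <- TRUE
  expect_null(locate_tail(only, r_S = 4)$tail_base)

  # tail-free convex blob never reports a tail for small r_S
  for (r in c(2, 4)) expect_null(locate_tail(ell, r_S = r)$tail_base)
})
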