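test_that("viewing direction follows the ear-midpoint-to-nose vector", {
  expect_equal(viewing_direction(c(0, 10), c(-2, 0), c(2, 0)), 90)
  expect_equal(viewing_direction(c(5, 0), c(0, 1), c(0, -1)), 0)
  # rotation equivariance
  set.seed(3)
  for (i in 1:10) {
    pts <- matrix(runif(6, -10, 10), 3, 2)
    phi0 <- viewing_direction(pts[1, ], pts[2, ], pts[3, ])
    rot <- rotate_polygon(pts, 30, center = c(0, 0))
    phi1 <- viewing_direction(rot[1, ], rot[2, ], rot[3, ])
    expect_equal(angle_diff(phi1, phi0 + 30), 0, tolerance = 1e-9)
  }
  expect_error(viewing_direction(c(0, 0), c(-1, 0), c(1, 0)), "midpoint")
  expect_error(viewing_direction(c(1, 1), c(2, 2), c(2, 2)), "distinct")
})

test_that("landmark transfer is exact on self-match and disambiguated by the tail hint", {
  ref <- cached("ref", make_test_reference())
  rc <- cached("rc_straight", rasterized_mouse_contour())
  res <- match_to_reference(ref$contour, ref, tail_hint = rc$tail_hint)
  expect_equal(res$H, 0)
  expect_false(res$flipped)
  expect_equal(res$landmarks$nose, unname(ref$contour[ref$landmarks$nose, ]))
  expect_equal(res$landmarks$tail_base,
               unname(ref$contour[ref$landmarks$tail_base, ]))

  # 180-degree rotated copy: the hint must keep nose and tail unswapped
  rot <- rotate_polygon(ref$contour, 180)
  true_tail <- rotate_polygon(ref$contour[ref$landmarks$tail_base, , drop = FALSE],
                              180, center = colMeans(ref$contour))
  res_rot <- match_to_reference(rot, ref, tail_hint = as.numeric(true_tail))
  expect_lt(sqrt(sum((res_rot$landmarks$tail_base - as.numeric(true_tail))^2)), 6)

  expect_error(match_to_reference(ref$contour, ref), "disambiguate")
})

test_that("orientation hint picks the nearer body-axis angle", {
  ref <- cached("ref", make_test_reference())
  rot <- rotate_polygon(ref$contour, 35)
  res <- match_to_reference(rot, ref, prev_orientation =
                              shapetrack:::body_axis_angle(lapply(
                                ref$landmarks, function(i) ref$contour[i, ])) - 35)
  axis <- shapetrack:::body_axis_angle(res$landmarks)
  # the chosen orientation lies within 90 degrees of the previous one
  prev <- shapetrack:::body_axis_angle(lapply(ref$landmarks,
                                              function(i) ref$contour[i, ])) - 35
  expect_lt(angle_diff(axis, prev), 90)
})

test_that("catalog gate is strict and alignment is vertical, nose down", {
  ref <- cached("ref", make_test_reference())
  ct <- ref$contour
  expect_false(is.null(gate_and_align(ct, ref$landmarks, 119.9, 120)))
  expect_null(gate_and_align(ct, ref$landmarks, 120, 120))

  aligned <- gate_and_align(ct, ref$landmarks, 10, 120)
  nose <- aligned[ref$landmarks$nose, ]
  tail <- aligned[ref$landmarks$tail_base, ]
  expect_equal(nose[1], tail[1], tolerance = 1e-9)
  expect_gt(nose[2], tail[2])                    # nose points image-down
  expect_equal(as.numeric((nose + tail) / 2), c(0, 0), tolerance = 1e-9)
})

test_that("rho calibration hits the target acceptance fraction", {
  rho <- calibrate_rho(1:100, 0.5)
  expect_equal(mean(1:100 < rho), 0.5)

  rho_hi <- calibrate_rho(1:100, 0.999)
  expect_gt(rho_hi, 100)

  set.seed(9)
  for (i in 1:10) {
    costs <- rexp(57, 1 / 50)
    c_v <- runif(1, 0.1, 0.9)
    rho <- calibrate_rho(costs, c_v)
    expect_lte(abs(mean(costs < rho) - c_v), 1 / length(costs) + 1e-12)
  }
  expect_error(calibrate_rho(1:5, 0.5), ">= 10")
})

test_that("catalog entries are stackable with frozen landmark indexing", {
  ref <- cached("ref", make_test_reference())
  cat0 <- new_catalog(ref, max_entries = 10)
  set.seed(14)
  for (bend in c(-20, 0, 15)) {
    rc <- rasterized_mouse_contour(bend = bend, heading = runif(1, 0, 360))
    res <- match_to_reference(rc$contour, ref, tail_hint = rc$tail_hint)
    aligned <- gate_and_align(res$corresponded, ref$landmarks, res$H, Inf)
    cat0 <- catalog_add(cat0, aligned, res$corresponded, res$H, frame = 1)
  }
  expect_length(cat0, 3)
  ns <- vapply(cat0$entries, function(e) nrow(e$aligned), integer(1))
  expect_true(all(ns == ref$n))
  # vertical alignment: nose.x - tail.x identically zero across the catalog
  dx <- vapply(cat0$entries, function(e) {
    e$aligned[ref$landmarks$nose, 1] - e$aligned[ref$landmarks$tail_base, 1]
  }, numeric(1))
  expect_equal(var(dx), 0, tolerance = 1e-18)
})

test_that("reference round-trips through JSON", {
  ref <- cached("ref", make_test_reference())
  path <- tempfile(fileext = ".json")
  write_reference(ref, path)
  ref2 <- read_reference(path)
  expect_equal(ref2$contour, ref$contour, tolerance = 1e-12)
  expect_equal(ref2$landmarks, ref$landmarks)
})
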