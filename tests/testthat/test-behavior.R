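# constructed two-animal track rows for predicate checks
mk_track <- function(noseA, tailA, phiA, noseB, tailB, phiB, n = 20,
                     overlap = 0) {
  dplyr::bind_rows(lapply(seq_len(n), function(f) tibble::tibble(
    frame = f, animal_id = c("A", "B"), regime = "separated",
    nose_x = c(noseA[1], noseB[1]), nose_y = c(noseA[2], noseB[2]),
    tail_x = c(tailA[1], tailB[1]), tail_y = c(tailA[2], tailB[2]),
    phi_deg = c(phiA, phiB), overlap_frac = overlap)))
}

test_that("positional conditions fire on constructed geometries", {
  cfg <- default_config()
  # body length 100 px; noses 12 px apart (< 0.25 BL): C1 active
  tr <- mk_track(c(0, 0), c(-100, 0), 0, c(12, 0), c(112, 0), 180)
  fl <- classify_social(tr, cfg)
  expect_true(all(fl$c1))
  expect_false(any(fl$c3))

  # animals 10 body lengths apart: nothing fires
  far <- mk_track(c(0, 0), c(-100, 0), 0, c(1000, 0), c(1100, 0), 180)
  ff <- classify_social(far, cfg)
  expect_false(any(ff$c1 | ff$c2_A | ff$c2_B | ff$c3 |
                     ff$c4_A | ff$c4_B | ff$c5_A | ff$c5_B))

  # B's nose at A's tail: C2_B (directional), not C2_A
  an <- mk_track(c(0, 0), c(-100, 0), 0, c(-115, 0), c(-215, 0), 0)
  fa <- classify_social(an, cfg)
  expect_true(all(fa$c2_B))
  expect_false(any(fa$c2_A))
  # sustained aligned trailing also counts as following
  expect_true(all(fa$c4_B))

  # side-by-side: close centers, antiparallel headings
  sb <- mk_track(c(0, 0), c(-100, 0), 0, c(-100, 40), c(0, 40), 180)
  fs <- classify_social(sb, cfg)
  expect_true(all(fs$c3))

  # mating: large overlap with aligned headings; mounting animal is behind
  mt <- mk_track(c(0, 0), c(-100, 0), 0, c(-20, 6), c(-120, 6), 5,
                 overlap = 0.6)
  fm <- classify_social(mt, cfg)
  expect_true(all(fm$c5_B))
  expect_false(any(fm$c5_A))
})

test_that("predicate symmetry: C1/C3 symmetric, C2 directional", {
  cfg <- default_config()
  tr <- mk_track(c(0, 0), c(-100, 0), 0, c(12, 0), c(112, 0), 180)
  sw <- tr
  sw$animal_id <- ifelse(tr$animal_id == "A", "B", "A")
  fl <- classify_social(tr, cfg); fs <- classify_social(sw, cfg)
  expect_equal(fl$c1, fs$c1)
  expect_equal(fl$c3, fs$c3)

  an <- mk_track(c(0, 0), c(-100, 0), 0, c(-115, 0), c(-215, 0), 0)
  answ <- an
  answ$animal_id <- ifelse(an$animal_id == "A", "B", "A")
  f1 <- classify_social(an, cfg); f2 <- classify_social(answ, cfg)
  expect_equal(f1$c2_B, f2$c2_A)
  expect_equal(f1$c2_A, f2$c2_B)
})

test_that("frame flags aggregate into events with smoothing and a minimum duration", {
  # 000111100, min 3 frames, no smoothing -> one event, frames 4-7
  ev <- frames_to_events(c(0, 0, 0, 1, 1, 1, 1, 0, 0) == 1, fps = 1,
                         min_duration_s = 3, smooth_window = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start_frame, ev$end_frame), c(4, 7))
  expect_equal(ev$duration_s, 4)

  # 0011000, min 3 -> too short, no events
  ev2 <- frames_to_events(c(0, 0, 1, 1, 0, 0, 0) == 1, fps = 1,
                          min_duration_s = 3, smooth_window = 1)
  expect_equal(nrow(ev2), 0)

  # 0110111 with window-3 majority vote -> hand-enumerated smoothing
  flags <- c(0, 1, 1, 0, 1, 1, 1) == 1
  sm_oracle <- vapply(seq_along(flags), function(i) {
    w <- flags[max(1, i - 1):min(7, i + 1)]
    if (i == 1) w <- c(flags[1], w)
    if (i == 7) w <- c(w, flags[7])
    sum(w) > 1
  }, logical(1))
  ev3 <- frames_to_events(flags, fps = 1, min_duration_s = 0, smooth_window = 3)
  ev_oracle <- frames_to_events(sm_oracle, fps = 1, min_duration_s = 0,
                                smooth_window = 1)
  expect_equal(ev3, ev_oracle)
  expect_equal(nrow(ev3), 1)              # single merged event

  # idempotence on its own output flags
  out_flags <- rep(FALSE, 7)
  for (j in seq_len(nrow(ev3))) out_flags[ev3$start_frame[j]:ev3$end_frame[j]] <- TRUE
  ev4 <- frames_to_events(out_flags, fps = 1, min_duration_s = 0,
                          smooth_window = 3)
  expect_equal(ev4$start_frame, ev3$start_frame)
  expect_equal(ev4$end_frame, ev3$end_frame)
})

test_that("duration error follows the relative-absolute definition", {
  expect_equal(duration_error(5, 4), 0.25)
  expect_equal(duration_error(4, 4), 0)
  expect_equal(duration_error(0, 9), 1)      # never-recognized convention
  expect_equal(duration_error(0, 0), 0)
  expect_warning(e <- duration_error(2, 0), "undefined")
  expect_true(is.na(e))
})

test_that("grooming SVM separates labeled clusters under interval-wise CV", {
  set.seed(41)
  n <- 400
  groom <- rep(c(FALSE, TRUE), each = n / 2)
  b2 <- ifelse(groom, rnorm(n, -6, 1), rnorm(n, 2, 1))
  feats <- cbind(rnorm(n, 0, 2), b2, rnorm(n, 0, 1))
  ord <- sample(n)
  feats <- feats[ord, ]; groom <- groom[ord]
  intervals <- rep(1:5, length.out = n)
  pr <- detect_grooming(feats, groom, intervals, seed = 41)
  expect_gte(balanced_accuracy(pr$pred, pr$label), 0.95)

  # single-class labels are rejected
  expect_error(detect_grooming(feats, rep(FALSE, n), intervals), "both classes")

  # determinism given a fixed seed
  pr2 <- detect_grooming(feats, groom, intervals, seed = 41)
  expect_identical(pr$pred, pr2$pred)
})
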