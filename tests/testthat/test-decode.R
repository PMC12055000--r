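test_that("encode then decode recovers keypoints to within 1e-6 * stride", {
  sk <- toy_skeleton()
  cfg <- toy_cfg()
  for (seed in 1:50) {
    fr <- generate_scene(scene_spec(seed = 2000 + seed))
    tg <- make_target_maps(fr, sk, cfg)
    det <- decode_single(list(heatmap = tg$heatmap, locref = tg$locref), cfg)
    expect_true(all(det$valid))
    err <- abs(as.matrix(det[, c("x", "y")]) - fr$instances[[1]]$keypoints)
    expect_lt(max(err), 1e-6 * cfg$stride)
    # peak-cell value exp(-d^2 / 2 sigma^2) for the sub-cell offset d:
    # always well above the detection cutoff on oracle heads
    expect_true(all(det$detected))
  }
})

test_that("a keypoint on a cell reference point decodes to cell * stride exactly", {
  cfg <- toy_cfg()
  hm <- array(0, c(6, 6, 1)); hm[3 + 1, 2 + 1, 1] <- 1
  lr <- array(0, c(6, 6, 2))
  det <- decode_single(list(heatmap = hm, locref = lr), cfg)
  expect_identical(det$x, 2 * 8)
  expect_identical(det$y, 3 * 8)
})

test_that("confidence at or below the cutoff is not a detection", {
  cfg <- toy_cfg()
  hm <- array(0, c(4, 4, 2))
  hm[2, 2, 1] <- 0.15   # below cutoff
  hm[3, 3, 2] <- 0.21   # above cutoff
  det <- decode_single(list(heatmap = hm, locref = array(0, c(4, 4, 4))), cfg)
  expect_false(det$detected[1])
  expect_true(det$detected[2])
  # an all-zero channel is invalid with confidence 0
  hm0 <- array(0, c(4, 4, 1))
  det0 <- decode_single(list(heatmap = hm0, locref = array(0, c(4, 4, 2))), cfg)
  expect_false(det0$valid[1])
  expect_false(det0$detected[1])
  expect_equal(det0$confidence[1], 0)
})

test_that("decoded coordinates are rescaled back to full resolution", {
  cfg <- adpt_config(stride = 8, sigma = 1.2, global_scale = 0.5)
  hm <- array(0, c(4, 4, 1)); hm[2, 3, 1] <- 1
  lr <- array(0, c(4, 4, 2)); lr[2, 3, 1] <- 1.5; lr[2, 3, 2] <- -1
  det <- decode_single(list(heatmap = hm, locref = lr), cfg)
  expect_equal(det$x, (2 * 8 + 1.5) / 0.5)
  expect_equal(det$y, (1 * 8 - 1) / 0.5)
})

test_that("frame identity is the argmax of per-channel LRSS mass", {
  cfg <- social_cfg()
  # map containing only identity-2 pixels
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 2L
  expect_equal(identity_of_frame(lab, cfg), 2L)
  # 60 px of identity 1 vs 40 of identity 2 at unit probability
  p <- array(0, c(10, 10, 3))
  p[, , 2][seq_len(60)] <- 1
  p[, , 3][61:100] <- 1
  expect_equal(identity_of_frame(p, cfg), 1L)
  # exact tie goes to the lowest label
  p2 <- array(0, c(10, 10, 3))
  p2[, , 2][1:40] <- 1
  p2[, , 3][41:80] <- 1
  expect_equal(identity_of_frame(p2, cfg), 1L)
  # all-background map is unknown
  expect_true(is.na(identity_of_frame(matrix(0L, 6, 6), cfg)))
})

test_that("identity map equals the LRSS footprint for exact targets", {
  sk <- toy_skeleton()
  cfg <- social_cfg()
  fr <- generate_scene(scene_spec(seed = 21))
  tg <- make_target_maps(fr, sk, cfg, identity_aware = TRUE, with_baf = TRUE)
  idm <- build_identity_map(tg$lrss, tg$baf, cfg)
  expect_identical(unname(idm[, ]), unname(tg$lrss))
  expect_equal(attr(idm, "clamped"), 0L)
})

test_that("zero BAF degenerates the identity map to the LRSS labels", {
  cfg <- social_cfg()
  lab <- matrix(0L, 8, 8); lab[3:5, 2:4] <- 2L
  idm <- build_identity_map(lab, array(0, c(8, 8, 2)), cfg)
  expect_identical(unname(idm[, ]), unname(lab))
})

test_that("two disjoint bodies each inherit their own identity, exhaustively", {
  sk <- toy_skeleton()
  cfg <- social_cfg()
  for (seed in c(5, 17, 29)) {
    fr <- pair_scene(seed)
    tg <- make_target_maps(fr, sk, cfg, identity_aware = TRUE, with_baf = TRUE)
    idm <- build_identity_map(tg$lrss, tg$baf, cfg)
    body <- which(tg$lrss != 0)
    expect_true(all(idm[body] == tg$lrss[body]))
  }
})

test_that("out-of-map centers are clamped and tallied", {
  cfg <- social_cfg()
  lab <- matrix(0L, 6, 6); lab[1, 1] <- 1L
  baf <- array(0, c(6, 6, 2)); baf[1, 1, 1] <- 10   # center far left of the map
  idm <- build_identity_map(lab, baf, cfg)
  expect_equal(attr(idm, "clamped"), 1L)
})

test_that("social decoding reduces to single decoding for one instance", {
  sk <- toy_skeleton()
  cfg <- social_cfg()
  fr <- generate_scene(scene_spec(seed = 33))
  tg <- make_target_maps(fr, sk, cfg, identity_aware = TRUE, with_baf = TRUE)
  idm <- build_identity_map(tg$lrss, tg$baf, cfg)
  heads <- list(heatmap = tg$heatmap, locref = tg$locref)
  soc <- decode_social(heads, idm, cfg)
  single <- decode_single(heads, cfg)
  det <- soc[["1"]]
  expect_true(all(det$valid))
  expect_equal(det$x, single$x)
  expect_equal(det$y, single$y)
  expect_equal(det$confidence, single$confidence)
  # nothing decoded for the absent identity
  expect_false(any(soc[["2"]]$valid))
})

test_that("social decoding recovers both instances with correct identities", {
  sk <- toy_skeleton()
  cfg <- social_cfg()
  for (seed in 1:25) {
    fr <- pair_scene(3000 + seed)
    tg <- make_target_maps(fr, sk, cfg, identity_aware = TRUE, with_baf = TRUE)
    idm <- build_identity_map(tg$lrss, tg$baf, cfg)
    dets <- decode_social(list(heatmap = tg$heatmap, locref = tg$locref),
                          idm, cfg)
    expect_length(dets, 2L)
    for (a in 1:2) {
      det <- dets[[as.character(a)]]
      expect_true(all(det$valid))
      err <- abs(as.matrix(det[, c("x", "y")]) - fr$instances[[a]]$keypoints)
      expect_lt(max(err), 1e-6 * cfg$stride)
    }
  }
})

test_that("peaks whose window holds only background are excluded and counted", {
  cfg <- social_cfg()
  hm <- array(0, c(10, 10, 1)); hm[2, 2, 1] <- 0.9
  idm <- matrix(0L, 10, 10)   # all background
  dets <- decode_social(list(heatmap = hm, locref = array(0, c(10, 10, 2))),
                        idm, cfg)
  expect_false(any(dets[["1"]]$valid))
  expect_equal(attr(dets, "diagnostics")$unmatched_peaks, 1L)
})

test_that("social decoding never exceeds n_identities instances or K keypoints", {
  sk <- toy_skeleton()
  cfg <- social_cfg()
  fr <- pair_scene(41)
  tg <- make_target_maps(fr, sk, cfg, identity_aware = TRUE, with_baf = TRUE)
  idm <- build_identity_map(tg$lrss, tg$baf, cfg)
  dets <- decode_social(list(heatmap = tg$heatmap, locref = tg$locref), idm, cfg)
  expect_lte(length(dets), cfg$n_identities)
  for (det in dets) expect_lte(nrow(det), n_keypoints(sk))
})

test_that("temporal identity correction is a fixed point on clean tracks", {
  vid <- generate_video(scene_spec(n_animals = 2, size = c(128, 128),
                                   min_sep = 2.8, seed = 8), 40)
  out <- temporal_identity_correction(vid$track, social_cfg())
  expect_equal(out$frames, vid$track$frames)
})

test_that("an injected single-frame swap is repaired and change rate drops to 0", {
  spec <- scene_spec(n_animals = 2, size = c(192, 192), min_sep = 6,
                     seed = 5, n_swaps = 1)
  vid <- generate_video(spec, 100)
  expect_equal(nrow(vid$events$swaps), 1L)
  cr_before <- change_rate(vid$track, alpha = 75)
  expect_gt(cr_before, 0)
  fixed <- temporal_identity_correction(vid$track, social_cfg())
  expect_equal(change_rate(fixed, alpha = 75), 0)
})

test_that("alternating labels of stationary instances converge to frame 1's", {
  kpA <- cbind(rep(10, 5), rep(10, 5))
  kpB <- cbind(rep(200, 5), rep(200, 5))
  frames <- lapply(1:30, function(f) {
    ids <- if (f %% 2 == 1) c(1L, 2L) else c(2L, 1L)
    list(list(keypoints = kpA, confidence = rep(1, 5), identity = ids[1],
              center = kpA[2, ]),
         list(keypoints = kpB, confidence = rep(1, 5), identity = ids[2],
              center = kpB[2, ]))
  })
  tr <- pose_track(frames)
  out <- temporal_identity_correction(tr, social_cfg())
  for (f in seq_along(out$frames)) {
    expect_equal(out$frames[[f]][[1]]$identity, 1L)
    expect_equal(out$frames[[f]][[2]]$identity, 2L)
  }
})

test_that("correction only relabels: coordinates and confidences untouched; idempotent", {
  spec <- scene_spec(n_animals = 2, size = c(192, 192), min_sep = 6,
                     seed = 13, n_swaps = 2)
  vid <- generate_video(spec, 60)
  cfg <- social_cfg()
  once <- temporal_identity_correction(vid$track, cfg)
  for (f in seq_along(once$frames)) {
    for (i in seq_along(once$frames[[f]])) {
      expect_identical(once$frames[[f]][[i]]$keypoints,
                       vid$track$frames[[f]][[i]]$keypoints)
      expect_identical(once$frames[[f]][[i]]$confidence,
                       vid$track$frames[[f]][[i]]$confidence)
    }
  }
  twice <- temporal_identity_correction(once, cfg)
  expect_equal(twice$frames, once$frames)
})

test_that("frames with zero instances pass through unchanged", {
  kp <- cbind(rep(10, 5), rep(10, 5))
  frames <- list(
    list(list(keypoints = kp, confidence = rep(1, 5), identity = 1L,
              center = kp[2, ])),
    list(),
    list(list(keypoints = kp, confidence = rep(1, 5), identity = 1L,
              center = kp[2, ])))
  out <- temporal_identity_correction(pose_track(frames), social_cfg())
  expect_length(out$frames[[2]], 0L)
  expect_equal(out$frames[[3]][[1]]$identity, 1L)
})
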