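test_that("drift fraction: constant trajectories, single jumps, defaults", {
  xy <- array(5, c(100, 3, 2))
  expect_equal(unname(drift_fraction(xy, alpha = 50)), c(0, 0, 0))
  # exactly one 60 px jump at alpha 50 -> 1/100
  xy[51:100, 2, 1] <- 5 + 60
  expect_equal(unname(drift_fraction(xy, alpha = 50)), c(0, 1 / 100, 0))
  expect_equal(formals(drift_fraction)$alpha, 50)
  expect_equal(adpt_config()$drift_alpha, 50)
  expect_error(drift_fraction(array(0, c(1, 2, 2)), 50), "at least 2")
  # the flag flips the indicator to count stable frames
  expect_equal(unname(drift_fraction(xy, alpha = 50, count_stable = TRUE)),
               c(99, 98, 99) / 100)
})

test_that("drift fraction matches the brute-force oracle on random tracks", {
  for (rep in 1:50) {
    xy <- adpt:::with_seed(rep, {
      F <- sample(2:50, 1); K <- sample(1:4, 1)
      array(rnorm(F * K * 2, 0, 40), c(F, K, 2))
    })
    alpha <- adpt:::with_seed(rep + 500, runif(1, 5, 80))
    expect_equal(unname(drift_fraction(xy, alpha)), oracle_drift(xy, alpha))
  }
})

test_that("drift is symmetric under frame-order reversal", {
  xy <- adpt:::with_seed(3, array(rnorm(40 * 2 * 2, 0, 30), c(40, 2, 2)))
  rev_xy <- xy[40:1, , , drop = FALSE]
  expect_equal(drift_fraction(xy, 25), drift_fraction(rev_xy, 25))
})

test_that("miss fraction uses the inclusive cutoff", {
  conf <- matrix(1, 10, 2)
  expect_equal(unname(miss_fraction(conf)), c(0, 0))
  conf[1, 1] <- 0.2    # exactly the cutoff counts as a miss
  expect_equal(unname(miss_fraction(conf, cutoff = 0.2)), c(0.1, 0))
  conf2 <- matrix(c(rep(0.1, 3), rep(0.9, 7)), ncol = 1)
  expect_equal(unname(miss_fraction(conf2, cutoff = 0.2)), 0.3)
  for (rep in 1:30) {
    conf <- adpt:::with_seed(rep, matrix(runif(50 * 3), 50, 3))
    expect_equal(unname(miss_fraction(conf, 0.2)), oracle_miss(conf, 0.2))
  }
})

test_that("change rate: stationary centers, swaps, oracle, default alpha", {
  centers <- array(10, c(50, 2, 2))
  centers[, 2, 1] <- 210   # animal 2 at x = 210
  expect_equal(change_rate(centers, alpha = 75), 0)
  # one swap between animals 200 px apart: both identities jump twice
  swapped <- centers
  swapped[25, 1, 1] <- 210; swapped[25, 2, 1] <- 10
  expect_equal(change_rate(swapped, alpha = 75), mean(c(2 / 50, 2 / 50)))
  expect_equal(formals(change_rate)$alpha, 75)
  expect_error(change_rate(array(0, c(1, 2, 2)), 75), "at least 2")
  for (rep in 1:30) {
    cs <- adpt:::with_seed(rep, array(rnorm(30 * 2 * 2, 0, 60), c(30, 2, 2)))
    expect_equal(change_rate(cs, 75), oracle_change_rate(cs, 75))
  }
})

test_that("PCK counts keypoints within tau * L, visible GT only", {
  sk <- toy_skeleton()
  gt <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(5, 5))
  expect_equal(pck(gt, gt, sk), 1)
  # L = sqrt(bbox area) = 10; single keypoint at d = 0.2 * L misses at tau 0.15
  pr <- gt; pr[5, ] <- gt[5, ] + c(2, 0)
  expect_equal(pck(pr, gt, sk, tau = 0.15), 4 / 5)
  # a skeleton can instead declare an edge as the reference length
  sk_edge <- skeleton(c("a", "b"), rbind(c(1L, 2L)), center = 1L,
                      pck_reference = "edge", pck_edge = 1L)
  gt2 <- rbind(c(0, 0), c(10, 0))
  pr2 <- rbind(c(0, 2), c(10, 0))   # d = 2 = 0.2 * L, L = 10
  expect_equal(pck(pr2, gt2, sk_edge, tau = 0.15), 1 / 2)
  expect_equal(pck(pr2, gt2, sk_edge, tau = 0.25), 1)
  expect_equal(formals(pck)$tau, 0.15)
  # no visible keypoints -> flagged NaN
  out <- pck(gt, gt, sk, visibility = rep(FALSE, 5))
  expect_true(is.nan(out))
  expect_true(attr(out, "undefined"))
})

test_that("OKS implements the printed form with s = 0.025", {
  gt <- rbind(c(10, 10), c(30, 20), c(20, 40))
  expect_equal(oks(gt, gt, area = 400), 1)
  # one visible keypoint at d = sqrt(area) * 2s gives exp(-0.5)
  s <- 0.025; area <- 400
  d <- sqrt(area) * 2 * s
  pr <- rbind(c(10 + d, 10))
  expect_equal(oks(pr, gt[1, , drop = FALSE], area = area),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(formals(oks)$s, 0.025)
  expect_error(oks(gt, gt, area = 400, visibility = rep(FALSE, 3)),
               "no visible")
  for (rep in 1:30) {
    env <- adpt:::with_seed(rep, list(
      gt = matrix(runif(10, 0, 100), 5, 2),
      noise = matrix(rnorm(10, 0, 5), 5, 2),
      v = runif(5) > 0.3, area = runif(1, 100, 2000)))
    if (!any(env$v)) env$v[1] <- TRUE
    expect_equal(
      oks(env$gt + env$noise, env$gt, area = env$area, visibility = env$v),
      oracle_oks(env$gt + env$noise, env$gt, env$area, 0.025, env$v))
  }
})

test_that("AP thresholds are strict and mAP averages 0.50..0.95 by 0.05", {
  expect_equal(map_score(rep(1, 4))$map, 1)
  ms <- map_score(c(0.6, 0.8))
  expect_equal(unname(ms$ap["AP@0.50"]), 1)
  expect_equal(unname(ms$ap["AP@0.70"]), 0.5)
  expect_equal(unname(ms$ap["AP@0.85"]), 0)
  th <- seq(0.5, 0.95, by = 0.05)
  expect_equal(ms$map, oracle_map(c(0.6, 0.8), th)$map)
  # strict inequality: the OKS of 0.8 does not count at threshold 0.80
  expect_equal(ms$map, 0.40)
  # a tie at the threshold does not count (strict >)
  expect_equal(unname(map_score(c(0.5))$ap["AP@0.50"]), 0)
  expect_error(map_score(numeric(0)), "at least one")
  for (rep in 1:30) {
    v <- adpt:::with_seed(rep, runif(sample(1:50, 1)))
    got <- map_score(v)
    want <- oracle_map(v, th)
    expect_equal(unname(got$ap), want$ap)
    expect_equal(got$map, want$map)
    # AP is non-increasing in the threshold
    expect_true(all(diff(got$ap) <= 0))
  }
})

test_that("RMSE is the root mean squared Euclidean error with cutoff modes", {
  gt <- rbind(c(0, 0), c(5, 5))
  expect_equal(rmse_px(gt, gt), 0)
  # a single (3, 4) offset is an error of 5
  pr <- rbind(c(3, 4))
  expect_equal(rmse_px(pr, rbind(c(0, 0))), 5)
  # cutoff keeps only confident predictions (strict >)
  pr2 <- rbind(c(3, 4), c(5, 5))
  conf <- c(0.1, 0.9)
  expect_equal(rmse_px(pr2, gt, confidence = conf, confidence_cutoff = 0.2), 0)
  expect_equal(rmse_px(pr2, gt, confidence = conf, confidence_cutoff = 0.05),
               sqrt(25 / 2))
  out <- rmse_px(pr2, gt, confidence = c(0.1, 0.1), confidence_cutoff = 0.6)
  expect_true(is.nan(out))
  for (rep in 1:30) {
    env <- adpt:::with_seed(rep, {
      n <- sample(1:50, 1)
      list(gt = matrix(runif(2 * n, 0, 50), n, 2),
           pr = matrix(runif(2 * n, 0, 50), n, 2))
    })
    expect_equal(rmse_px(env$pr, env$gt), oracle_rmse(env$pr, env$gt))
  }
})

test_that("drift report aggregates per-keypoint fractions and thresholds", {
  vid <- generate_video(scene_spec(seed = 3), 30)
  rep <- drift_report(vid$track, toy_cfg(), keypoint_names = toy_skeleton()$names)
  expect_equal(nrow(rep$per_keypoint), 5L)
  expect_true(all(rep$per_keypoint$drift >= 0 & rep$per_keypoint$drift <= 1))
  expect_true(all(rep$per_keypoint$miss >= 0 & rep$per_keypoint$miss <= 1))
  expect_equal(unname(rep$thresholds["drift_alpha"]), 50)
  pre <- withr::local_tempfile()
  paths <- write_drift_report(rep, pre)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$overall$drift, unname(rep$overall["drift"]))
})
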