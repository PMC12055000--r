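test_that("skeleton constructor enforces its invariants", {
  expect_error(skeleton(c("a", "b"), rbind(c(1, 3)), center = "a"),
               "valid keypoint indices")
  expect_error(skeleton(c("a", "b"), rbind(c(2, 2)), center = "a"),
               "self-edges")
  expect_error(skeleton(c("a", "b"), rbind(c(1, 2)), center = "c"),
               "not in names")
  sk <- toy_skeleton()
  expect_equal(sk$center_index, 2L)
  expect_equal(n_keypoints(sk), 5L)
})

test_that("config validates geometry parameters", {
  expect_error(adpt_config(global_scale = 0), "global_scale")
  expect_error(adpt_config(global_scale = 1.5), "global_scale")
  expect_error(adpt_config(stride = 6), "power of two")
  expect_error(adpt_config(sigma = 0), "sigma")
  cfg <- adpt_config()
  expect_equal(cfg$cutoff, 0.2)
  expect_equal(cfg$drift_alpha, 50)
  expect_equal(cfg$change_alpha, 75)
  expect_equal(cfg$locref_radius, 2 * cfg$sigma)
})

test_that("config and skeleton survive a YAML round trip", {
  cfg <- adpt_config(sigma = 2.5, n_identities = 3, epochs = 42L)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(cfg2$sigma, 2.5)
  expect_equal(cfg2$n_identities, 3L)
  expect_equal(cfg2$epochs, 42L)

  sk <- toy_skeleton()
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_skeleton(sk, p2)
  sk2 <- read_skeleton(p2)
  expect_equal(sk2$names, sk$names)
  expect_equal(sk2$edges, sk$edges)
  expect_equal(sk2$center_index, sk$center_index)
})

test_that("labeled frames reject out-of-bounds visible keypoints and duplicate ids", {
  img <- array(0, c(20, 20, 3))
  expect_error(
    labeled_frame(img, list(pose_instance(rbind(c(25, 5)), identity = 1))),
    "within image bounds")
  expect_error(
    labeled_frame(img, list(pose_instance(rbind(c(5, 5)), identity = 1),
                            pose_instance(rbind(c(8, 8)), identity = 1))),
    "unique")
  # NA coordinates become invisible, not (0, 0)-visible
  inst <- pose_instance(rbind(c(NA, 4), c(3, 3)))
  expect_false(inst$visibility[1])
  expect_true(inst$visibility[2])
})

test_that("native dataset layout round-trips losslessly", {
  sk <- toy_skeleton()
  dir <- withr::local_tempdir()
  frames <- lapply(1:3, function(i) generate_scene(scene_spec(seed = i)))
  # one frame with an invisible keypoint
  frames[[2]]$instances[[1]]$visibility[4] <- FALSE
  write_labeled_dataset(frames, dir, sk)
  back <- read_labeled_dataset(dir, adpt_config())
  expect_length(back, 3L)
  for (i in 1:3) {
    a <- frames[[i]]$instances[[1]]; b <- back[[i]]$instances[[1]]
    expect_equal(b$keypoints[b$visibility, ], a$keypoints[a$visibility, ],
                 tolerance = 1e-6)
    expect_equal(b$visibility, a$visibility)
    expect_equal(b$identity, a$identity)
  }
  expect_true(all(back[[1]]$instances[[1]]$visibility))
})

test_that("missing image and bodypart mismatch are hard errors", {
  sk <- toy_skeleton()
  dir <- withr::local_tempdir()
  frames <- list(generate_scene(scene_spec(seed = 1)))
  write_labeled_dataset(frames, dir, sk)
  file.remove(file.path(dir, "images", "frame_0001.png"))
  expect_error(read_labeled_dataset(dir), "missing image file 'images/frame_0001.png'")

  dir2 <- withr::local_tempdir()
  write_labeled_dataset(frames, dir2, sk)
  other <- skeleton(c("head", "thorax"), rbind(c(1L, 2L)), center = 1L)
  expect_error(read_labeled_dataset(dir2, skeleton = other),
               "does not match skeleton")
})

test_that("DeepLabCut-style CSV is parsed cell by cell, NaN means unannotated", {
  # hand-constructed 2-bodypart table, one NaN cell
  sk <- skeleton(c("head", "tail"), rbind(c(1L, 2L)), center = 1L)
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "img"))
  write_image(array(10, c(16, 16, 3)), file.path(dir, "img", "f1.png"))
  write_image(array(10, c(16, 16, 3)), file.path(dir, "img", "f2.png"))
  lines <- c(
    "scorer,me,me,me,me",
    "bodyparts,head,head,tail,tail",
    "coords,x,y,x,y",
    "img/f1.png,3.5,4.25,10,11",
    "img/f2.png,NaN,2,6,7")
  writeLines(lines, file.path(dir, "labels.csv"))
  frames <- read_labeled_dataset(dir, skeleton = sk)
  expect_length(frames, 2L)
  i1 <- frames[[1]]$instances[[1]]
  expect_equal(i1$keypoints, cbind(x = c(3.5, 10), y = c(4.25, 11)))
  expect_true(all(i1$visibility))
  i2 <- frames[[2]]$instances[[1]]
  expect_false(i2$visibility[1])          # the NaN cell
  expect_true(i2$visibility[2])           # others unchanged
  expect_equal(i2$keypoints[2, ], c(x = 6, y = 7))
})

test_that("dlc conversion emits a readable native dataset", {
  sk <- skeleton(c("head", "tail"), rbind(c(1L, 2L)), center = 1L)
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "img"))
  write_image(array(10, c(16, 16, 3)), file.path(dir, "img", "f1.png"))
  writeLines(c("scorer,me,me,me,me",
               "bodyparts,head,head,tail,tail",
               "coords,x,y,x,y",
               "img/f1.png,3,4,10,11"),
             file.path(dir, "labels.csv"))
  out <- withr::local_tempdir()
  convert_dlc_dataset(dir, out, sk)
  frames <- read_labeled_dataset(out)
  expect_equal(frames[[1]]$instances[[1]]$keypoints[1, ], c(x = 3, y = 4))
})

test_that("augment_frame with the identity transform returns the input", {
  fr <- flat_frame()
  out <- augment_frame(fr, params = list(rotate = 0, tx = 0, ty = 0, scale = 1))
  expect_equal(out$image, fr$image)
  expect_equal(out$instances[[1]]$keypoints, fr$instances[[1]]$keypoints)
})

test_that("pure translation shifts every keypoint exactly", {
  fr <- flat_frame()
  out <- augment_frame(fr, params = list(rotate = 0, tx = 10, ty = 0, scale = 1))
  expect_equal(out$instances[[1]]$keypoints[, 1],
               fr$instances[[1]]$keypoints[, 1] + 10)
  expect_equal(out$instances[[1]]$keypoints[, 2],
               fr$instances[[1]]$keypoints[, 2])
})

test_that("social protocol samples translation only, within the stated ranges", {
  fr <- flat_frame(H = 240, W = 240,
                   kp = rbind(c(120, 120), c(125, 125), c(130, 130),
                              c(120, 130), c(130, 120)))
  cfg <- adpt_config()
  rot <- tx <- ty <- sc <- numeric(1000)
  for (i in 1:1000) {
    rg <- cfg$augment$social_task
    p <- adpt:::with_seed(i, list(
      rotate = stats::runif(1, rg$rotate[1], rg$rotate[2]),
      tx = stats::runif(1, rg$tx[1], rg$tx[2]),
      ty = stats::runif(1, rg$ty[1], rg$ty[2]),
      scale = stats::runif(1, rg$scale[1], rg$scale[2])))
    rot[i] <- p$rotate; tx[i] <- p$tx; ty[i] <- p$ty; sc[i] <- p$scale
  }
  expect_true(all(rot == 0))
  expect_true(all(sc == 1))
  expect_true(all(tx >= -100 & tx <= 100))
  expect_true(all(ty >= -30 & ty <= 15))
})

test_that("identity protocol covers rotation, translation and scale ranges", {
  rg <- adpt_config()$augment$identity_task
  expect_equal(rg$rotate, c(-30, 30))
  expect_equal(rg$tx, c(-100, 100))
  expect_equal(rg$ty, c(-30, 15))
  expect_equal(rg$scale, c(0.9, 1.1))
})

test_that("augmentation is seed-reproducible and marks pushed-out keypoints invisible", {
  fr <- flat_frame()
  a <- augment_frame(fr, rng_seed = 99, mode = "identity_task")
  b <- augment_frame(fr, rng_seed = 99, mode = "identity_task")
  expect_identical(a, b)
  # push everything far outside: no error, all invisible
  out <- augment_frame(fr, params = list(rotate = 0, tx = 500, ty = 0, scale = 1))
  expect_false(any(out$instances[[1]]$visibility))
})

test_that("image warp and keypoint transform agree (marker pixel lands on keypoint)", {
  for (seed in 1:5) {
    kp <- adpt:::with_seed(seed, cbind(runif(1, 15, 35), runif(1, 15, 35)))
    img <- array(0, c(48, 48, 1))
    img[round(kp[2]) + 1, round(kp[1]) + 1, 1] <- 255
    fr <- labeled_frame(img, list(pose_instance(kp)))
    out <- augment_frame(fr, params = list(rotate = 20, tx = 3, ty = -2,
                                           scale = 1.05))
    hits <- which(out$image[, , 1] > 0, arr.ind = TRUE)
    expect_gt(nrow(hits), 0)
    kp2 <- out$instances[[1]]$keypoints
    d <- sqrt((hits[, 2] - 1 - kp2[1, 1])^2 + (hits[, 1] - 1 - kp2[1, 2])^2)
    expect_lt(min(d), 1.5)
  }
})
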