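#' Specify a synthetic toy scene
#'
#' Describes deterministic stick-figure "animals" — thick limb segments
#' plus an elliptical body blob, each with its own flat-colour-plus-noise
#' texture — rendered on a structured background. The exact keypoints and
#' identities are returned with every render, so training, mix-up,
#' identity and metric code paths are testable with no external data.
#'
#' @param size `c(H, W)` image size in pixels.
#' @param n_animals 1 or 2.
#' @param skeleton The 5-keypoint toy skeleton by default (nose, back =
#'   center, tail root, two paws).
#' @param background `"flat"`, `"gradient"` or `"checker"`.
#' @param seed Integer RNG seed; scenes are fully reproducible from
#'   (spec, seed).
#' @param scale_range Per-animal body scale factor range.
#' @param jitter_sd Joint-angle jitter (radians) around the canonical
#'   pose.
#' @param step_sd,turn_sd Video mode: per-frame standard deviation of the
#'   reflected random walk of the center (pixels) and of the heading
#'   (radians).
#' @param min_sep Minimum center separation between two animals, as a
#'   multiple of the body extent.
#' @param n_jumps,jump_px Video mode: number of single-frame keypoint
#'   jump events injected post hoc into the ground-truth track (not
#'   rendered), and their displacement in pixels.
#' @param n_swaps Video mode: number of single-frame identity swap
#'   events injected post hoc (two-animal scenes).
#' @return An object of class `adpt_scene_spec`.
#' @export
scene_spec <- function(size = c(64L, 64L), n_animals = 1L,
                       skeleton = toy_skeleton(), background = "flat",
                       seed = 0L, scale_range = c(0.9, 1.1),
                       jitter_sd = 0.15, step_sd = 1.5, turn_sd = 0.12,
                       min_sep = 1.6, n_jumps = 0L, jump_px = 100,
                       n_swaps = 0L) {
  stopifnot(n_animals %in% c(1L, 2L))
  structure(list(size = as.integer(size), n_animals = as.integer(n_animals),
                 skeleton = skeleton, background = background,
                 seed = as.integer(seed), scale_range = scale_range,
                 jitter_sd = jitter_sd, step_sd = step_sd, turn_sd = turn_sd,
                 min_sep = min_sep,
                 n_jumps = as.integer(n_jumps), jump_px = jump_px,
                 n_swaps = as.integer(n_swaps)),
            class = "adpt_scene_spec")
}

# Joint rejection sampling of all animal centers: every pair must be
# separated by min_sep * extent; whole configurations are resampled.
sample_centers <- function(spec, margin, H, W) {
  if (2 * margin > min(H, W) - 1) {
    stop("image of size ", H, "x", W, " cannot fit an animal of extent ", margin)
  }
  for (try in seq_len(200L)) {
    cs <- lapply(seq_len(spec$n_animals), function(a) {
      c(stats::runif(1, margin, W - 1 - margin),
        stats::runif(1, margin, H - 1 - margin))
    })
    ok <- TRUE
    if (spec$n_animals > 1L) {
      for (a in 2:spec$n_animals) {
        for (b in seq_len(a - 1L)) {
          if (sqrt(sum((cs[[a]] - cs[[b]])^2)) <= spec$min_sep * margin) ok <- FALSE
        }
      }
    }
    if (ok) return(cs)
  }
  stop("could not place ", spec$n_animals, " animals: minimum separation ",
       spec$min_sep, " x extent unreachable after 200 tries")
}

# Canonical toy body plan at scale 1: limb lengths from the back center.
toy_body_plan <- function() {
  list(nose_len = 13, tail_len = 11, paw_len = 8, body_w = 5.5,
       limb_w = 3, marker_r = 1.6)
}

# Distinct per-animal base colours and per-keypoint marker colours (RGB,
# 0..255). Markers give each body part a learnable local appearance cue,
# the desk-scale analogue of real part-specific coat appearance.
animal_palette <- function(texture) {
  base <- list(c(150, 120, 90), c(90, 130, 160))[[(texture - 1L) %% 2L + 1L]]
  markers <- rbind(
    c(250, 60, 60),    # nose
    c(250, 250, 90),   # back
    c(90, 250, 120),   # tailroot
    c(90, 120, 250),   # paw_l
    c(250, 120, 250))  # paw_r
  list(base = base, markers = markers)
}

sample_pose <- function(spec, center, theta, scale) {
  p <- toy_body_plan()
  j <- stats::rnorm(4L, 0, spec$jitter_sd)
  ang <- c(theta + j[1L], theta + pi + j[2L],
           theta + pi / 2 + j[3L], theta - pi / 2 + j[4L])
  len <- c(p$nose_len, p$tail_len, p$paw_len, p$paw_len) * scale
  kp <- matrix(0, 5L, 2L)
  kp[2L, ] <- center
  ends <- c(1L, 3L, 4L, 5L)
  for (i in seq_len(4L)) {
    kp[ends[i], ] <- center + len[i] * c(cos(ang[i]), sin(ang[i]))
  }
  kp
}

body_extent <- function(spec) {
  p <- toy_body_plan()
  (max(p$nose_len, p$tail_len, p$paw_len) * max(spec$scale_range) +
      p$limb_w + p$marker_r + 1)
}

render_background <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), times = W), H, W)
  base <- switch(spec$background,
    flat = matrix(45, H, W),
    gradient = 30 + 50 * gx / max(1, W - 1),
    checker = 35 + 25 * ((gx %/% 8 + gy %/% 8) %% 2),
    stop("unknown background kind: ", spec$background))
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- base + stats::rnorm(H * W, 0, 2)
  pmin(pmax(img, 0), 255)
}

render_animal <- function(img, kp, skeleton, texture) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  p <- toy_body_plan()
  pal <- animal_palette(texture)
  px <- rep(0:(W - 1), each = H)
  py <- rep(0:(H - 1), times = W)
  mask <- rep(FALSE, H * W)
  for (e in seq_len(nrow(skeleton$edges))) {
    a <- skeleton$edges[e, 1L]; b <- skeleton$edges[e, 2L]
    mask <- mask | point_segment_dist(px, py, kp[a, 1L], kp[a, 2L],
                                      kp[b, 1L], kp[b, 2L]) <= p$limb_w / 2
  }
  # elliptical body blob along the back-tail axis
  mid <- (kp[2L, ] + kp[3L, ]) / 2
  ax <- kp[3L, ] - kp[2L, ]
  L <- sqrt(sum(ax^2)); u <- if (L > 0) ax / L else c(1, 0)
  rx <- (px - mid[1L]) * u[1L] + (py - mid[2L]) * u[2L]
  ry <- -(px - mid[1L]) * u[2L] + (py - mid[2L]) * u[1L]
  mask <- mask | (rx / (L / 2 + p$body_w))^2 + (ry / p$body_w)^2 <= 1
  noise <- stats::runif(sum(mask), -18, 18)
  for (ch in 1:3) {
    sl <- img[, , ch]
    sl[mask] <- pmin(pmax(pal$base[ch] + noise, 0), 255)
    img[, , ch] <- sl
  }
  # keypoint markers: small distinct-colour discs
  for (k in seq_len(nrow(kp))) {
    mk <- sqrt((px - kp[k, 1L])^2 + (py - kp[k, 2L])^2) <= p$marker_r
    for (ch in 1:3) {
      sl <- img[, , ch]
      sl[mk] <- pal$markers[k, ch]
      img[, , ch] <- sl
    }
  }
  list(image = img, mask = matrix(mask, H, W))
}

#' Render one synthetic labeled scene
#'
#' @param spec An [scene_spec()].
#' @return An `adpt_frame` with exact keypoints and identities; the
#'   foreground masks are attached as attribute `"masks"`. The same
#'   (spec, seed) always renders the identical frame.
#' @export
generate_scene <- function(spec) {
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]
  margin <- body_extent(spec)
  if (2 * margin > min(H, W) - 1) {
    stop("image of size ", H, "x", W, " cannot fit an animal of extent ", margin)
  }
  img <- render_background(spec)
  masks <- list()
  insts <- list()
  placed_centers <- sample_centers(spec, margin, H, W)
  for (a in seq_len(spec$n_animals)) {
    center <- placed_centers[[a]]
    theta <- stats::runif(1, 0, 2 * pi)
    scale <- stats::runif(1, spec$scale_range[1L], spec$scale_range[2L])
    kp <- sample_pose(spec, center, theta, scale)
    r <- render_animal(img, kp, spec$skeleton, texture = a)
    img <- r$image
    masks[[a]] <- r$mask
    insts[[a]] <- pose_instance(kp, identity = a)
  }
  fr <- labeled_frame(img, insts)
  attr(fr, "masks") <- masks
  fr
}

#' Render a synthetic video with known events
#'
#' Animals follow a reflected random walk (the center never leaves the
#' frame) with slowly drifting heading and pose. Optional jump and
#' identity-swap events are injected post hoc into the returned
#' ground-truth track — not into the rendered images — and recorded in
#' the event log, so metric tests have exact expected values.
#'
#' @param spec An [scene_spec()].
#' @param n_frames Number of frames, >= 2.
#' @return List with `frames` (list of `adpt_frame`), `track` (the
#'   ground-truth `adpt_track`, including any injected events) and
#'   `events` (list with `jumps` and `swaps` data frames).
#' @export
generate_video <- function(spec, n_frames) {
  stopifnot(n_frames >= 2L)
  with_seed(spec$seed, generate_video_impl(spec, n_frames))
}

generate_video_impl <- function(spec, n_frames) {
  H <- spec$size[1L]; W <- spec$size[2L]
  margin <- body_extent(spec)
  n <- spec$n_animals
  thetas <- stats::runif(n, 0, 2 * pi)
  scales <- stats::runif(n, spec$scale_range[1L], spec$scale_range[2L])
  centers <- sample_centers(spec, margin, H, W)
  reflect <- function(x, lo, hi) {
    while (x < lo || x > hi) x <- if (x < lo) 2 * lo - x else 2 * hi - x
    x
  }
  frames <- vector("list", n_frames)
  gt <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- render_background(spec)
    insts <- vector("list", n)
    for (a in seq_len(n)) {
      kp <- sample_pose(spec, centers[[a]], thetas[a], scales[a])
      r <- render_animal(img, kp, spec$skeleton, texture = a)
      img <- r$image
      insts[[a]] <- list(keypoints = kp,
                         confidence = rep(1, nrow(kp)),
                         identity = a,
                         center = kp[spec$skeleton$center_index, ])
      centers[[a]][1L] <- reflect(centers[[a]][1L] + stats::rnorm(1, 0, spec$step_sd),
                                  margin, W - 1 - margin)
      centers[[a]][2L] <- reflect(centers[[a]][2L] + stats::rnorm(1, 0, spec$step_sd),
                                  margin, H - 1 - margin)
      thetas[a] <- thetas[a] + stats::rnorm(1, 0, spec$turn_sd)
    }
    frames[[f]] <- labeled_frame(img, lapply(insts, function(i) {
      pose_instance(i$keypoints, identity = i$identity)
    }))
    gt[[f]] <- insts
  }
  # inject events post hoc on the GT track only
  jumps <- data.frame(frame = integer(0), animal = integer(0),
                      keypoint = integer(0), dx = numeric(0), dy = numeric(0))
  K <- n_keypoints(spec$skeleton)
  if (spec$n_jumps > 0L) {
    jf <- sample(2:(n_frames - 1L), spec$n_jumps)
    for (f in jf) {
      a <- sample.int(n, 1L); k <- sample.int(K, 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      dx <- spec$jump_px * cos(ang); dy <- spec$jump_px * sin(ang)
      gt[[f]][[a]]$keypoints[k, ] <- gt[[f]][[a]]$keypoints[k, ] + c(dx, dy)
      if (k == spec$skeleton$center_index) {
        gt[[f]][[a]]$center <- gt[[f]][[a]]$keypoints[k, ]
      }
      jumps <- rbind(jumps, data.frame(frame = f, animal = a, keypoint = k,
                                       dx = dx, dy = dy))
    }
  }
  swaps <- data.frame(frame = integer(0))
  if (spec$n_swaps > 0L && n == 2L) {
    sf <- sample(2:(n_frames - 1L), spec$n_swaps)
    for (f in sf) {
      gt[[f]][[1L]]$identity <- 2L
      gt[[f]][[2L]]$identity <- 1L
      gt[[f]] <- gt[[f]][c(2L, 1L)]
    }
    swaps <- data.frame(frame = sort(sf))
  }
  list(frames = frames, track = pose_track(gt, spec$skeleton$names),
       events = list(jumps = jumps, swaps = swaps))
}
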