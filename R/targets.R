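#' Encode a labeled frame into training target maps
#'
#' Produces the four stride-aligned tensors the network is trained to
#' predict: per-keypoint Gaussian confidence heatmaps, location-refinement
#' offset maps with their supervision mask, the low-resolution semantic
#' segmentation (LRSS) label map painting limb segments with instance
#' identity, and the body affinity field (BAF) pointing every body pixel
#' at its instance center.
#'
#' Geometry: the frame is first rescaled by `config$global_scale`; maps
#' have size `ceiling(H / stride) x ceiling(W / stride)`. A map cell `c`
#' corresponds to rescaled-image position `c * stride`, so a keypoint
#' exactly on that position peaks at value 1 with zero offset.
#'
#' @param frame An `adpt_frame`.
#' @param skeleton An `adpt_skeleton`.
#' @param config An [adpt_config()].
#' @param identity_aware If `TRUE`, LRSS pixels carry the instance
#'   identity label; otherwise every instance paints label 1.
#' @param with_baf If `TRUE`, also build the BAF map (social protocol).
#' @return An object of class `adpt_targets`: list with `heatmap`
#'   (`Hm x Wm x K`, in \[0, 1\]), `locref` (`Hm x Wm x 2K`, rescaled-image
#'   pixels, channel order x1,y1,x2,y2,...), `locref_mask` (`Hm x Wm x K`),
#'   `lrss` (`Hm x Wm` integer, 0 = background), `baf` (`Hm x Wm x 2` or
#'   `NULL`), and a `warnings` counter list (keypoints outside the
#'   rescaled image, instances without a visible center).
#' @export
make_target_maps <- function(frame, skeleton, config,
                             identity_aware = FALSE, with_baf = FALSE) {
  fr <- rescale_frame(frame, config$global_scale)
  hl <- make_heatmap_and_locref(fr, skeleton, config, .rescaled = TRUE)
  lr <- make_lrss(fr, skeleton, config, identity_aware = identity_aware,
                  .rescaled = TRUE)
  out <- list(heatmap = hl$heatmap, locref = hl$locref,
              locref_mask = hl$locref_mask, lrss = lr,
              baf = NULL,
              warnings = hl$warnings)
  if (with_baf) {
    bf <- make_baf(fr, skeleton, config, .rescaled = TRUE)
    out$baf <- bf$baf
    out$warnings$missing_center <- bf$missing_center
  }
  structure(out, class = "adpt_targets")
}

map_dims <- function(frame, config) {
  d <- dim(frame$image)
  c(ceiling(d[1L] / config$stride), ceiling(d[2L] / config$stride))
}

#' Gaussian heatmap and location-refinement targets
#'
#' Heatmap channel `k` is the maximum over instances of
#' `exp(-d^2 / (2 sigma^2))` with `d` the distance, in map cells, from the
#' cell to keypoint `k`. Cells within `config$locref_radius` cells of a
#' keypoint carry the offset `(x_true - x_cell * stride,
#' y_true - y_cell * stride)` and a supervision mask of 1 (the nearest
#' instance wins where two overlap). Invisible keypoints contribute
#' nothing; visible keypoints falling outside the rescaled image are
#' skipped and counted in `warnings$outside`.
#'
#' @inheritParams make_target_maps
#' @param .rescaled Internal: set if `frame` is already at network scale.
#' @return List with `heatmap`, `locref`, `locref_mask`, `warnings`.
#' @export
make_heatmap_and_locref <- function(frame, skeleton, config, .rescaled = FALSE) {
  if (!.rescaled) frame <- rescale_frame(frame, config$global_scale)
  K <- n_keypoints(skeleton)
  md <- map_dims(frame, config)
  Hm <- md[1L]; Wm <- md[2L]
  stride <- config$stride
  sig2 <- 2 * config$sigma^2
  cellx <- rep(0:(Wm - 1L), each = Hm)   # column-major grid, matches array fill
  celly <- rep(0:(Hm - 1L), times = Wm)
  heatmap <- array(0, c(Hm, Wm, K))
  locref <- array(0, c(Hm, Wm, 2L * K))
  locref_mask <- array(0, c(Hm, Wm, K))
  bestd <- array(Inf, c(Hm, Wm, K))
  outside <- 0L
  Hpx <- dim(frame$image)[1L]; Wpx <- dim(frame$image)[2L]
  for (inst in frame$instances) {
    for (k in seq_len(K)) {
      if (!inst$visibility[k]) next
      x <- inst$keypoints[k, 1L]; y <- inst$keypoints[k, 2L]
      if (x < -0.5 || x > Wpx - 0.5 || y < -0.5 || y > Hpx - 0.5) {
        outside <- outside + 1L
        next
      }
      dx <- cellx - x / stride
      dy <- celly - y / stride
      d2 <- dx * dx + dy * dy
      g <- exp(-d2 / sig2)
      sl <- (k - 1L) * Hm * Wm
      heatmap[sl + seq_len(Hm * Wm)] <- pmax(heatmap[sl + seq_len(Hm * Wm)], g)
      near <- which(d2 <= config$locref_radius^2 & d2 < bestd[sl + seq_len(Hm * Wm)])
      if (length(near)) {
        bestd[sl + near] <- d2[near]
        locref_mask[sl + near] <- 1
        slx <- (2L * k - 2L) * Hm * Wm
        sly <- (2L * k - 1L) * Hm * Wm
        locref[slx + near] <- x - cellx[near] * stride
        locref[sly + near] <- y - celly[near] * stride
      }
    }
  }
  list(heatmap = heatmap, locref = locref, locref_mask = locref_mask,
       warnings = list(outside = outside))
}

#' Low-resolution semantic segmentation label map
#'
#' For every skeleton edge whose two endpoints are visible, the cells of
#' the thick rasterised segment between them (thickness
#' `config$lrss_thickness` map cells) receive the instance's identity
#' label (or 1 when not identity-aware); everywhere else is 0. Instances
#' are painted in listed order and never overwrite an earlier instance's
#' cells.
#'
#' @inheritParams make_heatmap_and_locref
#' @param identity_aware Paint identity labels instead of 1.
#' @return Integer matrix `Hm x Wm` with values in `0..n_identities`.
#' @export
make_lrss <- function(frame, skeleton, config, identity_aware = FALSE,
                      .rescaled = FALSE) {
  if (!.rescaled) frame <- rescale_frame(frame, config$global_scale)
  md <- map_dims(frame, config)
  Hm <- md[1L]; Wm <- md[2L]
  lab <- matrix(0L, Hm, Wm)
  for (inst in frame$instances) {
    lv <- if (identity_aware) inst$identity else 1L
    if (identity_aware && inst$identity > config$n_identities) {
      stop("instance identity ", inst$identity, " exceeds n_identities = ",
           config$n_identities)
    }
    m <- instance_lrss_mask(inst, skeleton, config, Hm, Wm)
    paint <- m & lab == 0L
    lab[paint] <- lv
  }
  lab
}

# Cells within thickness/2 (map cells) of any limb segment of one instance.
instance_lrss_mask <- function(inst, skeleton, config, Hm, Wm) {
  stride <- config$stride
  half <- config$lrss_thickness / 2
  cellx <- rep(0:(Wm - 1L), each = Hm)
  celly <- rep(0:(Hm - 1L), times = Wm)
  m <- rep(FALSE, Hm * Wm)
  ed <- skeleton$edges
  for (e in seq_len(nrow(ed))) {
    i <- ed[e, 1L]; j <- ed[e, 2L]
    if (!(inst$visibility[i] && inst$visibility[j])) next
    p1 <- inst$keypoints[i, ] / stride
    p2 <- inst$keypoints[j, ] / stride
    m <- m | point_segment_dist(cellx, celly, p1[1L], p1[2L], p2[1L], p2[2L]) <= half
  }
  matrix(m, Hm, Wm)
}

point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
  sqrt((px - x1 - t * vx)^2 + (py - y1 - t * vy)^2)
}

#' Body affinity field targets
#'
#' On every body cell `p` of an instance (its LRSS footprint), the BAF
#' stores the vector `(p_x - center_x, p_y - center_y)` in map-resolution
#' units, where the center is the instance's designated center keypoint;
#' `(0, 0)` off-body. Overlaps keep the first-listed instance. Instances
#' whose center keypoint is not visible contribute nothing and are
#' counted.
#'
#' @inheritParams make_heatmap_and_locref
#' @return List with `baf` (`Hm x Wm x 2`) and `missing_center` count.
#' @export
make_baf <- function(frame, skeleton, config, .rescaled = FALSE) {
  if (!.rescaled) frame <- rescale_frame(frame, config$global_scale)
  md <- map_dims(frame, config)
  Hm <- md[1L]; Wm <- md[2L]
  stride <- config$stride
  baf <- array(0, c(Hm, Wm, 2L))
  claimed <- matrix(FALSE, Hm, Wm)
  missing_center <- 0L
  cellx <- matrix(rep(0:(Wm - 1L), each = Hm), Hm, Wm)
  celly <- matrix(rep(0:(Hm - 1L), times = Wm), Hm, Wm)
  ci <- skeleton$center_index
  for (inst in frame$instances) {
    if (!inst$visibility[ci]) {
      missing_center <- missing_center + 1L
      next
    }
    cx <- inst$keypoints[ci, 1L] / stride
    cy <- inst$keypoints[ci, 2L] / stride
    m <- instance_lrss_mask(inst, skeleton, config, Hm, Wm) & !claimed
    claimed <- claimed | m
    bx <- baf[, , 1L]; by <- baf[, , 2L]
    bx[m] <- cellx[m] - cx
    by[m] <- celly[m] - cy
    baf[, , 1L] <- bx; baf[, , 2L] <- by
  }
  list(baf = baf, missing_center = missing_center)
}
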