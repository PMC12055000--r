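#' Decode single-animal head tensors into detections
#'
#' Per keypoint channel, the global argmax cell gives the coarse
#' location; the location-refinement offset at that cell is added and the
#' result is rescaled by `1 / global_scale` to full resolution. The
#' confidence is the heatmap value at the cell clipped to \[0, 1\]; a
#' keypoint is flagged detected when its confidence exceeds
#' `config$cutoff`.
#'
#' @param heads List with `heatmap` (`Hm x Wm x K`) and `locref`
#'   (`Hm x Wm x 2K`), as produced by [make_target_maps()] or the
#'   network.
#' @param config An [adpt_config()].
#' @return Data frame with one row per keypoint: `keypoint`, `x`, `y`,
#'   `confidence`, `detected`, `valid` (`FALSE` for an all-zero
#'   channel, whose coordinates are meaningless).
#' @export
decode_single <- function(heads, config = adpt_config()) {
  hm <- heads$heatmap; lr <- heads$locref
  K <- dim(hm)[3L]
  Hm <- dim(hm)[1L]; Wm <- dim(hm)[2L]
  stride <- config$stride
  out <- data.frame(keypoint = seq_len(K), x = NA_real_, y = NA_real_,
                    confidence = 0, detected = FALSE, valid = TRUE)
  for (k in seq_len(K)) {
    ch <- hm[, , k]
    i <- which.max(ch)
    cy <- (i - 1L) %% Hm          # 0-based row
    cx <- (i - 1L) %/% Hm         # 0-based col
    conf <- min(max(ch[i], 0), 1)
    if (max(ch) <= 0) {
      out$valid[k] <- FALSE
      out$confidence[k] <- 0
      next
    }
    x <- cx * stride + lr[cy + 1L, cx + 1L, 2L * k - 1L]
    y <- cy * stride + lr[cy + 1L, cx + 1L, 2L * k]
    out$x[k] <- x / config$global_scale
    out$y[k] <- y / config$global_scale
    out$confidence[k] <- conf
    out$detected[k] <- conf > config$cutoff
  }
  out
}

#' Frame identity from LRSS channel masses
#'
#' For a single-animal frame, sums each non-background LRSS probability
#' channel over all pixels and returns the argmax identity; exact ties go
#' to the lowest label. Returns `NA` ("unknown") when every identity
#' channel sums to zero.
#'
#' @param lrss_probabilities Array `Hm x Wm x (n_identities + 1)`;
#'   channel 1 is background. An integer label matrix is also accepted
#'   and converted to one-hot.
#' @param config An [adpt_config()].
#' @return Integer identity label, or `NA_integer_`.
#' @export
identity_of_frame <- function(lrss_probabilities, config = adpt_config()) {
  p <- lrss_probabilities
  if (is.matrix(p)) {   # integer labels -> one-hot
    nid <- config$n_identities
    oh <- array(0, c(dim(p), nid + 1L))
    for (c0 in 0:nid) oh[, , c0 + 1L][p == c0] <- 1
    p <- oh
  }
  sums <- apply(p, 3L, sum)[-1L]
  if (all(sums == 0)) return(NA_integer_)
  as.integer(which.max(sums))   # which.max takes the lowest on ties
}

#' Build a per-pixel identity map from LRSS and BAF
#'
#' Bottom-up / top-down identity resolution: every body pixel `p`
#' (non-background LRSS label) votes for the center it points at,
#' `c(p) = p - BAF(p)` rounded to the nearest cell; its identity is the
#' LRSS label at that center. If the center cell is background, the
#' majority non-background LRSS label within radius
#' `config$identity_radius` of the center is used. Centers falling
#' outside the map are clamped to the map bounds and tallied.
#'
#' @param lrss_labels Integer matrix `Hm x Wm` (0 = background).
#' @param baf Array `Hm x Wm x 2` of (dx, dy) to the instance center, in
#'   map cells.
#' @param config An [adpt_config()].
#' @return Integer matrix of identity labels in `0..n_identities`, with
#'   attribute `"clamped"` counting out-of-map centers.
#' @export
build_identity_map <- function(lrss_labels, baf, config = adpt_config()) {
  Hm <- nrow(lrss_labels); Wm <- ncol(lrss_labels)
  stopifnot(identical(dim(baf)[1:2], c(Hm, Wm)))
  out <- matrix(0L, Hm, Wm)
  clamped <- 0L
  body <- which(lrss_labels != 0L, arr.ind = TRUE)
  rho <- config$identity_radius
  for (r in seq_len(nrow(body))) {
    iy <- body[r, 1L]; ix <- body[r, 2L]
    px <- ix - 1L; py <- iy - 1L
    cx <- as.integer(round(px - baf[iy, ix, 1L]))
    cy <- as.integer(round(py - baf[iy, ix, 2L]))
    if (cx < 0L || cx > Wm - 1L || cy < 0L || cy > Hm - 1L) {
      clamped <- clamped + 1L
      cx <- min(max(cx, 0L), Wm - 1L)
      cy <- min(max(cy, 0L), Hm - 1L)
    }
    lab <- lrss_labels[cy + 1L, cx + 1L]
    if (lab == 0L) lab <- majority_label_near(lrss_labels, cx, cy, rho)
    out[iy, ix] <- lab
  }
  attr(out, "clamped") <- clamped
  out
}

majority_label_near <- function(labels, cx, cy, rho) {
  Hm <- nrow(labels); Wm <- ncol(labels)
  xs <- max(0L, cx - rho):min(Wm - 1L, cx + rho)
  ys <- max(0L, cy - rho):min(Hm - 1L, cy + rho)
  win <- labels[ys + 1L, xs + 1L]
  win <- win[win != 0L]
  if (!length(win)) return(0L)
  tab <- tabulate(win)
  as.integer(which.max(tab))
}

#' Decode social head tensors into per-identity detections
#'
#' Per keypoint channel, up to `n_identities` local maxima above the
#' confidence cutoff are extracted by non-maximum suppression (radius
#' `config$nms_radius` head cells). Each peak is assigned the majority
#' identity within a window of radius `config$identity_radius` around it
#' in the identity map; at most one peak survives per (keypoint,
#' identity), keeping the higher confidence (first in scan order on
#' exact ties, tallied). Peaks whose window holds only background get no
#' identity and are excluded (tallied).
#'
#' @param heads List with `heatmap` and `locref` arrays.
#' @param identity_map Integer matrix from [build_identity_map()].
#' @param config An [adpt_config()].
#' @return List of per-identity data frames (as [decode_single()]),
#'   named by identity label, with attribute `"diagnostics"` (counts of
#'   unmatched peaks and confidence ties).
#' @export
decode_social <- function(heads, identity_map, config = adpt_config()) {
  hm <- heads$heatmap; lr <- heads$locref
  K <- dim(hm)[3L]; Hm <- dim(hm)[1L]; Wm <- dim(hm)[2L]
  stride <- config$stride
  nid <- config$n_identities
  diag_ <- list(unmatched_peaks = 0L, confidence_ties = 0L)
  res <- list()
  for (id in seq_len(nid)) {
    res[[id]] <- data.frame(keypoint = seq_len(K), x = NA_real_, y = NA_real_,
                            confidence = 0, detected = FALSE, valid = FALSE)
  }
  for (k in seq_len(K)) {
    peaks <- find_peaks(hm[, , k], config$cutoff, config$nms_radius, nid)
    for (p in peaks) {
      lab <- peak_identity(identity_map, p$cx, p$cy, config$identity_radius)
      if (lab == 0L) { diag_$unmatched_peaks <- diag_$unmatched_peaks + 1L; next }
      cur <- res[[lab]]
      if (cur$valid[k]) {
        if (p$value == cur$confidence[k]) diag_$confidence_ties <- diag_$confidence_ties + 1L
        if (p$value <= cur$confidence[k]) next
      }
      x <- p$cx * stride + lr[p$cy + 1L, p$cx + 1L, 2L * k - 1L]
      y <- p$cy * stride + lr[p$cy + 1L, p$cx + 1L, 2L * k]
      cur$x[k] <- x / config$global_scale
      cur$y[k] <- y / config$global_scale
      cur$confidence[k] <- min(max(p$value, 0), 1)
      cur$detected[k] <- cur$confidence[k] > config$cutoff
      cur$valid[k] <- TRUE
      res[[lab]] <- cur
    }
  }
  names(res) <- as.character(seq_len(nid))
  attr(res, "diagnostics") <- diag_
  res
}

# Greedy NMS peak extraction: strongest remaining cell above `cutoff`,
# suppress a disc of `radius` around it, at most `max_peaks` peaks.
find_peaks <- function(channel, cutoff, radius, max_peaks) {
  Hm <- nrow(channel); Wm <- ncol(channel)
  ch <- channel
  peaks <- list()
  while (length(peaks) < max_peaks) {
    i <- which.max(ch)
    v <- ch[i]
    if (!length(v) || v <= cutoff) break
    cy <- (i - 1L) %% Hm; cx <- (i - 1L) %/% Hm
    peaks[[length(peaks) + 1L]] <- list(cx = cx, cy = cy, value = channel[i])
    xs <- max(0L, cx - radius):min(Wm - 1L, cx + radius)
    ys <- max(0L, cy - radius):min(Hm - 1L, cy + radius)
    dx <- rep(xs - cx, each = length(ys)); dy <- rep(ys - cy, times = length(xs))
    disc <- dx * dx + dy * dy <= radius^2
    idx <- (rep(xs, each = length(ys)))[disc] * Hm + (rep(ys, times = length(xs)))[disc] + 1L
    ch[idx] <- -Inf
  }
  peaks
}

peak_identity <- function(identity_map, cx, cy, rho) {
  majority_label_near(identity_map, cx, cy, rho)
}

#' Run the network over frames and assemble a track
#'
#' Applies the model to each frame, decodes it (single or social
#' pipeline) and optionally applies temporal identity correction.
#'
#' @param model An `adpt_model`.
#' @param frames List of `adpt_frame`s or images.
#' @param config An [adpt_config()].
#' @param skeleton An `adpt_skeleton` (for the center keypoint).
#' @param social Use the identity-aware social decoding pipeline.
#' @param correct_identities Apply [temporal_identity_correction()].
#' @return An `adpt_track`.
#' @export
predict_track <- function(model, frames, config, skeleton, social = FALSE,
                          correct_identities = social) {
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    img <- if (inherits(frames[[f]], "adpt_frame")) frames[[f]]$image else frames[[f]]
    heads <- model_forward(model, img, config)
    if (!social) {
      det <- decode_single(heads, config)
      kp <- as.matrix(det[, c("x", "y")])
      out[[f]] <- list(list(keypoints = kp, confidence = det$confidence,
                            identity = 1L,
                            center = kp[skeleton$center_index, ]))
    } else {
      lab <- lrss_argmax_labels(heads$lrss_prob)
      idm <- build_identity_map(lab, heads$baf, config)
      dets <- decode_social(heads, idm, config)
      insts <- list()
      for (id in seq_along(dets)) {
        det <- dets[[id]]
        if (!any(det$valid)) next
        kp <- as.matrix(det[, c("x", "y")])
        insts[[length(insts) + 1L]] <-
          list(keypoints = kp, confidence = det$confidence,
               identity = as.integer(names(dets)[id]),
               center = if (det$valid[skeleton$center_index])
                 kp[skeleton$center_index, ] else colMeans(kp[det$valid, , drop = FALSE]))
      }
      out[[f]] <- insts
    }
  }
  tr <- pose_track(out, keypoint_names = skeleton$names)
  if (correct_identities) tr <- temporal_identity_correction(tr, config)
  tr
}

lrss_argmax_labels <- function(lrss_prob) {
  Hm <- dim(lrss_prob)[1L]; Wm <- dim(lrss_prob)[2L]
  lab <- matrix(0L, Hm, Wm)
  flat <- matrix(lrss_prob, Hm * Wm, dim(lrss_prob)[3L])
  lab[] <- max.col(flat, ties.method = "first") - 1L
  lab
}
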