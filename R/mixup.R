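#' Extract an animal foreground by background subtraction
#'
#' Keeps the pixels whose channel-maximum absolute difference from the
#' background reaches `delta` (inclusive); everything else becomes 0. An
#' optional exclusion mask (e.g. a previously extracted animal) blanks
#' pixels already claimed.
#'
#' @param frame,background Numeric `H x W x C` arrays on the 0..255
#'   scale, same geometry (hard error otherwise).
#' @param delta Scalar intensity threshold, > 0.
#' @param exclusion_mask Optional logical `H x W` matrix; `TRUE` cells
#'   are excluded from the foreground.
#' @return List with `image` (masked foreground, 0 off-mask) and `mask`
#'   (logical `H x W`).
#' @export
extract_foreground <- function(frame, background, delta, exclusion_mask = NULL) {
  if (length(dim(frame)) == 2L) dim(frame) <- c(dim(frame), 1L)
  if (length(dim(background)) == 2L) dim(background) <- c(dim(background), 1L)
  if (!identical(dim(frame), dim(background))) {
    stop("frame and background geometry differ: ",
         paste(dim(frame), collapse = "x"), " vs ",
         paste(dim(background), collapse = "x"))
  }
  stopifnot(delta > 0)
  diff <- abs(frame - background)
  mask <- apply(diff, c(1L, 2L), max) >= delta
  if (!is.null(exclusion_mask)) mask <- mask & !exclusion_mask
  out <- frame
  for (ch in seq_len(dim(frame)[3L])) {
    sl <- out[, , ch]
    sl[!mask] <- 0
    out[, , ch] <- sl
  }
  list(image = out, mask = mask)
}

#' Composite two single-animal frames into one social frame
#'
#' Hard mix-up composite: animal 1 = pixels of `frame1` differing from
#' the background by at least `delta`; animal 2 = pixels of `frame2`
#' differing by at least `delta` *and* not claimed by animal 1; the
#' background fills the rest. No blending — every pixel comes from
#' exactly one source. The merged annotation relabels `frame1`'s
#' instance as identity 1 and `frame2`'s as identity 2; keypoints of
#' animal 2 that fall under animal 1's mask are marked occluded
#' (visibility 0).
#'
#' @param frame1,frame2 `adpt_frame`s over the same background.
#' @param background Numeric `H x W x C` array.
#' @param spec A [mixup_spec()] (only `delta` is used here).
#' @return An `adpt_frame` with two instances (or one, when a frame
#'   contributed no foreground and no annotation).
#' @export
mixup_frame <- function(frame1, frame2, background, spec = mixup_spec()) {
  if (length(dim(background)) == 2L) dim(background) <- c(dim(background), 1L)
  if (!identical(dim(frame1$image), dim(background)) ||
      !identical(dim(frame2$image), dim(background))) {
    stop("background geometry must match both frames")
  }
  m1 <- extract_foreground(frame1$image, background, spec$delta)
  m2 <- extract_foreground(frame2$image, background, spec$delta,
                           exclusion_mask = m1$mask)
  comp <- background
  for (ch in seq_len(dim(background)[3L])) {
    sl <- comp[, , ch]
    sl[m1$mask] <- frame1$image[, , ch][m1$mask]
    sl[m2$mask] <- frame2$image[, , ch][m2$mask]
    comp[, , ch] <- sl
  }
  insts <- list()
  for (inst in frame1$instances) {
    insts[[length(insts) + 1L]] <-
      list(identity = 1L, keypoints = inst$keypoints, visibility = inst$visibility)
  }
  H <- dim(background)[1L]; W <- dim(background)[2L]
  for (inst in frame2$instances) {
    v <- inst$visibility
    for (k in which(v)) {
      px <- as.integer(round(inst$keypoints[k, 1L])) + 1L
      py <- as.integer(round(inst$keypoints[k, 2L])) + 1L
      if (px >= 1L && px <= W && py >= 1L && py <= H && m1$mask[py, px]) v[k] <- FALSE
    }
    insts[[length(insts) + 1L]] <-
      list(identity = 2L, keypoints = inst$keypoints, visibility = v)
  }
  structure(list(image = comp, instances = insts), class = "adpt_frame")
}

#' Specification of a mix-up generation run
#'
#' @param delta Per-pixel foreground threshold on 8-bit intensities,
#'   > 0 (default 20).
#' @param seed Integer RNG seed; a fixed seed reproduces the dataset
#'   byte for byte.
#' @param pool1,pool2 Lists of single-animal `adpt_frame`s for animal 1
#'   and animal 2.
#' @param backgrounds List of background images.
#' @return An object of class `adpt_mixup_spec`.
#' @export
mixup_spec <- function(delta = 20, seed = 0L, pool1 = list(), pool2 = list(),
                       backgrounds = list()) {
  stopifnot(delta > 0)
  structure(list(delta = delta, seed = as.integer(seed),
                 pool1 = pool1, pool2 = pool2, backgrounds = backgrounds),
            class = "adpt_mixup_spec")
}

#' Generate a mix-up social dataset with identity-aware targets
#'
#' Draws `n` random (frame1, frame2, background) triples from the spec's
#' pools, composites each with [mixup_frame()], and encodes
#' identity-aware LRSS (labels 0, 1, 2 for a two-animal task) and BAF
#' targets anchored at the skeleton's center keypoint.
#'
#' @param spec A [mixup_spec()] with non-empty pools.
#' @param n Number of composites.
#' @param skeleton An `adpt_skeleton`.
#' @param config An [adpt_config()]; its `n_identities` must be >= 2.
#' @return List of length `n`; each element has `frame` (`adpt_frame`)
#'   and `targets` (`adpt_targets` with `baf`).
#' @export
generate_mixup_dataset <- function(spec, n, skeleton, config) {
  if (n == 0L) return(list())
  stopifnot(length(spec$pool1) > 0, length(spec$pool2) > 0,
            length(spec$backgrounds) > 0)
  with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      f1 <- spec$pool1[[sample.int(length(spec$pool1), 1L)]]
      f2 <- spec$pool2[[sample.int(length(spec$pool2), 1L)]]
      bg <- spec$backgrounds[[sample.int(length(spec$backgrounds), 1L)]]
      fr <- mixup_frame(f1, f2, bg, spec)
      tg <- make_target_maps(fr, skeleton, config,
                             identity_aware = TRUE, with_baf = TRUE)
      list(frame = fr, targets = tg)
    })
  })
}
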