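#' Augment a labeled frame with a random similarity transform
#'
#' Samples one similarity transform (rotation about the image center,
#' isotropic scale, pixel translation) from the ranges configured for the
#' requested training protocol and applies it jointly to the image (by
#' inverse-mapped nearest-neighbour warping) and to every keypoint.
#' Keypoints pushed outside the image are marked not visible. The same
#' seed always yields the same output.
#'
#' Protocols: `identity_task` uses rotation +/-30 degrees, translation
#' x in \[-100, 100\], y in \[-30, 15\] and scale in \[0.9, 1.1\];
#' `social_task` uses the pixel translation only; `default` is a mild
#' rotate-and-rescale.
#'
#' @param frame An `adpt_frame`.
#' @param rng_seed Integer seed; the global RNG state is left untouched.
#' @param mode One of `"identity_task"`, `"social_task"`, `"default"`.
#' @param config An [adpt_config()] holding the `augment` ranges.
#' @param params Optional list overriding the sampled transform, with
#'   elements `rotate` (degrees), `tx`, `ty` (pixels), `scale`.
#' @return The transformed `adpt_frame`. Frames whose keypoints all land
#'   outside are returned with all visibility flags cleared, never an
#'   error.
#' @export
augment_frame <- function(frame, rng_seed = 0L,
                          mode = c("default", "identity_task", "social_task"),
                          config = adpt_config(), params = NULL) {
  mode <- match.arg(mode)
  if (is.null(params)) {
    rg <- config$augment[[mode]]
    params <- with_seed(rng_seed, list(
      rotate = stats::runif(1, rg$rotate[1L], rg$rotate[2L]),
      tx     = stats::runif(1, rg$tx[1L], rg$tx[2L]),
      ty     = stats::runif(1, rg$ty[1L], rg$ty[2L]),
      scale  = stats::runif(1, rg$scale[1L], rg$scale[2L])
    ))
  }
  apply_similarity(frame, params)
}

# Forward map: p' = s R (p - c) + c + t  with c the image center.
apply_similarity <- function(frame, params) {
  H <- dim(frame$image)[1L]; W <- dim(frame$image)[2L]
  th <- params$rotate * pi / 180
  s <- params$scale
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  ct <- cos(th); st <- sin(th)

  img <- warp_image_similarity(frame$image, th, s, cx, cy, params$tx, params$ty)

  inst <- lapply(frame$instances, function(i) {
    x0 <- i$keypoints[, 1L] - cx; y0 <- i$keypoints[, 2L] - cy
    x1 <- s * (ct * x0 - st * y0) + cx + params$tx
    y1 <- s * (st * x0 + ct * y0) + cy + params$ty
    kp <- cbind(x = x1, y = y1)
    v <- i$visibility & x1 > -0.5 & x1 < W - 0.5 & y1 > -0.5 & y1 < H - 0.5
    kp[!v, ] <- 0
    list(identity = i$identity, keypoints = kp, visibility = v)
  })
  structure(list(image = img, instances = inst), class = "adpt_frame")
}

# Nearest-neighbour warp by inverse mapping; out-of-source pixels -> 0.
warp_image_similarity <- function(image, th, s, cx, cy, tx, ty) {
  H <- dim(image)[1L]; W <- dim(image)[2L]; C <- dim(image)[3L]
  ct <- cos(th); st <- sin(th)
  gx <- rep(0:(W - 1), each = H) - cx - tx
  gy <- rep(0:(H - 1), times = W) - cy - ty
  sx <- (ct * gx + st * gy) / s + cx
  sy <- (-st * gx + ct * gy) / s + cy
  ix <- as.integer(round(sx)) + 1L
  iy <- as.integer(round(sy)) + 1L
  ok <- ix >= 1L & ix <= W & iy >= 1L & iy <= H
  out <- array(0, dim(image))
  lin_out <- which(ok)
  lin_src <- (ix[ok] - 1L) * H + iy[ok]
  for (ch in seq_len(C)) {
    off <- (ch - 1L) * H * W
    out[off + lin_out] <- image[off + lin_src]
  }
  out
}

# Evaluate expr with a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
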