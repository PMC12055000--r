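#' Construct a labeled frame
#'
#' A labeled frame pairs an image with per-individual keypoint annotations.
#' Coordinates are 0-based pixels, origin at the top-left corner, x
#' rightward, y downward, with a keypoint located at the center of its
#' pixel. Images are numeric `H x W x C` arrays on the 0..255 intensity
#' scale.
#'
#' @param image Numeric array `H x W x C` (C = 1 or 3), values in 0..255.
#' @param instances List of instances as built by [pose_instance()].
#' @return An object of class `adpt_frame`.
#' @export
labeled_frame <- function(image, instances = list()) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  stopifnot(length(dim(image)) == 3L)
  ids <- vapply(instances, function(i) i$identity, integer(1))
  if (anyDuplicated(ids)) stop("identities within a frame must be unique")
  fr <- structure(list(image = image, instances = instances), class = "adpt_frame")
  validate_frame(fr)
  fr
}

#' Construct one pose instance
#'
#' @param keypoints `K x 2` numeric matrix of `(x, y)` pixel coordinates.
#' @param visibility Logical / 0-1 vector of length K; `FALSE`/0 means the
#'   keypoint is not annotated (or occluded) and contributes to no target.
#'   `NA` coordinates are coerced to invisible.
#' @param identity Small positive integer identity label.
#' @return A list with elements `identity`, `keypoints`, `visibility`.
#' @export
pose_instance <- function(keypoints, visibility = NULL, identity = 1L) {
  keypoints <- matrix(as.numeric(keypoints), ncol = 2L,
                      dimnames = list(NULL, c("x", "y")))
  if (is.null(visibility)) visibility <- rep(TRUE, nrow(keypoints))
  visibility <- as.logical(visibility)
  bad <- is.na(keypoints[, 1L]) | is.na(keypoints[, 2L])
  visibility[bad] <- FALSE
  keypoints[bad, ] <- 0
  identity <- as.integer(identity)
  if (identity < 1L) stop("identity must be a positive integer")
  list(identity = identity, keypoints = keypoints, visibility = visibility)
}

validate_frame <- function(frame) {
  H <- dim(frame$image)[1L]; W <- dim(frame$image)[2L]
  for (inst in frame$instances) {
    kp <- inst$keypoints; v <- inst$visibility
    stopifnot(nrow(kp) == length(v))
    vis <- which(v)
    if (length(vis)) {
      x <- kp[vis, 1L]; y <- kp[vis, 2L]
      if (any(x < -0.5 | x > W - 0.5 | y < -0.5 | y > H - 0.5)) {
        stop("visible keypoints must lie within image bounds")
      }
    }
  }
  invisible(frame)
}

#' @export
print.adpt_frame <- function(x, ...) {
  d <- dim(x$image)
  cat("<adpt_frame> ", d[1L], "x", d[2L], "x", d[3L], ", ",
      length(x$instances), " instance(s)\n", sep = "")
  invisible(x)
}

frame_size <- function(frame) dim(frame$image)[1:2]

#' Read / write an image as PNG
#'
#' Thin wrappers over the png package converting between files and the
#' package's 0..255 numeric `H x W x C` arrays.
#' @param path File path.
#' @param image Numeric array on the 0..255 scale.
#' @return `read_image` returns the array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img * 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  img <- pmin(pmax(image / 255, 0), 1)
  if (dim(img)[3L] == 1L) img <- img[, , 1L]
  png::writePNG(img, path)
  invisible(path)
}

# Rescale a frame (image nearest-neighbour + keypoints) by factor s <= 1.
# Keypoint at pixel-center x maps to (x + 0.5) * s - 0.5.
rescale_frame <- function(frame, s) {
  if (s == 1) return(frame)
  H <- dim(frame$image)[1L]; W <- dim(frame$image)[2L]
  Hn <- max(1L, floor(H * s)); Wn <- max(1L, floor(W * s))
  ys <- pmin(H, pmax(1L, floor((seq_len(Hn) - 0.5) / s + 0.5)))
  xs <- pmin(W, pmax(1L, floor((seq_len(Wn) - 0.5) / s + 0.5)))
  img <- frame$image[ys, xs, , drop = FALSE]
  inst <- lapply(frame$instances, function(i) {
    kp <- (i$keypoints + 0.5) * s - 0.5
    v <- i$visibility & kp[, 1L] > -0.5 & kp[, 1L] < Wn - 0.5 &
      kp[, 2L] > -0.5 & kp[, 2L] < Hn - 0.5
    kp[!v, ] <- 0
    list(identity = i$identity, keypoints = kp, visibility = v)
  })
  structure(list(image = img, instances = inst), class = "adpt_frame")
}
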