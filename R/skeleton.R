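#' Define a keypoint skeleton
#'
#' A skeleton names the body keypoints, the directed limb edges connecting
#' them (used to paint the low-resolution semantic segmentation), the
#' designated body-center keypoint (the anchor of the body affinity field),
#' and the rule used to derive the per-instance PCK normalisation length.
#'
#' @param names Character vector of keypoint labels, in channel order.
#' @param edges Two-column integer matrix (or list of length-2 vectors) of
#'   1-based keypoint index pairs `(i, j)`; each row is one limb segment.
#' @param center Keypoint used as the body center: a label or a 1-based
#'   index. For mice the back is the conventional choice.
#' @param pck_reference Rule for the per-instance reference length `L`
#'   used by [pck()]: `"bbox_sqrt"` (square root of the bounding-box area
#'   of the visible keypoints, the default) or `"edge"` together with
#'   `pck_edge`, the 1-based index of the edge whose length is used.
#' @param pck_edge Integer edge index, only for `pck_reference = "edge"`.
#'
#' @return An object of class `adpt_skeleton` with elements `names`,
#'   `edges` (0-based internally stored as 1-based matrix), `center_index`,
#'   `pck_reference`, `pck_edge`.
#' @examples
#' sk <- skeleton(
#'   names  = c("nose", "back", "tailroot", "paw_l", "paw_r"),
#'   edges  = rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5)),
#'   center = "back"
#' )
#' sk$center_index
#' @export
skeleton <- function(names, edges, center,
                     pck_reference = c("bbox_sqrt", "edge"),
                     pck_edge = 1L) {
  stopifnot(is.character(names), length(names) >= 1L, !anyDuplicated(names))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.integer(edges), ncol = 2L)
  K <- length(names)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > K)) {
      stop("edge indices must be valid keypoint indices (1..", K, ")")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not allowed")
  }
  if (is.character(center)) {
    center_index <- match(center, names)
    if (is.na(center_index)) stop("center keypoint '", center, "' not in names")
  } else {
    center_index <- as.integer(center)
    if (center_index < 1L || center_index > K) stop("center_index out of range")
  }
  structure(
    list(
      names = names,
      edges = edges,
      center_index = center_index,
      pck_reference = match.arg(pck_reference),
      pck_edge = as.integer(pck_edge)
    ),
    class = "adpt_skeleton"
  )
}

#' @export
print.adpt_skeleton <- function(x, ...) {
  cat("<adpt_skeleton> ", length(x$names), " keypoints, ",
      nrow(x$edges), " edges; center = '", x$names[x$center_index], "'\n",
      sep = "")
  invisible(x)
}

#' Number of keypoints in a skeleton
#' @param skeleton An `adpt_skeleton`.
#' @return Integer count of keypoints.
#' @export
n_keypoints <- function(skeleton) length(skeleton$names)

#' The default toy 5-keypoint rodent-like skeleton
#'
#' Nose, back (the body center), tail root and two paws; limbs connect the
#' back to every other keypoint. Used throughout the synthetic fixtures.
#' @return An `adpt_skeleton`.
#' @export
toy_skeleton <- function() {
  skeleton(
    names  = c("nose", "back", "tailroot", "paw_l", "paw_r"),
    edges  = rbind(c(2L, 1L), c(2L, 3L), c(2L, 4L), c(2L, 5L)),
    center = "back"
  )
}

skeleton_to_list <- function(sk) {
  list(
    names = sk$names,
    edges = lapply(seq_len(nrow(sk$edges)), function(i) as.integer(sk$edges[i, ])),
    center = sk$names[sk$center_index],
    pck_reference = sk$pck_reference,
    pck_edge = sk$pck_edge
  )
}

skeleton_from_list <- function(x) {
  skeleton(
    names = as.character(unlist(x$names)),
    edges = if (length(x$edges)) do.call(rbind, lapply(x$edges, as.integer)) else matrix(integer(), ncol = 2L),
    center = x$center,
    pck_reference = if (is.null(x$pck_reference)) "bbox_sqrt" else x$pck_reference,
    pck_edge = if (is.null(x$pck_edge)) 1L else as.integer(x$pck_edge)
  )
}

#' Write / read a skeleton as YAML
#' @param skeleton An `adpt_skeleton`.
#' @param path File path.
#' @return `read_skeleton` returns an `adpt_skeleton`; `write_skeleton`
#'   returns `path` invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  yaml::write_yaml(skeleton_to_list(skeleton), path)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) skeleton_from_list(yaml::read_yaml(path))
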