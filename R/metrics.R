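#' Per-keypoint tracking-drift fraction
#'
#' Fraction of frames whose frame-to-frame Euclidean displacement exceeds
#' the drift distance threshold `alpha` (50 px is the mouse default,
#' 30 px the monkey default), per keypoint, with the printed `1/F`
#' normalisation. The indicator counts displacement strictly greater than
#' `alpha`; `count_stable = TRUE` flips it to count the complementary
#' stable frames instead.
#'
#' @param track A pose track: either an `adpt_track` (see
#'   [pose_track()]) or a numeric array `F x K x 2` of coordinates.
#' @param alpha Drift distance threshold in pixels.
#' @param count_stable Flip the indicator direction.
#' @return Named numeric vector of per-keypoint fractions in \[0, 1\].
#' @export
drift_fraction <- function(track, alpha = 50, count_stable = FALSE) {
  xy <- track_coords(track)
  F <- dim(xy)[1L]
  if (F < 2L) stop("drift_fraction needs at least 2 frames")
  d <- sqrt(apply((xy[-1L, , , drop = FALSE] - xy[-F, , , drop = FALSE])^2,
                  c(1L, 2L), sum))
  hits <- if (count_stable) d <= alpha else d > alpha
  out <- colSums(hits) / F
  names(out) <- dimnames(xy)[[2L]]
  out
}

#' Per-keypoint detection-failure fraction
#'
#' Fraction of frames whose confidence score is at or below the cutoff
#' (inclusive; the default cutoff is 0.2).
#'
#' @param track An `adpt_track` or a numeric `F x K` confidence matrix.
#' @param cutoff Confidence cutoff.
#' @return Named numeric vector of per-keypoint fractions.
#' @export
miss_fraction <- function(track, cutoff = 0.2) {
  conf <- track_confidence(track)
  colMeans(conf <= cutoff)
}

#' Identity change rate
#'
#' For each identity's center trajectory, the fraction of frames whose
#' center displacement exceeds `alpha` (default 75 px), normalised by
#' `1/F` and averaged over identities. Center jumps beyond plausible
#' motion signal identity exchanges.
#'
#' @param centers Numeric array `F x n_identities x 2`, or a list of
#'   `F x 2` matrices (one per identity), or an `adpt_track` with centers.
#' @param alpha Distance threshold in pixels.
#' @param count_stable Flip the indicator direction (see
#'   [drift_fraction()]).
#' @return Single numeric fraction in \[0, 1\].
#' @export
change_rate <- function(centers, alpha = 75, count_stable = FALSE) {
  if (inherits(centers, "adpt_track")) centers <- track_centers(centers)
  if (is.list(centers) && !is.array(centers)) {
    centers <- simplify2array(centers)       # F x 2 x n -> permute
    centers <- aperm(centers, c(1L, 3L, 2L))
  }
  F <- dim(centers)[1L]
  if (F < 2L) stop("change_rate needs at least 2 frames")
  d <- sqrt(apply((centers[-1L, , , drop = FALSE] -
                     centers[-F, , , drop = FALSE])^2, c(1L, 2L), sum))
  hits <- if (count_stable) d <= alpha else d > alpha
  mean(colSums(hits) / F)
}

#' Percentage of correct keypoints (PCK)
#'
#' Fraction of visible ground-truth keypoints whose prediction error is
#' within `tau * L`, where `L` is the per-instance reference length given
#' by `skeleton$pck_reference` (default: square root of the visible
#' ground-truth bounding-box area).
#'
#' @param predictions,ground_truth `K x 2` matrices, or lists of such
#'   matrices (paired instances).
#' @param skeleton An `adpt_skeleton`.
#' @param tau Fraction of the reference length; default 0.15.
#' @param visibility Logical vector / list of vectors; defaults to all
#'   visible.
#' @return Score in \[0, 1\]; `NaN` (with attribute `undefined = TRUE`)
#'   when no keypoint is visible.
#' @export
pck <- function(predictions, ground_truth, skeleton, tau = 0.15,
                visibility = NULL) {
  if (!is.list(predictions)) predictions <- list(predictions)
  if (!is.list(ground_truth)) ground_truth <- list(ground_truth)
  if (!is.null(visibility) && !is.list(visibility)) visibility <- list(visibility)
  hits <- 0L; total <- 0L
  for (i in seq_along(predictions)) {
    gt <- ground_truth[[i]]; pr <- predictions[[i]]
    v <- if (is.null(visibility)) rep(TRUE, nrow(gt)) else as.logical(visibility[[i]])
    if (!any(v)) next
    L <- pck_reference_length(gt, v, skeleton)
    d <- sqrt(rowSums((pr - gt)^2))
    hits <- hits + sum(d[v] <= tau * L)
    total <- total + sum(v)
  }
  if (total == 0L) return(structure(NaN, undefined = TRUE))
  hits / total
}

pck_reference_length <- function(gt, v, skeleton) {
  if (skeleton$pck_reference == "edge") {
    e <- skeleton$edges[skeleton$pck_edge, ]
    return(sqrt(sum((gt[e[1L], ] - gt[e[2L], ])^2)))
  }
  w <- diff(range(gt[v, 1L])); h <- diff(range(gt[v, 2L]))
  sqrt(w * h)
}

#' Object keypoint similarity (OKS)
#'
#' `mean over visible i of exp(-d_i^2 / (2 * area * (2 s)^2))` with `area`
#' the ground-truth instance bounding-box area and `s` the uncertainty
#' factor (default 0.025). `mode = "coco"` instead uses the COCO-style
#' per-keypoint constants `kappa_i`:
#' `exp(-d_i^2 / (2 * area * kappa_i^2))`.
#'
#' @param predictions,ground_truth `K x 2` coordinate matrices.
#' @param area Ground-truth bounding-box area in pixels squared.
#' @param s Uncertainty factor.
#' @param visibility Logical vector; at least one keypoint must be
#'   visible (hard error otherwise, the denominator is zero).
#' @param mode `"printed"` (the default form above) or `"coco"`.
#' @param kappa Per-keypoint constants for `mode = "coco"`; default
#'   `2 * s` for every keypoint.
#' @return OKS score in \[0, 1\].
#' @export
oks <- function(predictions, ground_truth, area, s = 0.025,
                visibility = NULL, mode = c("printed", "coco"), kappa = NULL) {
  mode <- match.arg(mode)
  stopifnot(area > 0, s > 0)
  if (is.null(visibility)) visibility <- rep(TRUE, nrow(ground_truth))
  v <- as.logical(visibility)
  if (!any(v)) stop("OKS undefined: no visible keypoints")
  d2 <- rowSums((predictions - ground_truth)^2)
  denom <- if (mode == "printed") {
    rep(2 * area * (2 * s)^2, nrow(ground_truth))
  } else {
    if (is.null(kappa)) kappa <- rep(2 * s, nrow(ground_truth))
    2 * area * kappa^2
  }
  mean(exp(-d2[v] / denom[v]))
}

#' Average precision over OKS thresholds and mAP
#'
#' `AP@alpha` is the fraction of instances with OKS strictly greater than
#' `alpha`; `mAP` averages AP over the ten thresholds 0.50, 0.55, ...,
#' 0.95.
#'
#' @param oks_values Numeric vector of per-instance OKS scores in \[0, 1\].
#' @param thresholds Numeric thresholds.
#' @return List with `ap` (named per-threshold vector) and `map` (their
#'   mean).
#' @export
map_score <- function(oks_values, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (length(oks_values) == 0L) stop("map_score needs at least one OKS value")
  ap <- vapply(thresholds, function(a) mean(oks_values > a), numeric(1))
  names(ap) <- sprintf("AP@%.2f", thresholds)
  list(ap = ap, map = mean(ap))
}

#' Root-mean-square keypoint error
#'
#' Square root of the mean squared Euclidean distance between paired
#' predictions and ground truth. When `confidence_cutoff` is given, only
#' predictions with confidence strictly greater than the cutoff enter
#' (the 0.2 and 0.6 reporting modes).
#'
#' @param predictions,ground_truth `n x 2` coordinate matrices.
#' @param confidence Optional numeric vector of prediction confidences.
#' @param confidence_cutoff Optional cutoff.
#' @return RMSE in pixels; `NaN` with attribute `undefined = TRUE` when
#'   nothing passes the cutoff.
#' @export
rmse_px <- function(predictions, ground_truth, confidence = NULL,
                    confidence_cutoff = NULL) {
  keep <- rep(TRUE, nrow(ground_truth))
  if (!is.null(confidence_cutoff)) {
    if (is.null(confidence)) stop("confidence_cutoff given without confidences")
    keep <- confidence > confidence_cutoff
  }
  if (!any(keep)) return(structure(NaN, undefined = TRUE))
  d2 <- rowSums((predictions[keep, , drop = FALSE] -
                   ground_truth[keep, , drop = FALSE])^2)
  sqrt(mean(d2))
}

#' Summarise drift and miss behaviour of a track
#'
#' @param track An `adpt_track`.
#' @param config An [adpt_config()] supplying `drift_alpha`, `cutoff`
#'   and `change_alpha`.
#' @param keypoint_names Optional labels for the report rows.
#' @return An object of class `adpt_drift_report`: list with
#'   `per_keypoint` (data.frame of drift / miss fractions), `overall`
#'   drift and miss, `change_rate` (when centers are present), and the
#'   thresholds used.
#' @export
drift_report <- function(track, config = adpt_config(), keypoint_names = NULL) {
  dr <- drift_fraction(track, alpha = config$drift_alpha)
  ms <- miss_fraction(track, cutoff = config$cutoff)
  per <- data.frame(keypoint = keypoint_names %||% seq_along(dr),
                    drift = as.numeric(dr), miss = as.numeric(ms))
  cr <- NULL
  if (inherits(track, "adpt_track") && !is.null(track_centers(track))) {
    cr <- tryCatch(change_rate(track, alpha = config$change_alpha),
                   error = function(e) NULL)
  }
  structure(list(per_keypoint = per,
                 overall = c(drift = mean(per$drift), miss = mean(per$miss)),
                 change_rate = cr,
                 thresholds = c(drift_alpha = config$drift_alpha,
                                cutoff = config$cutoff,
                                change_alpha = config$change_alpha)),
            class = "adpt_drift_report")
}

#' @export
print.adpt_drift_report <- function(x, ...) {
  cat("<adpt_drift_report> overall drift", sprintf("%.4f", x$overall["drift"]),
      "miss", sprintf("%.4f", x$overall["miss"]), "\n")
  if (!is.null(x$change_rate)) cat("  change rate", sprintf("%.4f", x$change_rate), "\n")
  invisible(x)
}

#' Write a drift report as JSON and CSV
#' @param report An `adpt_drift_report`.
#' @param prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>.csv`.
#' @return The two paths, invisibly.
#' @export
write_drift_report <- function(report, prefix) {
  jp <- paste0(prefix, ".json"); cp <- paste0(prefix, ".csv")
  jsonlite::write_json(list(
    overall = as.list(report$overall),
    change_rate = report$change_rate,
    thresholds = as.list(report$thresholds),
    per_keypoint = report$per_keypoint
  ), jp, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_keypoint, cp, row.names = FALSE)
  invisible(c(jp, cp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
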