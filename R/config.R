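#' Build a configuration object
#'
#' Central bag of tunable parameters shared by target encoding, training,
#' decoding and evaluation. All defaults follow the package's standard
#' single-animal protocol; the identity / social protocols override the
#' schedule and augmentation through the `mode` arguments of the relevant
#' functions.
#'
#' @param global_scale Image resize factor applied before the network,
#'   in (0, 1]. Full-resolution coordinates are used everywhere outside the
#'   network; rescaling is internal.
#' @param stride Integer ratio between input image and head resolution;
#'   must be a power of two (the architecture emits heads at 1/8).
#' @param sigma Gaussian width of the confidence-heatmap targets, in
#'   output-map cells.
#' @param locref_radius Radius (map cells) around each keypoint within
#'   which the location-refinement loss applies; default `2 * sigma`.
#' @param lrss_thickness Rasterisation thickness of limb segments in the
#'   low-resolution segmentation, in map cells.
#' @param n_identities Number of identity classes (LRSS emits
#'   `n_identities + 1` channels, channel 0 = background).
#' @param cutoff Confidence cutoff: a keypoint with confidence at or below
#'   this value counts as a detection failure.
#' @param drift_alpha Drift distance threshold in pixels (50 for mice,
#'   30 for monkeys).
#' @param change_alpha Identity change-rate distance threshold in pixels.
#' @param nms_radius Non-maximum-suppression radius for multi-peak
#'   decoding, in head cells.
#' @param identity_radius Window radius (head cells) used when reading
#'   identities off the identity map, and for the background fallback.
#' @param smoothing_window Sliding window (frames, odd) for the majority
#'   smoothing step of temporal identity correction.
#' @param hysteresis Displacement margin (pixels) a motion-based relabel
#'   must win by before it overrides a raw identity.
#' @param loss_weights Named numeric vector of head loss weights
#'   (`heatmap`, `locref`, `lrss`, `baf`).
#' @param epochs,warmup_epochs,iters_per_epoch,batch_size Training
#'   schedule; the single-animal protocol is 190 epochs with 10 warm-up
#'   epochs at batch size 8.
#' @param lr_min,lr_max Learning-rate bounds of the warmup-cosine
#'   schedule: linear ramp `lr_min -> lr_max` over the warm-up epochs,
#'   then cosine decay back to `lr_min`.
#' @param weight_decay Decoupled weight-decay rate of the optimiser.
#' @param patience Early-stopping plateau length in epochs.
#' @param monitor Which loss the early stopper watches: `"val"` for
#'   single-animal training, `"train"` for identity / social training.
#' @param mixup_delta Foreground threshold on 8-bit intensities for the
#'   mix-up compositing.
#' @param oks_s OKS uncertainty factor.
#' @param augment Named list of per-mode augmentation ranges; see
#'   [augment_frame()].
#' @param ... Additional named entries stored verbatim.
#'
#' @return An object of class `adpt_config` (a named list).
#' @examples
#' cfg <- adpt_config(n_identities = 2)
#' cfg$cutoff
#' @export
adpt_config <- function(global_scale = 1,
                        stride = 8L,
                        sigma = 3,
                        locref_radius = NULL,
                        lrss_thickness = 2,
                        n_identities = 1L,
                        cutoff = 0.2,
                        drift_alpha = 50,
                        change_alpha = 75,
                        nms_radius = 5L,
                        identity_radius = 3L,
                        smoothing_window = 15L,
                        hysteresis = 20,
                        loss_weights = c(heatmap = 1, locref = 1, lrss = 1, baf = 1),
                        epochs = 190L,
                        warmup_epochs = 10L,
                        iters_per_epoch = NULL,
                        batch_size = 8L,
                        lr_min = 1e-5,
                        lr_max = 1e-3,
                        weight_decay = 1e-4,
                        patience = 30L,
                        monitor = c("val", "train"),
                        mixup_delta = 20,
                        oks_s = 0.025,
                        augment = NULL,
                        ...) {
  if (!(global_scale > 0 && global_scale <= 1)) stop("global_scale must be in (0, 1]")
  stride <- as.integer(stride)
  if (stride < 1L || bitwAnd(stride, stride - 1L) != 0L) stop("stride must be a power of two")
  if (!(sigma > 0)) stop("sigma must be > 0")
  if (is.null(locref_radius)) locref_radius <- 2 * sigma
  if (is.null(augment)) augment <- default_augment_ranges()
  cfg <- list(
    global_scale = global_scale, stride = stride, sigma = sigma,
    locref_radius = locref_radius, lrss_thickness = lrss_thickness,
    n_identities = as.integer(n_identities), cutoff = cutoff,
    drift_alpha = drift_alpha, change_alpha = change_alpha,
    nms_radius = as.integer(nms_radius),
    identity_radius = as.integer(identity_radius),
    smoothing_window = as.integer(smoothing_window), hysteresis = hysteresis,
    loss_weights = loss_weights,
    epochs = as.integer(epochs), warmup_epochs = as.integer(warmup_epochs),
    iters_per_epoch = if (is.null(iters_per_epoch)) NULL else as.integer(iters_per_epoch),
    batch_size = as.integer(batch_size),
    lr_min = lr_min, lr_max = lr_max, weight_decay = weight_decay,
    patience = as.integer(patience), monitor = match.arg(monitor),
    mixup_delta = mixup_delta, oks_s = oks_s, augment = augment
  )
  extra <- list(...)
  if (length(extra)) cfg[names(extra)] <- extra
  structure(cfg, class = "adpt_config")
}

# Augmentation parameter sets. identity_task and social_task follow the
# identity / social training protocols; "default" is a mild
# rotate-and-rescale in the style of standard keypoint-tool augmentation
# (exact default ranges are a package choice, see the methods vignette).
default_augment_ranges <- function() {
  list(
    identity_task = list(rotate = c(-30, 30), tx = c(-100, 100),
                         ty = c(-30, 15), scale = c(0.9, 1.1)),
    social_task   = list(rotate = c(0, 0), tx = c(-100, 100),
                         ty = c(-30, 15), scale = c(1, 1)),
    default       = list(rotate = c(-25, 25), tx = c(0, 0),
                         ty = c(0, 0), scale = c(0.75, 1.25))
  )
}

#' @export
print.adpt_config <- function(x, ...) {
  cat("<adpt_config> stride", x$stride, "sigma", x$sigma,
      "global_scale", x$global_scale, "n_identities", x$n_identities, "\n")
  invisible(x)
}

#' Read / write a configuration as YAML
#' @param config An `adpt_config`.
#' @param path File path.
#' @return `read_config` returns an `adpt_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$loss_weights <- as.list(x$loss_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$loss_weights)) x$loss_weights <- unlist(x$loss_weights)
  do.call(adpt_config, x)
}
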