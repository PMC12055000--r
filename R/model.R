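#' Specify the pose network
#'
#' The network is a cascaded CNN-transformer: a residual convolutional
#' stem extracts 1/4-scale features; three branches compute features at
#' 1/4, 1/8 and 1/16 scale and bring them all to 1/8 (stride-2
#' convolution down, learned 2x deconvolution up); the 1/16 branch is
#' flattened to tokens, receives learned 2-D positional embeddings and
#' runs through a multi-head self-attention encoder before upsampling;
#' branch outputs are concatenated by skip connections and fused by
#' convolution into four 1/8-scale heads: K heatmap channels, 2K
#' location-refinement channels, `n_identities + 1` LRSS channels
#' (softmax) and optionally 2 BAF channels.
#'
#' @param preset `"resnet_stack12"` (7x7 stem + residual stage, the
#'   full-scale default) or `"tiny"` (a 2-stage CNN stem with the same
#'   geometry, small enough for CPU work).
#' @param K Number of keypoints.
#' @param n_identities Identity classes for the LRSS head.
#' @param in_channels Image channels (3 for colour).
#' @param input_size `c(H, W)` nominal input size; fixes the token count
#'   of the learned positional embeddings (other sizes are handled by
#'   nearest-neighbour resampling at inference).
#' @param with_baf Add the 2-channel BAF head (social protocol).
#' @param no_transformer Ablation: remove the attention blocks from the
#'   1/16 branch (shapes are unchanged).
#' @param no_lrss Ablation: drop the LRSS head (other heads unchanged).
#' @param c_stem,c_backbone,n_res,c_branch,c_fuse Channel widths and
#'   residual-block count; `NULL` takes the preset default.
#' @param tf_layers,tf_heads,tf_dim,tf_mlp Transformer encoder size;
#'   `NULL` takes the preset default.
#' @return An object of class `adpt_model_spec`.
#' @export
model_spec <- function(preset = c("resnet_stack12", "tiny"),
                       K = 5L, n_identities = 1L, in_channels = 3L,
                       input_size = c(64L, 64L),
                       with_baf = FALSE, no_transformer = FALSE,
                       no_lrss = FALSE,
                       c_stem = NULL, c_backbone = NULL, n_res = NULL,
                       c_branch = NULL, c_fuse = NULL,
                       tf_layers = NULL, tf_heads = NULL,
                       tf_dim = NULL, tf_mlp = NULL) {
  preset <- match.arg(preset)
  d <- if (preset == "tiny") {
    list(c_stem = 12L, c_backbone = 24L, n_res = 0L, c_branch = 24L,
         c_fuse = 48L, tf_layers = 2L, tf_heads = 2L, tf_dim = 48L,
         tf_mlp = 96L)
  } else {
    list(c_stem = 64L, c_backbone = 256L, n_res = 3L, c_branch = 128L,
         c_fuse = 128L, tf_layers = 4L, tf_heads = 8L, tf_dim = 256L,
         tf_mlp = 512L)
  }
  spec <- list(
    preset = preset, K = as.integer(K),
    n_identities = as.integer(n_identities),
    in_channels = as.integer(in_channels),
    input_size = as.integer(input_size),
    with_baf = isTRUE(with_baf), no_transformer = isTRUE(no_transformer),
    no_lrss = isTRUE(no_lrss),
    c_stem = as.integer(c_stem %||% d$c_stem),
    c_backbone = as.integer(c_backbone %||% d$c_backbone),
    n_res = as.integer(n_res %||% d$n_res),
    c_branch = as.integer(c_branch %||% d$c_branch),
    c_fuse = as.integer(c_fuse %||% d$c_fuse),
    tf_layers = as.integer(tf_layers %||% d$tf_layers),
    tf_heads = as.integer(tf_heads %||% d$tf_heads),
    tf_dim = as.integer(tf_dim %||% d$tf_dim),
    tf_mlp = as.integer(tf_mlp %||% d$tf_mlp)
  )
  structure(spec, class = "adpt_model_spec")
}

#' Build a model from a specification
#'
#' Allocates the network and initialises its weights (He-scaled normal
#' for convolution / linear weights, unit gamma and zero beta for layer
#' norms, small normal positional embeddings, zero biases) from the
#' given seed.
#'
#' @param spec An [model_spec()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `adpt_model`.
#' @export
build_model <- function(spec, seed = 0L) {
  ptr <- nn_create(unclass(spec))
  info <- nn_param_info(ptr)
  ws <- with_seed(seed, lapply(info, function(p) {
    switch(p$kind,
      weight = matrix(stats::rnorm(p$nrow * p$ncol, 0, sqrt(2 / max(1L, p$fan_in))),
                      p$nrow, p$ncol),
      bias = matrix(0, p$nrow, p$ncol),
      ln_gamma = matrix(1, p$nrow, p$ncol),
      ln_beta = matrix(0, p$nrow, p$ncol),
      posemb = matrix(stats::rnorm(p$nrow * p$ncol, 0, 0.02), p$nrow, p$ncol),
      stop("unknown param kind ", p$kind))
  }))
  nn_set_weights(ptr, ws, reset_opt = TRUE)
  structure(list(ptr = ptr, spec = spec), class = "adpt_model")
}

#' @export
print.adpt_model <- function(x, ...) {
  cat("<adpt_model> preset '", x$spec$preset, "', ", nn_n_params(x$ptr),
      " parameters, K = ", x$spec$K, "\n", sep = "")
  invisible(x)
}

# 0..255 image -> normalized network input, padded to a multiple of 16
# (pad-and-record, never crash on awkward sizes).
prepare_input <- function(image, config) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  if (config$global_scale != 1) {
    fr <- rescale_frame(structure(list(image = image, instances = list()),
                                  class = "adpt_frame"), config$global_scale)
    image <- fr$image
  }
  H <- dim(image)[1L]; W <- dim(image)[2L]
  Hp <- 16L * ceiling(H / 16L); Wp <- 16L * ceiling(W / 16L)
  x <- array(0, c(Hp, Wp, dim(image)[3L]))
  x[seq_len(H), seq_len(W), ] <- image / 255 - 0.5
  attr(x, "pad") <- c(Hp - H, Wp - W)
  x
}

#' Run the network on one image
#'
#' Rescales by `config$global_scale`, pads to a multiple of 16, and
#' returns the head tensors (`heatmap`, `locref`, `lrss_prob`, `baf`)
#' at 1/8 of the padded input.
#'
#' @param model An `adpt_model`.
#' @param image Numeric `H x W x C` array, 0..255 scale.
#' @param config An [adpt_config()].
#' @return Named list of head arrays.
#' @export
model_forward <- function(model, image, config = adpt_config()) {
  x <- prepare_input(image, config)
  out <- nn_forward(model$ptr, x)
  out$locref <- out$locref * config$stride   # stride-normalised -> pixels
  out
}

#' Warmup-cosine learning-rate schedule
#'
#' Linear ramp from `lr_min` to `lr_max` over the warm-up epochs, then
#' cosine decay back to `lr_min` over the remaining epochs. Steps are
#' 0-based; `lr_at(0)` is `lr_min`, the end of warm-up gives `lr_max`,
#' and the final step (`epochs * iters_per_epoch`) gives `lr_min` again.
#'
#' @param step 0-based global step (may be a vector).
#' @param config An [adpt_config()] with `epochs`, `warmup_epochs`,
#'   `iters_per_epoch`, `lr_min`, `lr_max`.
#' @return Learning rate(s).
#' @export
lr_at <- function(step, config) {
  it <- config$iters_per_epoch
  if (is.null(it)) stop("config$iters_per_epoch must be set for lr_at")
  total <- config$epochs * it
  warm <- config$warmup_epochs * it
  step <- pmin(pmax(step, 0), total)
  ifelse(step < warm,
         config$lr_min + (config$lr_max - config$lr_min) * step / warm,
         config$lr_min + 0.5 * (config$lr_max - config$lr_min) *
           (1 + cos(pi * (step - warm) / (total - warm))))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file with the weight matrices plus a JSON
#' sidecar (`<path>.json`) recording the model specification and,
#' optionally, the training configuration.
#'
#' @param model An `adpt_model`.
#' @param path Checkpoint path (`.rds`).
#' @param config Optional [adpt_config()] stored in the sidecar.
#' @return `load_checkpoint` returns an `adpt_model`.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  saveRDS(list(spec = unclass(model$spec), weights = nn_get_weights(model$ptr)),
          path)
  side <- list(spec = unclass(model$spec))
  if (!is.null(config)) {
    cf <- unclass(config)
    cf$loss_weights <- as.list(cf$loss_weights)
    side$config <- cf
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- structure(ck$spec, class = "adpt_model_spec")
  model <- build_model(spec, seed = 0L)
  nn_set_weights(model$ptr, ck$weights, reset_opt = TRUE)
  model
}
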