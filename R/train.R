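#' Encode frames into a training dataset
#'
#' Pairs each labeled frame with its network input (normalised, padded)
#' and its target maps at the padded geometry.
#'
#' @param frames List of `adpt_frame`s.
#' @param skeleton An `adpt_skeleton`.
#' @param config An [adpt_config()].
#' @param identity_aware,with_baf Passed to [make_target_maps()].
#' @return List of samples, each with `x` (input array) and `targets`
#'   (list with 0-based `lrss` labels as the loss expects).
#' @export
encode_dataset <- function(frames, skeleton, config,
                           identity_aware = FALSE, with_baf = FALSE) {
  lapply(frames, function(fr) {
    x <- prepare_input(fr$image, config)
    # targets must match the padded geometry the network sees
    pad <- attr(x, "pad")
    frp <- fr
    if (any(pad > 0L)) {
      d <- dim(fr$image)
      img <- array(0, c(d[1L] + pad[1L], d[2L] + pad[2L], d[3L]))
      img[seq_len(d[1L]), seq_len(d[2L]), ] <- fr$image
      frp <- structure(list(image = img, instances = fr$instances),
                       class = "adpt_frame")
    }
    tg <- make_target_maps(frp, skeleton, config,
                           identity_aware = identity_aware, with_baf = with_baf)
    # the network learns stride-normalised offsets (balanced loss scales);
    # model_forward undoes the scaling so decoded offsets are in pixels
    targets <- list(heatmap = tg$heatmap, locref = tg$locref / config$stride,
                    locref_mask = tg$locref_mask,
                    lrss = matrix(as.integer(tg$lrss), nrow(tg$lrss), ncol(tg$lrss)))
    targets$baf <- if (with_baf) tg$baf else array(0, c(dim(tg$lrss), 2L))
    list(x = x, targets = targets)
  })
}

#' Train the network
#'
#' Runs the warmup-cosine AdamW protocol: the learning rate ramps from
#' `lr_min` to `lr_max` over the warm-up epochs and cosine-decays back;
#' the loss is `w_hm * RMSE(heatmap) + w_lr * RMSE(locref, masked) +
#' w_seg * sparseCE(LRSS) + w_baf * RMSE(BAF)`; training stops early
#' after `config$patience` epochs without improvement of the monitored
#' loss (validation loss under `monitor = "val"`, the single-animal
#' protocol; training loss under `"train"`, the identity / social
#' protocols). The best-monitored weights are restored into the model at
#' the end.
#'
#' @param model An `adpt_model` (modified in place and returned).
#' @param dataset List of encoded samples from [encode_dataset()], or of
#'   `adpt_frame`s (then encoded here with `skeleton`).
#' @param config An [adpt_config()]. `iters_per_epoch` defaults to
#'   `ceiling(n_train / batch_size)`.
#' @param seed Integer seed driving the train/validation split and the
#'   batch shuffling; a fixed seed reproduces the loss trajectory.
#' @param skeleton Needed only when `dataset` holds raw frames.
#' @param val_fraction Validation share of the dataset (default 5%).
#' @param augment_copies When `dataset` holds raw frames, number of
#'   augmented copies of each training frame added to the pool (0 =
#'   no augmentation).
#' @param augment_mode Augmentation protocol passed to
#'   [augment_frame()].
#' @param verbose Print a line every 10 epochs.
#' @return An object of class `adpt_train_state`: list with `log`
#'   (data.frame epoch / train_loss / val_loss / lr), `best_loss`,
#'   `best_epoch`, `epochs_run`, `stopped_early`, and `model`.
#' @export
train <- function(model, dataset, config, seed = 0L, skeleton = NULL,
                  val_fraction = 0.05, augment_copies = 0L,
                  augment_mode = "default", verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training dataset")
  raw <- inherits(dataset[[1L]], "adpt_frame")
  if (raw && is.null(skeleton)) stop("skeleton needed to encode raw frames")
  identity_aware <- config$n_identities > 1L
  n <- length(dataset)
  use_val <- config$monitor == "val" && n >= 20L
  split <- with_seed(seed, {
    idx <- sample.int(n)
    nv <- if (use_val) max(1L, floor(n * val_fraction)) else 0L
    list(val = idx[seq_len(nv)], train = idx[setdiff(seq_len(n), seq_len(nv))])
  })
  tr_idx <- split$train; va_idx <- split$val
  if (raw) {
    frames <- dataset
    if (augment_copies > 0L) {
      aug <- list()
      for (r in seq_len(augment_copies)) {
        aug <- c(aug, lapply(tr_idx, function(i) {
          augment_frame(frames[[i]], rng_seed = seed + 7919L * r + i,
                        mode = augment_mode, config = config)
        }))
      }
      frames <- c(frames, aug)
      tr_idx <- c(tr_idx, n + seq_along(aug))
    }
    dataset <- encode_dataset(frames, skeleton, config,
                              identity_aware = identity_aware,
                              with_baf = model$spec$with_baf)
  }
  cfg <- config
  if (is.null(cfg$iters_per_epoch)) {
    cfg$iters_per_epoch <- as.integer(ceiling(length(tr_idx) / cfg$batch_size))
  }
  lw <- cfg$loss_weights
  xs_all <- lapply(dataset, `[[`, "x")
  tg_all <- lapply(dataset, `[[`, "targets")

  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), lr = numeric(0))
  best <- Inf; best_epoch <- 0L; best_w <- NULL
  plateau <- 0L; gstep <- 0L
  stopped_early <- FALSE

  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(seed + epoch, sample(rep_len(sample(tr_idx),
                     cfg$iters_per_epoch * cfg$batch_size)))
    ep_loss <- 0
    last_lr <- NA_real_
    for (it in seq_len(cfg$iters_per_epoch)) {
      bi <- ord[((it - 1L) * cfg$batch_size + 1L):(it * cfg$batch_size)]
      last_lr <- lr_at(gstep, cfg)
      st <- tryCatch(
        nn_train_step(model$ptr, xs_all[bi], tg_all[bi], lw, last_lr,
                      cfg$weight_decay),
        error = function(e) stop("training aborted at epoch ", epoch,
                                 ", iteration ", it, ": ", conditionMessage(e)))
      ep_loss <- ep_loss + st$total
      gstep <- gstep + 1L
    }
    ep_loss <- ep_loss / cfg$iters_per_epoch
    val_loss <- NA_real_
    if (use_val) {
      val_loss <- nn_eval_loss(model$ptr, xs_all[va_idx], tg_all[va_idx], lw)$total
    }
    monitored <- if (use_val) val_loss else ep_loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_loss = val_loss, lr = last_lr))
    if (verbose && epoch %% 10L == 0L) {
      message(sprintf("epoch %d train %.5f val %s lr %.2e", epoch, ep_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss)),
                      last_lr))
    }
    if (monitored < best - 1e-9) {
      best <- monitored; best_epoch <- epoch; plateau <- 0L
      best_w <- nn_get_weights(model$ptr)
    } else {
      plateau <- plateau + 1L
      if (plateau >= cfg$patience) { stopped_early <- TRUE; break }
    }
  }
  if (!is.null(best_w)) nn_set_weights(model$ptr, best_w, reset_opt = FALSE)
  structure(list(log = log, best_loss = best, best_epoch = best_epoch,
                 epochs_run = nrow(log), stopped_early = stopped_early,
                 model = model, config = cfg),
            class = "adpt_train_state")
}

#' @export
print.adpt_train_state <- function(x, ...) {
  cat("<adpt_train_state> ", x$epochs_run, " epochs (best ",
      sprintf("%.5f", x$best_loss), " at epoch ", x$best_epoch,
      if (x$stopped_early) ", stopped early" else "", ")\n", sep = "")
  invisible(x)
}

#' Write a training log as CSV
#' @param state An `adpt_train_state`.
#' @param path CSV path.
#' @export
write_train_log <- function(state, path) {
  utils::write.csv(state$log, path, row.names = FALSE)
  invisible(path)
}
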