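test_that("tiny preset on a 64x64 input emits 8x8 heads with the right channels", {
  spec <- model_spec("tiny", K = 5, n_identities = 2, with_baf = TRUE,
                     input_size = c(64, 64))
  m <- build_model(spec, seed = 1)
  x <- array(0.1, c(64, 64, 3))
  h <- adpt:::nn_forward(m$ptr, x)
  expect_equal(dim(h$heatmap), c(8, 8, 5))
  expect_equal(dim(h$locref), c(8, 8, 10))
  expect_equal(dim(h$lrss_prob), c(8, 8, 3))
  expect_equal(dim(h$baf), c(8, 8, 2))
  # LRSS probabilities are a softmax across channels
  expect_equal(apply(h$lrss_prob, c(1, 2), sum),
               matrix(1, 8, 8), tolerance = 1e-12)
})

test_that("the 1/16 branch tokenises a 64x64 input into 16 positions", {
  spec <- model_spec("tiny", K = 5, input_size = c(64, 64))
  m <- build_model(spec, seed = 1)
  info <- adpt:::nn_param_info(m$ptr)
  pos <- Filter(function(p) p$kind == "posemb", info)
  expect_length(pos, 1L)
  expect_equal(pos[[1]]$nrow, 16L)          # (64/16)^2 tokens
  expect_equal(pos[[1]]$ncol, spec$tf_dim)
})

test_that("evaluation is deterministic for fixed weights and input", {
  m <- build_model(micro_spec(), seed = 3)
  x <- adpt:::with_seed(5, array(stats::rnorm(32 * 32 * 3, 0, 0.3), c(32, 32, 3)))
  a <- adpt:::nn_forward(m$ptr, x)
  b <- adpt:::nn_forward(m$ptr, x)
  expect_identical(a, b)
})

test_that("inputs not divisible by 16 are padded, never crash", {
  m <- build_model(model_spec("tiny", K = 5, input_size = c(64, 64)), seed = 1)
  cfg <- toy_cfg()
  img <- array(40, c(60, 52, 3))
  x <- adpt:::prepare_input(img, cfg)
  expect_equal(attr(x, "pad"), c(4, 12))
  h <- model_forward(m, img, cfg)
  expect_equal(dim(h$heatmap)[1:2], c(8, 8))  # 64 x 64 padded -> 8 x 8
})

test_that("analytic gradients match finite differences", {
  m <- build_model(micro_spec(), seed = 42)
  x <- adpt:::with_seed(1, array(stats::rnorm(32 * 32 * 3, 0, 0.3), c(32, 32, 3)))
  tg <- random_targets_for(4, 4, 2, 2)
  lw <- c(heatmap = 1, locref = 1, lrss = 1, baf = 1)
  ws0 <- adpt:::nn_get_weights(m$ptr)
  lg <- adpt:::nn_loss_and_grad(m$ptr, list(x), list(tg), lw)
  eps <- 1e-5
  check <- adpt:::with_seed(7, lapply(seq_along(ws0), function(pi) {
    sample(length(ws0[[pi]]), min(2, length(ws0[[pi]])))
  }))
  for (pi in seq_along(ws0)) {
    for (i in check[[pi]]) {
      wp <- ws0; wp[[pi]][i] <- wp[[pi]][i] + eps
      adpt:::nn_set_weights(m$ptr, wp, TRUE)
      lp <- adpt:::nn_eval_loss(m$ptr, list(x), list(tg), lw)$total
      wm <- ws0; wm[[pi]][i] <- wm[[pi]][i] - eps
      adpt:::nn_set_weights(m$ptr, wm, TRUE)
      lm <- adpt:::nn_eval_loss(m$ptr, list(x), list(tg), lw)$total
      num <- (lp - lm) / (2 * eps)
      ana <- lg$grads[[pi]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("learning rate schedule hits its anchors and is monotone per segment", {
  cfg <- adpt_config(epochs = 190L, warmup_epochs = 10L, iters_per_epoch = 10L,
                     lr_min = 1e-5, lr_max = 1e-3)
  total <- 190L * 10L; warm <- 10L * 10L
  expect_equal(lr_at(0, cfg), 1e-5)
  expect_equal(lr_at(warm, cfg), 1e-3)
  expect_equal(lr_at(total, cfg), 1e-5, tolerance = 1e-12)
  ramp <- lr_at(0:warm, cfg)
  expect_true(all(diff(ramp) > 0))
  decay <- lr_at(warm:total, cfg)
  expect_true(all(diff(decay) < 0))
})

test_that("default single-animal schedule follows the training protocol", {
  cfg <- adpt_config()
  expect_equal(cfg$epochs, 190L)
  expect_equal(cfg$warmup_epochs, 10L)
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$patience, 30L)
  expect_equal(cfg$monitor, "val")
})

test_that("a short training run reduces the monitored loss and logs lr_at", {
  sk <- toy_skeleton()
  cfg <- toy_cfg(epochs = 8L, warmup_epochs = 2L, batch_size = 8L,
                 patience = 30L, monitor = "train")
  frames <- lapply(1:32, function(i) generate_scene(scene_spec(seed = 600 + i)))
  m <- build_model(model_spec("tiny", K = 5, input_size = c(64, 64)), seed = 2)
  st <- train(m, frames, cfg, seed = 2, skeleton = sk)
  expect_lt(st$log$train_loss[nrow(st$log)], st$log$train_loss[1])
  expect_equal(st$best_loss, min(st$log$train_loss))
  # the logged lr is lr_at of the last step of each epoch
  it <- st$config$iters_per_epoch
  want <- lr_at((seq_len(nrow(st$log)) * it) - 1L, st$config)
  expect_equal(st$log$lr, want)
})

test_that("training is reproducible from the seed", {
  sk <- toy_skeleton()
  cfg <- toy_cfg(epochs = 2L, warmup_epochs = 1L, batch_size = 4L,
                 monitor = "train")
  frames <- lapply(1:8, function(i) generate_scene(scene_spec(seed = 700 + i)))
  ds <- encode_dataset(frames, sk, cfg)
  m1 <- build_model(micro_spec(K = 5, n_identities = 1, with_baf = FALSE,
                               input_size = c(64, 64)), seed = 9)
  st1 <- train(m1, ds, cfg, seed = 4)
  m2 <- build_model(micro_spec(K = 5, n_identities = 1, with_baf = FALSE,
                               input_size = c(64, 64)), seed = 9)
  st2 <- train(m2, ds, cfg, seed = 4)
  expect_equal(st1$log, st2$log)
})

test_that("empty dataset is a hard error", {
  m <- build_model(micro_spec(), seed = 1)
  expect_error(train(m, list(), toy_cfg()), "empty")
})

test_that("ablation flags keep the remaining head shapes unchanged", {
  x <- array(0.1, c(64, 64, 3))
  base <- build_model(model_spec("tiny", K = 5, n_identities = 2,
                                 with_baf = TRUE, input_size = c(64, 64)),
                      seed = 1)
  hb <- adpt:::nn_forward(base$ptr, x)
  no_tf <- build_model(model_spec("tiny", K = 5, n_identities = 2,
                                  with_baf = TRUE, no_transformer = TRUE,
                                  input_size = c(64, 64)), seed = 1)
  ht <- adpt:::nn_forward(no_tf$ptr, x)
  expect_equal(dim(ht$heatmap), dim(hb$heatmap))
  expect_equal(dim(ht$locref), dim(hb$locref))
  expect_equal(dim(ht$lrss_prob), dim(hb$lrss_prob))
  expect_equal(dim(ht$baf), dim(hb$baf))
  no_seg <- build_model(model_spec("tiny", K = 5, n_identities = 2,
                                   with_baf = TRUE, no_lrss = TRUE,
                                   input_size = c(64, 64)), seed = 1)
  hs <- adpt:::nn_forward(no_seg$ptr, x)
  expect_null(hs$lrss_prob)
  expect_equal(dim(hs$heatmap), dim(hb$heatmap))
  expect_equal(dim(hs$baf), dim(hb$baf))
})

test_that("checkpoints round-trip through save and load", {
  m <- build_model(micro_spec(), seed = 11)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p, config = toy_cfg())
  m2 <- load_checkpoint(p)
  x <- adpt:::with_seed(2, array(stats::rnorm(32 * 32 * 3, 0, 0.2), c(32, 32, 3)))
  expect_equal(adpt:::nn_forward(m$ptr, x), adpt:::nn_forward(m2$ptr, x))
  expect_true(file.exists(paste0(p, ".json")))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$spec$preset, "tiny")
})

test_that("the full-scale preset builds and keeps the 1/8 head geometry", {
  spec <- model_spec("resnet_stack12", K = 3, input_size = c(64, 64),
                     c_stem = 16, c_backbone = 32, n_res = 1, c_branch = 16,
                     c_fuse = 32, tf_layers = 1, tf_heads = 2, tf_dim = 32,
                     tf_mlp = 64)
  m <- build_model(spec, seed = 1)
  h <- adpt:::nn_forward(m$ptr, array(0.1, c(64, 64, 3)))
  expect_equal(dim(h$heatmap), c(8, 8, 3))
})
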