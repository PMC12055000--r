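# Shared fixtures: everything is generated in code at test time.

toy_cfg <- function(...) {
  adpt_config(stride = 8, sigma = 1.2, n_identities = 1, ...)
}

social_cfg <- function(...) {
  adpt_config(stride = 8, sigma = 1.2, n_identities = 2, ...)
}

# a small hand-posed single-instance frame on a flat background
flat_frame <- function(H = 48, W = 48, kp = NULL, identity = 1L) {
  img <- array(40, c(H, W, 3L))
  if (is.null(kp)) {
    kp <- rbind(c(30, 14), c(24, 22), c(18, 30), c(30, 26), c(18, 18))
  }
  labeled_frame(img, list(pose_instance(kp, identity = identity)))
}

# well-separated two-animal scene used by the identity pipeline tests
pair_scene <- function(seed) {
  generate_scene(scene_spec(n_animals = 2, size = c(128, 128),
                            min_sep = 2.8, seed = seed))
}

# micro network spec for gradient-level tests; named overrides win
micro_spec <- function(...) {
  base <- list(preset = "tiny", K = 2, n_identities = 2, with_baf = TRUE,
               input_size = c(32, 32), c_stem = 4, c_backbone = 6,
               c_branch = 6, c_fuse = 8, tf_layers = 1, tf_heads = 2,
               tf_dim = 8, tf_mlp = 16)
  do.call(model_spec, utils::modifyList(base, list(...)))
}

random_targets_for <- function(Hm, Wm, K, n_identities, seed = 1) {
  adpt:::with_seed(seed, list(
    heatmap = array(stats::runif(Hm * Wm * K), c(Hm, Wm, K)),
    locref = array(stats::rnorm(Hm * Wm * 2 * K), c(Hm, Wm, 2 * K)),
    locref_mask = array(stats::rbinom(Hm * Wm * K, 1, 0.5), c(Hm, Wm, K)),
    lrss = matrix(sample(0:n_identities, Hm * Wm, TRUE), Hm, Wm),
    baf = array(stats::rnorm(Hm * Wm * 2), c(Hm, Wm, 2))
  ))
}
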