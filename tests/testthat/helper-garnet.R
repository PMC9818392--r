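# shared fixtures, all generated in code

# exhaustive lattice count of the worked circular mask, frozen from
# enumeration: sum over the 256^2 (resp. 64^2) 0-based grid of
# (x - c)^2 + (y - c)^2 <= (size/4)^2 with c = size/2 - 0.5
WORKED_FG_256 <- 12892L
WORKED_FG_64 <- 812L

rand_img <- function(h, w = h, c = 3L) array(runif(h * w * c), c(h, w, c))
rand_mask <- function(h, w = h, p = 0.3) {
  matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
}

# centered disc mask with a broadcast 3-channel image, kept away from borders
disc_fixture <- function(size = 64L, radius = 10) {
  m <- matrix(0, size, size)
  ctr <- (size + 1) / 2
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- 1
  list(mask = m, image = array(rep(m, 3), c(size, size, 3)))
}

aug_only <- function(...) {
  on <- list(...)
  probs <- as.list(stats::setNames(
    rep(0, 11), c("p_saturation", "p_brightness", "p_contrast", "p_hflip",
                  "p_vflip", "p_scale", "p_rotate", "p_median_blur",
                  "p_gaussian_blur", "p_motion_blur", "p_noise")))
  for (nm in names(on)) probs[[nm]] <- on[[nm]]
  do.call(augmentation_config, probs)
}

tiny_model <- function(size = 16L, base = 4L, depth = 2L, seed = 1L) {
  build_garnet(garnet_config(size, base, depth, seed = seed))
}

tiny_pairs <- function(n, size = 16L, seed = 1L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    list(image = rand_img(size), mask = rand_mask(size))
  }))
}

# a small on-disk synthetic dataset, memoised per test run
synth_records <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 8L, size = 64L, seed = 11L) {
    key <- paste(n, size, seed, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("garnet_synth_", key))
      unlink(dir, recursive = TRUE)
      cache[[key]] <- generate_dataset(
        synthetic_spec(n_images = n, size = size, seed = seed), dir)
    }
    cache[[key]]
  }
})

load_pairs <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    list(image = load_image(records$image_path[i]),
         mask = load_mask(records$mask_path[i]))
  })
}

# the study-scale overfit demonstration: a reduced network trained 300 steps
# on 8 synthetic pairs; the learning rate is deliberately aggressive because
# the fixture's purpose is memorization, not generalization
overfit_fixture <- function(seed = 11L) {
  recs <- synth_records(8L, 64L, seed)
  pairs <- load_pairs(recs)
  model <- build_garnet(garnet_config(64L, 8L, 3L, seed = seed + 1L))
  fit <- train_garnet(model, pairs, pairs,
                      train_config(epochs = 150L, batch_size = 4L,
                                   initial_lr = 2e-2, seed = seed + 2L))
  outs <- garnet_forward(model, lapply(pairs, `[[`, "image"))
  soft_dice <- mean(vapply(seq_along(pairs), function(i) {
    1 - dice_loss(outs[[i]]$y_pred, pairs[[i]]$mask)
  }, numeric(1)))
  list(fit = fit, model = model, pairs = pairs, train_soft_dice = soft_dice)
}
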