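test_that("the plateau scheduler reduces after `patience` flat epochs", {
  s <- garnet:::new_plateau(1e-4, factor = 0.1, patience = 2L)
  lrs <- numeric(5)
  for (e in 1:5) {
    s <- garnet:::plateau_step(s, 0.5)
    lrs[e] <- s$lr
  }
  # first 0.5 is an improvement over Inf; reductions then land on epoch 3 and 5
  expect_identical(s$reduced_at, c(3L, 5L))
  expect_equal(lrs, c(1e-4, 1e-4, 1e-5, 1e-5, 1e-6))

  # an improvement resets the wait counter
  s2 <- garnet:::new_plateau(1e-4, 0.1, 2L)
  for (v in c(0.5, 0.6, 0.4, 0.6)) s2 <- garnet:::plateau_step(s2, v)
  expect_identical(s2$reduced_at, integer(0))
  # the floor is respected
  s3 <- garnet:::new_plateau(1e-6, 0.1, 1L, min_lr = 1e-7)
  for (e in 1:5) s3 <- garnet:::plateau_step(s3, 0.5)
  expect_equal(s3$lr, 1e-7)
})

test_that("one small optimizer step strictly decreases the batch loss", {
  m <- tiny_model(16, 4, 2, seed = 12)
  pairs <- tiny_pairs(2, 16, seed = 13)
  bl1 <- garnet:::batch_loss_nodes(m, pairs, training = TRUE)
  garnet:::backward(bl1$total)
  opt <- garnet:::new_adam()
  garnet:::adam_step(opt, m$store$theta, garnet:::collect_grads(bl1$ctx), 1e-5)
  bl2 <- garnet:::batch_loss_nodes(m, pairs, training = TRUE)
  expect_lt(bl2$total$value, bl1$total$value)
})

test_that("a short training run fills the log and snapshots the best epoch", {
  m <- tiny_model(16, 4, 2, seed = 14)
  pairs <- tiny_pairs(4, 16, seed = 15)
  ckdir <- tempfile("ck_")
  fit <- train_garnet(m, pairs, pairs,
                      train_config(epochs = 3L, batch_size = 2L,
                                   initial_lr = 1e-3, seed = 16,
                                   checkpoint_dir = ckdir))
  expect_identical(nrow(fit$log), 3L)
  expect_identical(fit$log$epoch, 1:3)
  expect_true(all(diff(fit$log$lr) <= 0))
  expect_equal(fit$best_val_loss, min(fit$log$val_total))
  expect_identical(fit$best_epoch, which.min(fit$log$val_total))

  # the snapshot reproduces the recorded best validation loss
  re <- garnet:::evaluate_losses(fit$model, pairs)
  expect_equal(re$total, fit$best_val_loss, tolerance = 1e-12)

  # side-car files: checkpoint + csv log
  expect_true(file.exists(file.path(ckdir, "best.rds")))
  lg <- utils::read.csv(file.path(ckdir, "train_log.csv"))
  expect_identical(nrow(lg), 3L)

  # tidy/glance/autoplot surface
  expect_identical(tidy(fit), fit$log)
  expect_identical(glance(fit)$best_epoch, fit$best_epoch)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("training is reproducible under a fixed seed", {
  pairs <- tiny_pairs(4, 16, seed = 17)
  run <- function() {
    m <- tiny_model(16, 4, 2, seed = 18)
    train_garnet(m, pairs, pairs,
                 train_config(epochs = 2L, batch_size = 2L,
                              initial_lr = 1e-3, seed = 19))$log
  }
  expect_identical(run(), run())
})

test_that("non-finite inputs abort with the batch identified", {
  m <- tiny_model(16, 4, 2, seed = 20)
  bad <- tiny_pairs(2, 16, seed = 21)
  bad[[1]]$image[1] <- NaN
  expect_error(train_garnet(m, bad, bad,
                            train_config(epochs = 1L, batch_size = 2L)),
               "finite|non-finite")
})

test_that("an untrained model with a zeroed head predicts the background prior", {
  m <- build_garnet(garnet_config(64, 8, 3, seed = 22))
  zero_parameters(m, which = "final.out")
  wp <- generate_worked_pair(64L)
  out <- garnet_forward(m, wp$image)[[1]]
  expect_identical(unique(as.vector(out$y_pred)), 0.5)
  mt <- evaluate_garnet(m, list(wp))
  expect_equal(mt$dice, 0)
  expect_equal(mt$pixel_accuracy, 1 - WORKED_FG_64 / 64^2)
  # deterministic evaluation
  expect_identical(unclass(mt), unclass(evaluate_garnet(m, list(wp))))
})

test_that("predicted mask files are binary PNGs that match the in-memory maps", {
  m <- tiny_model(32, 4, 2, seed = 23)
  src <- tempfile("imgs_"); dir.create(src)
  withr::with_seed(24, for (i in 1:3) {
    png::writePNG(rand_img(40), file.path(src, sprintf("im%d.png", i)))
  })
  outdir <- tempfile("preds_")
  res <- predict(m, src, outdir)
  expect_identical(nrow(res), 3L)
  expect_true(all(file.exists(res$mask_file)))
  for (i in 1:3) {
    disk <- png::readPNG(res$mask_file[i])
    expect_true(all(disk %in% c(0, 1)))
    img <- load_image(res$image[i])
    x <- pmin(pmax(resize_image(img, 32, 32, "bicubic"), 0), 1)
    y <- garnet_forward(m, x)[[1]]$y_pred
    expect_identical(disk, (y[, , 1] > 0.5) * 1)
  }
  # native-size masks are written alongside at the source resolution
  predict(m, src, outdir, native_size = TRUE)
  nat <- png::readPNG(file.path(outdir, "im1_pred_native.png"))
  expect_identical(dim(nat), c(40L, 40L))
})

test_that("the attention panel is deterministic and has one tile per map plus two", {
  m <- tiny_model(32, 4, 3, seed = 25)  # 32 divisible by 2^3; 2 attention maps
  img <- withr::with_seed(26, rand_img(32))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  r1 <- visualize_attention(m, img, f1)
  visualize_attention(m, img, f2)
  expect_identical(attr(r1, "n_tiles"), 4L)  # input + 2 attention + output
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))

  # default-depth models render the full 6-tile panel
  m5 <- tiny_model(32, 4, 5, seed = 27)
  r5 <- visualize_attention(m5, img, tempfile(fileext = ".png"))
  expect_identical(attr(r5, "n_tiles"), 6L)
})
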