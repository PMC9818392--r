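# Training: Adam on the multi-task loss, learning-rate plateau scheduling on
# the validation loss, and best-validation-checkpoint selection.

#' Training configuration
#'
#' @param epochs number of training epochs (default 120).
#' @param batch_size images per optimizer step (default 4).
#' @param initial_lr initial Adam learning rate (default 1e-4).
#' @param plateau_factor multiplier applied to the learning rate when the
#'   validation loss stops improving (default 0.1).
#' @param plateau_patience epochs without improvement before a reduction
#'   (default 10).
#' @param min_lr learning-rate floor (default 1e-7).
#' @param seed seed for shuffling and augmentation streams.
#' @param checkpoint_dir optional directory; when set, the best checkpoint is
#'   written there as `best.rds`.
#' @return an object of class `garnet_train_config`.
#' @export
train_config <- function(epochs = 120L, batch_size = 4L, initial_lr = 1e-4,
                         plateau_factor = 0.1, plateau_patience = 10L,
                         min_lr = 1e-7, seed = 1L, checkpoint_dir = NULL) {
  assert_that(epochs >= 1L, "epochs must be >= 1")
  assert_that(batch_size >= 1L, "batch_size must be >= 1")
  assert_that(initial_lr > 0, "initial_lr must be positive")
  assert_that(plateau_factor > 0 && plateau_factor < 1,
              "plateau_factor must be in (0, 1)")
  assert_that(plateau_patience >= 1L, "plateau_patience must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "garnet_train_config")
}

## ---- Adam --------------------------------------------------------------------

new_adam <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  e$t <- 0L
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(opt, theta, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- 0 * g; v <- 0 * g }
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    theta[[nm]] <- theta[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  invisible(opt)
}

## ---- learning-rate plateau scheduler ----------------------------------------

# Pure scheduler state machine, exposed so the reduce-on-plateau contract can
# be tested in isolation: the first observation always counts as an
# improvement; after `patience` consecutive non-improving epochs the rate is
# multiplied by `factor` (never below `min_lr`) and the wait counter resets.
new_plateau <- function(initial_lr, factor, patience, min_lr = 0) {
  list(lr = initial_lr, factor = factor, patience = patience, min_lr = min_lr,
       best = Inf, wait = 0L, reduced_at = integer(0), epoch = 0L)
}

plateau_step <- function(s, val_loss) {
  s$epoch <- s$epoch + 1L
  if (val_loss < s$best - 1e-12) {
    s$best <- val_loss
    s$wait <- 0L
  } else {
    s$wait <- s$wait + 1L
    if (s$wait >= s$patience) {
      s$lr <- max(s$lr * s$factor, s$min_lr)
      s$reduced_at <- c(s$reduced_at, s$epoch)
      s$wait <- 0L
    }
  }
  s
}

## ---- data plumbing -----------------------------------------------------------

# accept either a records tibble or a list of list(image=, mask=) pairs
materialize_eval <- function(data, size) {
  if (is.data.frame(data)) {
    lapply(seq_len(nrow(data)), function(i) prepare_eval_sample(data[i, ], size))
  } else data
}

fetch_train_pair <- function(data, i, aug, size, seed) {
  if (is.data.frame(data)) {
    prepare_train_sample(data[i, ], aug, seed = seed, size = size)
  } else data[[i]]
}

batch_loss_nodes <- function(model, pairs, training = TRUE) {
  x <- as_batch(lapply(pairs, `[[`, "image"))
  out <- garnet_forward_nodes(model, nd_new(x), training = training)
  n <- length(pairs)
  g_main <- array(0, dim = c(dim(x)[1], dim(x)[2], 1L, n))
  for (s in seq_len(n)) g_main[, , 1, s] <- pairs[[s]]$mask
  main <- op_dice_batch(out$y, g_main)
  att <- lapply(out$attn, function(a) {
    sz <- dim(a$value)[1]
    g <- array(0, dim = c(sz, sz, 1L, n))
    for (s in seq_len(n)) {
      g[, , 1, s] <- resize_mask_for_stage(pairs[[s]]$mask, sz)
    }
    op_bce_mean(a, g)
  })
  total <- op_sum_scalars(c(list(main), att))
  list(main = main, att = att, total = total, ctx = out$ctx)
}

## ---- the training loop -------------------------------------------------------

#' Train a GAR-Net model
#'
#' Minimizes the total multi-task loss (soft dice on the main map plus
#' per-stage attention cross-entropy) with Adam. After every epoch the
#' validation loss is computed in evaluation mode; the learning rate is
#' multiplied by `plateau_factor` after `plateau_patience` epochs without
#' validation improvement, and the returned model is the snapshot from the
#' epoch with the lowest validation loss.
#'
#' @param model a `garnet` model (trained in place; the returned best
#'   snapshot is a deep copy).
#' @param train_data,val_data either record tibbles from
#'   [discover_dataset()]/[split_dataset()] (training records are then
#'   augmented per epoch with `aug_config`), or lists of preloaded
#'   `list(image =, mask =)` pairs at the model's input size.
#' @param config a [train_config()].
#' @param aug_config augmentation for record-based training data;
#'   [no_augmentation()] by default.
#' @param verbose print a line per epoch.
#' @return an object of class `garnet_fit`: `model` (best snapshot), `log`
#'   (one tibble row per epoch), `best_epoch`, `best_val_loss`.
#' @export
train_garnet <- function(model, train_data, val_data, config = train_config(),
                         aug_config = no_augmentation(), verbose = FALSE) {
  stopifnot(inherits(model, "garnet"), inherits(config, "garnet_train_config"))
  size <- model$config$input_size
  n_train <- if (is.data.frame(train_data)) nrow(train_data) else length(train_data)
  assert_that(n_train >= 1L, "train_data must be non-empty")
  val_pairs <- materialize_eval(val_data, size)
  assert_that(length(val_pairs) >= 1L, "val_data must be non-empty")

  opt <- new_adam()
  sched <- new_plateau(config$initial_lr, config$plateau_factor,
                       config$plateau_patience, config$min_lr)
  best <- list(val = Inf, epoch = 0L, model = NULL)
  rows <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    eseed <- derive_seed(config$seed, epoch)
    ord <- local_seed(eseed, sample.int(n_train))
    tr_main <- tr_att <- tr_tot <- 0
    n_batches <- 0L
    for (b0 in seq(1L, n_train, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n_train)]
      pairs <- lapply(seq_along(idx), function(q) {
        fetch_train_pair(train_data, idx[q], aug_config, size,
                         seed = derive_seed(eseed, idx[q]))
      })
      bl <- batch_loss_nodes(model, pairs, training = TRUE)
      if (!is.finite(bl$total$value)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch,
                     n_batches + 1L), call. = FALSE)
      }
      backward(bl$total)
      adam_step(opt, model$store$theta, collect_grads(bl$ctx), sched$lr)
      tr_main <- tr_main + bl$main$value
      tr_att <- tr_att + sum(vapply(bl$att, function(a) a$value, numeric(1)))
      tr_tot <- tr_tot + bl$total$value
      n_batches <- n_batches + 1L
    }

    val <- evaluate_losses(model, val_pairs)
    sched <- plateau_step(sched, val$total)
    if (val$total < best$val) {
      best <- list(val = val$total, epoch = epoch, model = clone_model(model))
    }
    rows[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_main = tr_main / n_batches,
      train_attention = tr_att / n_batches,
      train_total = tr_tot / n_batches,
      val_main = val$main, val_attention = val$attention,
      val_total = val$total, val_dice = val$dice, val_miou = val$miou,
      lr = sched$lr)
    if (verbose) {
      message(sprintf(
        "epoch %3d | train %.4f | val %.4f | val dice %.4f | lr %.2e",
        epoch, tr_tot / n_batches, val$total, val$dice, sched$lr))
    }
  }

  fit <- structure(list(model = best$model, log = do.call(rbind, rows),
                        best_epoch = best$epoch, best_val_loss = best$val,
                        config = config),
                   class = "garnet_fit")
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    write_checkpoint(best$model, file.path(config$checkpoint_dir, "best.rds"))
    utils::write.csv(fit$log,
                     file.path(config$checkpoint_dir, "train_log.csv"),
                     row.names = FALSE)
  }
  fit
}

# evaluation-mode losses and hard metrics over preloaded pairs
evaluate_losses <- function(model, pairs, batch_size = 4L) {
  main <- att <- tot <- 0
  preds <- gnds <- vector("list", length(pairs))
  for (b0 in seq(1L, length(pairs), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, length(pairs))
    outs <- garnet_forward(model, lapply(pairs[idx], `[[`, "image"))
    for (q in seq_along(idx)) {
      lb <- total_loss(outs[[q]], pairs[[idx[q]]]$mask)
      main <- main + lb$main; att <- att + sum(lb$attention)
      tot <- tot + lb$total
      preds[[idx[q]]] <- outs[[q]]$y_pred
      gnds[[idx[q]]] <- pairs[[idx[q]]]$mask
    }
  }
  n <- length(pairs)
  mt <- evaluate_metrics(preds, gnds)
  list(main = main / n, attention = att / n, total = tot / n,
       dice = mt$dice, miou = mt$miou)
}

#' @export
print.garnet_fit <- function(x, ...) {
  cat(sprintf("<garnet_fit> %d epochs; best val loss %.4f at epoch %d\n",
              nrow(x$log), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' Per-epoch training log
#' @param x a `garnet_fit`.
#' @param ... unused.
#' @return the log tibble, one row per epoch.
#' @export
tidy.garnet_fit <- function(x, ...) x$log

#' One-row fit summary
#' @param x a `garnet_fit`.
#' @param ... unused.
#' @export
glance.garnet_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_val_dice = last$val_dice,
                 final_val_miou = last$val_miou, final_lr = last$lr)
}

#' Plot training curves
#'
#' Total train/validation loss and validation Dice per epoch.
#'
#' @param object a `garnet_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.garnet_fit <- function(object, ...) {
  lg <- object$log
  df <- tibble::tibble(
    epoch = rep(lg$epoch, 3),
    value = c(lg$train_total, lg$val_total, lg$val_dice),
    series = rep(c("train total loss", "val total loss", "val dice"),
                 each = nrow(lg)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

## ---- evaluation / prediction -------------------------------------------------

#' Evaluate a model on a dataset
#'
#' Runs evaluation preprocessing, a forward pass in evaluation mode and
#' [evaluate_metrics()]. Deterministic for a fixed checkpoint.
#'
#' @param model a `garnet` model or a checkpoint path.
#' @param data records tibble or list of preloaded pairs.
#' @param threshold binarization threshold.
#' @return a `garnet_metrics` report.
#' @export
evaluate_garnet <- function(model, data, threshold = 0.5) {
  model <- as_model(model)
  pairs <- materialize_eval(data, model$config$input_size)
  preds <- gnds <- vector("list", length(pairs))
  for (b0 in seq(1L, length(pairs), by = 4L)) {
    idx <- b0:min(b0 + 3L, length(pairs))
    outs <- garnet_forward(model, lapply(pairs[idx], `[[`, "image"))
    for (q in seq_along(idx)) {
      preds[[idx[q]]] <- outs[[q]]$y_pred
      gnds[[idx[q]]] <- pairs[[idx[q]]]$mask
    }
  }
  evaluate_metrics(preds, gnds, threshold = threshold)
}

#' Predict segmentation masks for image files
#'
#' Each image is resized to the model input, segmented, binarized at
#' `threshold` and written as an 8-bit {0, 255} PNG named `<stem>_pred.png`.
#'
#' @param object a `garnet` model or checkpoint path.
#' @param images directory of images or a character vector of image files.
#' @param out_dir output directory (created if missing).
#' @param threshold binarization threshold (strict `>`).
#' @param native_size if `TRUE`, masks are also resized back to each source
#'   resolution (nearest-neighbour) and written as `<stem>_pred_native.png`.
#' @param ... unused.
#' @return tibble with columns `image`, `mask_file` (invisibly).
#' @export
predict.garnet <- function(object, images, out_dir, threshold = 0.5,
                           native_size = FALSE, ...) {
  model <- as_model(object)
  files <- if (length(images) == 1L && dir.exists(images)) {
    fs <- list_rasters(images)
    fs[!grepl("_mask$", stem(fs))]
  } else images
  assert_that(length(files) >= 1L, "no input images found")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  size <- model$config$input_size
  out_files <- character(length(files))
  for (i in seq_along(files)) {
    img <- load_image(files[i])
    x <- pmin(pmax(resize_image(img, size, size, "bicubic"), 0), 1)
    y <- garnet_forward(model, x)[[1]]$y_pred
    m <- (drop_unit_channel(y) > threshold) * 1
    out_files[i] <- file.path(out_dir, paste0(stem(files[i]), "_pred.png"))
    write_mask(m, out_files[i])
    if (native_size) {
      mn <- resize_image(m, dim(img)[1], dim(img)[2], "nearest")
      write_mask(mn, file.path(out_dir,
                               paste0(stem(files[i]), "_pred_native.png")))
    }
  }
  invisible(tibble::tibble(image = files, mask_file = out_files))
}

## ---- attention visualization -------------------------------------------------

# map a [0,1] matrix through a simple blue-red heat ramp
heat_rgb <- function(m) {
  m <- pmin(pmax(m, 0), 1)
  array(c(m, 0.2 + 0.3 * m, 1 - m), dim = c(dim(m), 3L))
}

#' Render the attention panel for one image
#'
#' Writes a deterministic PNG panel showing the input, every consolidated
#' attention map upsampled to the input size on a common [0, 1] color scale,
#' and the main segmentation probability map — the package's counterpart of
#' an attention-map comparison figure. With the default depth the panel has
#' exactly 6 tiles (input, four attention stages, output).
#'
#' @param model a `garnet` model or checkpoint path.
#' @param image an `(h, w, 3)` array or an image file path.
#' @param out_file PNG file to write.
#' @return `out_file`, invisibly; the attribute `"n_tiles"` records the
#'   number of tiles rendered.
#' @export
visualize_attention <- function(model, image, out_file) {
  model <- as_model(model)
  size <- model$config$input_size
  if (is.character(image)) image <- load_image(image)
  if (any(dim(image)[1:2] != size)) {
    image <- pmin(pmax(resize_image(image, size, size, "bicubic"), 0), 1)
  }
  out <- garnet_forward(model, image)[[1]]
  tiles <- c(list(image),
             lapply(out$attention, function(a) {
               heat_rgb(resize_image(drop_unit_channel(a), size, size,
                                     "bilinear"))
             }),
             list(heat_rgb(drop_unit_channel(out$y_pred))))
  n <- length(tiles)
  ncol <- 3L
  nrow <- ceiling(n / ncol)
  sep <- 2L
  panel <- array(1, dim = c(nrow * size + (nrow - 1L) * sep,
                            ncol * size + (ncol - 1L) * sep, 3L))
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% ncol
    c0 <- (i - 1L) %% ncol
    panel[r * (size + sep) + seq_len(size),
          c0 * (size + sep) + seq_len(size), ] <- tiles[[i]]
  }
  png::writePNG(panel, out_file)
  invisible(structure(out_file, n_tiles = n))
}
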