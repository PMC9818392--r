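# GAR-Net assembly: stem convolution, strided modified-residual encoder,
# residual bottleneck, guided-attention decoder with deep-supervision heads,
# and a final non-attended upsampling stage.

#' Model configuration
#'
#' @param input_size square input resolution in pixels; must be divisible by
#'   `2^depth`. The reference configuration is 256.
#' @param base_filters channel width of the first stage (>= 4); encoder stage
#'   i uses `base_filters * min(2^(i-1), 8)` channels.
#' @param depth number of 2x downsamplings (>= 2). The decoder emits
#'   `depth - 1` consolidated attention maps at resolutions
#'   `input_size / 2^(depth-1)`, ..., `input_size / 2`.
#' @param seed RNG seed fixing He-uniform weight initialization.
#' @return an object of class `garnet_config`.
#' @export
garnet_config <- function(input_size = 256L, base_filters = 32L, depth = 5L,
                          seed = 1L) {
  input_size <- as.integer(input_size)
  base_filters <- as.integer(base_filters)
  depth <- as.integer(depth)
  assert_that(depth >= 2L, "depth must be at least 2")
  assert_that(base_filters >= 4L, "base_filters must be at least 4")
  assert_that(input_size %% (2L^depth) == 0L,
              sprintf("input_size (%d) must be divisible by 2^depth (%d)",
                      input_size, 2L^depth))
  structure(list(input_size = input_size, base_filters = base_filters,
                 depth = depth, seed = as.integer(seed)),
            class = "garnet_config")
}

stage_widths <- function(config) {
  config$base_filters * pmin(2L^(seq_len(config$depth) - 1L), 8L)
}

#' Build a GAR-Net model
#'
#' Assembles the encoder-bottleneck-decoder network. The encoder is a stem
#' 3x3 convolution at full resolution followed by `depth` modified residual
#' blocks with stride 2. The bottleneck applies two plain residual blocks at
#' the coarsest resolution. Each of the `depth - 1` decoder stages bilinearly
#' upsamples the high-level maps, projects them to the skip width with a 3x3
#' convolution, gates the encoder skip features through a guided attention
#' module, emits a consolidated single-channel attention map through the
#' guided-attention head, concatenates gated skip and upsampled maps and
#' fuses them with a stride-1 modified residual block. A final upsampling
#' stage without attention and a 1x1 sigmoid head produce the segmentation
#' probability map at full resolution.
#'
#' @param config a [garnet_config()].
#' @return an object of class `garnet`, a callable network handle holding the
#'   parameter store and configuration.
#' @export
build_garnet <- function(config) {
  stopifnot(inherits(config, "garnet_config"))
  store <- new_param_store()
  w <- stage_widths(config)
  d <- config$depth
  local_seed(config$seed, {
    init_conv(store, "stem.conv", 3L, 3L, w[1])
    init_bn(store, "stem.bn", w[1])
    cin <- w[1]
    for (i in seq_len(d)) {
      init_modified_block(store, paste0("enc", i), cin,
                          block_spec(c(w[i], w[i]), 2L))
      cin <- w[i]
    }
    init_residual_block(store, "bot1", w[d], block_spec(c(w[d], w[d]), 1L))
    init_residual_block(store, "bot2", w[d], block_spec(c(w[d], w[d]), 1L))
    cur <- w[d]
    for (j in seq_len(d - 1L)) {
      ks <- w[d - j]  # skip width of this stage
      init_conv(store, sprintf("dec%d.up.conv", j), 3L, cur, ks)
      init_bn(store, sprintf("dec%d.up.bn", j), ks)
      init_gam(store, sprintf("dec%d.gam", j), ks)
      init_gal(store, sprintf("dec%d.gal", j), ks)
      init_modified_block(store, sprintf("dec%d.fuse", j), 2L * ks,
                          block_spec(c(ks, ks), 1L))
      cur <- ks
    }
    init_conv(store, "final.up.conv", 3L, cur, cur)
    init_bn(store, "final.up.bn", cur)
    init_conv(store, "final.out.conv", 1L, cur, 1L)
    init_bn(store, "final.out.bn", 1L)
  })
  structure(list(config = config, store = store), class = "garnet")
}

#' @export
print.garnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<garnet> input %dx%dx3, base_filters %d, depth %d, %d attention stages, %s parameters\n",
    cfg$input_size, cfg$input_size, cfg$base_filters, cfg$depth,
    cfg$depth - 1L, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# build the full graph; x must be an (h, w, 3, n) node
garnet_forward_nodes <- function(model, xnode, training = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  w <- stage_widths(cfg)
  ctx <- new_fctx(model$store, training = training)

  h <- op_relu(bn_l(ctx, conv_l(ctx, xnode, "stem.conv"), "stem.bn"))
  skips <- vector("list", d)
  cin <- w[1]
  for (i in seq_len(d)) {
    h <- fwd_modified_block(ctx, h, paste0("enc", i), block_spec(c(w[i], w[i]), 2L))
    skips[[i]] <- h
  }
  h <- fwd_residual_block(ctx, h, "bot1", block_spec(c(w[d], w[d]), 1L))
  h <- fwd_residual_block(ctx, h, "bot2", block_spec(c(w[d], w[d]), 1L))

  attn <- vector("list", d - 1L)
  for (j in seq_len(d - 1L)) {
    ks <- w[d - j]
    up <- op_upsample2x(h)
    up <- op_relu(bn_l(ctx, conv_l(ctx, up, sprintf("dec%d.up.conv", j)),
                       sprintf("dec%d.up.bn", j)))
    gm <- fwd_gam(ctx, skips[[d - j]], up, sprintf("dec%d.gam", j))
    attn[[j]] <- fwd_gal(ctx, gm$A, sprintf("dec%d.gal", j))
    h <- fwd_modified_block(ctx, op_concat_c(gm$O, up),
                            sprintf("dec%d.fuse", j), block_spec(c(ks, ks), 1L))
  }
  up <- op_upsample2x(h)
  up <- op_relu(bn_l(ctx, conv_l(ctx, up, "final.up.conv"), "final.up.bn"))
  y <- op_sigmoid(bn_l(ctx, conv_l(ctx, up, "final.out.conv"), "final.out.bn"))
  list(y = y, attn = attn, ctx = ctx)
}

check_batch_input <- function(model, x) {
  d <- dim(x)
  sz <- model$config$input_size
  if (d[1] != sz || d[2] != sz) {
    stop(sprintf("input spatial size is %dx%d but the model expects %dx%d",
                 d[1], d[2], sz, sz), call. = FALSE)
  }
  if (d[3] != 3L) {
    stop(sprintf("input has %d channels but the model expects 3", d[3]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the network forward
#'
#' @param model a model from [build_garnet()] or [read_checkpoint()].
#' @param images one `(h, w, 3)` image in `[0, 1]`, or a list of them, all
#'   sized `config$input_size`.
#' @param training logical; evaluation mode (the default) uses running
#'   normalization statistics, so repeated forward passes are bit-identical
#'   and each batch element is independent of the others.
#' @return a list with one element per image, each of class `garnet_outputs`:
#'   `y_pred` (`input_size x input_size x 1`, entries in (0, 1)) and
#'   `attention`, the list of consolidated single-channel attention maps at
#'   increasing resolution.
#' @export
garnet_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "garnet"))
  x <- as_batch(images)
  check_batch_input(model, x)
  out <- garnet_forward_nodes(model, nd_new(x), training = training)
  n <- dim(x)[4]
  slice_map <- function(a, s) {
    d <- dim(a)
    v <- a[, , , s, drop = FALSE]
    dim(v) <- d[1:3]
    v
  }
  lapply(seq_len(n), function(s) {
    structure(list(
      y_pred = slice_map(out$y$value, s),
      attention = lapply(out$attn, function(a) slice_map(a$value, s))
    ), class = "garnet_outputs")
  })
}

#' @export
print.garnet_outputs <- function(x, ...) {
  res <- vapply(x$attention, function(a) dim(a)[1], numeric(1))
  cat(sprintf("<garnet_outputs> y_pred %dx%d, attention maps at %s\n",
              dim(x$y_pred)[1], dim(x$y_pred)[2],
              paste(res, collapse = "/")))
  invisible(x)
}

## ---- checkpoints -------------------------------------------------------------

#' Save a model checkpoint
#'
#' Serializes every parameter array keyed by its stable layer path, the
#' normalization running statistics and the model configuration into a single
#' archive. Reloading restores bit-identical evaluation behaviour.
#'
#' @param model a `garnet` model.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "garnet"))
  saveRDS(list(format = "garnet-checkpoint-1",
               config = unclass(model$config),
               theta = as.list(model$store$theta, all.names = TRUE),
               state = as.list(model$store$state, all.names = TRUE)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [write_checkpoint()].
#' @return a `garnet` model.
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  assert_that(identical(ck$format, "garnet-checkpoint-1"),
              "not a garnet checkpoint file")
  cfg <- do.call(garnet_config, ck$config)
  store <- new_param_store()
  for (nm in names(ck$theta)) store$theta[[nm]] <- ck$theta[[nm]]
  for (nm in names(ck$state)) store$state[[nm]] <- ck$state[[nm]]
  structure(list(config = cfg, store = store), class = "garnet")
}

as_model <- function(x) {
  if (inherits(x, "garnet")) x
  else if (is.character(x) && length(x) == 1L) read_checkpoint(x)
  else stop("expected a garnet model or a checkpoint path", call. = FALSE)
}

# deep copy of the mutable stores (used for best-epoch snapshots)
clone_model <- function(model) {
  store <- new_param_store()
  for (nm in ls(model$store$theta, all.names = TRUE)) {
    store$theta[[nm]] <- model$store$theta[[nm]]
  }
  for (nm in ls(model$store$state, all.names = TRUE)) {
    store$state[[nm]] <- model$store$state[[nm]]
  }
  structure(list(config = model$config, store = store), class = "garnet")
}

#' Model summary row
#'
#' @param x a `garnet` model.
#' @param ... unused.
#' @return a one-row tibble with the configuration and parameter count.
#' @export
glance.garnet <- function(x, ...) {
  tibble::tibble(input_size = x$config$input_size,
                 base_filters = x$config$base_filters,
                 depth = x$config$depth,
                 n_attention_stages = x$config$depth - 1L,
                 n_parameters = count_parameters(x))
}
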