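# The three building blocks of the network, exposed both as standalone
# array-in/array-out operations (for study and testing) and as internal
# tape-level forward functions reused by the assembled model.

#' Block hyper-parameter specification
#'
#' Describes one residual-style block: the number of filters of each
#' convolution on the main path and the stride of the last convolution.
#'
#' @param filters_per_conv ordered vector of positive integers; one 3x3
#'   convolution per entry on the main path.
#' @param last_stride stride of the final main-path convolution (and of the
#'   skip projection in the modified block); 1 or 2.
#' @return an object of class `garnet_block_spec`.
#' @export
block_spec <- function(filters_per_conv, last_stride = 1L) {
  filters_per_conv <- as.integer(filters_per_conv)
  assert_that(length(filters_per_conv) >= 1L && all(filters_per_conv >= 1L),
              "filters_per_conv must be a non-empty vector of positive integers")
  assert_that(last_stride %in% c(1L, 2L), "last_stride must be 1 or 2")
  structure(list(filters_per_conv = filters_per_conv,
                 last_stride = as.integer(last_stride)),
            class = "garnet_block_spec")
}

## ---- parameter initialization per block -------------------------------------

init_residual_block <- function(store, prefix, in_channels, spec) {
  f <- spec$filters_per_conv
  cin <- in_channels
  for (i in seq_along(f)) {
    init_conv(store, sprintf("%s.main.conv%d", prefix, i), 3L, cin, f[i])
    init_bn(store, sprintf("%s.main.bn%d", prefix, i), f[i])
    cin <- f[i]
  }
  invisible(store)
}

init_modified_block <- function(store, prefix, in_channels, spec) {
  init_residual_block(store, prefix, in_channels, spec)
  f <- spec$filters_per_conv
  init_conv(store, paste0(prefix, ".skip.conv"), 1L, in_channels, f[length(f)])
  invisible(store)
}

init_gam <- function(store, prefix, k) {
  init_conv(store, paste0(prefix, ".convL"), 1L, k, k)
  init_conv(store, paste0(prefix, ".convH"), 1L, k, k)
  init_bn(store, paste0(prefix, ".bn1"), k)
  init_conv(store, paste0(prefix, ".conv2"), 1L, k, k)
  init_bn(store, paste0(prefix, ".bn2"), k)
  invisible(store)
}

init_gal <- function(store, prefix, k) {
  init_conv(store, paste0(prefix, ".conv"), 1L, k, 1L)
  init_bn(store, paste0(prefix, ".bn"), 1L)
  invisible(store)
}

## ---- tape-level forwards -----------------------------------------------------

# main path shared by both residual blocks: conv->norm->act ... conv->norm,
# the stride applied to the last convolution only
fwd_main_path <- function(ctx, x, prefix, spec) {
  f <- spec$filters_per_conv
  h <- x
  for (i in seq_along(f)) {
    s <- if (i == length(f)) spec$last_stride else 1L
    h <- conv_l(ctx, h, sprintf("%s.main.conv%d", prefix, i), stride = s)
    h <- bn_l(ctx, h, sprintf("%s.main.bn%d", prefix, i))
    if (i < length(f)) h <- op_relu(h)
  }
  h
}

fwd_residual_block <- function(ctx, x, prefix, spec) {
  op_relu(op_add(fwd_main_path(ctx, x, prefix, spec), x))
}

fwd_modified_block <- function(ctx, x, prefix, spec) {
  main <- fwd_main_path(ctx, x, prefix, spec)
  skip <- conv_l(ctx, x, paste0(prefix, ".skip.conv"), stride = spec$last_stride)
  op_relu(op_add(main, skip))
}

# A = sigmoid(norm(conv1x1(relu(norm(conv1x1(L) + conv1x1(H)))))), O = A * L
fwd_gam <- function(ctx, L, H, prefix) {
  s <- op_add(conv_l(ctx, L, paste0(prefix, ".convL")),
              conv_l(ctx, H, paste0(prefix, ".convH")))
  s <- op_relu(bn_l(ctx, s, paste0(prefix, ".bn1")))
  A <- op_sigmoid(bn_l(ctx, conv_l(ctx, s, paste0(prefix, ".conv2")),
                       paste0(prefix, ".bn2")))
  list(O = op_mul(A, L), A = A)
}

fwd_gal <- function(ctx, A, prefix) {
  op_sigmoid(bn_l(ctx, conv_l(ctx, A, paste0(prefix, ".conv")),
                  paste0(prefix, ".bn")))
}

## ---- standalone block objects ------------------------------------------------

new_block <- function(type, init_call, spec = NULL, seed = 1L,
                      in_channels = NULL) {
  store <- new_param_store()
  local_seed(seed, init_call(store))
  structure(list(type = type, spec = spec, store = store, seed = seed,
                 in_channels = in_channels),
            class = c(paste0("garnet_", type), "garnet_block"))
}

#' Create a residual block
#'
#' A residual block with an identity skip: the main path applies
#' `length(filters_per_conv)` 3x3 convolutions (each followed by batch
#' normalization, with ReLU between them), the input is added unchanged, and
#' a final ReLU is applied. The identity skip requires the input channel
#' count to equal the block's output channel count, and the stride must be 1.
#'
#' @param in_channels channel count of the input feature maps.
#' @param spec a [block_spec()]; `last_stride` must be 1 and the final filter
#'   count must equal `in_channels`.
#' @param seed RNG seed for He-uniform weight initialization.
#' @return a block object usable with [residual_block()].
#' @export
new_residual_block <- function(in_channels, spec, seed = 1L) {
  assert_that(spec$last_stride == 1L,
              "residual block requires last_stride = 1 (identity skip)")
  f <- spec$filters_per_conv
  assert_that(in_channels == f[length(f)],
              sprintf(paste0("identity skip is not addable: input has %d ",
                             "channels but the block outputs %d"),
                      in_channels, f[length(f)]))
  new_block("residual_block",
            function(store) init_residual_block(store, "block", in_channels, spec),
            spec = spec, seed = seed, in_channels = in_channels)
}

#' Create a modified residual block
#'
#' Like the residual block, but the skip connection carries a learned 1x1
#' convolution (with the block's output filter count and the block stride)
#' instead of the identity, letting the skip path suppress noise and letting
#' the block change resolution and channel count.
#'
#' @inheritParams new_residual_block
#' @param spec a [block_spec()]; any `last_stride` in {1, 2}.
#' @return a block object usable with [modified_residual_block()].
#' @export
new_modified_residual_block <- function(in_channels, spec, seed = 1L) {
  new_block("modified_residual_block",
            function(store) init_modified_block(store, "block", in_channels, spec),
            spec = spec, seed = seed, in_channels = in_channels)
}

#' Create a guided attention module
#'
#' The module fuses a low-level skip feature map `L` and an (already
#' upsampled) high-level feature map `H` of identical shape: 1x1 convolutions
#' of both are summed, normalized and ReLU-activated, then a further 1x1
#' convolution, normalization and sigmoid produce a per-channel attention map
#' set `A` with entries in (0, 1). The output is `O = A * L`, the skip
#' features reweighted per channel and per pixel.
#'
#' @param k channel count of both inputs.
#' @param seed RNG seed for weight initialization.
#' @return a module object usable with [guided_attention_module()].
#' @export
new_guided_attention_module <- function(k, seed = 1L) {
  new_block("gam", function(store) init_gam(store, "block", k),
            seed = seed, in_channels = k)
}

#' Create a guided-attention consolidation head
#'
#' A 1x1 convolution with a single filter, normalization and sigmoid that
#' consolidates an attention map set into one single-channel map, which deep
#' supervision then trains against the resized ground-truth mask.
#'
#' @inheritParams new_guided_attention_module
#' @return a head object usable with [gal_head()].
#' @export
new_gal_head <- function(k, seed = 1L) {
  new_block("gal", function(store) init_gal(store, "block", k),
            seed = seed, in_channels = k)
}

## ---- array-level application -------------------------------------------------

apply_block <- function(block, fwd, inputs, training = FALSE) {
  squeeze <- length(dim(inputs[[1]])) == 3L
  inputs <- lapply(inputs, function(x) {
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    check_finite(x)
    if (dim(x)[3] != block$in_channels) {
      stop(sprintf("input has %d channels but the block expects %d",
                   dim(x)[3], block$in_channels), call. = FALSE)
    }
    nd_new(x)
  })
  ctx <- new_fctx(block$store, training = training)
  out <- do.call(fwd, c(list(ctx), inputs, list(prefix = "block"),
                        if (!is.null(block$spec)) list(spec = block$spec)))
  strip <- function(nd) {
    v <- nd$value
    if (squeeze) dim(v) <- dim(v)[1:3]
    v
  }
  if (is_node(out)) strip(out) else lapply(out, strip)
}

check_finite <- function(x) {
  assert_that(all(is.finite(x)), "feature maps must contain only finite values")
}

#' Apply a residual block
#'
#' @param x feature maps `(h, w, c)` or `(h, w, c, n)` with finite values.
#' @param block a block from [new_residual_block()].
#' @param training logical; in training mode normalization uses batch
#'   statistics (and updates the running ones), in evaluation mode it uses the
#'   stored running statistics.
#' @return feature maps with the same spatial size and the block's output
#'   channel count.
#' @export
residual_block <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "garnet_residual_block"))
  apply_block(block, fwd_residual_block, list(x), training)
}

#' Apply a modified residual block
#'
#' Output spatial size is `ceiling(h / last_stride)` by
#' `ceiling(w / last_stride)`; channels follow the last filter count.
#'
#' @inheritParams residual_block
#' @param block a block from [new_modified_residual_block()].
#' @export
modified_residual_block <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "garnet_modified_residual_block"))
  apply_block(block, fwd_modified_block, list(x), training)
}

#' Apply a guided attention module
#'
#' @param L low-level (skip) feature maps `(h, w, k)` or `(h, w, k, n)`.
#' @param H high-level feature maps, already upsampled to the shape of `L`.
#' @param module a module from [new_guided_attention_module()].
#' @param training see [residual_block()].
#' @return a list with `O` (attention-weighted skip features) and `A` (the
#'   attention map set, entries strictly inside (0, 1)), both shaped like `L`.
#' @export
guided_attention_module <- function(L, H, module, training = FALSE) {
  stopifnot(inherits(module, "garnet_gam"))
  dL <- dim(L); dH <- dim(H)
  if (!identical(dL, dH)) {
    stop(sprintf("L and H must have identical shape; got %s vs %s",
                 paste(dL, collapse = "x"), paste(dH, collapse = "x")),
         call. = FALSE)
  }
  apply_block(module, fwd_gam, list(L, H), training)
}

#' Consolidate an attention map set into a single-channel map
#'
#' @param A attention map set `(h, w, k)` or `(h, w, k, n)`.
#' @param head a head from [new_gal_head()].
#' @param training see [residual_block()].
#' @return single-channel map with entries in (0, 1) and the same spatial
#'   size as `A`.
#' @export
gal_head <- function(A, head, training = FALSE) {
  stopifnot(inherits(head, "garnet_gal"))
  apply_block(head, fwd_gal, list(A), training)
}
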