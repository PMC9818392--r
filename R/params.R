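# Parameter store and layer primitives.
#
# Trainable arrays live in an environment (`theta`) keyed by a stable layer
# path such as "enc1.main.conv1.w"; batch-norm running statistics live in a
# parallel `state` environment keyed by the norm layer path. Checkpoints
# serialize both plus the model configuration.

new_param_store <- function() {
  list(theta = new.env(parent = emptyenv()),
       state = new.env(parent = emptyenv()))
}

# He-uniform fan-in initialization for a k x k convolution
init_conv <- function(store, name, k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  store$theta[[paste0(name, ".w")]] <-
    array(stats::runif(k * k * cin * cout, -lim, lim), dim = c(k, k, cin, cout))
  store$theta[[paste0(name, ".b")]] <- numeric(cout)
  invisible(store)
}

init_bn <- function(store, name, channels) {
  store$theta[[paste0(name, ".gamma")]] <- rep(1, channels)
  store$theta[[paste0(name, ".beta")]] <- rep(0, channels)
  store$state[[name]] <- list(rmean = rep(0, channels), rvar = rep(1, channels))
  invisible(store)
}

#' Reset convolution weights and biases to zero
#'
#' Sets every convolution kernel and bias in a block or model to zero and
#' resets normalization layers to the identity (unit scale, zero shift,
#' zero running mean, unit running variance). Useful for verifying the
#' closed-form gate behaviour of attention modules: with zeroed parameters
#' every pre-sigmoid activation is exactly 0, so attention maps are exactly
#' 0.5 everywhere.
#'
#' @param object a block created by [new_residual_block()] and friends, or a
#'   model from [build_garnet()].
#' @param which optional character vector of layer-path prefixes to restrict
#'   zeroing to (e.g. `"final.out"`); default zeroes everything.
#' @return the modified object, invisibly (stores are environments, so the
#'   change is in place).
#' @export
zero_parameters <- function(object, which = NULL) {
  store <- object$store
  for (nm in ls(store$theta)) {
    if (!is.null(which) && !any(startsWith(nm, which))) next
    if (endsWith(nm, ".gamma")) {
      store$theta[[nm]][] <- 1
    } else {
      store$theta[[nm]][] <- 0
    }
  }
  for (nm in ls(store$state)) {
    if (!is.null(which) && !any(startsWith(nm, which))) next
    st <- store$state[[nm]]
    store$state[[nm]] <- list(rmean = 0 * st$rmean, rvar = 0 * st$rvar + 1)
  }
  invisible(object)
}

## ---- forward context ---------------------------------------------------------

# A forward context wraps the store for one graph construction: parameters are
# materialized as leaf nodes exactly once so gradients accumulate per array.
new_fctx <- function(store, training = FALSE) {
  list(store = store, training = training,
       pnodes = new.env(parent = emptyenv()))
}

pnode <- function(ctx, name) {
  nd <- ctx$pnodes[[name]]
  if (is.null(nd)) {
    v <- ctx$store$theta[[name]]
    if (is.null(v)) stop("unknown parameter: ", name, call. = FALSE)
    nd <- nd_new(v)
    ctx$pnodes[[name]] <- nd
  }
  nd
}

conv_l <- function(ctx, x, name, stride = 1L) {
  op_conv2d(x, pnode(ctx, paste0(name, ".w")), pnode(ctx, paste0(name, ".b")),
            stride = stride)
}

bn_l <- function(ctx, x, name) {
  op_bn(x, pnode(ctx, paste0(name, ".gamma")), pnode(ctx, paste0(name, ".beta")),
        ctx$store$state, name, ctx$training)
}

collect_grads <- function(ctx) {
  out <- list()
  for (nm in ls(ctx$pnodes)) {
    g <- ctx$pnodes[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

## ---- plain-array primitives --------------------------------------------------

#' Low-level 2-D convolution
#'
#' Direct "same"-padded convolution of a feature-map stack, exposed so that
#' block outputs can be cross-checked against hand-rolled compositions of the
#' primitive operations.
#'
#' @param x numeric array `(h, w, c_in)` or `(h, w, c_in, n)`.
#' @param w kernel array `(k, k, c_in, c_out)`.
#' @param b bias vector of length `c_out`.
#' @param stride integer stride (1 or 2); output height is `ceiling(h/stride)`.
#' @return array with the batch dimension matching the input form.
#' @export
conv2d <- function(x, w, b = numeric(dim(w)[4]), stride = 1L) {
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  y <- conv2d_fw_cpp(x, w, b, as.integer(stride))
  if (squeeze) dim(y) <- dim(y)[1:3]
  y
}

#' Low-level batch normalization (inference form)
#'
#' Normalizes each channel with the supplied statistics:
#' `gamma * (x - mean) / sqrt(var + eps) + beta`.
#'
#' @param x array `(h, w, c)` or `(h, w, c, n)`.
#' @param gamma,beta per-channel scale and shift.
#' @param mean,var per-channel normalization statistics.
#' @param eps numerical stabilizer added to the variance.
#' @return array shaped like `x`.
#' @export
batch_norm <- function(x, gamma = NULL, beta = NULL, mean = NULL, var = NULL,
                       eps = 1e-5) {
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  gamma <- gamma %||% rep(1, d[3]); beta <- beta %||% rep(0, d[3])
  mean <- mean %||% rep(0, d[3]); var <- var %||% rep(1, d[3])
  y <- bcast_c(gamma / sqrt(var + eps), d) * (x - bcast_c(mean, d)) +
    bcast_c(beta, d)
  if (squeeze) dim(y) <- d[1:3]
  y
}

#' Total number of trainable parameters
#'
#' Counts every scalar in convolution kernels, biases and normalization
#' scale/shift vectors. Running statistics are not trainable and are not
#' counted.
#'
#' @param object a block or a model built by this package.
#' @return integer count.
#' @export
count_parameters <- function(object) {
  sum(vapply(ls(object$store$theta),
             function(nm) length(object$store$theta[[nm]]), numeric(1)))
}
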