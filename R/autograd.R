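# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A node is an environment holding `value` (numeric array), the list of parent
# nodes, a `backfn` mapping the incoming gradient to one gradient per parent,
# a creation index (global topological order: the graph is built forward, so
# reversing creation order is a valid reverse topological sort), and the
# accumulated `grad`. Leaves (inputs, parameters) have no backfn.

.garnet_env <- new.env(parent = emptyenv())
.garnet_env$node_idx <- 0L

nd_new <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  .garnet_env$node_idx <- .garnet_env$node_idx + 1L
  e$idx <- .garnet_env$node_idx
  class(e) <- "garnet_node"
  e
}

is_node <- function(x) inherits(x, "garnet_node")
nd_value <- function(x) if (is_node(x)) x$value else x
as_node <- function(x) if (is_node(x)) x else nd_new(x)

nd_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Backpropagate from a scalar (or seeded) root through the reachable graph.
backward <- function(root, seed = 1) {
  stopifnot(is_node(root))
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$idx)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$idx, integer(1)), decreasing = TRUE)
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim = dim(root$value))
  for (nd in nodes[ord]) {
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      if (!is.null(gs[[i]])) nd_acc(nd$parents[[i]], gs[[i]])
    }
  }
  invisible(root)
}

zero_grads <- function(nodes) {
  for (nd in nodes) nd$grad <- NULL
  invisible(NULL)
}

## ---- elementwise and structural ops ----------------------------------------

op_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  nd_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  nd_new(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_relu <- function(x) {
  x <- as_node(x)
  keep <- x$value > 0
  nd_new(x$value * keep, list(x), function(g) list(g * keep))
}

op_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$value))
  nd_new(s, list(x), function(g) list(g * s * (1 - s)))
}

# concatenate two (h, w, c, n) tensors along the channel axis
op_concat_c <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(length(da) == 4L, all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a$value
  out[, , da[3] + seq_len(db[3]), ] <- b$value
  nd_new(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

op_sum_scalars <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  v <- sum(vapply(nodes, function(n) n$value, numeric(1)))
  nd_new(v, nodes, function(g) rep(list(g), length(nodes)))
}

## ---- convolution ------------------------------------------------------------

op_conv2d <- function(x, w, b, stride = 1L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value; wv <- w$value
  y <- conv2d_fw_cpp(xv, wv, b$value, as.integer(stride))
  nd_new(y, list(x, w, b), function(g) {
    gr <- conv2d_bw_cpp(xv, wv, g, as.integer(stride))
    list(gr$dx, gr$dw, gr$db)
  })
}

## ---- bilinear 2x upsampling -------------------------------------------------

# interpolation matrix for a fixed 2x factor (half-pixel centers)
upsample2x_matrix <- function(n_in) {
  key <- paste0("up2x_", n_in)
  if (!is.null(.garnet_env[[key]])) return(.garnet_env[[key]])
  n_out <- 2L * n_in
  U <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out) - 1L) {
    s <- (i + 0.5) / 2 - 0.5
    i0 <- floor(s)
    t <- s - i0
    lo <- min(max(i0, 0), n_in - 1)
    hi <- min(max(i0 + 1, 0), n_in - 1)
    U[i + 1L, lo + 1L] <- U[i + 1L, lo + 1L] + (1 - t)
    U[i + 1L, hi + 1L] <- U[i + 1L, hi + 1L] + t
  }
  .garnet_env[[key]] <- U
  U
}

op_upsample2x <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  U <- upsample2x_matrix(d[1])
  V <- upsample2x_matrix(d[2])
  out <- array(0, dim = c(2L * d[1], 2L * d[2], d[3], d[4]))
  for (s in seq_len(d[4])) for (c in seq_len(d[3])) {
    out[, , c, s] <- U %*% x$value[, , c, s] %*% t(V)
  }
  nd_new(out, list(x), function(g) {
    dx <- array(0, dim = d)
    for (s in seq_len(d[4])) for (c in seq_len(d[3])) {
      dx[, , c, s] <- t(U) %*% g[, , c, s] %*% V
    }
    list(dx)
  })
}

## ---- batch normalization ----------------------------------------------------

# broadcast a per-channel vector over an (h, w, c, n) shape
bcast_c <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

channel_stat <- function(x, fn) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  apply(x, 2, fn)
}

# Batch normalization over (h, w, n) per channel. `state` is an environment
# keyed by `key` holding running mean/var (biased), updated in training mode
# and used verbatim in evaluation mode.
op_bn <- function(x, gamma, beta, state, key, training,
                  momentum = 0.1, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  st <- state[[key]]
  if (training) {
    mu <- channel_stat(x$value, mean)
    vr <- channel_stat((x$value - bcast_c(mu, d))^2, mean)
    state[[key]] <- list(rmean = (1 - momentum) * st$rmean + momentum * mu,
                         rvar  = (1 - momentum) * st$rvar + momentum * vr)
  } else {
    mu <- st$rmean
    vr <- st$rvar
  }
  inv <- 1 / sqrt(vr + eps)
  xhat <- (x$value - bcast_c(mu, d)) * bcast_c(inv, d)
  y <- bcast_c(gamma$value, d) * xhat + bcast_c(beta$value, d)
  gv <- gamma$value
  nd_new(y, list(x, gamma, beta), function(g) {
    dgamma <- channel_stat(g * xhat, sum)
    dbeta <- channel_stat(g, sum)
    if (training) {
      mg <- channel_stat(g, mean)
      mgx <- channel_stat(g * xhat, mean)
      dx <- bcast_c(gv * inv, d) *
        (g - bcast_c(mg, d) - xhat * bcast_c(mgx, d))
    } else {
      dx <- g * bcast_c(gv * inv, d)
    }
    list(dx, dgamma, dbeta)
  })
}

## ---- losses as tape ops ------------------------------------------------------

# mean over the batch of per-image soft dice loss; p: (h,w,1,n), g: (h,w,1,n)
op_dice_batch <- function(p, g_arr, smooth = 1e-6) {
  p <- as_node(p)
  d <- dim(p$value)
  n <- d[4]
  num <- den <- numeric(n)
  for (s in seq_len(n)) {
    ps <- p$value[, , 1, s]; gs <- g_arr[, , 1, s]
    num[s] <- 2 * sum(ps * gs) + smooth
    den[s] <- sum(ps) + sum(gs) + smooth
  }
  v <- mean(1 - num / den)
  nd_new(v, list(p), function(g) {
    dp <- array(0, dim = d)
    for (s in seq_len(n)) {
      gs <- g_arr[, , 1, s]
      dp[, , 1, s] <- -(2 * gs * den[s] - num[s]) / den[s]^2 / n
    }
    list(g * dp)
  })
}

# per-pixel mean binary cross-entropy with probability clipping
op_bce_mean <- function(p, g_arr, clip = 1e-7) {
  p <- as_node(p)
  pv <- pmin(pmax(p$value, clip), 1 - clip)
  inside <- p$value > clip & p$value < 1 - clip
  m <- length(pv)
  v <- -sum(g_arr * log(pv) + (1 - g_arr) * log(1 - pv)) / m
  nd_new(v, list(p), function(g) {
    dp <- (-g_arr / pv + (1 - g_arr) / (1 - pv)) / m
    dp[!inside] <- 0
    list(g * dp)
  })
}
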