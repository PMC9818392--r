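# Separable image resampling via interpolation matrices. Sample positions use
# half-pixel centers: source position of output pixel i (0-based) is
# (i + 0.5) * n_in / n_out - 0.5, so resizing to the same size is exactly the
# identity for every method.

keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

interp_matrix <- function(n_out, n_in, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  M <- matrix(0, n_out, n_in)
  clamp <- function(i) pmin(pmax(i, 0L), n_in - 1L)
  for (i in seq_len(n_out) - 1L) {
    s <- (i + 0.5) * n_in / n_out - 0.5
    i0 <- floor(s)
    t <- s - i0
    if (method == "bilinear") {
      taps <- i0 + c(0L, 1L)
      wts <- c(1 - t, t)
    } else {
      taps <- i0 + (-1L:2L)
      wts <- keys_kernel(t - (-1:2))
    }
    for (q in seq_along(taps)) {
      j <- clamp(taps[q])  # replicate edges
      M[i + 1L, j + 1L] <- M[i + 1L, j + 1L] + wts[q]
    }
  }
  M
}

nearest_index <- function(n_out, n_in) {
  pmin(floor((seq_len(n_out) - 0.5) * n_in / n_out), n_in - 1L) + 1L
}

#' Resize an image or mask
#'
#' Separable resampling. `"bicubic"` uses the Keys cubic kernel (a = -0.5)
#' with replicated edges, `"bilinear"` linear interpolation, `"nearest"`
#' nearest-neighbour center sampling (the only method that keeps binary
#' inputs exactly binary). Resizing to the input size is the identity.
#'
#' @param x matrix `(h, w)` or array `(h, w, c)`.
#' @param out_h,out_w output size in pixels.
#' @param method one of `"bicubic"`, `"bilinear"`, `"nearest"`.
#' @return resized matrix or array. Bicubic output can overshoot the input
#'   range; callers clip as appropriate.
#' @export
resize_image <- function(x, out_h, out_w = out_h,
                         method = c("bicubic", "bilinear", "nearest")) {
  method <- match.arg(method)
  squeeze <- is.matrix(x)
  if (squeeze) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (method == "nearest") {
    ri <- nearest_index(out_h, d[1])
    ci <- nearest_index(out_w, d[2])
    out <- x[ri, ci, , drop = FALSE]
  } else {
    U <- interp_matrix(out_h, d[1], method)
    V <- interp_matrix(out_w, d[2], method)
    out <- array(0, dim = c(out_h, out_w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- U %*% x[, , c] %*% t(V)
  }
  if (squeeze) dim(out) <- dim(out)[1:2]
  out
}
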