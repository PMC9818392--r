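# The multi-task training objective: soft dice on the main segmentation map
# plus per-stage binary cross-entropy on the consolidated attention maps,
# each supervised by the ground-truth mask resized to the stage resolution.

check_same_shape <- function(a, b, what_a, what_b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("%s (%s) and %s (%s) must have the same shape",
                 what_a, paste(da, collapse = "x"),
                 what_b, paste(db, collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

drop_unit_channel <- function(x) {
  d <- dim(x)
  if (length(d) == 3L && d[3] == 1L) dim(x) <- d[1:2]
  x
}

#' Soft dice loss
#'
#' The differentiable complement of the Dice coefficient for probability
#' predictions: `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, with a
#' small smoothing term `eps` making the empty-vs-empty case well defined.
#' The value lies in `[0, 1]`; it is 0 for a perfect prediction and 1 for a
#' disjoint one (up to `eps`).
#'
#' @param y_pred probability map in `[0, 1]` (matrix, or `h x w x 1` array).
#' @param y_gnd binary ground-truth mask of the same spatial shape.
#' @param smooth smoothing constant `eps` (default 1e-6).
#' @return scalar loss.
#' @export
dice_loss <- function(y_pred, y_gnd, smooth = 1e-6) {
  y_pred <- drop_unit_channel(y_pred)
  y_gnd <- drop_unit_channel(y_gnd)
  check_same_shape(y_pred, y_gnd, "y_pred", "y_gnd")
  1 - (2 * sum(y_pred * y_gnd) + smooth) /
    (sum(y_pred) + sum(y_gnd) + smooth)
}

#' Guided-attention supervision loss
#'
#' Per-pixel binary cross-entropy between a consolidated attention map and
#' the ground-truth mask already resized to the map's resolution (see
#' [resize_mask_for_stage()]), averaged over pixels. Probabilities are
#' clipped to `[clip, 1 - clip]` for numerical safety.
#'
#' @param a_pred attention map with entries in (0, 1).
#' @param y_gnd binary mask of the same spatial shape.
#' @param clip probability clipping bound (default 1e-7).
#' @return scalar loss, always >= 0.
#' @export
attention_loss <- function(a_pred, y_gnd, clip = 1e-7) {
  a_pred <- drop_unit_channel(a_pred)
  y_gnd <- drop_unit_channel(y_gnd)
  check_same_shape(a_pred, y_gnd, "a_pred", "y_gnd")
  p <- pmin(pmax(a_pred, clip), 1 - clip)
  -mean(y_gnd * log(p) + (1 - y_gnd) * log(1 - p))
}

#' Resize a binary mask to an attention-stage resolution
#'
#' Nearest-neighbour downsampling so the result stays exactly binary; the
#' target size must divide the mask size. The resized mask is the deep
#' supervision target for the attention map emitted at that stage (a perfect
#' attention map resembles the segmentation map at its own resolution).
#'
#' @param y_gnd binary mask (square matrix).
#' @param target_size output side length in pixels.
#' @return binary `target_size x target_size` matrix.
#' @export
resize_mask_for_stage <- function(y_gnd, target_size) {
  y_gnd <- drop_unit_channel(y_gnd)
  n <- nrow(y_gnd)
  target_size <- as.integer(target_size)
  assert_that(n %% target_size == 0L,
              sprintf("target_size (%d) must divide the mask size (%d)",
                      target_size, n))
  f <- n / target_size
  idx <- floor((seq_len(target_size) - 0.5) * f) + 1L
  y_gnd[idx, idx]
}

#' Total multi-task loss
#'
#' Aggregates the five supervision signals: soft dice on the main map and
#' binary cross-entropy on every consolidated attention map against the
#' correspondingly resized ground truth. The total is exactly
#' `main + sum(attention)`.
#'
#' @param outputs a `garnet_outputs` element from [garnet_forward()], or a
#'   list with `y_pred` and `attention`.
#' @param y_gnd full-resolution binary mask.
#' @return an object of class `garnet_loss_bundle` with fields `main`,
#'   `attention` (one value per stage) and `total`.
#' @export
total_loss <- function(outputs, y_gnd) {
  y_gnd <- drop_unit_channel(y_gnd)
  main <- dice_loss(outputs$y_pred, y_gnd)
  att <- vapply(outputs$attention, function(a) {
    a <- drop_unit_channel(a)
    attention_loss(a, resize_mask_for_stage(y_gnd, nrow(a)))
  }, numeric(1))
  structure(list(main = main, attention = att, total = main + sum(att)),
            class = "garnet_loss_bundle")
}

#' @export
print.garnet_loss_bundle <- function(x, ...) {
  cat(sprintf("<loss bundle> main %.4f + attention (%s) = total %.4f\n",
              x$main, paste(sprintf("%.4f", x$attention), collapse = ", "),
              x$total))
  invisible(x)
}

#' @export
tidy.garnet_loss_bundle <- function(x, ...) {
  tibble::tibble(
    term = c("main", paste0("attention_", seq_along(x$attention)), "total"),
    loss = c(x$main, x$attention, x$total))
}
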