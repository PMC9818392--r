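# Evaluation metrics: hard Dice, two-class mean IoU and pixel accuracy,
# averaged over images after binarizing predictions at a threshold.

confusion_counts <- function(pred, gnd) {
  tp <- sum(pred == 1 & gnd == 1)
  fp <- sum(pred == 1 & gnd == 0)
  fn <- sum(pred == 0 & gnd == 1)
  tn <- sum(pred == 0 & gnd == 0)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# IoU with the absent-class convention: a class missing from both prediction
# and ground truth scores 1 for that image.
safe_iou <- function(inter, union) if (union == 0) 1 else inter / union

image_metrics <- function(pred, gnd) {
  cc <- confusion_counts(pred, gnd)
  dice <- if (2 * cc["tp"] + cc["fp"] + cc["fn"] == 0) 1 else
    2 * cc["tp"] / (2 * cc["tp"] + cc["fp"] + cc["fn"])
  iou_fg <- safe_iou(cc["tp"], cc["tp"] + cc["fp"] + cc["fn"])
  iou_bg <- safe_iou(cc["tn"], cc["tn"] + cc["fp"] + cc["fn"])
  c(dice = unname(dice), miou = unname((iou_fg + iou_bg) / 2),
    pixel_accuracy = unname((cc["tp"] + cc["tn"]) / sum(cc)))
}

#' Segmentation metrics over a set of images
#'
#' Binarizes each probability map at `threshold` (strictly greater than),
#' then computes per image the hard Dice coefficient
#' `2TP / (2TP + FP + FN)`, the mean IoU over the foreground and background
#' classes, and the pixel accuracy, and averages each metric over images. A
#' class absent from both prediction and ground truth contributes IoU 1 for
#' that image.
#'
#' @param pred_masks list of probability maps (values in `[0, 1]`), or of
#'   already-binary masks.
#' @param gnd_masks list of binary ground-truth masks, same length and
#'   matching shapes.
#' @param threshold binarization threshold (default 0.5, strict `>`).
#' @return an object of class `garnet_metrics` with fields `dice`, `miou`,
#'   `pixel_accuracy` (each in `[0, 1]`) and `n_images`.
#' @export
evaluate_metrics <- function(pred_masks, gnd_masks, threshold = 0.5) {
  assert_that(length(pred_masks) >= 1L, "pred_masks must be non-empty")
  assert_that(length(pred_masks) == length(gnd_masks),
              "pred_masks and gnd_masks must have equal length")
  per <- vapply(seq_along(pred_masks), function(i) {
    p <- drop_unit_channel(pred_masks[[i]])
    g <- drop_unit_channel(gnd_masks[[i]])
    check_same_shape(p, g, sprintf("pred_masks[[%d]]", i),
                     sprintf("gnd_masks[[%d]]", i))
    image_metrics(as.numeric(p > threshold), g)
  }, numeric(3))
  structure(list(dice = mean(per["dice", ]),
                 miou = mean(per["miou", ]),
                 pixel_accuracy = mean(per["pixel_accuracy", ]),
                 n_images = length(pred_masks)),
            class = "garnet_metrics")
}

#' @export
print.garnet_metrics <- function(x, ...) {
  cat(sprintf(
    "<metrics over %d images> dice %.4f | mIoU %.4f | pixel accuracy %.4f\n",
    x$n_images, x$dice, x$miou, x$pixel_accuracy))
  invisible(x)
}

#' @export
tidy.garnet_metrics <- function(x, ...) {
  tibble::tibble(metric = c("dice", "miou", "pixel_accuracy"),
                 value = c(x$dice, x$miou, x$pixel_accuracy),
                 n_images = x$n_images)
}

#' Serialize metrics to JSON
#'
#' Writes (or returns) the report as a flat JSON object with keys `dice`,
#' `miou`, `pixel_accuracy` and `n_images`.
#'
#' @param x a `garnet_metrics` object.
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
metrics_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "garnet_metrics"))
  js <- jsonlite::toJSON(list(dice = x$dice, miou = x$miou,
                              pixel_accuracy = x$pixel_accuracy,
                              n_images = x$n_images),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
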