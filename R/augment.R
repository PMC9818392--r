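# Mask-aligned training augmentation and train/eval preprocessing.
#
# Geometric transforms (flips, scaling, rotation) are applied with identical
# sample coordinates to image and mask; the mask is re-binarized at > 0.5
# after resampling so the pair stays exactly aligned and the mask exactly
# binary. Photometric transforms (HSV saturation, brightness, contrast),
# blurs (median, gaussian, motion) and gaussian noise touch the image only.

#' Augmentation configuration
#'
#' Per-transform application probabilities and parameter ranges. Every
#' transform fires independently with its own probability (default 0.5).
#' Factor ranges are multiplicative; rotation angles are degrees drawn
#' uniformly from `rotation_range`; blur kernel sizes are drawn from
#' `blur_kernels`; gaussian noise draws its standard deviation (on the
#' [0, 1] intensity scale) from `noise_sigma_range`.
#'
#' @param p_saturation,p_brightness,p_contrast,p_hflip,p_vflip,p_scale,p_rotate,p_median_blur,p_gaussian_blur,p_motion_blur,p_noise
#'   application probabilities in `[0, 1]`.
#' @param saturation_range,brightness_range,contrast_range,scale_range
#'   multiplicative factor ranges.
#' @param rotation_range rotation range in degrees, a subset of `[0, 90]`.
#' @param blur_kernels odd kernel sizes to draw from.
#' @param noise_sigma_range gaussian-noise sigma range (<= 0.1).
#' @return an object of class `garnet_aug_config`.
#' @export
augmentation_config <- function(p_saturation = 0.5, p_brightness = 0.5,
                                p_contrast = 0.5, p_hflip = 0.5, p_vflip = 0.5,
                                p_scale = 0.5, p_rotate = 0.5,
                                p_median_blur = 0.5, p_gaussian_blur = 0.5,
                                p_motion_blur = 0.5, p_noise = 0.5,
                                saturation_range = c(0.8, 1.2),
                                brightness_range = c(0.8, 1.2),
                                contrast_range = c(0.8, 1.2),
                                scale_range = c(0.9, 1.1),
                                rotation_range = c(0, 90),
                                blur_kernels = c(3L, 5L),
                                noise_sigma_range = c(0.002, 0.02)) {
  cfg <- as.list(environment())
  probs <- unlist(cfg[startsWith(names(cfg), "p_")])
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0, 1]")
  assert_that(rotation_range[1] >= 0 && rotation_range[2] <= 90 &&
                diff(rotation_range) >= 0,
              "rotation_range must be an ordered subset of [0, 90] degrees")
  ranges <- cfg[endsWith(names(cfg), "_range")]
  assert_that(all(vapply(ranges, function(r) diff(r) >= 0, logical(1))),
              "ranges must be well ordered")
  structure(cfg, class = "garnet_aug_config")
}

#' Configuration with every augmentation disabled
#' @return a `garnet_aug_config` whose probabilities are all 0.
#' @export
no_augmentation <- function() {
  do.call(augmentation_config,
          stats::setNames(as.list(rep(0, 11)),
                          grep("^p_", names(formals(augmentation_config)),
                               value = TRUE)))
}

## ---- geometric warp ----------------------------------------------------------

# mirror index into [0, n-1] (reflect without edge repeat, period 2n-2)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * n - 2L
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

# inverse-mapped affine resample: rotate by `angle` degrees and scale by
# `scale` about the image center. Image channels are sampled bilinearly with
# reflected borders; the mask uses the same coordinates with constant-0
# outside and is re-binarized at > 0.5.
warp_pair <- function(image, mask, angle = 0, scale = 1) {
  h <- nrow(mask); w <- ncol(mask)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  th <- -angle * pi / 180  # inverse rotation
  dy <- matrix(seq_len(h) - 1 - cy, h, w)
  dx <- matrix(rep(seq_len(w) - 1 - cx, each = h), h, w)
  sy <- (cos(th) * dy - sin(th) * dx) / scale + cy
  sx <- (sin(th) * dy + cos(th) * dx) / scale + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gather <- function(ch, yi, xi, outside_zero) {
    yi <- as.vector(yi); xi <- as.vector(xi)
    v <- ch[cbind(reflect_index(yi, h) + 1, reflect_index(xi, w) + 1)]
    if (outside_zero) v[yi < 0 | yi >= h | xi < 0 | xi >= w] <- 0
    matrix(v, h, w)
  }
  bilinear <- function(ch, outside_zero) {
    gather(ch, y0, x0, outside_zero) * (1 - fy) * (1 - fx) +
      gather(ch, y0 + 1, x0, outside_zero) * fy * (1 - fx) +
      gather(ch, y0, x0 + 1, outside_zero) * (1 - fy) * fx +
      gather(ch, y0 + 1, x0 + 1, outside_zero) * fy * fx
  }
  img_out <- image
  for (c in seq_len(dim(image)[3])) {
    img_out[, , c] <- bilinear(image[, , c], outside_zero = FALSE)
  }
  list(image = img_out, mask = (bilinear(mask, outside_zero = TRUE) > 0.5) * 1)
}

## ---- photometric -------------------------------------------------------------

hsv_to_rgb <- function(h, s, v) {
  hh <- (h %% 1) * 6
  i <- floor(hh)
  f <- hh - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  r[i == 1] <- q[i == 1]; r[i == 2] <- p[i == 2]; r[i == 3] <- p[i == 3]
  r[i == 4] <- t[i == 4]
  g[i == 0] <- t[i == 0]; g[i == 3] <- q[i == 3]; g[i == 4] <- p[i == 4]
  g[i == 5] <- p[i == 5]
  b[i == 0] <- p[i == 0]; b[i == 1] <- p[i == 1]; b[i == 2] <- t[i == 2]
  b[i == 5] <- q[i == 5]
  list(r = r, g = g, b = b)
}

adjust_saturation <- function(image, factor) {
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  rgb <- hsv_to_rgb(hsv[1, ], pmin(hsv[2, ] * factor, 1), hsv[3, ])
  array(c(rgb$r, rgb$g, rgb$b), dim = d)
}

## ---- blurs -------------------------------------------------------------------

as_ebimage <- function(image) EBImage::Image(aperm(image, c(2, 1, 3)),
                                             colormode = "Color")
from_ebimage <- function(img) aperm(EBImage::imageData(img), c(2, 1, 3))

apply_median_blur <- function(image, k) {
  from_ebimage(EBImage::medianFilter(as_ebimage(pmin(pmax(image, 0), 1)),
                                     size = (k - 1) / 2))
}

apply_gaussian_blur <- function(image, k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  from_ebimage(EBImage::gblur(as_ebimage(image), sigma = sigma))
}

motion_kernel <- function(k, angle) {
  kern <- matrix(0, k, k)
  c0 <- (k + 1) / 2
  t <- seq(-(k - 1) / 2, (k - 1) / 2, length.out = 4L * k)
  ys <- round(c0 + t * sin(angle * pi / 180))
  xs <- round(c0 + t * cos(angle * pi / 180))
  for (q in seq_along(t)) kern[ys[q], xs[q]] <- 1
  kern / sum(kern)
}

apply_motion_blur <- function(image, k, angle) {
  from_ebimage(EBImage::filter2(as_ebimage(image), motion_kernel(k, angle),
                                boundary = "replicate"))
}

## ---- the augmentation stack --------------------------------------------------

#' Augment an image/mask pair
#'
#' Applies the training augmentation stack: geometric transforms (horizontal
#' and vertical flips, scaling, rotation) identically to image and mask, then
#' image-only photometric transforms (HSV saturation, brightness, contrast),
#' blurs (median, gaussian, motion) and gaussian noise. The output image is
#' clipped to `[0, 1]` and the output mask stays exactly binary.
#'
#' @param image `(h, w, 3)` array in `[0, 1]`.
#' @param mask binary `(h, w)` matrix aligned with `image`.
#' @param config an [augmentation_config()].
#' @param seed optional seed making the call reproducible; `NULL` uses the
#'   current RNG stream.
#' @return list with `image` and `mask`; the attribute `"params"` records
#'   which transforms fired and the sampled magnitudes (`NA` when a transform
#'   did not fire).
#' @export
augment_pair <- function(image, mask, config = augmentation_config(),
                         seed = NULL) {
  stopifnot(inherits(config, "garnet_aug_config"))
  check_same_shape(image[, , 1], mask, "image", "mask")
  local_seed(seed, {
    fire <- function(p) stats::runif(1) < p
    draw <- function(r) stats::runif(1, r[1], r[2])
    prm <- list(hflip = fire(config$p_hflip), vflip = fire(config$p_vflip),
                scale = NA_real_, angle = NA_real_, saturation = NA_real_,
                brightness = NA_real_, contrast = NA_real_,
                median_k = NA_integer_, gaussian_k = NA_integer_,
                motion_k = NA_integer_, noise_sigma = NA_real_)
    if (prm$hflip) {
      image <- image[, rev(seq_len(ncol(mask))), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if (prm$vflip) {
      image <- image[rev(seq_len(nrow(mask))), , , drop = FALSE]
      mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    }
    if (fire(config$p_scale)) prm$scale <- draw(config$scale_range)
    if (fire(config$p_rotate)) prm$angle <- draw(config$rotation_range)
    if (!is.na(prm$scale) || !is.na(prm$angle)) {
      wp <- warp_pair(image, mask,
                      angle = if (is.na(prm$angle)) 0 else prm$angle,
                      scale = if (is.na(prm$scale)) 1 else prm$scale)
      image <- wp$image; mask <- wp$mask
    }
    if (fire(config$p_saturation)) {
      prm$saturation <- draw(config$saturation_range)
      image <- adjust_saturation(image, prm$saturation)
    }
    if (fire(config$p_brightness)) {
      prm$brightness <- draw(config$brightness_range)
      image <- image * prm$brightness
    }
    if (fire(config$p_contrast)) {
      prm$contrast <- draw(config$contrast_range)
      m <- mean(image)
      image <- (image - m) * prm$contrast + m
    }
    if (fire(config$p_median_blur)) {
      prm$median_k <- sample_from(config$blur_kernels)
      image <- apply_median_blur(image, prm$median_k)
    }
    if (fire(config$p_gaussian_blur)) {
      prm$gaussian_k <- sample_from(config$blur_kernels)
      image <- apply_gaussian_blur(image, prm$gaussian_k)
    }
    if (fire(config$p_motion_blur)) {
      prm$motion_k <- sample_from(config$blur_kernels)
      image <- apply_motion_blur(image, prm$motion_k, stats::runif(1, 0, 180))
    }
    if (fire(config$p_noise)) {
      prm$noise_sigma <- draw(config$noise_sigma_range)
      image <- image + stats::rnorm(length(image), 0, prm$noise_sigma)
    }
    structure(list(image = pmin(pmax(image, 0), 1), mask = mask),
              params = prm)
  })
}

## ---- sample preparation ------------------------------------------------------

crop_margin <- 14L  # pre-crop size is target + 14, giving 15 x 15 offsets

#' Prepare one training sample
#'
#' Decodes the record's files, resizes to `size + 14` (bicubic for the image,
#' nearest-neighbour for the mask), augments the pair, and takes a random
#' `size x size` crop at an offset drawn uniformly from the 15 x 15 valid
#' positions, identical for image and mask. The image is clipped to `[0, 1]`.
#'
#' @param record one-row tibble (or list) with `image_path` and `mask_path`.
#' @param config an [augmentation_config()].
#' @param seed optional reproducibility seed covering augmentation and crop.
#' @param size output side length (default 256).
#' @param crop_offset optional fixed 0-based `c(row, col)` crop offset,
#'   bypassing the random draw.
#' @return list with `image` (`size x size x 3`) and `mask` (`size x size`).
#' @export
prepare_train_sample <- function(record, config = augmentation_config(),
                                 seed = NULL, size = 256L, crop_offset = NULL) {
  img <- load_image(record$image_path)
  msk <- load_mask(record$mask_path)
  pre <- as.integer(size) + crop_margin
  img <- pmin(pmax(resize_image(img, pre, pre, "bicubic"), 0), 1)
  msk <- resize_image(msk, pre, pre, "nearest")
  local_seed(seed, {
    aug <- augment_pair(img, msk, config)
    off <- if (is.null(crop_offset)) {
      c(sample.int(crop_margin + 1L, 1L), sample.int(crop_margin + 1L, 1L)) - 1L
    } else as.integer(crop_offset)
    ri <- off[1] + seq_len(size)
    ci <- off[2] + seq_len(size)
    list(image = aug$image[ri, ci, , drop = FALSE], mask = aug$mask[ri, ci])
  })
}

#' Prepare one evaluation sample
#'
#' Bicubic image resize to `size x size` (then clipped to `[0, 1]`) and
#' nearest-neighbour mask resize; no augmentation.
#'
#' @inheritParams prepare_train_sample
#' @return list with `image` and `mask`.
#' @export
prepare_eval_sample <- function(record, size = 256L) {
  img <- load_image(record$image_path)
  msk <- load_mask(record$mask_path)
  list(image = pmin(pmax(resize_image(img, size, size, "bicubic"), 0), 1),
       mask = resize_image(msk, size, size, "nearest"))
}
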