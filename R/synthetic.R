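# Seeded generator of polyp-like image/mask pairs. The generator targets the
# visual stressors of real colonoscopy frames -- textured reddish mucosa,
# bright irregular protrusions of widely varying size, illumination
# gradients, specular highlights, overlay text / color-patch artifacts and
# sensor noise -- rather than photo-realism, so every pipeline stage can be
# exercised without downloading clinical data.

#' Synthetic dataset specification
#'
#' @param n_images number of image/mask pairs to generate.
#' @param size square image side in pixels.
#' @param blobs_per_image inclusive integer range for the number of polyp
#'   blobs per image (default 1-3).
#' @param blob_radius_fraction range of the blob base radius as a fraction of
#'   the image side (default 0.05-0.35).
#' @param illumination_strength strength of the linear illumination gradient
#'   in `[0, 1]`.
#' @param highlight_count inclusive range for the number of small saturated
#'   specular highlight discs.
#' @param artifact_probability probability of stamping an overlay artifact (a
#'   white text-like bar or a green color patch) into a corner.
#' @param noise_sigma gaussian pixel-noise standard deviation (<= 0.1).
#' @param seed base seed; each image derives its own stream from it.
#' @param allow_touching if `FALSE`, blob supports are resampled until they
#'   are pairwise separated, so the mask's connected-component count equals
#'   the blob count.
#' @return an object of class `garnet_synth_spec`.
#' @export
synthetic_spec <- function(n_images = 16L, size = 128L,
                           blobs_per_image = c(1L, 3L),
                           blob_radius_fraction = c(0.05, 0.35),
                           illumination_strength = 0.35,
                           highlight_count = c(2L, 6L),
                           artifact_probability = 0.3,
                           noise_sigma = 0.01, seed = 1L,
                           allow_touching = TRUE) {
  assert_that(diff(range(blobs_per_image)) >= 0 && min(blobs_per_image) >= 1,
              "blobs_per_image must be a positive ordered range")
  assert_that(blob_radius_fraction[1] > 0 &&
                diff(blob_radius_fraction) >= 0 &&
                blob_radius_fraction[2] < 0.5,
              "blob_radius_fraction must be an ordered range inside (0, 0.5)")
  assert_that(illumination_strength >= 0 && illumination_strength <= 1,
              "illumination_strength must be in [0, 1]")
  assert_that(artifact_probability >= 0 && artifact_probability <= 1,
              "artifact_probability must be in [0, 1]")
  assert_that(noise_sigma >= 0 && noise_sigma <= 0.1,
              "noise_sigma must be in [0, 0.1]")
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 blobs_per_image = as.integer(range(blobs_per_image)),
                 blob_radius_fraction = blob_radius_fraction,
                 illumination_strength = illumination_strength,
                 highlight_count = as.integer(range(highlight_count)),
                 artifact_probability = artifact_probability,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 allow_touching = isTRUE(allow_touching)),
            class = "garnet_synth_spec")
}

# draw one integer uniformly from an inclusive range (safe for lo == hi)
sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

# low-frequency texture: coarse gaussian grid upsampled bicubically
low_freq_noise <- function(size, coarse = 8L, sd = 1) {
  g <- matrix(stats::rnorm(coarse^2, 0, sd), coarse, coarse)
  resize_image(g, size, size, "bicubic")
}

# one blob: ellipse with angularly modulated boundary radius; returns the
# binary support and the signed distance-like field used for soft shading
sample_blob <- function(size, radius_range) {
  r0 <- stats::runif(1, radius_range[1], radius_range[2]) * size
  margin <- r0 * 1.15 + 2
  cy <- stats::runif(1, margin, size - 1 - margin)
  cx <- stats::runif(1, margin, size - 1 - margin)
  ecc <- stats::runif(1, 0.8, 1)      # ellipse axis ratio
  phi <- stats::runif(1, 0, pi)       # orientation
  m <- 2:4                            # angular modulation harmonics
  amp <- stats::runif(3, 0, 0.033)    # total boundary modulation <= ~10%
  psi <- stats::runif(3, 0, 2 * pi)
  yy <- matrix(seq_len(size) - 1 - cy, size, size)
  xx <- matrix(rep(seq_len(size) - 1 - cx, each = size), size, size)
  u <- cos(phi) * xx + sin(phi) * yy
  v <- (-sin(phi) * xx + cos(phi) * yy) / ecc
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rb <- r0 * (1 + amp[1] * cos(m[1] * theta + psi[1]) +
                amp[2] * cos(m[2] * theta + psi[2]) +
                amp[3] * cos(m[3] * theta + psi[3]))
  list(inside = rho <= rb, excess = rb - rho, center = c(cy, cx),
       reach = r0 * 1.1 * max(1, 1 / ecc))
}

render_synthetic_pair <- function(spec) {
  size <- spec$size
  base <- c(0.52, 0.26, 0.22) * stats::runif(3, 0.9, 1.1)
  img <- array(0, dim = c(size, size, 3))
  tex <- low_freq_noise(size, coarse = max(4L, size %/% 16L))
  for (c in 1:3) {
    img[, , c] <- base[c] + 0.06 * tex + 0.03 * low_freq_noise(size, 6L)
  }

  n_blobs <- sample_range(spec$blobs_per_image)
  mask <- matrix(0, size, size)
  blobs <- list()
  for (b in seq_len(n_blobs)) {
    for (try in 1:50) {
      bl <- sample_blob(size, spec$blob_radius_fraction)
      if (spec$allow_touching || !length(blobs)) break
      dists <- vapply(blobs, function(o) {
        sqrt(sum((o$center - bl$center)^2)) - o$reach - bl$reach
      }, numeric(1))
      if (all(dists > 3)) break
    }
    blobs[[b]] <- bl
    mask[bl$inside] <- 1
    shade <- pmin(pmax(bl$excess / 1.5 + 0.5, 0), 1)  # soft-edged alpha
    glow <- pmin(pmax(bl$excess, 0) / max(bl$reach, 1), 1)
    col <- c(0.78, 0.47, 0.43) * stats::runif(3, 0.92, 1.08)
    for (c in 1:3) {
      blob_col <- col[c] * (1 + 0.18 * glow)
      img[, , c] <- img[, , c] * (1 - shade) + blob_col * shade
    }
  }

  # linear illumination gradient along a random direction
  ang <- stats::runif(1, 0, 2 * pi)
  yy <- matrix(seq_len(size) - 1, size, size) / (size - 1) - 0.5
  xx <- matrix(rep(seq_len(size) - 1, each = size), size, size) / (size - 1) - 0.5
  grad <- (cos(ang) * xx + sin(ang) * yy) * spec$illumination_strength
  img <- img * (1 + array(rep(grad, 3), dim = dim(img)))

  # specular highlights: small saturated discs
  n_h <- sample_range(spec$highlight_count)
  for (q in seq_len(n_h)) {
    hy <- stats::runif(1, 2, size - 3); hx <- stats::runif(1, 2, size - 3)
    hr <- stats::runif(1, 1, 3)
    d2 <- (matrix(seq_len(size) - 1 - hy, size, size))^2 +
      (matrix(rep(seq_len(size) - 1 - hx, each = size), size, size))^2
    spot <- d2 <= hr^2
    for (c in 1:3) img[, , c][spot] <- stats::runif(1, 0.95, 1)
  }

  # overlay artifacts: white text-like bar or green patch in a corner
  if (stats::runif(1) < spec$artifact_probability) {
    bh <- max(3L, round(size * stats::runif(1, 0.06, 0.10)))
    bw <- max(6L, round(size * stats::runif(1, 0.25, 0.40)))
    corner <- sample(1:4, 1L)
    ri <- if (corner %in% c(1, 2)) 2L + seq_len(bh) else size - 1L - bh + seq_len(bh)
    ci <- if (corner %in% c(1, 3)) 2L + seq_len(bw) else size - 1L - bw + seq_len(bw)
    if (stats::runif(1) < 0.5) {
      for (c in 1:3) img[ri, ci, c] <- 0.92  # text-like white bar
      img[ri[seq(1, bh, by = 2)], ci, ] <- 0.75
    } else {
      img[ri, ci, 1] <- 0.15; img[ri, ci, 2] <- 0.7; img[ri, ci, 3] <- 0.25
    }
  }

  img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Generate a synthetic polyp dataset on disk
#'
#' Writes `n_images` PNG image/mask pairs in the `flat` layout
#' (`synth_0001.png` + `synth_0001_mask.png`). Generation is fully seeded:
#' the same spec writes byte-identical files on every run. The records
#' round-trip through [discover_dataset()].
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @param overwrite refuse to overwrite existing files unless `TRUE`.
#' @return tibble of records as from [discover_dataset()].
#' @export
generate_dataset <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "garnet_synth_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("synth_%04d", seq_len(spec$n_images))
  img_paths <- file.path(out_dir, paste0(ids, ".png"))
  msk_paths <- file.path(out_dir, paste0(ids, "_mask.png"))
  existing <- c(img_paths, msk_paths)[file.exists(c(img_paths, msk_paths))]
  if (length(existing) && !overwrite) {
    stop(sprintf("refusing to overwrite %d existing file(s) under %s",
                 length(existing), out_dir), call. = FALSE)
  }
  for (i in seq_len(spec$n_images)) {
    pair <- local_seed(derive_seed(spec$seed, i), render_synthetic_pair(spec))
    write_image(pair$image, img_paths[i])
    write_mask(pair$mask, msk_paths[i])
  }
  tibble::tibble(id = ids, image_path = img_paths, mask_path = msk_paths)
}

#' The canonical worked image/mask pair
#'
#' A fixed, parameter-free fixture: a centered circular polyp of radius
#' `size/4` on a reddish background with a vertical illumination gradient.
#' The mask is the exact lattice set
#' `(x - (size/2 - 0.5))^2 + (y - (size/2 - 0.5))^2 <= (size/4)^2`
#' over 0-based pixel coordinates; for size 256, exhaustive enumeration gives
#' 12,892 foreground pixels.
#'
#' @param size square side length (>= 32).
#' @return list with `image` (`size x size x 3` in `[0, 1]`) and the binary
#'   `mask`.
#' @export
generate_worked_pair <- function(size = 256L) {
  size <- as.integer(size)
  assert_that(size >= 32L, "size must be at least 32")
  ctr <- size / 2 - 0.5
  r <- size / 4
  yy <- matrix(seq_len(size) - 1 - ctr, size, size)
  xx <- matrix(rep(seq_len(size) - 1 - ctr, each = size), size, size)
  d2 <- yy^2 + xx^2
  mask <- (d2 <= r^2) * 1
  img <- array(0, dim = c(size, size, 3))
  base <- c(0.5, 0.25, 0.2)
  gradient <- (matrix(seq_len(size) - 1, size, size)) / (size - 1) * 0.2
  shade <- pmin(pmax((r - sqrt(d2)) / 1.5 + 0.5, 0), 1)
  col <- c(0.78, 0.48, 0.44)
  for (c in 1:3) {
    img[, , c] <- base[c] + gradient
    img[, , c] <- img[, , c] * (1 - shade) + col[c] * shade
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}
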