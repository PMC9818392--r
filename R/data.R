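# Dataset discovery and splitting.

raster_exts <- c("png", "jpg", "jpeg", "tif", "tiff")

list_rasters <- function(dir) {
  fs <- list.files(dir, full.names = TRUE)
  fs <- fs[tolower(tools::file_ext(fs)) %in% raster_exts]
  sort(fs)
}

stem <- function(path) tools::file_path_sans_ext(basename(path))

pair_by_stem <- function(imgs, msks, img_ids = stem(imgs), msk_ids = stem(msks)) {
  orphans_i <- setdiff(img_ids, msk_ids)
  orphans_m <- setdiff(msk_ids, img_ids)
  if (length(orphans_i) || length(orphans_m)) {
    stop(sprintf(
      "unpaired files: %d image(s) without mask [%s]; %d mask(s) without image [%s]",
      length(orphans_i), paste(orphans_i, collapse = ", "),
      length(orphans_m), paste(orphans_m, collapse = ", ")), call. = FALSE)
  }
  ord <- order(img_ids)
  tibble::tibble(id = img_ids[ord], image_path = imgs[ord],
                 mask_path = msks[match(img_ids, msk_ids)][ord])
}

#' Discover paired image/mask records
#'
#' Scans a dataset directory for image/mask pairs under one of three layouts:
#' `"kvasir"` (`images/` and `masks/` subdirectories with shared file stems),
#' `"cvc"` (`Original/` and `Ground Truth/` subdirectories with shared,
#' typically numeric, stems) and `"flat"` (a single directory where each
#' `x.png` is paired with a sibling `x_mask.png`). Records are ordered
#' lexicographically by id, so repeated scans are stable.
#'
#' @param root dataset directory.
#' @param layout one of `"kvasir"`, `"cvc"`, `"flat"`.
#' @return tibble with columns `id`, `image_path`, `mask_path`.
#' @export
discover_dataset <- function(root, layout = c("kvasir", "cvc", "flat")) {
  layout <- match.arg(layout)
  assert_that(dir.exists(root), paste0("directory does not exist: ", root))
  if (layout == "kvasir") {
    recs <- pair_by_stem(list_rasters(file.path(root, "images")),
                         list_rasters(file.path(root, "masks")))
  } else if (layout == "cvc") {
    gt <- if (dir.exists(file.path(root, "Ground Truth"))) "Ground Truth"
          else "GroundTruth"
    recs <- pair_by_stem(list_rasters(file.path(root, "Original")),
                         list_rasters(file.path(root, gt)))
  } else {
    fs <- list_rasters(root)
    is_mask <- grepl("_mask$", stem(fs))
    imgs <- fs[!is_mask]
    msks <- fs[is_mask]
    recs <- pair_by_stem(imgs, msks, stem(imgs), sub("_mask$", "", stem(msks)))
  }
  assert_that(nrow(recs) >= 1L, paste0("no image/mask pairs found under ", root))
  recs
}

#' Split records into train/validation/test sets
#'
#' Seeded shuffle followed by partition. With fractions `(0.8, 0.1, 0.1)`,
#' validation and test sizes are `floor(0.1 * n)` each and the remainder goes
#' to training, so n = 1000 gives 800/100/100 and n = 612 gives 490/61/61.
#' Membership depends only on the seed; the three sets are disjoint and cover
#' the input.
#'
#' @param records tibble from [discover_dataset()] (>= 10 rows).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed shuffle seed.
#' @return named list of tibbles `train`, `val`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- nrow(records)
  assert_that(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  assert_that(n >= 10L, "need at least 10 records to form non-empty splits")
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  assert_that(n_val >= 1L && n_test >= 1L && n - n_val - n_test >= 1L,
              "fractions leave an empty split")
  idx <- local_seed(seed, sample.int(n))
  list(train = records[sort(idx[seq_len(n - n_val - n_test)]), ],
       val = records[sort(idx[n - n_val - n_test + seq_len(n_val)]), ],
       test = records[sort(idx[n - n_test + seq_len(n_test)]), ])
}
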