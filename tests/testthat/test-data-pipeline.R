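write_tiny_pair <- function(img_path, msk_path, size = 12L, seed = 1L) {
  withr::with_seed(seed, {
    png::writePNG(array(runif(size * size * 3), c(size, size, 3)), img_path)
    png::writePNG(rand_mask(size), msk_path)
  })
}

make_layout <- function(layout, n = 10L) {
  root <- tempfile("ds_")
  if (layout == "kvasir") {
    dir.create(file.path(root, "images"), recursive = TRUE)
    dir.create(file.path(root, "masks"))
    for (i in seq_len(n)) {
      write_tiny_pair(file.path(root, "images", sprintf("case%02d.png", i)),
                      file.path(root, "masks", sprintf("case%02d.png", i)),
                      seed = i)
    }
  } else if (layout == "cvc") {
    dir.create(file.path(root, "Original"), recursive = TRUE)
    dir.create(file.path(root, "Ground Truth"))
    for (i in seq_len(n)) {
      write_tiny_pair(file.path(root, "Original", sprintf("%d.png", i)),
                      file.path(root, "Ground Truth", sprintf("%d.png", i)),
                      seed = i)
    }
  } else {
    dir.create(root)
    for (i in seq_len(n)) {
      write_tiny_pair(file.path(root, sprintf("f%02d.png", i)),
                      file.path(root, sprintf("f%02d_mask.png", i)), seed = i)
    }
  }
  root
}

test_that("discovery pairs files under all three layouts, in stable order", {
  for (layout in c("kvasir", "cvc", "flat")) {
    root <- make_layout(layout)
    recs <- discover_dataset(root, layout)
    expect_identical(nrow(recs), 10L)
    expect_identical(recs$id, sort(recs$id))
    expect_identical(recs, discover_dataset(root, layout))
    expect_true(all(file.exists(recs$image_path)))
    expect_true(all(file.exists(recs$mask_path)))
  }
})

test_that("unpaired files raise an error naming the orphans", {
  root <- make_layout("kvasir", n = 3L)
  file.remove(file.path(root, "masks", "case02.png"))
  expect_error(discover_dataset(root, "kvasir"),
               "1 image\\(s\\) without mask \\[case02\\]")
  expect_error(discover_dataset(tempfile(), "flat"), "does not exist")
})

test_that("split sizes follow the floor rule at the benchmark counts", {
  fake <- function(n) tibble::tibble(id = sprintf("r%04d", seq_len(n)),
                                     image_path = NA, mask_path = NA)
  sp1000 <- split_dataset(fake(1000), seed = 5)
  expect_identical(vapply(sp1000, nrow, integer(1)),
                   c(train = 800L, val = 100L, test = 100L))
  sp612 <- split_dataset(fake(612), seed = 5)
  expect_identical(vapply(sp612, nrow, integer(1)),
                   c(train = 490L, val = 61L, test = 61L))

  expect_identical(split_dataset(fake(612), seed = 5)$val$id, sp612$val$id)
  expect_false(identical(split_dataset(fake(612), seed = 6)$val$id,
                         sp612$val$id))
  expect_error(split_dataset(fake(5)), "at least 10")
})

test_that("splits are disjoint and cover the dataset for many sizes", {
  fake <- function(n) tibble::tibble(id = sprintf("r%04d", seq_len(n)),
                                     image_path = NA, mask_path = NA)
  set.seed(3)
  for (n in c(10L, 11L, 37L, sample(12:2000, 8))) {
    sp <- split_dataset(fake(n), seed = n)
    ids <- c(sp$train$id, sp$val$id, sp$test$id)
    expect_identical(length(ids), n)
    expect_identical(anyDuplicated(ids), 0L)
    expect_setequal(ids, sprintf("r%04d", seq_len(n)))
    expect_identical(nrow(sp$val), as.integer(floor(0.1 * n)))
    expect_identical(nrow(sp$test), as.integer(floor(0.1 * n)))
  }
})

test_that("a double horizontal flip is the identity", {
  fx <- disc_fixture(32, radius = 6)
  cfg <- aug_only(p_hflip = 1)
  once <- augment_pair(fx$image, fx$mask, cfg, seed = 1)
  twice <- augment_pair(once$image, once$mask, cfg, seed = 2)
  expect_equal(twice$image, fx$image, tolerance = 1e-12)
  expect_identical(twice$mask, fx$mask)
})

test_that("photometric-only augmentation never touches the mask", {
  fx <- disc_fixture(32, radius = 6)
  cfg <- aug_only(p_saturation = 1, p_brightness = 1, p_contrast = 1,
                  p_median_blur = 1, p_gaussian_blur = 1, p_motion_blur = 1,
                  p_noise = 1)
  for (s in 1:25) {
    out <- augment_pair(fx$image, fx$mask, cfg, seed = s)
    expect_identical(out$mask, fx$mask)
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("sampled rotation angles stay inside [0, 90] degrees", {
  fx <- disc_fixture(16, radius = 3)
  cfg <- aug_only(p_rotate = 1)
  angles <- vapply(1:1000, function(s) {
    attr(augment_pair(fx$image, fx$mask, cfg, seed = s), "params")$angle
  }, numeric(1))
  expect_true(all(angles >= 0 & angles <= 90))
})

test_that("geometric transforms keep image and mask exactly aligned", {
  fx <- disc_fixture(64, radius = 10)
  geo <- aug_only(p_hflip = 1, p_vflip = 1, p_scale = 1, p_rotate = 1)
  for (s in 1:200) {
    out <- augment_pair(fx$image, fx$mask, geo, seed = s)
    expect_identical((out$image[, , 1] > 0.5) * 1, out$mask)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("photometric transforms on a binary image preserve the 0.5 level set", {
  fx <- disc_fixture(64, radius = 10)
  pho <- aug_only(p_saturation = 1, p_brightness = 1, p_contrast = 1,
                  p_noise = 1)
  for (s in 1:100) {
    out <- augment_pair(fx$image, fx$mask, pho, seed = s)
    expect_identical((out$image[, , 1] > 0.5) * 1, out$mask)
  }
})

test_that("augmentation is reproducible under a fixed seed", {
  fx <- disc_fixture(48, radius = 8)
  cfg <- augmentation_config()
  a <- augment_pair(fx$image, fx$mask, cfg, seed = 99)
  b <- augment_pair(fx$image, fx$mask, cfg, seed = 99)
  expect_identical(a, b)
})

test_that("training samples have the contracted shape and are seeded", {
  recs <- synth_records(2L, 96L, seed = 21L)
  s1 <- prepare_train_sample(recs[1, ], augmentation_config(), seed = 5,
                             size = 64L)
  expect_identical(dim(s1$image), c(64L, 64L, 3L))
  expect_identical(dim(s1$mask), c(64L, 64L))
  expect_true(all(s1$mask %in% c(0, 1)))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  s2 <- prepare_train_sample(recs[1, ], augmentation_config(), seed = 5,
                             size = 64L)
  expect_identical(s1, s2)
})

test_that("with augmentation off and a centered crop, the pipeline equals plain resize+crop", {
  recs <- synth_records(2L, 96L, seed = 21L)
  got <- prepare_train_sample(recs[1, ], no_augmentation(), seed = 1,
                              size = 64L, crop_offset = c(7L, 7L))
  # independent path: decode, bicubic/nearest resize to 78, center-crop 64
  img <- load_image(recs$image_path[1])
  msk <- load_mask(recs$mask_path[1])
  ri <- 7 + seq_len(64)
  expect_equal(got$image,
               pmin(pmax(resize_image(img, 78, 78, "bicubic"), 0), 1)[ri, ri, ],
               tolerance = 1e-12)
  expect_identical(got$mask, resize_image(msk, 78, 78, "nearest")[ri, ri])
})

test_that("evaluation samples are bicubic-resized without augmentation", {
  root <- tempfile("cvcish_")
  dir.create(root)
  # a 288 x 384 frame, the classic clinical resolution
  withr::with_seed(1, {
    png::writePNG(array(runif(288 * 384 * 3), c(288, 384, 3)),
                  file.path(root, "f1.png"))
    png::writePNG(rand_mask(288, 384), file.path(root, "f1_mask.png"))
  })
  recs <- discover_dataset(root, "flat")
  ev <- prepare_eval_sample(recs[1, ], size = 256L)
  expect_identical(dim(ev$image), c(256L, 256L, 3L))
  expect_identical(dim(ev$mask), c(256L, 256L))
  expect_true(all(ev$mask %in% c(0, 1)))

  # resizing an already-256 image is the identity up to resampler tolerance
  x <- rand_img(256)
  expect_equal(resize_image(x, 256, 256, "bicubic"), x, tolerance = 1e-6)
})
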