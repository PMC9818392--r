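test_that("config invariants are enforced at build time", {
  expect_error(garnet_config(100, 32, 5), "divisible")
  expect_error(garnet_config(64, 2, 3), "base_filters")
  expect_error(garnet_config(64, 8, 1), "depth")
  expect_s3_class(garnet_config(64, 8, 3), "garnet_config")
})

test_that("the output-resolution ladder holds across configurations", {
  # depth 3 at 64: attention at 16 and 32 = input/4, input/2
  m <- tiny_model(64, 8, 3, seed = 2)
  out <- garnet_forward(m, rand_img(64))[[1]]
  expect_length(out$attention, 2L)
  expect_identical(vapply(out$attention, function(a) dim(a)[1], integer(1)),
                   c(16L, 32L))
  expect_identical(dim(out$y_pred), c(64L, 64L, 1L))
  expect_true(all(out$y_pred > 0 & out$y_pred < 1))

  # depth 5 at 128: four maps at input/16, /8, /4, /2
  m5 <- tiny_model(128, 4, 5, seed = 3)
  out5 <- garnet_forward(m5, rand_img(128))[[1]]
  expect_length(out5$attention, 4L)
  expect_identical(vapply(out5$attention, function(a) dim(a)[1], integer(1)),
                   c(8L, 16L, 32L, 64L))
})

test_that("evaluation-mode forward passes are bit-identical and batch independent", {
  m <- tiny_model(32, 4, 2, seed = 4)
  img <- rand_img(32)
  o1 <- garnet_forward(m, img)[[1]]
  o2 <- garnet_forward(m, img)[[1]]
  expect_identical(o1, o2)

  others <- lapply(1:3, function(i) rand_img(32))
  batch <- garnet_forward(m, c(list(img), others))
  expect_length(batch, 4L)
  expect_identical(batch[[1]]$y_pred, o1$y_pred)
  expect_identical(batch[[1]]$attention, o1$attention)
})

test_that("malformed inputs are rejected with the offending dimension named", {
  m <- tiny_model(32, 4, 2)
  expect_error(garnet_forward(m, rand_img(16)), "16x16.*32x32")
  expect_error(garnet_forward(m, rand_img(32, 32, 2)), "2 channels")
  expect_error(garnet_forward(m, list(rand_img(32), rand_img(16))),
               "image 2")
})

test_that("parameter count matches an independent per-layer tally", {
  cfg <- garnet_config(64, 8, 3, seed = 1)
  m <- build_garnet(cfg)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  mod_block <- function(cin, f) {
    conv_n(3, cin, f) + bn_n(f) + conv_n(3, f, f) + bn_n(f) + conv_n(1, cin, f)
  }
  res_block <- function(f) conv_n(3, f, f) + bn_n(f) + conv_n(3, f, f) + bn_n(f)
  gam_n <- function(k) 2 * conv_n(1, k, k) + bn_n(k) + conv_n(1, k, k) + bn_n(k)
  gal_n <- function(k) conv_n(1, k, 1) + bn_n(1)
  dec_n <- function(cin, ks) {
    conv_n(3, cin, ks) + bn_n(ks) + gam_n(ks) + gal_n(ks) + mod_block(2 * ks, ks)
  }
  expected <- conv_n(3, 3, 8) + bn_n(8) +            # stem
    mod_block(8, 8) + mod_block(8, 16) + mod_block(16, 32) +  # encoder
    2 * res_block(32) +                              # bottleneck
    dec_n(32, 16) + dec_n(16, 8) +                   # decoder stages
    conv_n(3, 8, 8) + bn_n(8) + conv_n(1, 8, 1) + bn_n(1)  # final stage
  expect_identical(count_parameters(m), expected)
})

test_that("parameter count is seed invariant and ~quadratic in width", {
  c8 <- count_parameters(build_garnet(garnet_config(32, 8, 2, seed = 1)))
  c8b <- count_parameters(build_garnet(garnet_config(32, 8, 2, seed = 99)))
  expect_identical(c8, c8b)
  c16 <- count_parameters(build_garnet(garnet_config(32, 16, 2, seed = 1)))
  expect_gt(c16 / c8, 3.5)
  expect_lt(c16 / c8, 4.5)
})

test_that("checkpoints restore bit-identical evaluation behaviour", {
  m <- tiny_model(32, 4, 2, seed = 6)
  img <- rand_img(32)
  before <- garnet_forward(m, img)[[1]]
  path <- tempfile(fileext = ".rds")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_identical(unclass(m2$config), unclass(m$config))
  expect_identical(garnet_forward(m2, img)[[1]], before)
  expect_error(read_checkpoint({
    p <- tempfile(); saveRDS(list(a = 1), p); p
  }), "checkpoint")
})

test_that("the full loss is differentiable end to end", {
  m <- tiny_model(16, 4, 2, seed = 7)
  pairs <- tiny_pairs(2, 16, seed = 8)
  bl <- garnet:::batch_loss_nodes(m, pairs, training = TRUE)
  garnet:::backward(bl$total)
  g <- garnet:::collect_grads(bl$ctx)
  expect_identical(sort(names(g)), sort(ls(m$store$theta)))
  expect_true(all(vapply(g, function(x) all(is.finite(x)), logical(1))))
  expect_gt(max(vapply(g, function(x) max(abs(x)), numeric(1))), 0)
})
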