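test_that("residual block keeps shape and enforces the identity-skip contract", {
  blk <- new_residual_block(16, block_spec(c(16, 16)), seed = 3)
  x <- rand_img(32, 32, 16)
  y <- residual_block(x, blk)
  expect_identical(dim(y), c(32L, 32L, 16L))

  expect_error(new_residual_block(16, block_spec(c(16, 16), last_stride = 2)),
               "last_stride = 1")
  expect_error(new_residual_block(8, block_spec(c(16, 16))), "not addable")
  expect_error(residual_block(rand_img(8, 8, 4), blk), "channels")
  expect_error(residual_block(array(c(NA, rand_img(8, 8, 16)[-1]),
                                    c(8, 8, 16)), blk), "finite")
})

test_that("zeroed main path reduces the residual block to activation(x)", {
  blk <- zero_parameters(new_residual_block(4, block_spec(c(4, 4)), seed = 1))
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_identical(residual_block(x, blk), pmax(x, 0))
})

test_that("residual block equals a hand-rolled conv/norm/act composition", {
  set.seed(42)
  blk <- new_residual_block(4, block_spec(c(4, 4)), seed = 9)
  th <- blk$store$theta
  x <- rand_img(8, 8, 4)
  # independent re-composition from the primitive operations (evaluation
  # mode: fresh running stats are mean 0 / var 1)
  h1 <- batch_norm(conv2d(x, th[["block.main.conv1.w"]], th[["block.main.conv1.b"]]),
                   th[["block.main.bn1.gamma"]], th[["block.main.bn1.beta"]])
  h1 <- pmax(h1, 0)
  h2 <- batch_norm(conv2d(h1, th[["block.main.conv2.w"]], th[["block.main.conv2.b"]]),
                   th[["block.main.bn2.gamma"]], th[["block.main.bn2.beta"]])
  expect_equal(residual_block(x, blk), pmax(h2 + x, 0), tolerance = 1e-12)
})

test_that("modified residual block follows the stride/channel shape algebra", {
  blk <- new_modified_residual_block(16, block_spec(c(32, 32), 2), seed = 2)
  y <- modified_residual_block(rand_img(64, 64, 16), blk)
  expect_identical(dim(y), c(32L, 32L, 32L))

  blk1 <- new_modified_residual_block(16, block_spec(c(32, 32), 1), seed = 2)
  y1 <- modified_residual_block(rand_img(64, 64, 16), blk1)
  expect_identical(dim(y1), c(64L, 64L, 32L))

  # grid over sizes and strides: output dims are ceiling(h / stride)
  for (h in c(8L, 16L, 32L)) for (s in c(1L, 2L)) {
    b <- new_modified_residual_block(3, block_spec(c(4, 6), s), seed = h + s)
    out <- modified_residual_block(rand_img(h, h, 3), b)
    expect_identical(dim(out), c(as.integer(ceiling(h / s)),
                                 as.integer(ceiling(h / s)), 6L))
  }
})

test_that("zeroing both paths of the modified block yields activation(0) = 0", {
  blk <- zero_parameters(new_modified_residual_block(4, block_spec(c(8, 8), 2)))
  y <- modified_residual_block(rand_img(16, 16, 4), blk)
  expect_identical(y, array(0, c(8, 8, 8)))
})

test_that("guided attention module matches shapes and the zero closed form", {
  gam <- new_guided_attention_module(32, seed = 5)
  L <- rand_img(64, 64, 32); H <- rand_img(64, 64, 32)
  out <- guided_attention_module(L, H, gam)
  expect_identical(dim(out$A), c(64L, 64L, 32L))
  expect_identical(dim(out$O), c(64L, 64L, 32L))
  expect_error(guided_attention_module(L, rand_img(32, 32, 32), gam),
               "identical shape")

  # zeroed parameters with identity normalization: pre-sigmoid is exactly 0
  zero_parameters(gam)
  L2 <- array(rnorm(8 * 8 * 32), c(8, 8, 32))
  out2 <- guided_attention_module(L2, rand_img(8, 8, 32), gam)
  expect_identical(out2$A, array(0.5, c(8, 8, 32)))
  expect_identical(out2$O, 0.5 * L2)
})

test_that("gal head consolidates to one channel and honours the zero form", {
  head <- new_gal_head(32, seed = 6)
  a <- gal_head(rand_img(64, 64, 32), head)
  expect_identical(dim(a), c(64L, 64L, 1L))
  zero_parameters(head)
  expect_identical(gal_head(rand_img(8, 8, 32), head), array(0.5, c(8, 8, 1)))
})

test_that("attention maps stay strictly inside (0, 1) over random trials", {
  set.seed(7)
  for (trial in seq_len(1000)) {
    k <- sample(2:4, 1)
    gam <- new_guided_attention_module(k, seed = trial)
    head <- new_gal_head(k, seed = trial + 1)
    out <- guided_attention_module(array(rnorm(4 * 4 * k, sd = 1.5), c(4, 4, k)),
                                   array(rnorm(4 * 4 * k, sd = 1.5), c(4, 4, k)),
                                   gam)
    a <- gal_head(out$A, head)
    expect_true(all(out$A > 0 & out$A < 1))
    expect_true(all(a > 0 & a < 1))
  }
})

test_that("gradients flow through every block to its input", {
  set.seed(8)
  configs <- list(
    list(fwd = garnet:::fwd_residual_block, init = garnet:::init_residual_block,
         spec = block_spec(c(3, 3)), cin = 3L),
    list(fwd = garnet:::fwd_modified_block, init = garnet:::init_modified_block,
         spec = block_spec(c(4, 4), 2), cin = 3L))
  for (cf in configs) {
    store <- garnet:::new_param_store()
    cf$init(store, "b", cf$cin, cf$spec)
    ctx <- garnet:::new_fctx(store, training = TRUE)
    xn <- garnet:::nd_new(array(rnorm(8 * 8 * cf$cin * 2), c(8, 8, cf$cin, 2)))
    out <- cf$fwd(ctx, xn, "b", cf$spec)
    s <- garnet:::op_bce_mean(
      garnet:::op_sigmoid(out),
      array(rbinom(length(out$value), 1, 0.4), dim(out$value)))
    garnet:::backward(s)
    expect_false(is.null(xn$grad))
    expect_gt(max(abs(xn$grad)), 0)
  }
})
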