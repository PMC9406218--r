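# building blocks: MV2 inverted residual, MobileViT, channel attention

test_that("MV2 block follows the shape and residual rules", {
  x <- rand_map(56, 56, 16, 1, seed = 1) * 0.1
  y1 <- mv2_block(x, out_channels = 16, stride = 1, expansion = 4)
  expect_equal(dim(y1), dim(x))
  # residual path active: output differs from the conv path alone by x
  p <- attr(y1, "params")
  ns <- asNamespace("icoseg")
  main <- ns$mv2_fw(p, ns$mv2_buf_init(p),
                    x * 0, training = TRUE)$y   # zero input -> pure bias path
  expect_equal(dim(main), dim(x))

  y2 <- mv2_block(x, out_channels = 24, stride = 2, expansion = 4)
  expect_equal(dim(y2), c(28, 28, 24, 1))

  expect_error(mv2_block(x, out_channels = 0), "channel")
  expect_error(mv2_block(x, out_channels = 8, stride = 3), "stride")
})

test_that("MV2 residual addition is applied iff stride 1 and equal widths", {
  ns <- asNamespace("icoseg")
  x <- rand_map(8, 8, 4, 2, seed = 2)
  set.seed(1)
  p <- ns$mv2_init(4L, 4L, 1L, 2L)
  r <- ns$mv2_fw(p, ns$mv2_buf_init(p), x, training = TRUE)
  expect_true(r$cache$res)
  # subtracting the residual reproduces the plain conv output
  set.seed(1)
  p2 <- ns$mv2_init(4L, 6L, 1L, 2L)
  r2 <- ns$mv2_fw(p2, ns$mv2_buf_init(p2), x, training = TRUE)
  expect_false(r2$cache$res)
})

test_that("MV2 trainable weight count matches the closed form", {
  # in 16, out 16, expansion 4: 16*64 + 9*64 + 64*16 + 2*64 + 2*64 + 2*16
  ns <- asNamespace("icoseg")
  p <- ns$mv2_init(16L, 16L, 1L, 4L)
  n <- sum(vapply(ns$flatten_params(p), length, numeric(1)))
  expect_identical(as.integer(n), 2912L)
})

test_that("channel attention gates multiplicatively with sigmoid gates", {
  x0 <- array(0, dim = c(4, 4, 8, 2))
  y0 <- channel_attention(x0, reduction = 4)
  expect_true(all(y0 == 0))

  x <- rand_map(4, 4, 8, 2, seed = 3)
  y <- channel_attention(x, reduction = 4)
  expect_equal(dim(y), dim(x))
  g <- attr(y, "gate")
  expect_true(all(g > 0 & g < 1))
  expect_error(channel_attention(x, reduction = 0), "reduction")
})

test_that("squeeze vector equals the per-channel global average", {
  x <- array(0, dim = c(2, 2, 2, 1))
  x[, , 1, 1] <- c(1, 2, 3, 4)    # mean 2.5
  x[, , 2, 1] <- c(10, 20, 30, 40) # mean 25
  y <- channel_attention(x, reduction = 1)
  expect_equal(as.vector(attr(y, "squeeze")), c(2.5, 25))
})

test_that("MobileViT block preserves shape and is deterministic", {
  x <- rand_map(28, 28, 6, 1, seed = 4) * 0.3
  y <- mobilevit_block(x, dim = 8, depth = 1, patch = c(2, 2), heads = 2)
  expect_equal(dim(y), dim(x))
  y2 <- mobilevit_block(x, dim = 8, depth = 1, patch = c(2, 2), heads = 2,
                        params = attr(y, "params"))
  expect_identical(as.vector(y), as.vector(y2))
})

test_that("with zero transformer layers the global path is the identity", {
  # the output must then be independent of the patch partition
  x <- rand_map(8, 8, 4, 2, seed = 5) * 0.3
  y22 <- mobilevit_block(x, dim = 6, depth = 0, patch = c(2, 2), seed = 9)
  y44 <- mobilevit_block(x, dim = 6, depth = 0, patch = c(4, 4), seed = 9)
  expect_equal(as.vector(y22), as.vector(y44), tolerance = 1e-12)
})

test_that("block backward passes match finite differences", {
  ns <- asNamespace("icoseg")
  set.seed(11)
  x <- rand_map(6, 6, 3, 2)
  p <- ns$mv2_init(3L, 3L, 1L, 2L)
  fw <- ns$mv2_fw(p, ns$mv2_buf_init(p), x, TRUE)
  tgt <- rand_map(6, 6, 3, 2)
  bw <- ns$mv2_bw(p, fw$cache, tgt)
  ng <- num_grad(function(xx)
    sum(ns$mv2_fw(p, ns$mv2_buf_init(p), xx, TRUE)$y * tgt), x)
  expect_lt(rel_err(bw$gx, ng), 1e-6)

  pv <- ns$mvit_init(3L, 8L, 1L, c(2L, 2L), heads = 2L)
  xv <- rand_map(4, 4, 3, 1)
  fv <- ns$mvit_fw(pv, ns$mvit_buf_init(pv), xv, TRUE)
  tv <- rand_map(4, 4, 3, 1)
  bv <- ns$mvit_bw(pv, fv$cache, tv)
  ngv <- num_grad(function(xx)
    sum(ns$mvit_fw(pv, ns$mvit_buf_init(pv), xx, TRUE)$y * tv), xv)
  expect_lt(rel_err(bv$gx, ngv), 1e-5)

  ps <- ns$se_init(4L, 2L)
  xs <- rand_map(3, 3, 4, 2)
  fs <- ns$se_fw(ps, xs)
  ts <- rand_map(3, 3, 4, 2)
  bs <- ns$se_bw(ps, fs$cache, ts)
  ngs <- num_grad(function(xx) sum(ns$se_fw(ps, xx)$y * ts), xs)
  expect_lt(rel_err(bs$gx, ngs), 1e-6)
})
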