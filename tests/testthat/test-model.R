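# network assembly: shapes, strides, determinism, parameter bookkeeping,
# thresholding and checkpoints

small64 <- function() icoseg_init(icoseg_config("small"), seed = 5)

test_that("forward pass maps inputs to probability maps of the same size", {
  m <- small64()
  x <- array(runif(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  y <- icoseg_forward(x, m)
  expect_equal(dim(y), c(64, 64, 1, 2))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(icoseg_forward(x * 300, m), "normalized")
  expect_error(icoseg_forward(array(0.5, c(32, 32, 3, 1)), m), "input")
})

test_that("encoder stage strides are 2, 4, 8, 16, 32", {
  m <- small64()
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  fd <- icoseg:::icoseg_core_fw(m, x, training = FALSE)$feat_dims
  sides <- vapply(fd[c("s1", "s2", "s3", "s4", "s5")],
                  function(d) d[1L], numeric(1))
  expect_equal(unname(64 / sides), c(2, 4, 8, 16, 32))
})

test_that("batched inputs are processed independently", {
  m <- small64()
  x1 <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  xb <- array(c(x1, x1), dim = c(64, 64, 3, 2))
  yb <- icoseg_forward(xb, m)
  expect_equal(yb[, , , 1], yb[, , , 2], tolerance = 1e-12)
  y1 <- icoseg_forward(x1, m)
  expect_equal(as.vector(y1), as.vector(yb[, , , 1]), tolerance = 1e-12)
})

test_that("forward pass is deterministic for fixed weights", {
  m <- small64()
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  expect_identical(icoseg_forward(x, m), icoseg_forward(x, m))
})

test_that("predict_mask thresholds with ties to foreground and idempotence", {
  p <- matrix(c(0.4, 0.6), 1, 2)
  expect_equal(as.vector(predict_mask(p)), c(0L, 1L))
  expect_true(all(predict_mask(matrix(0.5, 2, 2)) == 1L))
  pm <- predict_mask(matrix(runif(16), 4, 4))
  expect_identical(predict_mask(pm, 0.5), pm)
  expect_error(predict_mask(p, threshold = 0), "threshold")
})

coef_params <- function(m) icoseg:::flatten_params(m$params)

test_that("count_parameters equals an independent enumeration of arrays", {
  m <- small64()
  # independent walk: every numeric leaf that is not structural metadata
  meta <- c("stride", "cin", "cout", "hid", "d", "patch", "heads",
            "channels")
  count_walk <- function(node, name = "") {
    if (is.numeric(node)) return(length(node))
    if (!is.list(node)) return(0)
    nms <- names(node)
    tot <- 0
    for (i in seq_along(node)) {
      if (!is.null(nms) && nms[i] %in% meta) next
      tot <- tot + count_walk(node[[i]])
    }
    tot
  }
  expect_equal(count_parameters(m), count_walk(m$params))
  expect_equal(count_parameters(m), sum(lengths(coef_params(m))))
})

test_that("parameter count grows superlinearly when widths double", {
  base <- icoseg_config("small")
  wide <- icoseg_config("small",
                        stem_channels = 16L,
                        stage_channels = base$stage_channels * 2L,
                        vit_dims = base$vit_dims * 2L,
                        bottleneck_channels = 256L,
                        decoder_channels = base$decoder_channels * 2L)
  expect_gt(count_parameters(wide), 2 * count_parameters(base))
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  m <- small64()
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f, meta = list(note = "test"))
  m2 <- load_checkpoint(f)
  expect_equal(m2$params, m$params)
  expect_equal(attr(m2, "meta")$note, "test")
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  expect_identical(icoseg_forward(x, m), icoseg_forward(x, m2))

  # corrupt the stored config: hash check must refuse
  obj <- readRDS(f)
  obj$cfg$threshold <- 0.7
  saveRDS(obj, f)
  expect_error(load_checkpoint(f), "hash mismatch")
})

test_that("describe_model totals agree with count_parameters", {
  m <- small64()
  tab <- describe_model(m)
  expect_equal(attr(tab, "total"), count_parameters(m))
  expect_equal(nrow(tab), 12L)
})

test_that("the full-size map that does not tile exactly is handled", {
  # 224-px reference topology at stride 32 gives a 7x7 map with a 2x2
  # transformer patch; the block resizes around the transformer, and the
  # resize is an exact linear adjoint pair
  ns <- asNamespace("icoseg")
  x <- rand_map(7, 7, 2, 1, seed = 8)
  r <- ns$resize_map_fw(x, 8, 8)
  gy <- rand_map(8, 8, 2, 1, seed = 9)
  gx <- ns$resize_map_bw(r$cache, gy)
  expect_equal(sum(r$y * gy), sum(x * gx), tolerance = 1e-12)
})
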