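# training engine: splits, preprocessing, augmentation, the decay rule,
# a short optimization run and end-to-end evaluation

test_that("splits have round(n * ratio) sizes with the remainder to train", {
  man <- data.frame(id = sprintf("p%03d", 1:100))
  sp <- split_dataset(man, c(0.6, 0.1, 0.3), seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 60L, val = 10L, test = 30L))
  all_ids <- unlist(lapply(sp, function(d) d$id))
  expect_setequal(all_ids, man$id)
  expect_equal(anyDuplicated(all_ids), 0L)

  sp2 <- split_dataset(man, c(0.6, 0.1, 0.3), seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(man, c(0.6, 0.1, 0.3), seed = 2)
  expect_false(identical(sp$train$id, sp3$train$id))

  expect_error(split_dataset(man[1:2, , drop = FALSE]), "at least 3")
  expect_error(split_dataset(man, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("preprocessing resizes and normalizes as specified", {
  set.seed(6)
  img <- array(runif(256 * 256 * 3, 0, 255), dim = c(256, 256, 3))
  msk <- matrix(0L, 256, 256); msk[40:120, 60:200] <- 1L
  pp <- preprocess_patch(img, msk, 224L)
  expect_equal(dim(pp$image), c(224, 224, 3))
  expect_true(all(pp$image >= 0 & pp$image <= 1))
  expect_equal(dim(pp$mask), c(224, 224))
  expect_true(all(pp$mask %in% c(0L, 1L)))

  white <- array(255, dim = c(64, 64, 3))
  expect_true(all(preprocess_patch(white, NULL, 32L)$image == 1))
  expect_error(preprocess_patch(img, matrix(0L, 10, 10), 224L), "differ")
})

test_that("augmentation applies paired, invertible transforms", {
  set.seed(7)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  msk <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)

  none <- augment_pair(img, msk, aug_prob = 0)
  expect_identical(none$image, img)
  expect_equal(none$mask, msk, ignore_attr = TRUE)

  ff <- augment_pair(img, msk, ops = "hflip")
  ff2 <- augment_pair(ff$image, ff$mask, ops = "hflip")
  expect_equal(ff2$image, img)
  expect_equal(ff2$mask, msk, ignore_attr = TRUE)

  # rot90 counter-clockwise: (r, c) -> (W - 1 - c, r); pixel (0, 3) -> (0, 0)
  m4 <- matrix(0L, 4, 4); m4[1, 4] <- 1L
  i4 <- array(0, dim = c(4, 4, 3)); i4[1, 4, ] <- 1
  rr <- augment_pair(i4, m4, ops = "rot90")
  expect_equal(which(rr$mask == 1L), 1L)       # row 1, col 1
  expect_equal(rr$image[1, 1, 1], 1)

  sc <- augment_pair(img, msk, ops = "scale")
  expect_equal(dim(sc$image), dim(img))
  expect_equal(dim(sc$mask), dim(msk))
  expect_true(all(sc$mask %in% c(0L, 1L)))
})

test_that("the decay rule fires after the stated non-improvement runs", {
  expect_equal(lr_step(c(0.70, 0.69, 0.68), 1e-4), 5e-5)
  expect_equal(lr_step(c(0.70, 0.69), 1e-4), 1e-4)   # only one bad epoch
  expect_equal(lr_step(c(0.5, 0.6, 0.7), 1e-4), 1e-4)
  expect_equal(lr_step(c(0.70, 0.71, 0.71, 0.70), 1e-4), 5e-5)
  # counter resets after a decay: epoch 4 alone does not re-trigger
  expect_equal(lr_step(c(0.70, 0.69, 0.68, 0.67), 1e-4), 1e-4)
  expect_equal(lr_step(c(0.70, 0.69, 0.68, 0.67, 0.66), 1e-4), 5e-5)
  expect_equal(lr_step(0.7, 1e-4), 1e-4)
  expect_error(lr_step(c(0.7, 0.6), 1e-4, patience = 0), "patience")
})

test_that("a short training run fulfils the engine contract", {
  man <- tiny_dataset()
  mc <- icoseg_config("small")
  tc <- train_config(input_size = 64L, epochs = 2L, batch_size = 4L,
                     split = c(0.6, 0.2, 0.2), seed = 11L)
  fit <- icoseg(man, model_config = mc, config = tc, verbose = FALSE)
  expect_s3_class(fit, "icoseg")
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_equal(fit$best_val_dice, max(fit$history$val_dice))

  # checkpoint loadable and predicts like the fit
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  m2 <- load_checkpoint(ck)
  img <- read_image(file.path(attr(man, "dir"), man$image[1]))
  p1 <- predict(fit, img, type = "prob")[[1]]
  p2 <- predict(m2, img, type = "prob")[[1]]
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  # standard S3 surface
  expect_equal(sum(lengths(coef(fit))), fit$n_parameters)
  expect_output(print(fit), "Fitted")
  grDevices::pdf(NULL)
  plot(fit)
  grDevices::dev.off()
})

test_that("training is reproducible under a fixed seed", {
  man <- tiny_dataset()
  mc <- icoseg_config("small")
  tc <- train_config(input_size = 64L, epochs = 2L, batch_size = 4L,
                     split = c(0.6, 0.2, 0.2), seed = 12L)
  f1 <- icoseg(man, model_config = mc, config = tc, verbose = FALSE)
  f2 <- icoseg(man, model_config = mc, config = tc, verbose = FALSE)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-6)
  expect_equal(f1$history$val_dice, f2$history$val_dice, tolerance = 1e-6)
  expect_identical(f1$splits$train$id, f2$splits$train$id)
})

test_that("injected ground-truth predictions evaluate to perfect scores", {
  man <- tiny_dataset()
  dir <- attr(man, "dir")
  test_man <- man[1:4, , drop = FALSE]
  attr(test_man, "dir") <- dir
  preds <- lapply(seq_len(nrow(test_man)), function(i) {
    inst <- read_instance_png(file.path(dir, test_man$instances[i]))
    matrix(as.integer(inst > 0), nrow(inst), ncol(inst))
  })
  rep <- evaluate_model(list(cfg = icoseg_config("small")), test_man,
                        predictions = preds)
  expect_true(all(rep$aggregate$mean == 1))
  expect_true(all(rep$aggregate$sd == 0))
  expect_equal(nrow(rep$per_patch), 4L)
  expect_equal(unname(rep$totals["gt_cells"]),
               unname(rep$totals["pred_cells"]))
})
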