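# Training engine: dataset splitting, preprocessing, augmentation, the
# Adam + step-decay optimization loop, and end-to-end evaluation.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with initial learning rate
#' 1e-4, batch size 8, 50 epochs, loss weighting gamma 0.4, step decay of
#' the learning rate (halving) when the validation Dice has not improved
#' for two consecutive epochs, 224 x 224 inputs normalized to `[0, 1]`,
#' a 60/10/30 train/validation/test split, and per-transform augmentation
#' probability 0.5.
#'
#' @param lr initial learning rate.
#' @param batch_size images per optimization step.
#' @param epochs training epochs.
#' @param gamma BCE weight in the combined loss.
#' @param decay_factor multiplicative learning-rate decay.
#' @param patience consecutive non-improving epochs before decay.
#' @param input_size network input side in pixels.
#' @param split train/validation/test fractions (must sum to 1).
#' @param aug_prob per-transform augmentation probability.
#' @param seed master seed for splitting, initialization, shuffling and
#'   augmentation.
#' @param threshold probability threshold for validation Dice.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 8L, epochs = 50L,
                         gamma = 0.4, decay_factor = 0.5, patience = 2L,
                         input_size = 224L, split = c(0.6, 0.1, 0.3),
                         aug_prob = 0.5, seed = 42L, threshold = 0.5) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (gamma < 0 || gamma > 1) stop("invalid-config: gamma must be in [0, 1]")
  if (patience < 1L) stop("patience must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), gamma = gamma,
                 decay_factor = decay_factor, patience = as.integer(patience),
                 input_size = as.integer(input_size), split = split,
                 aug_prob = aug_prob, seed = as.integer(seed),
                 threshold = threshold),
            class = "train_config")
}

#' Split a manifest into train/validation/test sets
#'
#' Seeded shuffle followed by partition. The validation and test sizes are
#' `round(n * ratio)`; the remainder goes to the training set. Partitions
#' are disjoint and exhaustive.
#'
#' @param manifest data.frame of patches (or anything with rows).
#' @param ratios train/val/test fractions summing to 1.
#' @param seed shuffle seed.
#' @return list with data.frames `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, ratios = c(0.6, 0.1, 0.3), seed = 42L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  n <- nrow(manifest)
  if (is.null(n) || n < 3L) stop("need at least 3 patches to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample.int(n)
  n_val <- round(n * ratios[2L])
  n_test <- round(n * ratios[3L])
  n_train <- n - n_val - n_test
  idx <- list(train = ord[seq_len(n_train)],
              val = ord[n_train + seq_len(n_val)],
              test = ord[n_train + n_val + seq_len(n_test)])
  lapply(idx, function(i) manifest[i, , drop = FALSE])
}

#' Preprocess an image/mask pair for the network
#'
#' The image is resized bilinearly to `size x size` and rescaled from
#' 0--255 to `[0, 1]`; the mask is resized with nearest-neighbour
#' interpolation so it stays strictly binary.
#'
#' @param image RGB array `(H, W, 3)`, values 0--255.
#' @param mask binary matrix `(H, W)` or `NULL`.
#' @param size target side in pixels.
#' @return list with `image` (`(size, size, 3)`, in `[0, 1]`) and `mask`.
#' @export
preprocess_patch <- function(image, mask = NULL, size = 224L) {
  if (!is.null(mask) &&
      !identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask shapes differ")
  img <- resize_bilinear(image, size, size) / 255
  img <- pmin(pmax(img, 0), 1)
  out_mask <- NULL
  if (!is.null(mask)) {
    out_mask <- resize_nearest(mask, size, size)
    storage.mode(out_mask) <- "integer"
  }
  list(image = img, mask = out_mask)
}

rot90ccw <- function(m) {
  if (length(dim(m)) == 2L) return(t(m[, rev(seq_len(ncol(m))), drop = FALSE]))
  out <- array(0, dim = c(ncol(m), nrow(m), dim(m)[3L]))
  for (ch in seq_len(dim(m)[3L])) out[, , ch] <- rot90ccw(m[, , ch])
  out
}

hflip <- function(m) {
  if (length(dim(m)) == 2L) return(m[, rev(seq_len(ncol(m))), drop = FALSE])
  m[, rev(seq_len(ncol(m))), , drop = FALSE]
}

scale_jitter <- function(img, mask, zoom) {
  size <- nrow(if (length(dim(img)) == 3L) img[, , 1L] else img)
  zs <- max(8L, round(size * zoom))
  zi <- resize_bilinear(img, zs, zs)
  zm <- resize_nearest(mask, zs, zs)
  if (zs >= size) {
    off <- (zs - size) %/% 2L
    rows <- off + seq_len(size)
    img <- zi[rows, rows, , drop = FALSE]
    mask <- zm[rows, rows, drop = FALSE]
  } else {
    off <- (size - zs) %/% 2L
    img <- array(1, dim = c(size, size, dim(zi)[3L]))   # white tissue-free pad
    mask <- matrix(0L, size, size)
    img[off + seq_len(zs), off + seq_len(zs), ] <- zi
    mask[off + seq_len(zs), off + seq_len(zs)] <- zm
  }
  list(image = img, mask = mask)
}

#' Paired data augmentation
#'
#' Applies each of 90-degree counter-clockwise rotation, horizontal flip
#' and scale jitter (uniform zoom in `[0.8, 1.2]` followed by center
#' crop/pad back to size) independently with probability `aug_prob`,
#' identically to the image and its mask (nearest-neighbour for the mask).
#' Randomness comes from the current R RNG stream so training runs remain
#' reproducible under a fixed seed.
#'
#' @param image normalized image array `(H, W, 3)`.
#' @param mask binary matrix `(H, W)`.
#' @param aug_prob per-transform probability.
#' @param ops optional character vector to force an exact transform list
#'   (any of `"rot90"`, `"hflip"`, `"scale"`), bypassing randomness; a
#'   forced `"scale"` draws its zoom from the RNG.
#' @return list with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, aug_prob = 0.5, ops = NULL) {
  if (is.null(ops)) {
    draws <- stats::runif(3)
    ops <- c("rot90", "hflip", "scale")[draws < aug_prob]
  }
  if ("rot90" %in% ops) {
    image <- rot90ccw(image)
    mask <- rot90ccw(mask)
  }
  if ("hflip" %in% ops) {
    image <- hflip(image)
    mask <- hflip(mask)
  }
  if ("scale" %in% ops) {
    sj <- scale_jitter(image, mask, stats::runif(1, 0.8, 1.2))
    image <- sj$image
    mask <- sj$mask
  }
  storage.mode(mask) <- "integer"
  list(image = image, mask = mask)
}

#' Learning-rate step decay on validation Dice
#'
#' Multiplies the learning rate by `factor` when the validation Dice has
#' failed to exceed its running best for `patience` consecutive epochs;
#' the non-improvement counter resets on improvement and after a decay.
#'
#' @param history numeric vector of per-epoch validation Dice, oldest
#'   first, up to and including the current epoch.
#' @param lr current learning rate.
#' @param patience consecutive non-improving epochs required.
#' @param factor multiplicative decay.
#' @return the (possibly decayed) learning rate for the next epoch.
#' @export
lr_step <- function(history, lr, patience = 2L, factor = 0.5) {
  if (patience < 1L) stop("patience must be >= 1")
  if (decay_now(history, patience)) lr * factor else lr
}

decay_now <- function(history, patience) {
  best <- -Inf
  counter <- 0L
  trigger <- FALSE
  for (d in history) {
    if (d > best) {
      best <- d
      counter <- 0L
      trigger <- FALSE
    } else {
      counter <- counter + 1L
      trigger <- counter >= patience
      if (trigger) counter <- 0L
    }
  }
  trigger
}

## ---- Adam -------------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    if (is.null(g)) stop("missing gradient for ", k)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

## ---- batch assembly ----------------------------------------------------

load_split_arrays <- function(split_df, dir, size) {
  n <- nrow(split_df)
  imgs <- array(0, dim = c(size, size, 3L, n))
  masks <- array(0L, dim = c(size, size, 1L, n))
  for (i in seq_len(n)) {
    img <- read_image(file.path(dir, split_df$image[i]))
    msk <- read_mask(file.path(dir, split_df$mask[i]))
    pp <- preprocess_patch(img, msk, size)
    imgs[, , , i] <- pp$image
    masks[, , 1L, i] <- pp$mask
  }
  list(images = imgs, masks = masks, ids = split_df$id)
}

batch_dice <- function(gt, pred) {
  # mean per-image pixel Dice at the decision threshold
  n <- dim(gt)[4L]
  vapply(seq_len(n), function(i) {
    pixel_metrics(confusion_counts(gt[, , , i], pred[, , , i]))[["dice"]]
  }, numeric(1))
}

#' Fit the segmentation network
#'
#' The main model-fitting entry point: trains the conv-transformer
#' segmentation network on a synthetic (or compatible) patch dataset with
#' the combined BCE + Dice loss, Adam, per-epoch validation Dice, step
#' learning-rate decay and best-checkpoint tracking. Fully seeded: two runs
#' with the same configuration and seed produce identical loss
#' trajectories.
#'
#' @param manifest dataset manifest: the data.frame returned by
#'   [generate_dataset()] or a path to its `manifest.csv`.
#' @param model_config an [icoseg_config()].
#' @param config a [train_config()].
#' @param dir dataset directory (defaults to the manifest's).
#' @param verbose print one line per epoch to stderr.
#' @return an object of class `icoseg`: the fitted model (best-validation
#'   weights), training `history` (data.frame with epoch, train_loss,
#'   val_dice, lr), the splits, and the configurations. Standard methods
#'   ([predict.icoseg()], `print`, `summary`, `coef`, `plot`) apply.
#' @export
icoseg <- function(manifest, model_config = icoseg_config("small"),
                   config = train_config(input_size =
                                            model_config$input_size),
                   dir = NULL, verbose = TRUE) {
  manifest <- load_manifest(manifest, dir)
  dir <- attr(manifest, "dir")
  if (config$input_size != model_config$input_size)
    stop("train input_size must match the model configuration")

  splits <- split_dataset(manifest, config$split, config$seed)
  if (nrow(splits$train) == 0L || nrow(splits$val) == 0L)
    stop("empty train or validation split")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  model <- icoseg_init(model_config, seed = config$seed)
  tr <- load_split_arrays(splits$train, dir, config$input_size)
  va <- load_split_arrays(splits$val, dir, config$input_size)

  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  lr <- config$lr
  n_tr <- dim(tr$images)[4L]
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric(), lr = numeric())
  best <- list(dice = -Inf, params = model$params, buffers = model$buffers,
               epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    losses <- c()
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      nb <- length(ids)
      xb <- array(0, dim = c(config$input_size, config$input_size, 3L, nb))
      gb <- array(0L, dim = c(config$input_size, config$input_size, 1L, nb))
      for (j in seq_len(nb)) {
        au <- augment_pair(tr$images[, , , ids[j]],
                           tr$masks[, , 1L, ids[j]], config$aug_prob)
        xb[, , , j] <- au$image
        gb[, , 1L, j] <- au$mask
      }
      fw <- icoseg_core_fw(model, xb, training = TRUE)
      model$buffers <- fw$buffers
      lo <- total_loss(gb, fw$y, gamma = config$gamma)
      if (!is.finite(lo$value))
        stop("non-finite training loss at epoch ", epoch,
             " (bce=", lo$components["bce"],
             ", dice=", lo$components["dice"], ")")
      losses <- c(losses, lo$value)
      gy <- total_loss_grad(gb, fw$y, gamma = config$gamma)
      bw <- icoseg_core_bw(model, fw$caches, gy)
      gflat <- flatten_params(bw$grads)
      upd <- adam_step(flat, gflat, opt, lr)
      flat <- upd$flat
      opt <- upd$state
      model$params <- assign_flat(model$params, flat)
    }

    vd <- validation_dice(model, va, config$threshold)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dice = vd, lr = lr))
    if (vd > best$dice)
      best <- list(dice = vd, params = model$params,
                   buffers = model$buffers, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %.2e",
                      epoch, mean(losses), vd, lr))
    lr <- lr_step(history$val_dice, lr, config$patience, config$decay_factor)
  }

  model$params <- best$params
  model$buffers <- best$buffers
  structure(list(params = model$params, buffers = model$buffers,
                 cfg = model_config, train_config = config,
                 history = history, best_epoch = best$epoch,
                 best_val_dice = best$dice, splits = splits,
                 data_dir = dir, n_parameters = count_parameters(model)),
            class = c("icoseg", "icoseg_model"))
}

validation_dice <- function(model, va, threshold, batch = 4L) {
  n <- dim(va$images)[4L]
  dices <- numeric(0)
  for (start in seq(1L, n, by = batch)) {
    ids <- start:min(start + batch - 1L, n)
    y <- icoseg_core_fw(model, va$images[, , , ids, drop = FALSE],
                        training = FALSE, grad = FALSE)$y
    pm <- predict_mask(y, threshold)
    dices <- c(dices, batch_dice(va$masks[, , , ids, drop = FALSE], pm))
  }
  mean(dices)
}

#' Evaluate a fitted model on a test manifest
#'
#' Runs preprocess, forward pass and thresholding over the test patches and
#' scores them against the instance ground truth with [evaluate_pairs()].
#'
#' @param model an `icoseg` fit or `icoseg_model` (e.g. a loaded
#'   checkpoint).
#' @param manifest test manifest (data.frame or path to `manifest.csv`);
#'   defaults to the fit's own test split.
#' @param dir dataset directory.
#' @param threshold probability threshold.
#' @param min_area minimum component area for cell counting.
#' @param predictions optional list of precomputed binary masks (pure
#'   evaluation mode, bypassing the network).
#' @return a [evaluate_pairs()] `metrics_report`.
#' @export
evaluate_model <- function(model, manifest = NULL, dir = NULL,
                           threshold = model$cfg$threshold, min_area = 10L,
                           predictions = NULL) {
  if (is.null(manifest)) {
    if (!inherits(model, "icoseg")) stop("manifest required")
    manifest <- model$splits$test
    dir <- model$data_dir
  }
  manifest <- load_manifest(manifest, dir)
  dir <- attr(manifest, "dir")
  size <- model$cfg$input_size
  pairs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    inst <- read_instance_png(file.path(dir, manifest$instances[i]))
    if (is.null(predictions)) {
      # network mode: score at the network's resolution
      gt <- resize_nearest(inst, size, size)
      storage.mode(gt) <- "integer"
    } else {
      # pure evaluation mode: score at the ground truth's own resolution
      # (resizing can close the one-pixel gap between touching instances)
      gt <- inst
    }
    if (is.null(predictions)) {
      img <- read_image(file.path(dir, manifest$image[i]))
      pp <- preprocess_patch(img, NULL, size)
      x <- array(pp$image, dim = c(size, size, 3L, 1L))
      y <- icoseg_core_fw(structure(list(params = model$params,
                                         buffers = model$buffers,
                                         cfg = model$cfg),
                                    class = "icoseg_model"),
                          x, training = FALSE, grad = FALSE)$y
      pred <- matrix(predict_mask(y, threshold), size, size)
    } else {
      pred <- predictions[[i]]
      if (!identical(dim(pred), dim(gt)))
        pred <- resize_nearest(pred, nrow(gt), ncol(gt))
      pred <- matrix(as.integer(pred > 0), nrow(gt), ncol(gt))
    }
    pairs[[i]] <- list(id = manifest$id[i], gt = gt, pred = pred)
  }
  evaluate_pairs(pairs, min_area = min_area)
}
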