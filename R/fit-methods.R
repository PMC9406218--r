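# S3 methods for fitted models and configurations.

#' @export
print.icoseg_config <- function(x, ...) {
  cat("Segmentation network configuration (preset:", x$preset, ")\n")
  cat("  input", x$input_size, "x", x$input_size,
      " threshold", x$threshold, "\n")
  cat("  encoder: stem", x$stem_channels, "| stages",
      paste(x$stage_channels, collapse = "/"),
      "| transformer dims", paste(x$vit_dims, collapse = "/"),
      "depths", paste(x$vit_depths, collapse = "/"), "\n")
  cat("  bottleneck", x$bottleneck_channels,
      "(channel attention, reduction", paste0(x$se_reduction, ")"),
      "| decoder", paste(x$decoder_channels, collapse = "/"), "\n")
  invisible(x)
}

#' Per-stage shape and parameter table
#'
#' Describes the instantiated network: one row per stage with its output
#' spatial size, channels and trainable-parameter count, plus the total.
#'
#' @param model an `icoseg_model` or [icoseg_config()].
#' @return data.frame with columns `stage`, `out_size`, `channels`,
#'   `parameters`.
#' @export
describe_model <- function(model = icoseg_config()) {
  if (inherits(model, "icoseg_config")) model <- icoseg_init(model, seed = 1L)
  cfg <- model$cfg
  p <- model$params
  np <- function(sub) sum(vapply(flatten_params(sub), length, numeric(1)))
  sz <- cfg$input_size
  sides <- sz / 2^(1:5)
  rows <- data.frame(
    stage = c("stem", "enc1", "enc2", "enc3", "enc4",
              "enc5+attention", paste0("dec", 1:5), "head"),
    out_size = c(sides[1L], sides[1L], sides[2L], sides[3L], sides[4L],
                 sides[5L], rev(sides), sz),
    channels = c(cfg$stem_channels, cfg$stage_channels[1:5],
                 cfg$decoder_channels, 1L),
    parameters = c(np(p$stem), np(p$s1), np(p$s2), np(p$s3), np(p$s4),
                   np(p$s5), vapply(p$decoder, np, numeric(1)), np(p$head)))
  attr(rows, "total") <- sum(rows$parameters)
  rows
}

#' @export
print.icoseg_model <- function(x, ...) {
  print(x$cfg)
  cat(sprintf("  trainable parameters: %s (%.1f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
print.icoseg <- function(x, ...) {
  cat("Fitted ICOS-positive cell segmentation network\n")
  print(x$cfg)
  cat(sprintf("  trainable parameters: %.2f M\n", x$n_parameters / 1e6))
  cat(sprintf("  trained %d epochs on %d patches; best val Dice %.4f (epoch %d)\n",
              nrow(x$history), nrow(x$splits$train), x$best_val_dice,
              x$best_epoch))
  invisible(x)
}

#' @export
summary.icoseg <- function(object, ...) {
  print(object)
  cat("\nPer-stage parameters:\n")
  print(describe_model(object), row.names = FALSE)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.icoseg <- function(object, ...) {
  flatten_params(object$params)
}

#' Predict segmentation masks from a fitted model
#'
#' @param object an `icoseg` fit (or loaded checkpoint model).
#' @param newdata an RGB image array `(H, W, 3)` with values 0--255, a list
#'   of such arrays, or a character vector of PNG paths.
#' @param type `"mask"` for thresholded binary masks, `"prob"` for raw
#'   probability maps.
#' @param threshold probability threshold (default: the model's).
#' @param ... unused.
#' @return a list (one element per input) of `(size, size)` matrices.
#' @export
predict.icoseg <- function(object, newdata, type = c("mask", "prob"),
                           threshold = object$cfg$threshold, ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- lapply(newdata, read_image)
  if (!is.list(newdata)) newdata <- list(newdata)
  size <- object$cfg$input_size
  model <- structure(list(params = object$params, buffers = object$buffers,
                          cfg = object$cfg), class = "icoseg_model")
  lapply(newdata, function(img) {
    pp <- preprocess_patch(img, NULL, size)
    x <- array(pp$image, dim = c(size, size, 3L, 1L))
    y <- icoseg_core_fw(model, x, training = FALSE, grad = FALSE)$y
    out <- matrix(y, size, size)
    if (type == "mask") matrix(predict_mask(out, threshold), size, size)
    else out
  })
}

#' @export
predict.icoseg_model <- function(object, newdata, ...) {
  predict.icoseg(object, newdata, ...)
}

#' @export
plot.icoseg <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss",
                 main = "combined BCE + Dice loss", ...)
  graphics::plot(h$epoch, h$val_dice, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation Dice",
                 main = "validation Dice", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey40")
  invisible(x)
}

## ---- functional block wrappers (single-call API) ----------------------

#' Apply an MV2 (inverted residual) block
#'
#' Point-wise expansion, 3 x 3 depth-wise convolution (optionally strided),
#' point-wise projection, each followed by batch normalization (the last
#' without activation); a residual connection is added when the stride is 1
#' and the channel count is unchanged. Weights are drawn under `seed`
#' unless `params` is supplied.
#'
#' @param x feature map `(H, W, C, N)`.
#' @param out_channels output channels.
#' @param stride 1 or 2.
#' @param expansion expansion ratio (>= 1).
#' @param params optional parameter list from a previous call (attribute
#'   `params` of the result).
#' @param seed weight seed when `params` is missing.
#' @return feature map `(H', W', out_channels, N)` with attribute `params`.
#' @export
mv2_block <- function(x, out_channels, stride = 1L, expansion = 4L,
                      params = NULL, seed = 1L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  x <- as_feature_map(x)
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- mv2_init(dim(x)[3L], as.integer(out_channels),
                       as.integer(stride), as.integer(expansion))
  }
  y <- mv2_fw(params, mv2_buf_init(params), x, training = TRUE)$y
  attr(y, "params") <- params
  y
}

#' Apply a MobileViT (conv + transformer) block
#'
#' Local 3 x 3 convolution, point-wise projection to the transformer
#' dimension, patch unfold, `depth` pre-norm transformer layers applied
#' across patches at each intra-patch position, fold, point-wise projection
#' back, concatenation with the input and a 3 x 3 fusion convolution. The
#' output shape equals the input shape.
#'
#' @inheritParams mv2_block
#' @param dim transformer embedding dimension.
#' @param depth number of transformer layers (0 makes the global path the
#'   identity).
#' @param patch patch size `(ph, pw)`; must divide the spatial dims.
#' @param heads attention heads.
#' @export
mobilevit_block <- function(x, dim, depth, patch = c(2L, 2L), heads = 4L,
                            params = NULL, seed = 1L) {
  x <- as_feature_map(x)
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- mvit_init(base::dim(x)[3L], as.integer(dim), as.integer(depth),
                        as.integer(patch), as.integer(heads))
  }
  y <- mvit_fw(params, mvit_buf_init(params), x, training = TRUE)$y
  attr(y, "params") <- params
  y
}

#' Apply squeeze-and-excitation channel attention
#'
#' Global average pooling per channel, a two-layer bottleneck MLP
#' (`C -> C/reduction -> C`) with ReLU then sigmoid, and per-channel
#' multiplicative gating of the input. Output shape equals input shape.
#'
#' @inheritParams mv2_block
#' @param reduction bottleneck reduction ratio (> 0).
#' @return gated feature map with attributes `params`, `gate` (the
#'   `(N, C)` gate values in `(0, 1)`) and `squeeze` (the pooled means).
#' @export
channel_attention <- function(x, reduction = 16L, params = NULL, seed = 1L) {
  x <- as_feature_map(x)
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- se_init(dim(x)[3L], as.integer(reduction))
  }
  r <- se_fw(params, x)
  y <- r$y
  attr(y, "params") <- params
  attr(y, "gate") <- r$gate
  attr(y, "squeeze") <- r$squeeze
  y
}
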