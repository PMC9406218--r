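# Training losses: binary cross-entropy, Dice (squared-magnitude
# denominator), and their convex combination weighted by gamma.

check_same_shape <- function(gt, p) {
  if (!identical(as.integer(dim_or_len(gt)), as.integer(dim_or_len(p))))
    stop("ground truth and prediction shapes differ")
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Binary cross-entropy loss
#'
#' Mean over all pixels of `-[g log(p) + (1 - g) log(1 - p)]`, with
#' probabilities clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param gt binary ground-truth mask (values in `{0, 1}`).
#' @param p predicted probabilities in `[0, 1]`, same shape as `gt`.
#' @param eps clipping constant for the logarithm (default `1e-7`).
#' @return scalar loss value.
#' @export
bce_loss <- function(gt, p, eps = 1e-7) {
  check_same_shape(gt, p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(gt * log(pc) + (1 - gt) * log(1 - pc))
}

bce_loss_grad <- function(gt, p, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  g <- (-gt / pc + (1 - gt) / (1 - pc)) / length(p)
  g[p < eps | p > 1 - eps] <- 0   # clipped region is flat
  dim(g) <- dim(p)
  g
}

#' Dice loss
#'
#' `1 - (2 * sum(g*p) + s) / (sum(g^2) + sum(p^2) + s)` with smoothing `s`
#' added to numerator and denominator; the squared-magnitude denominator
#' makes the loss differentiable in the soft prediction. Computed per image
#' (4th axis) and averaged over the batch.
#'
#' @inheritParams bce_loss
#' @param smooth smoothing constant `s` (default 1), which also defines the
#'   empty-vs-empty case as a perfect match.
#' @return scalar loss value.
#' @export
dice_loss <- function(gt, p, smooth = 1) {
  check_same_shape(gt, p)
  mean(vapply(per_image(gt, p), function(ab) {
    1 - (2 * sum(ab$g * ab$p) + smooth) /
      (sum(ab$g^2) + sum(ab$p^2) + smooth)
  }, numeric(1)))
}

dice_loss_grad <- function(gt, p, smooth = 1) {
  imgs <- per_image(gt, p)
  gs <- lapply(imgs, function(ab) {
    den <- sum(ab$g^2) + sum(ab$p^2) + smooth
    num <- 2 * sum(ab$g * ab$p) + smooth
    -(2 * ab$g * den - num * 2 * ab$p) / den^2
  })
  g <- unlist(gs) / length(imgs)
  dim(g) <- dim(p)
  g
}

per_image <- function(gt, p) {
  d <- dim(p)
  if (is.null(d) || length(d) < 4L || d[4L] == 1L)
    return(list(list(g = as.vector(gt), p = as.vector(p))))
  lapply(seq_len(d[4L]), function(n)
    list(g = as.vector(gt[, , , n]), p = as.vector(p[, , , n])))
}

#' Combined segmentation training loss
#'
#' The weighted sum `gamma * BCE + (1 - gamma) * Dice` used to train the
#' network; the default weighting is `gamma = 0.4`.
#'
#' @inheritParams bce_loss
#' @param gamma weight of the BCE component, in `[0, 1]`.
#' @param smooth Dice smoothing constant.
#' @return an object of class `icoseg_loss`: a list with `value`, the two
#'   `components` (`bce`, `dice`) and `gamma`.
#' @export
total_loss <- function(gt, p, gamma = 0.4, eps = 1e-7, smooth = 1) {
  if (gamma < 0 || gamma > 1) stop("invalid-config: gamma must be in [0, 1]")
  b <- bce_loss(gt, p, eps)
  d <- dice_loss(gt, p, smooth)
  structure(list(value = gamma * b + (1 - gamma) * d,
                 components = c(bce = b, dice = d), gamma = gamma),
            class = "icoseg_loss")
}

total_loss_grad <- function(gt, p, gamma = 0.4, eps = 1e-7, smooth = 1) {
  gamma * bce_loss_grad(gt, p, eps) +
    (1 - gamma) * dice_loss_grad(gt, p, smooth)
}

#' @export
print.icoseg_loss <- function(x, ...) {
  cat(sprintf("total loss %.6f = %.2f * BCE(%.6f) + %.2f * Dice(%.6f)\n",
              x$value, x$gamma, x$components["bce"], 1 - x$gamma,
              x$components["dice"]))
  invisible(x)
}
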