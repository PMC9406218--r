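# Network assembly: a five-stage conv + MobileViT encoder with a
# squeeze-and-excitation bottleneck, and a five-stage transposed-convolution
# decoder with concatenative skip connections, ending in a sigmoid head.

# parameter-list fields that are structural metadata, not trainable weights
.meta_fields <- c("stride", "cin", "cout", "hid", "d", "patch", "heads",
                  "channels")

#' Network configuration
#'
#' Builds the full channel/depth/patch-size schedule of the segmentation
#' network. The `"reference"` preset is the shipped full-size model: a
#' MobileViT-S style encoder (stem 16; stage widths 32, 64, 96, 128, 160;
#' transformer dims 144/192/240 with depths 2/4/3; point-wise expansion to
#' 640) with channel attention at the bottleneck and decoder widths frozen
#' at (216, 112, 64, 32, 16) so the trainable-parameter total lands at
#' 8.1 M. The `"small"` preset is a scaled-down configuration of the same
#' topology for CPU training experiments and tests.
#'
#' @param preset `"reference"` or `"small"`.
#' @param ... named overrides of individual fields (e.g. `input_size`,
#'   `threshold`, `decoder_channels`).
#' @return an object of class `icoseg_config` (a named list).
#' @export
icoseg_config <- function(preset = c("reference", "small"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    reference = list(
      stem_channels = 16L,
      stage_channels = c(32L, 64L, 96L, 128L, 160L),
      mv2_expansion = 4L,
      vit_dims = c(144L, 192L, 240L),
      vit_depths = c(2L, 4L, 3L),
      vit_patch = c(2L, 2L),
      vit_heads = 4L,
      mlp_ratio = 2L,
      bottleneck_channels = 640L,
      se_reduction = 16L,
      decoder_channels = c(216L, 112L, 64L, 32L, 16L),
      threshold = 0.5,
      input_size = 224L),
    small = list(
      stem_channels = 8L,
      stage_channels = c(16L, 24L, 32L, 48L, 64L),
      mv2_expansion = 2L,
      vit_dims = c(32L, 48L, 64L),
      vit_depths = c(1L, 1L, 1L),
      vit_patch = c(2L, 2L),
      vit_heads = 2L,
      mlp_ratio = 2L,
      bottleneck_channels = 128L,
      se_reduction = 8L,
      decoder_channels = c(64L, 48L, 32L, 24L, 16L),
      threshold = 0.5,
      input_size = 64L))
  over <- list(...)
  cfg[names(over)] <- over
  cfg$preset <- preset
  validate_config(cfg)
  structure(cfg, class = "icoseg_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$stage_channels) == 5L,
            length(cfg$decoder_channels) == 5L,
            length(cfg$vit_dims) == 3L, length(cfg$vit_depths) == 3L)
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (cfg$se_reduction <= 0L) stop("invalid channel-attention reduction")
  if (any(unlist(cfg[c("stem_channels", "stage_channels",
                       "bottleneck_channels", "decoder_channels")]) < 1L))
    stop("invalid-config: non-positive channel count")
  # transformer stages sit at strides 8/16/32; a map that does not tile
  # exactly (e.g. 7x7 at stride 32 for a 224 input) is bilinearly resized
  # inside the block, so only require at least one pixel per stage
  if (cfg$input_size %% 32L != 0L || cfg$input_size < 32L)
    stop("input_size must be a positive multiple of 32")
  invisible(cfg)
}

#' Instantiate the network
#'
#' Draws all trainable weights (Kaiming-normal convolutions,
#' truncated-normal transformer weights, unit-gamma normalizations) under a
#' fixed seed and returns the model object used by [icoseg_forward()] and
#' the training engine.
#'
#' @param cfg an [icoseg_config()].
#' @param seed integer seed for weight initialization.
#' @return a list with elements `params`, `buffers` (normalization running
#'   statistics) and `cfg`, of class `icoseg_model`.
#' @export
icoseg_init <- function(cfg = icoseg_config(), seed = 1L) {
  validate_config(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sc <- cfg$stage_channels
  e <- cfg$mv2_expansion
  p <- list(
    stem = list(conv = kaiming_conv(3L, 3L, cfg$stem_channels),
                bn = bn_init(cfg$stem_channels)),
    s1 = mv2_init(cfg$stem_channels, sc[1L], 1L, e),
    s2 = list(mv2_init(sc[1L], sc[2L], 2L, e),
              mv2_init(sc[2L], sc[2L], 1L, e),
              mv2_init(sc[2L], sc[2L], 1L, e)),
    s3 = list(mv2 = mv2_init(sc[2L], sc[3L], 2L, e),
              vit = mvit_init(sc[3L], cfg$vit_dims[1L], cfg$vit_depths[1L],
                              cfg$vit_patch, cfg$vit_heads, cfg$mlp_ratio)),
    s4 = list(mv2 = mv2_init(sc[3L], sc[4L], 2L, e),
              vit = mvit_init(sc[4L], cfg$vit_dims[2L], cfg$vit_depths[2L],
                              cfg$vit_patch, cfg$vit_heads, cfg$mlp_ratio)),
    s5 = list(mv2 = mv2_init(sc[4L], sc[5L], 2L, e),
              vit = mvit_init(sc[5L], cfg$vit_dims[3L], cfg$vit_depths[3L],
                              cfg$vit_patch, cfg$vit_heads, cfg$mlp_ratio),
              expand = matrix(stats::rnorm(sc[5L] * cfg$bottleneck_channels,
                                           sd = sqrt(2 / sc[5L])),
                              sc[5L], cfg$bottleneck_channels),
              bn = bn_init(cfg$bottleneck_channels),
              se = se_init(cfg$bottleneck_channels, cfg$se_reduction)))
  dc <- cfg$decoder_channels
  din <- c(cfg$bottleneck_channels,
           dc[1L] + sc[4L], dc[2L] + sc[3L], dc[3L] + sc[2L],
           dc[4L] + sc[1L] + cfg$stem_channels)
  p$decoder <- lapply(1:5, function(i) {
    fan <- 16L * din[i]
    list(w = array(stats::rnorm(16L * dc[i] * din[i], sd = sqrt(2 / fan)),
                   dim = c(4L, 4L, dc[i], din[i])),
         bn = bn_init(dc[i]))
  })
  p$head <- list(w = matrix(stats::rnorm(dc[5L], sd = sqrt(2 / dc[5L])),
                            dc[5L], 1L),
                 b = 0)
  b <- list(
    stem = bn_buf_init(cfg$stem_channels),
    s1 = mv2_buf_init(p$s1),
    s2 = lapply(p$s2, mv2_buf_init),
    s3 = list(mv2 = mv2_buf_init(p$s3$mv2), vit = mvit_buf_init(p$s3$vit)),
    s4 = list(mv2 = mv2_buf_init(p$s4$mv2), vit = mvit_buf_init(p$s4$vit)),
    s5 = list(mv2 = mv2_buf_init(p$s5$mv2), vit = mvit_buf_init(p$s5$vit),
              bn = bn_buf_init(cfg$bottleneck_channels)),
    decoder = lapply(dc, bn_buf_init))
  structure(list(params = p, buffers = b, cfg = cfg, seed = seed),
            class = "icoseg_model")
}

# full forward pass; returns caches only when training/grad is requested
icoseg_core_fw <- function(model, x, training = FALSE, grad = training) {
  p <- model$params; b <- model$buffers
  cc <- if (grad) list() else NULL
  keep <- function(name, cache) if (grad) cc[[name]] <<- cache

  st <- conv_fw(p$stem$conv, x, stride = 2L, pad = 1L)
  sb <- bn_fw(p$stem$bn, b$stem, st$y, training)
  sa <- silu_fw(sb$y)
  b$stem <- sb$buf
  keep("stem", list(conv = st$cache, bn = sb$cache, act = sa$cache))

  r1 <- mv2_fw(p$s1, b$s1, sa$y, training); b$s1 <- r1$buf
  keep("s1", r1$cache)
  f1 <- r1$y

  x2 <- f1
  c2 <- vector("list", 3L)
  for (i in 1:3) {
    r <- mv2_fw(p$s2[[i]], b$s2[[i]], x2, training)
    b$s2[[i]] <- r$buf; x2 <- r$y; c2[[i]] <- r$cache
  }
  keep("s2", c2)
  f2 <- x2

  r3m <- mv2_fw(p$s3$mv2, b$s3$mv2, f2, training); b$s3$mv2 <- r3m$buf
  r3v <- mvit_fw(p$s3$vit, b$s3$vit, r3m$y, training); b$s3$vit <- r3v$buf
  keep("s3", list(mv2 = r3m$cache, vit = r3v$cache))
  f3 <- r3v$y

  r4m <- mv2_fw(p$s4$mv2, b$s4$mv2, f3, training); b$s4$mv2 <- r4m$buf
  r4v <- mvit_fw(p$s4$vit, b$s4$vit, r4m$y, training); b$s4$vit <- r4v$buf
  keep("s4", list(mv2 = r4m$cache, vit = r4v$cache))
  f4 <- r4v$y

  r5m <- mv2_fw(p$s5$mv2, b$s5$mv2, f4, training); b$s5$mv2 <- r5m$buf
  r5v <- mvit_fw(p$s5$vit, b$s5$vit, r5m$y, training); b$s5$vit <- r5v$buf
  ex <- pwconv_fw(p$s5$expand, r5v$y)
  eb <- bn_fw(p$s5$bn, b$s5$bn, ex$y, training); b$s5$bn <- eb$buf
  ea <- silu_fw(eb$y)
  se <- se_fw(p$s5$se, ea$y)
  keep("s5", list(mv2 = r5m$cache, vit = r5v$cache, ex = ex$cache,
                  bn = eb$cache, act = ea$cache, se = se$cache))
  f5 <- se$y

  skips <- list(NULL, f4, f3, f2, NULL)
  dcc <- vector("list", 5L)
  dx <- f5
  for (i in 1:5) {
    din <- dx
    if (i == 5L) din <- abind_ch(abind_ch(dx, f1), sa$y)
    else if (!is.null(skips[[i]])) din <- abind_ch(dx, skips[[i]])
    dv <- convt_fw(p$decoder[[i]]$w, din)
    db <- bn_fw(p$decoder[[i]]$bn, b$decoder[[i]], dv$y, training)
    b$decoder[[i]] <- db$buf
    da <- relu_fw(db$y)
    dcc[[i]] <- list(deconv = dv$cache, bn = db$cache, act = da$cache,
                     cin_main = dim(dx)[3L])
    dx <- da$y
  }
  keep("decoder", dcc)
  keep("decoder_stem_ch", dim(sa$y)[3L])

  hd <- pwconv_fw(p$head$w, dx, bias = p$head$b)
  sg <- sigmoid_fw(hd$y)
  keep("head", list(pw = hd$cache, sg = sg$cache))

  feats <- list(stem = dim(sa$y), s1 = dim(f1), s2 = dim(f2), s3 = dim(f3),
                s4 = dim(f4), s5 = dim(f5))
  list(y = sg$y, buffers = b, caches = cc, feat_dims = feats)
}

icoseg_core_bw <- function(model, caches, gy) {
  p <- model$params
  g <- list()

  gh <- sigmoid_bw(caches$head$sg, gy)
  ghd <- pwconv_bw(p$head$w, caches$head$pw, gh, bias = TRUE)
  g$head <- list(w = ghd$gw, b = ghd$gb)
  gd <- ghd$gx

  gskip <- list()
  g$decoder <- vector("list", 5L)
  for (i in 5:1) {
    dc <- caches$decoder[[i]]
    ga <- relu_bw(dc$act, gd)
    gb <- bn_bw(p$decoder[[i]]$bn, dc$bn, ga)
    gv <- convt_bw(p$decoder[[i]]$w, dc$deconv, gb$gx)
    g$decoder[[i]] <- list(w = gv$gw,
                           bn = list(gamma = gb$ggamma, beta = gb$gbeta))
    gin <- gv$gx
    cm <- dc$cin_main
    if (i == 5L) {
      sp <- split_ch(gin, cm)
      c1 <- dim(sp$b)[3L] - caches$decoder_stem_ch
      sp2 <- split_ch(sp$b, c1)
      gskip$s1 <- sp2$a; gskip$stem <- sp2$b
      gd <- sp$a
    } else if (i %in% 2:4) {
      sp <- split_ch(gin, cm)
      gskip[[c("", "s4", "s3", "s2")[i]]] <- sp$b
      gd <- sp$a
    } else {
      gd <- gin
    }
  }
  gf5 <- gd

  s5 <- caches$s5
  gse <- se_bw(p$s5$se, s5$se, gf5)
  gea <- silu_bw(s5$act, gse$gx)
  geb <- bn_bw(p$s5$bn, s5$bn, gea)
  gex <- pwconv_bw(p$s5$expand, s5$ex, geb$gx)
  g5v <- mvit_bw(p$s5$vit, s5$vit, gex$gx)
  g5m <- mv2_bw(p$s5$mv2, s5$mv2, g5v$gx)
  g$s5 <- list(mv2 = g5m$grads, vit = g5v$grads, expand = gex$gw,
               bn = list(gamma = geb$ggamma, beta = geb$gbeta),
               se = gse$grads)

  gf4 <- g5m$gx + gskip$s4
  g4v <- mvit_bw(p$s4$vit, caches$s4$vit, gf4)
  g4m <- mv2_bw(p$s4$mv2, caches$s4$mv2, g4v$gx)
  g$s4 <- list(mv2 = g4m$grads, vit = g4v$grads)

  gf3 <- g4m$gx + gskip$s3
  g3v <- mvit_bw(p$s3$vit, caches$s3$vit, gf3)
  g3m <- mv2_bw(p$s3$mv2, caches$s3$mv2, g3v$gx)
  g$s3 <- list(mv2 = g3m$grads, vit = g3v$grads)

  gf2 <- g3m$gx + gskip$s2
  g$s2 <- vector("list", 3L)
  gx2 <- gf2
  for (i in 3:1) {
    r <- mv2_bw(p$s2[[i]], caches$s2[[i]], gx2)
    g$s2[[i]] <- r$grads
    gx2 <- r$gx
  }

  gf1 <- gx2 + gskip$s1
  r1 <- mv2_bw(p$s1, caches$s1, gf1)
  g$s1 <- r1$grads

  gstem <- r1$gx + gskip$stem
  gsa <- silu_bw(caches$stem$act, gstem)
  gsb <- bn_bw(p$stem$bn, caches$stem$bn, gsa)
  gsc <- conv_bw(p$stem$conv, caches$stem$conv, gsb$gx)
  g$stem <- list(conv = gsc$gw,
                 bn = list(gamma = gsb$ggamma, beta = gsb$gbeta))
  list(grads = g, gx = gsc$gx)
}

#' Run the network on normalized patches
#'
#' @param x numeric array: `(H, W, 3)` or `(H, W, 3, N)` with values in
#'   `[0, 1]` and `H = W = cfg$input_size`.
#' @param model an `icoseg_model` (see [icoseg_init()]); a freshly
#'   initialized reference model is built if omitted.
#' @return per-pixel positive-cell probability map(s), array
#'   `(H, W, 1, N)` with all values in `[0, 1]`.
#' @export
icoseg_forward <- function(x, model = icoseg_init()) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  sz <- model$cfg$input_size
  if (d[1L] != sz || d[2L] != sz || d[3L] != 3L)
    stop("input must be (", sz, ", ", sz, ", 3[, N]) for this configuration")
  if (min(x) < 0 || max(x) > 1)
    stop("input values must be normalized to [0, 1]")
  icoseg_core_fw(model, x, training = FALSE, grad = FALSE)$y
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to `threshold` become
#' foreground; ties are assigned to foreground.
#'
#' @param p numeric array of probabilities in `[0, 1]`.
#' @param threshold decision threshold in `(0, 1)`; default 0.5.
#' @return integer array of the same shape with values in `{0, 1}`.
#' @export
predict_mask <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  m <- as.integer(p >= threshold)
  dim(m) <- dim(p)
  m
}

## ---- parameter bookkeeping --------------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    if (nm %in% .meta_fields) next
    v <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else if (is.numeric(v)) out[[key]] <- v
  }
  if (is.null(names(p)) && length(p)) {  # unnamed list (stages, layers)
    for (i in seq_along(p)) {
      key <- paste0(prefix, "[", i, "]")
      v <- p[[i]]
      if (is.list(v)) out <- c(out, flatten_params(v, key))
      else if (is.numeric(v)) out[[key]] <- v
    }
  }
  out
}

assign_flat <- function(p, flat) {
  i <- 0L
  walk <- function(node) {
    if (is.list(node)) {
      nms <- names(node)
      for (j in seq_along(node)) {
        if (!is.null(nms) && nms[j] %in% .meta_fields) next
        node[[j]] <- walk(node[[j]])
      }
      node
    } else if (is.numeric(node)) {
      i <<- i + 1L
      v <- flat[[i]]
      dim(v) <- dim(node)
      v
    } else node
  }
  out <- walk(p)
  stopifnot(i == length(flat))
  out
}

#' Count trainable parameters
#'
#' Enumerates every trainable weight array of the instantiated network and
#' sums their element counts. For the reference configuration this totals
#' 8.1 million.
#'
#' @param model an `icoseg_model` or an [icoseg_config()] (which is then
#'   instantiated).
#' @return integer: number of trainable scalars.
#' @export
count_parameters <- function(model = icoseg_config()) {
  if (inherits(model, "icoseg_config")) model <- icoseg_init(model, seed = 1L)
  sum(vapply(flatten_params(model$params), length, numeric(1)))
}

## ---- checkpoints -------------------------------------------------------

# tiny FNV-1a hash so checkpoints can refuse a mismatched configuration
config_hash <- function(cfg) {
  raw <- serialize(cfg[order(names(cfg))], NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized file holding the weights, the
#' normalization running statistics, the full configuration plus its hash,
#' and any training metadata. [load_checkpoint()] refuses a file whose
#' stored configuration no longer matches its own hash.
#'
#' @param model an `icoseg_model`.
#' @param path file path.
#' @param meta optional list of training metadata stored alongside.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `icoseg_model` with a `meta` attribute.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  obj <- list(params = model$params, buffers = model$buffers,
              cfg = unclass(model$cfg), cfg_hash = config_hash(model$cfg),
              meta = meta, format = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$cfg, class = "icoseg_config")
  if (!identical(config_hash(cfg), obj$cfg_hash))
    stop("checkpoint refused: configuration hash mismatch")
  model <- structure(list(params = obj$params, buffers = obj$buffers,
                          cfg = cfg), class = "icoseg_model")
  attr(model, "meta") <- obj$meta
  model
}

## ---- RNG bookkeeping ---------------------------------------------------

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
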