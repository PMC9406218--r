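# Low-level neural-network primitives: every op has a forward returning
# (y, cache) and a backward mapping the upstream gradient to input/parameter
# gradients. Feature maps are column-major arrays of dim (H, W, C, N).

#' @useDynLib icoseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("feature maps must be 4-d arrays (H, W, C, N)")
  storage.mode(x) <- "double"
  x
}

# reshape (H,W,C,N) -> matrix (H*W*N, C) with channels in columns
chan_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

chan_unmat <- function(m, d_out) {
  dim(m) <- c(d_out[1L], d_out[2L], d_out[4L], d_out[3L])
  aperm(m, c(1L, 2L, 4L, 3L))
}

## ---- convolutions -----------------------------------------------------

conv_fw <- function(w, x, stride = 1L, pad = 0L, groups = 1L) {
  y <- conv2d_fw_cpp(x, w, as.integer(stride), as.integer(pad),
                     as.integer(groups))
  list(y = y, cache = list(x = x, stride = stride, pad = pad,
                           groups = groups))
}

conv_bw <- function(w, cache, gy) {
  d <- dim(cache$x)
  gx <- conv2d_bwin_cpp(gy, w, d[1L], d[2L], as.integer(cache$stride),
                        as.integer(cache$pad), as.integer(cache$groups))
  gw <- conv2d_bww_cpp(cache$x, gy, dim(w)[1L], as.integer(cache$stride),
                       as.integer(cache$pad), as.integer(cache$groups))
  list(gx = gx, gw = gw)
}

# Transposed convolution (x2 upsampling with k = 4, stride = 2, pad = 1).
# Weight layout (k, k, Cout, Cin): the op is the adjoint of a forward
# convolution with that weight.
convt_fw <- function(w, x, stride = 2L, pad = 1L) {
  d <- dim(x); k <- dim(w)[1L]
  hout <- (d[1L] - 1L) * stride - 2L * pad + k
  wout <- (d[2L] - 1L) * stride - 2L * pad + k
  y <- conv2d_bwin_cpp(x, w, as.integer(hout), as.integer(wout),
                       as.integer(stride), as.integer(pad), 1L)
  list(y = y, cache = list(x = x, stride = stride, pad = pad))
}

convt_bw <- function(w, cache, gy) {
  gx <- conv2d_fw_cpp(gy, w, as.integer(cache$stride),
                      as.integer(cache$pad), 1L)
  gw <- conv2d_bww_cpp(gy, cache$x, dim(w)[1L], as.integer(cache$stride),
                       as.integer(cache$pad), 1L)
  list(gx = gx, gw = gw)
}

# 1x1 convolution as a channel-space matrix product; w is (Cin, Cout).
pwconv_fw <- function(w, x, bias = NULL) {
  d <- dim(x)
  m <- chan_mat(x)
  y <- m %*% w
  if (!is.null(bias)) y <- sweep(y, 2L, bias, "+")
  list(y = chan_unmat(y, c(d[1L], d[2L], ncol(w), d[4L])),
       cache = list(m = m, d = d))
}

pwconv_bw <- function(w, cache, gy, bias = FALSE) {
  d <- cache$d
  gm <- chan_mat(gy)
  gx <- chan_unmat(gm %*% t(w), d)
  out <- list(gx = gx, gw = crossprod(cache$m, gm))
  if (bias) out$gb <- colSums(gm)
  out
}

## ---- activations ------------------------------------------------------

silu_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}

silu_bw <- function(cache, gy) {
  s <- cache$s
  gy * (s * (1 + cache$x * (1 - s)))
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = list(pos = x > 0))

relu_bw <- function(cache, gy) gy * cache$pos

sigmoid_fw <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = list(y = y))
}

sigmoid_bw <- function(cache, gy) gy * cache$y * (1 - cache$y)

## ---- batch normalization ----------------------------------------------

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels))
}

bn_buf_init <- function(channels) {
  list(mean = rep(0, channels), var = rep(1, channels))
}

bn_fw <- function(p, buf, x, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- chan_mat(x)
  n <- nrow(m)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu, "-")
    v <- colMeans(xc * xc)
    if (n > 1L) {
      buf$mean <- (1 - momentum) * buf$mean + momentum * mu
      buf$var <- (1 - momentum) * buf$var + momentum * v * n / (n - 1L)
    }
  } else {
    mu <- buf$mean
    v <- buf$var
    xc <- sweep(m, 2L, mu, "-")
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = chan_unmat(y, d), buf = buf,
       cache = list(xhat = xhat, inv = inv, d = d, training = training))
}

bn_bw <- function(p, cache, gy) {
  d <- cache$d
  gm <- chan_mat(gy)
  xhat <- cache$xhat
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  gxhat <- sweep(gm, 2L, p$gamma, "*")
  if (cache$training) {
    n <- nrow(gm)
    t1 <- sweep(gxhat, 2L, colMeans(gxhat), "-")
    t2 <- sweep(xhat, 2L, colSums(gxhat * xhat) / n, "*")
    gx <- sweep(t1 - t2, 2L, cache$inv, "*")
  } else {
    gx <- sweep(gxhat, 2L, cache$inv, "*")
  }
  list(gx = chan_unmat(gx, d), ggamma = ggamma, gbeta = gbeta)
}

## ---- layer normalization (tokens in rows) -----------------------------

ln_init <- function(dimension) {
  list(gamma = rep(1, dimension), beta = rep(0, dimension))
}

ln_fw <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

ln_bw <- function(p, cache, gy) {
  xhat <- cache$xhat
  ggamma <- colSums(gy * xhat)
  gbeta <- colSums(gy)
  gxhat <- sweep(gy, 2L, p$gamma, "*")
  gx <- (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat)) * cache$inv
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## ---- dense layer (tokens in rows) -------------------------------------

linear_init <- function(din, dout, rng_sd = 0.02) {
  w <- matrix(trunc_normal(din * dout, sd = rng_sd), din, dout)
  list(w = w, b = rep(0, dout))
}

linear_fw <- function(p, x) {
  list(y = sweep(x %*% p$w, 2L, p$b, "+"), cache = list(x = x))
}

linear_bw <- function(p, cache, gy) {
  list(gx = gy %*% t(p$w), gw = crossprod(cache$x, gy), gb = colSums(gy))
}

## ---- multi-head self-attention over one sequence ----------------------

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# x: (T, d) tokens; heads: number of attention heads
mhsa_fw <- function(p, x, heads) {
  d <- ncol(x)
  dh <- d %/% heads
  qkv <- sweep(x %*% p$wqkv, 2L, p$bqkv, "+")
  heads_cache <- vector("list", heads)
  o <- matrix(0, nrow(x), d)
  scale <- 1 / sqrt(dh)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    q <- qkv[, idx, drop = FALSE]
    k <- qkv[, d + idx, drop = FALSE]
    v <- qkv[, 2L * d + idx, drop = FALSE]
    a <- softmax_rows(tcrossprod(q, k) * scale)
    o[, idx] <- a %*% v
    heads_cache[[h]] <- list(q = q, k = k, v = v, a = a)
  }
  y <- sweep(o %*% p$wo, 2L, p$bo, "+")
  list(y = y, cache = list(x = x, qkv = qkv, o = o, heads = heads_cache,
                           scale = scale, dh = dh))
}

mhsa_bw <- function(p, cache, gy) {
  x <- cache$x
  d <- ncol(x)
  dh <- cache$dh
  go <- gy %*% t(p$wo)
  gwo <- crossprod(cache$o, gy)
  gbo <- colSums(gy)
  gqkv <- matrix(0, nrow(x), 3L * d)
  for (h in seq_along(cache$heads)) {
    hc <- cache$heads[[h]]
    idx <- (h - 1L) * dh + seq_len(dh)
    goh <- go[, idx, drop = FALSE]
    ga <- tcrossprod(goh, hc$v)
    gv <- crossprod(hc$a, goh)
    # softmax backward per row
    gs <- (ga - rowSums(ga * hc$a)) * hc$a
    gq <- (gs %*% hc$k) * cache$scale
    gk <- crossprod(gs, hc$q) * cache$scale
    gqkv[, idx] <- gq
    gqkv[, d + idx] <- gk
    gqkv[, 2L * d + idx] <- gv
  }
  gx <- gqkv %*% t(p$wqkv)
  list(gx = gx, gwqkv = crossprod(x, gqkv), gbqkv = colSums(gqkv),
       gwo = gwo, gbo = gbo)
}

## ---- differentiable bilinear resize -----------------------------------

# interpolation matrix (out x in), half-pixel-center convention
bilinear_matrix <- function(n_out, n_in) {
  a <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    lo <- floor(src)
    fr <- src - lo
    l <- min(max(lo + 1, 1), n_in)
    r <- min(max(lo + 2, 1), n_in)
    a[i, l] <- a[i, l] + (1 - fr)
    a[i, r] <- a[i, r] + fr
  }
  a
}

# y[,,c,n] = A %*% x[,,c,n] %*% t(B); its exact adjoint uses t(A), t(B)
resize_map_apply <- function(x, a, b) {
  d <- dim(x)
  m <- a %*% matrix(x, d[1L], d[2L] * d[3L] * d[4L])
  ho <- nrow(a)
  dim(m) <- c(ho, d[2L], d[3L], d[4L])
  m <- aperm(m, c(2L, 1L, 3L, 4L))
  m2 <- b %*% matrix(m, d[2L], ho * d[3L] * d[4L])
  dim(m2) <- c(nrow(b), ho, d[3L], d[4L])
  aperm(m2, c(2L, 1L, 3L, 4L))
}

resize_map_fw <- function(x, hout, wout) {
  d <- dim(x)
  a <- bilinear_matrix(hout, d[1L])
  b <- bilinear_matrix(wout, d[2L])
  list(y = resize_map_apply(x, a, b), cache = list(a = a, b = b))
}

resize_map_bw <- function(cache, gy) {
  resize_map_apply(gy, t(cache$a), t(cache$b))
}

## ---- initializers -----------------------------------------------------

trunc_normal <- function(n, sd = 0.02, bound = 2) {
  x <- stats::rnorm(n, sd = sd)
  out <- abs(x) > bound * sd
  while (any(out)) {
    x[out] <- stats::rnorm(sum(out), sd = sd)
    out <- abs(x) > bound * sd
  }
  x
}

kaiming_conv <- function(k, cin_g, cout) {
  fan_in <- k * k * cin_g
  array(stats::rnorm(k * k * cin_g * cout, sd = sqrt(2 / fan_in)),
        dim = c(k, k, cin_g, cout))
}
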