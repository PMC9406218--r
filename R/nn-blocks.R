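# Composite blocks of the encoder: MobileNetV2 inverted residuals, the
# MobileViT conv+transformer block, and squeeze-and-excitation channel
# attention. Each block has *_init (parameters), *_fw (returns y, cache and
# updated normalization buffers) and *_bw (returns gx and a gradient list
# mirroring the parameter list).

## ---- MV2 inverted residual --------------------------------------------

mv2_init <- function(cin, cout, stride, expansion) {
  if (cin < 1L || cout < 1L || expansion < 1L)
    stop("invalid MV2 configuration: non-positive channels/expansion")
  hid <- cin * expansion
  list(pw1 = matrix(stats::rnorm(cin * hid, sd = sqrt(2 / cin)), cin, hid),
       bn1 = bn_init(hid),
       dw = kaiming_conv(3L, 1L, hid),
       bn2 = bn_init(hid),
       pw2 = matrix(stats::rnorm(hid * cout, sd = sqrt(2 / hid)), hid, cout),
       bn3 = bn_init(cout),
       stride = stride, cin = cin, cout = cout, hid = hid)
}

mv2_buf_init <- function(p) {
  list(bn1 = bn_buf_init(p$hid), bn2 = bn_buf_init(p$hid),
       bn3 = bn_buf_init(p$cout))
}

mv2_fw <- function(p, buf, x, training) {
  f1 <- pwconv_fw(p$pw1, x)
  b1 <- bn_fw(p$bn1, buf$bn1, f1$y, training)
  a1 <- silu_fw(b1$y)
  f2 <- conv_fw(p$dw, a1$y, stride = p$stride, pad = 1L, groups = p$hid)
  b2 <- bn_fw(p$bn2, buf$bn2, f2$y, training)
  a2 <- silu_fw(b2$y)
  f3 <- pwconv_fw(p$pw2, a2$y)
  b3 <- bn_fw(p$bn3, buf$bn3, f3$y, training)
  res <- p$stride == 1L && p$cin == p$cout
  y <- if (res) b3$y + x else b3$y
  buf$bn1 <- b1$buf; buf$bn2 <- b2$buf; buf$bn3 <- b3$buf
  list(y = y, buf = buf,
       cache = list(f1 = f1$cache, b1 = b1$cache, a1 = a1$cache,
                    f2 = f2$cache, b2 = b2$cache, a2 = a2$cache,
                    f3 = f3$cache, b3 = b3$cache, res = res))
}

mv2_bw <- function(p, cache, gy) {
  g3 <- bn_bw(p$bn3, cache$b3, gy)
  gf3 <- pwconv_bw(p$pw2, cache$f3, g3$gx)
  ga2 <- silu_bw(cache$a2, gf3$gx)
  g2 <- bn_bw(p$bn2, cache$b2, ga2)
  gf2 <- conv_bw(p$dw, cache$f2, g2$gx)
  ga1 <- silu_bw(cache$a1, gf2$gx)
  g1 <- bn_bw(p$bn1, cache$b1, ga1)
  gf1 <- pwconv_bw(p$pw1, cache$f1, g1$gx)
  gx <- if (cache$res) gf1$gx + gy else gf1$gx
  list(gx = gx,
       grads = list(pw1 = gf1$gw,
                    bn1 = list(gamma = g1$ggamma, beta = g1$gbeta),
                    dw = gf2$gw,
                    bn2 = list(gamma = g2$ggamma, beta = g2$gbeta),
                    pw2 = gf3$gw,
                    bn3 = list(gamma = g3$ggamma, beta = g3$gbeta)))
}

## ---- transformer encoder layer ----------------------------------------

txl_init <- function(d, mlp_ratio = 2L) {
  dm <- d * mlp_ratio
  list(ln1 = ln_init(d),
       attn = list(wqkv = matrix(trunc_normal(d * 3L * d), d, 3L * d),
                   bqkv = rep(0, 3L * d),
                   wo = matrix(trunc_normal(d * d), d, d),
                   bo = rep(0, d)),
       ln2 = ln_init(d),
       fc1 = linear_init(d, dm),
       fc2 = linear_init(dm, d))
}

# tokens: matrix (n_tokens, d); seqs: list of row-index vectors, one per
# attention sequence (attention mixes tokens only within a sequence).
txl_fw <- function(p, tokens, seqs, heads) {
  l1 <- ln_fw(p$ln1, tokens)
  att <- vector("list", length(seqs))
  a_out <- tokens
  for (s in seq_along(seqs)) {
    r <- mhsa_fw(p$attn, l1$y[seqs[[s]], , drop = FALSE], heads)
    a_out[seqs[[s]], ] <- r$y
    att[[s]] <- r$cache
  }
  x1 <- tokens + a_out
  l2 <- ln_fw(p$ln2, x1)
  m1 <- linear_fw(p$fc1, l2$y)
  ms <- silu_fw(m1$y)
  m2 <- linear_fw(p$fc2, ms$y)
  y <- x1 + m2$y
  list(y = y, cache = list(l1 = l1$cache, att = att, l2 = l2$cache,
                           m1 = m1$cache, ms = ms$cache, m2 = m2$cache,
                           seqs = seqs))
}

txl_bw <- function(p, cache, gy, heads) {
  gm2 <- linear_bw(p$fc2, cache$m2, gy)
  gms <- silu_bw(cache$ms, gm2$gx)
  gm1 <- linear_bw(p$fc1, cache$m1, gms)
  gl2 <- ln_bw(p$ln2, cache$l2, gm1$gx)
  gx1 <- gy + gl2$gx
  ga <- gx1
  gl1y <- gx1 * 0
  gattn <- NULL
  for (s in seq_along(cache$seqs)) {
    r <- mhsa_bw(p$attn, cache$att[[s]], ga[cache$seqs[[s]], , drop = FALSE])
    gl1y[cache$seqs[[s]], ] <- r$gx
    gs <- list(wqkv = r$gwqkv, bqkv = r$gbqkv, wo = r$gwo, bo = r$gbo)
    gattn <- if (is.null(gattn)) gs else Map(`+`, gattn, gs)
  }
  gl1 <- ln_bw(p$ln1, cache$l1, gl1y)
  gx <- gx1 + gl1$gx
  list(gx = gx,
       grads = list(ln1 = list(gamma = gl1$ggamma, beta = gl1$gbeta),
                    attn = gattn,
                    ln2 = list(gamma = gl2$ggamma, beta = gl2$gbeta),
                    fc1 = list(w = gm1$gw, b = gm1$gb),
                    fc2 = list(w = gm2$gw, b = gm2$gb)))
}

## ---- MobileViT block ---------------------------------------------------

mvit_init <- function(cin, d, depth, patch = c(2L, 2L), heads = 4L,
                      mlp_ratio = 2L) {
  list(conv3 = kaiming_conv(3L, cin, cin),
       bnl = bn_init(cin),
       pwin = matrix(stats::rnorm(cin * d, sd = sqrt(2 / cin)), cin, d),
       layers = lapply(seq_len(depth), function(i) txl_init(d, mlp_ratio)),
       lnf = ln_init(d),
       pwout = matrix(stats::rnorm(d * cin, sd = sqrt(2 / d)), d, cin),
       bno = bn_init(cin),
       fuse = kaiming_conv(3L, 2L * cin, cin),
       bnf = bn_init(cin),
       d = d, cin = cin, patch = as.integer(patch), heads = heads)
}

mvit_buf_init <- function(p) {
  list(bnl = bn_buf_init(p$cin), bno = bn_buf_init(p$cin),
       bnf = bn_buf_init(p$cin))
}

# map unfolded (P, Np, d, N) to token matrix (P*Np*N, d) + sequence indices
tokens_of_unfold <- function(u) {
  du <- dim(u)
  tk <- aperm(u, c(1L, 2L, 4L, 3L))
  dim(tk) <- c(du[1L] * du[2L] * du[4L], du[3L])
  tk
}

unfold_of_tokens <- function(tk, du) {
  dim(tk) <- c(du[1L], du[2L], du[4L], du[3L])
  aperm(tk, c(1L, 2L, 4L, 3L))
}

attn_seqs <- function(P, np, n) {
  out <- vector("list", P * n)
  i <- 1L
  for (b in seq_len(n)) {
    base <- (b - 1L) * P * np
    for (p in seq_len(P)) {
      out[[i]] <- base + p + P * (seq_len(np) - 1L)
      i <- i + 1L
    }
  }
  out
}

mvit_fw <- function(p, buf, x, training) {
  f1 <- conv_fw(p$conv3, x, stride = 1L, pad = 1L)
  b1 <- bn_fw(p$bnl, buf$bnl, f1$y, training)
  a1 <- silu_fw(b1$y)
  pin <- pwconv_fw(p$pwin, a1$y)
  # when the map does not tile exactly (e.g. 7x7 with a 2x2 patch at the
  # bottleneck of a 224 input) it is bilinearly resized to the next multiple
  # around the transformer, as in the source architecture
  dp <- dim(pin$y)
  need <- ceiling(dp[1:2] / p$patch) * p$patch
  rs <- NULL
  pin_y <- pin$y
  if (any(need != dp[1:2])) {
    rs <- resize_map_fw(pin$y, need[1L], need[2L])
    pin_y <- rs$y
  }
  u <- unfold_patches(pin_y, p$patch)
  du <- dim(u)
  tk <- tokens_of_unfold(u)
  seqs <- attn_seqs(du[1L], du[2L], du[4L])
  lcaches <- vector("list", length(p$layers))
  for (i in seq_along(p$layers)) {
    r <- txl_fw(p$layers[[i]], tk, seqs, p$heads)
    tk <- r$y
    lcaches[[i]] <- r$cache
  }
  # with zero transformer layers the global path is the identity (the
  # final layer norm only closes a non-empty transformer stack)
  lf <- if (length(p$layers)) ln_fw(p$lnf, tk) else list(y = tk, cache = NULL)
  uf <- unfold_of_tokens(lf$y, du)
  folded <- fold_patches(uf, patch = p$patch, source_dim = dim(pin_y))
  if (!is.null(rs)) {
    rs_back <- resize_map_fw(folded, dp[1L], dp[2L])
    folded <- rs_back$y
  } else rs_back <- NULL
  pout <- pwconv_fw(p$pwout, folded)
  bo <- bn_fw(p$bno, buf$bno, pout$y, training)
  ao <- silu_fw(bo$y)
  cat2 <- abind_ch(x, ao$y)                        # (H, W, 2C, N)
  ff <- conv_fw(p$fuse, cat2, stride = 1L, pad = 1L)
  bf <- bn_fw(p$bnf, buf$bnf, ff$y, training)
  af <- silu_fw(bf$y)
  buf$bnl <- b1$buf; buf$bno <- bo$buf; buf$bnf <- bf$buf
  list(y = af$y, buf = buf,
       cache = list(f1 = f1$cache, b1 = b1$cache, a1 = a1$cache,
                    pin = pin$cache, du = du, pin_dim = dim(pin_y),
                    rs = rs, rs_back = rs_back,
                    layers = lcaches, lf = lf$cache,
                    pout = pout$cache, bo = bo$cache, ao = ao$cache,
                    ff = ff$cache, bf = bf$cache, af = af$cache,
                    cin = dim(x)[3L]))
}

mvit_bw <- function(p, cache, gy) {
  gaf <- silu_bw(cache$af, gy)
  gbf <- bn_bw(p$bnf, cache$bf, gaf)
  gff <- conv_bw(p$fuse, cache$ff, gbf$gx)
  parts <- split_ch(gff$gx, cache$cin)
  gx_skip <- parts$a
  gao <- silu_bw(cache$ao, parts$b)
  gbo <- bn_bw(p$bno, cache$bo, gao)
  gpout <- pwconv_bw(p$pwout, cache$pout, gbo$gx)
  gfolded <- gpout$gx
  if (!is.null(cache$rs_back))
    gfolded <- resize_map_bw(cache$rs_back$cache, gfolded)
  gu <- unfold_patches(gfolded, p$patch)         # adjoint of fold = unfold
  gtk <- tokens_of_unfold(gu)
  if (length(p$layers)) {
    glf <- ln_bw(p$lnf, cache$lf, gtk)
    gtk <- glf$gx
  } else {
    glf <- list(ggamma = p$lnf$gamma * 0, gbeta = p$lnf$beta * 0)
  }
  glayers <- vector("list", length(p$layers))
  for (i in rev(seq_along(p$layers))) {
    r <- txl_bw(p$layers[[i]], cache$layers[[i]], gtk, p$heads)
    gtk <- r$gx
    glayers[[i]] <- r$grads
  }
  guf <- unfold_of_tokens(gtk, cache$du)
  gpin_y <- fold_patches(guf, patch = p$patch, source_dim = cache$pin_dim)
  if (!is.null(cache$rs))
    gpin_y <- resize_map_bw(cache$rs$cache, gpin_y)
  gpin <- pwconv_bw(p$pwin, cache$pin, gpin_y)
  ga1 <- silu_bw(cache$a1, gpin$gx)
  gb1 <- bn_bw(p$bnl, cache$b1, ga1)
  gf1 <- conv_bw(p$conv3, cache$f1, gb1$gx)
  list(gx = gx_skip + gf1$gx,
       grads = list(conv3 = gf1$gw,
                    bnl = list(gamma = gb1$ggamma, beta = gb1$gbeta),
                    pwin = gpin$gw,
                    layers = glayers,
                    lnf = list(gamma = glf$ggamma, beta = glf$gbeta),
                    pwout = gpout$gw,
                    bno = list(gamma = gbo$ggamma, beta = gbo$gbeta),
                    fuse = gff$gw,
                    bnf = list(gamma = gbf$ggamma, beta = gbf$gbeta)))
}

# channel concatenation / split helpers
abind_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1L):d[3L], , drop = FALSE])
}

## ---- squeeze-and-excitation channel attention -------------------------

se_init <- function(channels, reduction) {
  if (reduction <= 0L) stop("invalid channel-attention reduction")
  cr <- max(1L, channels %/% reduction)
  list(fc1 = linear_init(channels, cr, rng_sd = sqrt(2 / channels)),
       fc2 = linear_init(cr, channels, rng_sd = sqrt(2 / cr)),
       channels = channels)
}

se_fw <- function(p, x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  z_cn <- matrix(colMeans(matrix(x, hw, d[3L] * d[4L])), d[3L], d[4L])
  z <- t(z_cn)                                     # (N, C) tokens
  f1 <- linear_fw(p$fc1, z)
  r1 <- relu_fw(f1$y)
  f2 <- linear_fw(p$fc2, r1$y)
  sg <- sigmoid_fw(f2$y)                           # (N, C) gates in (0,1)
  scale <- rep(as.vector(t(sg$y)), each = hw)      # broadcast over H,W
  y <- x * scale
  list(y = y, cache = list(x = x, f1 = f1$cache, r1 = r1$cache,
                           f2 = f2$cache, sg = sg$cache, scale = scale,
                           z = z, d = d, hw = hw),
       gate = sg$y, squeeze = z)
}

se_bw <- function(p, cache, gy) {
  d <- cache$d; hw <- cache$hw
  gx <- gy * cache$scale
  gs_cn <- matrix(colSums(matrix(gy * cache$x, hw, d[3L] * d[4L])),
                  d[3L], d[4L])
  gs <- sigmoid_bw(cache$sg, t(gs_cn))
  gf2 <- linear_bw(p$fc2, cache$f2, gs)
  gr1 <- relu_bw(cache$r1, gf2$gx)
  gf1 <- linear_bw(p$fc1, cache$f1, gr1)
  gz <- gf1$gx                                     # (N, C)
  gx <- gx + rep(as.vector(t(gz)), each = hw) / hw
  list(gx = gx,
       grads = list(fc1 = list(w = gf1$gw, b = gf1$gb),
                    fc2 = list(w = gf2$gw, b = gf2$gb)))
}
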