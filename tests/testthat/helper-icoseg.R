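# shared test helpers: finite-difference gradients, random feature maps,
# and an independent brute-force oracle for the aggregated Jaccard index

num_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

rand_map <- function(h, w, c, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * c * n), dim = c(h, w, c, n))
}

# independent AJI oracle: plain pixel-set arithmetic, one gt instance at a
# time, best Jaccard by direct enumeration over predicted components
aji_oracle <- function(gt, pred) {
  gl <- setdiff(sort(unique(as.vector(gt))), 0L)
  pl <- setdiff(sort(unique(as.vector(pred))), 0L)
  if (length(gl) == 0L && length(pl) == 0L) return(1)
  if (length(gl) == 0L || length(pl) == 0L) return(0)
  gsets <- lapply(gl, function(l) which(gt == l))
  psets <- lapply(pl, function(l) which(pred == l))
  used <- logical(length(pl))
  num <- 0; den <- 0
  for (gs in gsets) {
    best_j <- 0; best_k <- 0
    for (k in seq_along(psets)) {
      inter <- length(intersect(gs, psets[[k]]))
      uni <- length(union(gs, psets[[k]]))
      j <- inter / uni
      if (j > best_j) { best_j <- j; best_k <- k }
    }
    if (best_k > 0) {
      used[best_k] <- TRUE
      num <- num + length(intersect(gs, psets[[best_k]]))
      den <- den + length(union(gs, psets[[best_k]]))
    } else {
      den <- den + length(gs)
    }
  }
  for (k in seq_along(psets)) if (!used[k]) den <- den + length(psets[[k]])
  num / den
}

# random instance map: up to max_inst blobs on a small grid
rand_instance_map <- function(h, w, max_inst, seed) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  n <- sample.int(max_inst + 1L, 1L) - 1L
  for (l in seq_len(n)) {
    ch <- sample.int(h, 1L); cw <- sample.int(w, 1L)
    rh <- sample.int(3L, 1L); rw <- sample.int(3L, 1L)
    rows <- max(1L, ch - rh):min(h, ch + rh)
    cols <- max(1L, cw - rw):min(w, cw + rw)
    m[rows, cols] <- l
  }
  # relabel into connected components so each instance is connected
  if (max(m) > 0L) {
    out <- matrix(0L, h, w)
    nxt <- 0L
    for (l in sort(unique(m[m > 0L]))) {
      cc <- connected_components((m == l) * 1L, 8L)
      for (k in seq_len(max(cc))) {
        nxt <- nxt + 1L
        out[cc == k] <- nxt
      }
    }
    m <- out
  }
  m
}

# tiny synthetic dataset shared across engine/cli tests (built once)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "icoseg-tiny-ds")
      if (!dir.exists(dir)) {
        params <- synth_params(patch_size = 96L, radius_range = c(6, 11),
                               cell_count_mean = 5)
        generate_dataset(12L, params, dir, seed = 303L)
      }
      man <- load_manifest_q(file.path(dir, "manifest.csv"))
      cache <<- man
    }
    cache
  }
})

load_manifest_q <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(man, "dir") <- dirname(path)
  man
}
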