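# Seeded generator of synthetic IHC-like patches: brown (DAB) cytoplasmic
# positive cells with blue (hematoxylin) nuclei, blue-only negative nuclei,
# pink tissue background, optional blur artifacts, and exact instance
# ground truth. Colors are composited in optical density and converted to
# transmitted intensity with image = 255 * exp(-sum OD).

#' Parameters of the synthetic patch generator
#'
#' Defaults emulate 256 x 256 patches from 40x IHC slides with on average
#' six positive cells per patch. The optical-density triples are standard
#' DAB (brown), hematoxylin (blue) and a weak eosin-like pink background.
#'
#' @param patch_size patch side in pixels (>= 64).
#' @param cell_count_mean Poisson mean of the positive-cell count.
#' @param radius_range min/max cell radius in pixels.
#' @param eccentricity_range range of ellipse eccentricity in `[0, 1)`.
#' @param touching_pair_prob probability that a cell is placed touching the
#'   previous one, producing fused boundaries in the image.
#' @param negative_cell_rate negative (blue-only) nuclei per positive cell,
#'   used as a Poisson mean multiplier.
#' @param stain_od_positive,stain_od_negative,stain_od_background RGB
#'   optical-density triples of the DAB cytoplasm, hematoxylin nuclei and
#'   background tissue.
#' @param noise_sd standard deviation of Gaussian pixel noise on the
#'   normalized intensity scale.
#' @param blur_prob,blur_sigma probability and strength of a local
#'   Gaussian-blur dye artifact.
#' @param seed default seed used by [generate_patch()] when none is given.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(patch_size = 256L,
                         cell_count_mean = 6,
                         radius_range = c(9, 18),
                         eccentricity_range = c(0, 0.6),
                         touching_pair_prob = 0.25,
                         negative_cell_rate = 0.5,
                         stain_od_positive = c(0.30, 0.65, 0.90),
                         stain_od_negative = c(0.72, 0.78, 0.32),
                         stain_od_background = c(0.035, 0.14, 0.06),
                         noise_sd = 0.01,
                         blur_prob = 0.3,
                         blur_sigma = 2.5,
                         seed = 1L) {
  p <- list(patch_size = as.integer(patch_size),
            cell_count_mean = cell_count_mean,
            radius_range = radius_range,
            eccentricity_range = eccentricity_range,
            touching_pair_prob = touching_pair_prob,
            negative_cell_rate = negative_cell_rate,
            stain_od_positive = stain_od_positive,
            stain_od_negative = stain_od_negative,
            stain_od_background = stain_od_background,
            noise_sd = noise_sd, blur_prob = blur_prob,
            blur_sigma = blur_sigma, seed = as.integer(seed))
  if (p$patch_size < 64L) stop("patch_size must be >= 64")
  if (diff(radius_range) < 0 || radius_range[1L] <= 0)
    stop("degenerate radius range")
  probs <- c(touching_pair_prob, negative_cell_rate * 0, blur_prob)
  if (any(probs < 0) || touching_pair_prob > 1 || blur_prob > 1)
    stop("probabilities must lie in [0, 1]")
  structure(p, class = "synth_params")
}

# elliptical footprint with low-frequency boundary jitter; returns a list
# with the cell's pixel logical mask over the full patch and its nucleus OD
cell_footprint <- function(sz, cx, cy, r, ecc, theta, jitter_amp = 0.08) {
  ra <- r / sqrt(sqrt(1 - ecc^2))
  rb <- r * sqrt(sqrt(1 - ecc^2))
  half <- ceiling(max(ra, rb) * (1 + jitter_amp) + 2)
  xs <- max(1L, floor(cx - half)):min(sz, ceiling(cx + half))
  ys <- max(1L, floor(cy - half)):min(sz, ceiling(cy + half))
  gx <- outer(ys * 0, xs, function(a, b) b) - cx   # columns vary with x
  gy <- outer(ys, xs * 0, function(a, b) a) - cy
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  rho <- sqrt((xr / ra)^2 + (yr / rb)^2)
  phi <- atan2(yr / rb, xr / ra)
  j1 <- stats::runif(1, 0, jitter_amp); p1 <- stats::runif(1, 0, 2 * pi)
  j2 <- stats::runif(1, 0, jitter_amp); p2 <- stats::runif(1, 0, 2 * pi)
  edge <- 1 + j1 * sin(2 * phi + p1) + j2 * sin(3 * phi + p2)
  inside <- rho <= edge
  # soft cytoplasm density: full inside, feathered over the outer 15%
  dens <- pmin(1, pmax(0, (edge - rho) / (0.15 * edge) ))
  dens[!inside & dens > 0] <- pmin(dens[!inside & dens > 0], 0.4)
  nuc <- rho <= 0.48 * edge
  list(rows = ys, cols = xs, inside = inside, dens = dens, nucleus = nuc,
       ra = ra, rb = rb)
}

dilate8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  sh <- function(dr, dc) {
    s <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    s
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | sh(dr, dc)
  out
}

# smooth multiplicative texture field from an upsampled coarse noise grid
texture_field <- function(sz, cells = 8L, amp = 0.3) {
  coarse <- matrix(stats::rnorm(cells * cells), cells, cells)
  up <- resize_bilinear(coarse, sz, sz)
  1 + amp * up / max(abs(up), 1e-8)
}

#' Generate one synthetic IHC patch
#'
#' Samples `n_positive ~ Poisson(cell_count_mean)` elliptical DAB-positive
#' cells (brown cytoplasm, darker blue nucleus) with boundary jitter, some
#' placed as touching pairs; adds blue-only negative nuclei and pink tissue
#' texture; composites the stains in optical density; applies Gaussian
#' noise and, with probability `blur_prob`, a local blur artifact. The
#' instance map records every positive cell exactly, before noise; touching
#' instances are separated by a one-pixel label gap while their appearance
#' in the image stays fused.
#'
#' @param params a [synth_params()] object.
#' @param seed integer seed; defaults to `params$seed`.
#' @return a list of class `synth_patch`: `image` (H x W x 3, values
#'   0--255), `instances` (integer H x W instance map of positive cells),
#'   `n_positive`, `n_negative`.
#' @export
generate_patch <- function(params = synth_params(), seed = params$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sz <- params$patch_size
  od_pos <- params$stain_od_positive
  od_neg <- params$stain_od_negative
  od_bg <- params$stain_od_background

  dab <- matrix(0, sz, sz)       # DAB amount per pixel
  hem <- matrix(0, sz, sz)       # hematoxylin amount per pixel
  inst <- matrix(0L, sz, sz)

  n_pos <- stats::rpois(1L, params$cell_count_mean)
  margin <- params$radius_range[2L]
  prev <- NULL
  label <- 0L
  for (i in seq_len(n_pos)) {
    r <- stats::runif(1, params$radius_range[1L], params$radius_range[2L])
    ecc <- stats::runif(1, params$eccentricity_range[1L],
                        params$eccentricity_range[2L])
    theta <- stats::runif(1, 0, pi)
    touching <- !is.null(prev) && stats::runif(1) < params$touching_pair_prob
    placed <- FALSE
    for (try in 1:50) {
      if (touching) {
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- (prev$r + r) * stats::runif(1, 0.80, 0.95)
        cx <- prev$cx + dist * cos(ang)
        cy <- prev$cy + dist * sin(ang)
        if (cx < margin || cx > sz - margin ||
            cy < margin || cy > sz - margin) next
      } else {
        cx <- stats::runif(1, margin, sz - margin)
        cy <- stats::runif(1, margin, sz - margin)
      }
      if (touching || is.null(prev) ||
          (cx - prev$cx)^2 + (cy - prev$cy)^2 > (1.2 * (prev$r + r))^2 ||
          try == 50L) {
        placed <- TRUE
        break
      }
    }
    if (!placed) { cx <- sz / 2; cy <- sz / 2 }
    fp <- cell_footprint(sz, cx, cy, r, ecc, theta)
    label <- label + 1L
    # paint stains (union appearance: fused for touching cells)
    dab[fp$rows, fp$cols] <- pmax(dab[fp$rows, fp$cols], fp$dens)
    hem[fp$rows, fp$cols] <- pmax(hem[fp$rows, fp$cols],
                                  ifelse(fp$nucleus, 1.3, 0.15 * fp$dens))
    # instance label: never overwrite earlier labels, keep a 1-px gap
    sub <- inst[fp$rows, fp$cols]
    free <- fp$inside & sub == 0L & !dilate8(sub > 0L)
    sub[free] <- label
    inst[fp$rows, fp$cols] <- sub
    prev <- list(cx = cx, cy = cy, r = r)
  }
  # drop labels that lost every pixel, keep largest component per label
  inst <- tidy_instances(inst)
  n_pos_final <- max(inst)

  n_neg <- stats::rpois(1L, params$cell_count_mean * params$negative_cell_rate)
  for (i in seq_len(n_neg)) {
    r <- stats::runif(1, 0.45, 0.7) * stats::runif(
      1, params$radius_range[1L], params$radius_range[2L])
    cx <- stats::runif(1, r, sz - r); cy <- stats::runif(1, r, sz - r)
    ecc <- stats::runif(1, 0, 0.5); theta <- stats::runif(1, 0, pi)
    fp <- cell_footprint(sz, cx, cy, r, ecc, theta)
    hem[fp$rows, fp$cols] <- pmax(hem[fp$rows, fp$cols],
                                  ifelse(fp$nucleus, 1.0, 0.3 * fp$dens))
  }

  bg_tex <- texture_field(sz)
  hem_tex <- texture_field(sz, cells = 6L, amp = 0.5)
  img <- array(0, dim = c(sz, sz, 3L))
  for (ch in 1:3) {
    od <- od_bg[ch] * bg_tex + od_pos[ch] * dab +
      od_neg[ch] * hem * pmax(hem_tex, 0.2)
    img[, , ch] <- exp(-od)
  }

  if (stats::runif(1) < params$blur_prob) {
    bc <- stats::runif(2, sz * 0.2, sz * 0.8)
    br <- stats::runif(1, sz * 0.1, sz * 0.25)
    d2 <- outer((seq_len(sz) - bc[1L])^2, (seq_len(sz) - bc[2L])^2, "+")
    w <- exp(-d2 / (2 * br^2))
    blurred <- gaussian_blur_rgb(img, params$blur_sigma)
    for (ch in 1:3) img[, , ch] <- (1 - w) * img[, , ch] + w * blurred[, , ch]
  }
  if (params$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = params$noise_sd),
                       dim = dim(img))
  img <- round(pmin(pmax(img, 0), 1) * 255)

  structure(list(image = img, instances = inst,
                 n_positive = n_pos_final, n_negative = n_neg,
                 seed = seed),
            class = "synth_patch")
}

tidy_instances <- function(inst) {
  labs <- sort(unique(inst[inst > 0L]))
  out <- matrix(0L, nrow(inst), ncol(inst))
  nxt <- 0L
  for (l in labs) {
    m <- inst == l
    cc <- cc_label_cpp(matrix(as.integer(m), nrow(inst)), 8L)
    if (max(cc) == 0L) next
    areas <- tabulate(cc[cc > 0L], nbins = max(cc))
    keep <- which.max(areas)
    nxt <- nxt + 1L
    out[cc == keep] <- nxt
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` patches with per-patch seeds derived from the master seed
#' (so any patch is regenerable in isolation) and writes RGB images, binary
#' masks, 16-bit instance maps and a CSV manifest.
#'
#' @param n number of patches (>= 1).
#' @param params a [synth_params()] object.
#' @param out_dir output directory; `images/`, `masks/`, `instances/`
#'   subdirectories are created.
#' @param seed master seed.
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.csv`), with an attribute `path`.
#' @export
generate_dataset <- function(n, params = synth_params(), out_dir,
                             seed = params$seed) {
  if (n < 1L) stop("n must be >= 1")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  for (d in c("images", "masks", "instances"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- patch_seed(seed, i)
    sp <- generate_patch(params, seed = ps)
    id <- sprintf("patch_%04d", i)
    ipath <- file.path("images", paste0(id, ".png"))
    mpath <- file.path("masks", paste0(id, ".png"))
    npath <- file.path("instances", paste0(id, ".png"))
    png::writePNG(sp$image / 255, file.path(out_dir, ipath))
    png::writePNG((sp$instances > 0L) * 1, file.path(out_dir, mpath))
    write_instance_png(sp$instances, file.path(out_dir, npath))
    rows[[i]] <- data.frame(id = id, image = ipath, mask = mpath,
                            instances = npath, n_positive = sp$n_positive,
                            n_negative = sp$n_negative, seed = ps)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "path") <- file.path(out_dir, "manifest.csv")
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

# per-patch seeds below 2^31, reproducible from the master seed
patch_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483629)
}

#' @export
print.synth_patch <- function(x, ...) {
  cat(sprintf("synthetic IHC patch %dx%d: %d positive cells, %d negative nuclei (seed %d)\n",
              nrow(x$instances), ncol(x$instances), x$n_positive,
              x$n_negative, x$seed))
  invisible(x)
}
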