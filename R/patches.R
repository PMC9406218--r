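# Lossless unfold/fold between feature maps and non-overlapping patch
# sequences, the pixel re-arrangement at the heart of the MobileViT block.

patch_perm <- function(h, w, ph, pw) {
  # permutation p such that u_flat[p[i]] = x_flat[i] for one channel plane,
  # where x is column-major (h fastest) and u is (P, N_patch) column-major.
  tw <- w %/% pw
  hh <- rep(seq_len(h) - 1L, times = w)
  ww <- rep(seq_len(w) - 1L, each = h)
  tile <- (hh %/% ph) * tw + (ww %/% pw)          # row-major tile index
  pos <- (hh %% ph) * pw + (ww %% pw)             # row-major within tile
  pos + (ph * pw) * tile + 1L
}

#' Unfold a feature map into non-overlapping patches
#'
#' Partitions an `(H, W, C, N)` feature map into `patch[1] x patch[2]` tiles
#' and rearranges it as an array of dim `(P, N_patch, C, N)` where
#' `P = patch[1] * patch[2]` is the number of pixel positions inside a tile
#' and `N_patch = H * W / P` is the number of tiles. Both the tile order and
#' the position order within a tile are row-major, and no pixel is duplicated
#' or dropped, so [fold_patches()] restores the input bit-exactly.
#'
#' @param x numeric 4-d array `(H, W, C, N)`.
#' @param patch integer vector `(patch_h, patch_w)`; each must divide the
#'   corresponding spatial dimension.
#' @return array of dim `(P, N_patch, C, N)` with attributes `patch` and
#'   `source_dim` used by [fold_patches()].
#' @seealso [fold_patches()]
#' @export
unfold_patches <- function(x, patch) {
  x <- as_feature_map(x)
  d <- dim(x)
  ph <- as.integer(patch[1L]); pw <- as.integer(patch[2L])
  if (d[1L] %% ph != 0L || d[2L] %% pw != 0L)
    stop("patch dims (", ph, ",", pw, ") must divide spatial dims (",
         d[1L], ",", d[2L], ")")
  perm <- patch_perm(d[1L], d[2L], ph, pw)
  m <- x
  dim(m) <- c(d[1L] * d[2L], d[3L] * d[4L])
  u <- m
  u[perm, ] <- m
  dim(u) <- c(ph * pw, d[1L] * d[2L] / (ph * pw), d[3L], d[4L])
  attr(u, "patch") <- c(ph, pw)
  attr(u, "source_dim") <- d
  u
}

#' Fold a patch sequence back into a feature map
#'
#' Exact inverse of [unfold_patches()].
#'
#' @param u array produced by [unfold_patches()], or any array of dim
#'   `(P, N_patch, C, N)` carrying `patch` and `source_dim` attributes.
#' @param patch,source_dim overrides for the attributes carried by `u`.
#' @return the restored `(H, W, C, N)` array.
#' @export
fold_patches <- function(u, patch = attr(u, "patch"),
                         source_dim = attr(u, "source_dim")) {
  if (is.null(patch) || is.null(source_dim))
    stop("fold_patches needs patch and source_dim")
  d <- source_dim
  du <- dim(u)
  if (du[1L] != patch[1L] * patch[2L] ||
      du[1L] * du[2L] != d[1L] * d[2L] ||
      du[3L] != d[3L] || du[4L] != d[4L])
    stop("inconsistent patch/source dims in fold_patches")
  perm <- patch_perm(d[1L], d[2L], patch[1L], patch[2L])
  m <- u
  dim(m) <- c(du[1L] * du[2L], du[3L] * du[4L])
  x <- m[perm, , drop = FALSE]
  dim(x) <- d
  x
}
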