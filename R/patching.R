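# Patch-token front end: image <-> patch-sequence conversion, random mask
# sampling for the reconstruction stage, and fixed 2-D sin-cos positional
# embeddings.

#' Split an image into a row-major patch-token sequence
#'
#' The image is zero-padded on the right/bottom to the next multiple of
#' `patch_size` (padding lies outside image content, so boxes are unaffected),
#' then cut into non-overlapping `patch_size x patch_size` patches, ordered
#' row-major over the patch grid. Each token is the patch flattened row-major
#' (within-patch rows, then columns, channel-major last).
#'
#' @param pixels A height x width matrix (grayscale) or height x width x C array.
#' @param patch_size Patch side in pixels (default 16).
#' @return A list of class `lesiondet_patchseq`: `tokens` (n_patches x
#'   patch_size^2*C matrix), `grid_shape` `(rows, cols)`, `patch_size`,
#'   `channels`, `orig_shape`.
#' @export
patchify <- function(pixels, patch_size = 16) {
  if (length(dim(pixels)) == 2) pixels <- array(pixels, dim = c(dim(pixels), 1))
  h <- dim(pixels)[1]; w <- dim(pixels)[2]; ch <- dim(pixels)[3]
  hp <- ceiling(h / patch_size) * patch_size
  wp <- ceiling(w / patch_size) * patch_size
  if (hp != h || wp != w) {
    padded <- array(0, dim = c(hp, wp, ch))
    padded[seq_len(h), seq_len(w), ] <- pixels
    pixels <- padded
  }
  rows <- hp %/% patch_size; cols <- wp %/% patch_size
  tokens <- matrix(0, nrow = rows * cols, ncol = patch_size^2 * ch)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      blk <- pixels[(r - 1) * patch_size + seq_len(patch_size),
                    (c - 1) * patch_size + seq_len(patch_size), , drop = FALSE]
      # flatten within-patch row-major: transpose each channel slab
      tokens[k, ] <- as.vector(vapply(seq_len(ch), function(cc) {
        as.vector(t(blk[, , cc]))
      }, numeric(patch_size^2)))
    }
  }
  structure(list(tokens = tokens, grid_shape = c(rows, cols),
                 patch_size = as.integer(patch_size), channels = as.integer(ch),
                 orig_shape = c(h, w)),
            class = "lesiondet_patchseq")
}

#' Reassemble pixels from a patch sequence (exact inverse of [patchify()])
#'
#' @param seq A `lesiondet_patchseq` (its `tokens` may have been replaced, e.g.
#'   by reconstructed patches).
#' @param channels Number of channels (defaults to the value recorded in `seq`).
#' @return A matrix (1 channel) or array of the original (unpadded) shape.
#' @export
unpatchify <- function(seq, channels = seq$channels) {
  ps <- seq$patch_size
  rows <- seq$grid_shape[1]; cols <- seq$grid_shape[2]
  if (nrow(seq$tokens) != rows * cols) {
    stopf("token count %d inconsistent with grid %dx%d", nrow(seq$tokens), rows, cols)
  }
  out <- array(0, dim = c(rows * ps, cols * ps, channels))
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      tok <- seq$tokens[k, ]
      for (cc in seq_len(channels)) {
        slab <- matrix(tok[(cc - 1) * ps^2 + seq_len(ps^2)], nrow = ps, byrow = TRUE)
        out[(r - 1) * ps + seq_len(ps), (c - 1) * ps + seq_len(ps), cc] <- slab
      }
    }
  }
  out <- out[seq_len(seq$orig_shape[1]), seq_len(seq$orig_shape[2]), , drop = FALSE]
  if (channels == 1) out <- out[, , 1] else out
}

#' Sample a random visible/masked patch split
#'
#' Draws `round(mask_ratio * n_patches)` masked indices uniformly without
#' replacement. Both sides of the split must be nonempty.
#'
#' @param n_patches Number of patches (>= 2).
#' @param mask_ratio Fraction masked, in (0, 1). Default 0.75, the upper end of
#'   the 65-75% band that works best for reconstruction pretraining.
#' @param seed Integer seed; the plan is deterministic per seed.
#' @return A list of class `lesiondet_maskplan`: sorted integer vectors
#'   `visible_idx` and `masked_idx` (1-based), `mask_ratio`, `seed`.
#' @export
sample_mask <- function(n_patches, mask_ratio = 0.75, seed = 1) {
  if (n_patches < 2) stopf("need at least 2 patches")
  if (mask_ratio <= 0 || mask_ratio >= 1) stopf("mask_ratio must be in (0,1)")
  n_masked <- round(mask_ratio * n_patches)
  if (n_masked < 1 || n_masked > n_patches - 1) {
    stopf("mask_ratio %.3f leaves an empty visible or masked set for n=%d",
          mask_ratio, n_patches)
  }
  masked <- with_seed(seed, sort(sample.int(n_patches, n_masked)))
  structure(list(visible_idx = setdiff(seq_len(n_patches), masked),
                 masked_idx = masked, mask_ratio = mask_ratio, seed = seed),
            class = "lesiondet_maskplan")
}

#' Fixed 2-D sin-cos positional embedding table
#'
#' Standard transformer sinusoids, computed separately for the row and column
#' coordinate of each grid position and concatenated (dim/2 each). Deterministic
#' given the grid and dimension.
#'
#' @param rows,cols Patch-grid shape.
#' @param dim Embedding width (multiple of 4).
#' @return A `rows*cols` x `dim` matrix, rows in row-major grid order.
#' @export
position_table <- function(rows, cols, dim) {
  if (dim %% 4 != 0) stopf("embedding dim must be a multiple of 4")
  half <- dim %/% 2
  sincos_1d <- function(pos, d) {
    omega <- 1 / 10000^(2 * (seq_len(d %/% 2) - 1) / d)
    ang <- outer(pos, omega)
    cbind(sin(ang), cos(ang))
  }
  rpos <- rep(seq_len(rows) - 1, each = cols)
  cpos <- rep(seq_len(cols) - 1, times = rows)
  cbind(sincos_1d(rpos, half), sincos_1d(cpos, half))
}
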