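# Hierarchical windowed-attention backbone.
#
# Scaled dot-product self-attention (query/key/value maps f, g, h plus an
# output map W_v), applied either globally, inside non-overlapping M x M
# windows (W-MSA), or inside windows shifted by floor(M/2) with wrapped pairs
# masked out (SW-MSA). Pairs of W-MSA/SW-MSA blocks with pre-LN residuals and
# MLPs are stacked into stages separated by 2x2 patch merging, halving the
# spatial grid and doubling channels at each stage.

#' Construct a feature map
#'
#' A feature map is an `h x w` grid of channel vectors stored as a row-major
#' `(h*w) x C` token matrix.
#'
#' @param tokens `(h*w) x C` numeric matrix, rows in row-major grid order.
#' @param h,w Grid height and width.
#' @return A list of class `lesiondet_fmap` with fields `tokens`, `h`, `w`.
#' @export
feature_map <- function(tokens, h, w) {
  stopifnot(nrow(tokens) == h * w, h >= 1, w >= 1, ncol(tokens) >= 1)
  structure(list(tokens = tokens, h = as.integer(h), w = as.integer(w)),
            class = "lesiondet_fmap")
}

#' Initialise self-attention parameters
#'
#' Creates the learnable maps of one attention operator: per-head query/key
#' projections `W_f`, `W_g` (width `d_k` each), value projection `W_h`
#' (C/heads per head) and the output map `W_v` (C x C).
#'
#' @param C Channel dimension of the feature map.
#' @param heads Number of attention heads (must divide C). `heads = 1`
#'   reproduces the single-head equations exactly.
#' @param attention_scale `"sqrt"` scales scores by `1/sqrt(d_k)` (default,
#'   the standard transformer choice); `"linear"` scales by `1/d_k` (the
#'   literal printed form).
#' @param sd Init scale for the Gaussian weight init.
#' @return A list of class `lesiondet_attn_params`.
#' @export
attention_params <- function(C, heads = 1, attention_scale = c("sqrt", "linear"),
                             sd = 0.02) {
  attention_scale <- match.arg(attention_scale)
  if (C %% heads != 0) stopf("heads (%d) must divide C (%d)", heads, C)
  d_head <- C %/% heads
  structure(list(
    Wf = ad_param(init_mat(C, C, sd)),
    Wg = ad_param(init_mat(C, C, sd)),
    Wh = ad_param(init_mat(C, C, sd)),
    Wv = ad_param(init_mat(C, C, sd)),
    heads = as.integer(heads), d_head = d_head, C = as.integer(C),
    attention_scale = attention_scale
  ), class = "lesiondet_attn_params")
}

# Tape-level multi-head self-attention over an n x C token matrix node.
# `mask` is an optional additive n x n matrix (-1e9 forbids a pair).
self_attention_node <- function(x, params, mask = NULL) {
  x <- as_ad(x)
  H <- params$heads
  d <- params$d_head
  scale <- if (params$attention_scale == "sqrt") 1 / sqrt(d) else 1 / d
  f_all <- ad_matmul(x, params$Wf)
  g_all <- ad_matmul(x, params$Wg)
  h_all <- ad_matmul(x, params$Wh)
  outs <- vector("list", H)
  for (hh in seq_len(H)) {
    cols <- (hh - 1) * d + seq_len(d)
    f <- ad_cols(f_all, cols)
    g <- ad_cols(g_all, cols)
    v <- ad_cols(h_all, cols)
    e <- ad_scale(ad_matmul(f, ad_transpose(g)), scale)
    a <- ad_softmax_rows(e, mask = mask)
    outs[[hh]] <- ad_matmul(a, v)
  }
  concat <- if (H == 1) outs[[1]] else ad_cbind(outs)
  ad_matmul(concat, params$Wv)
}

#' Global self-attention over a feature map
#'
#' Computes `e_{t,i} = f(x_t)' g(x_i) * scale`, row-softmax attention weights,
#' and outputs `Z = W_v (A h(x))`, where `f, g, h` are learned linear maps and
#' the scale is `1/sqrt(d_k)` (or `1/d_k` with `attention_scale = "linear"`).
#'
#' @param x A `lesiondet_fmap` (or plain token matrix).
#' @param params [attention_params()] with `C == ncol(tokens)`.
#' @return Same type as `x`, with attended tokens.
#' @export
self_attention <- function(x, params) {
  toks <- if (inherits(x, "lesiondet_fmap")) x$tokens else x
  out <- ad_run(self_attention_node(ad_const(toks), params))
  if (inherits(x, "lesiondet_fmap")) feature_map(out, x$h, x$w) else out
}

#' Partition a feature-map grid into non-overlapping M x M windows
#'
#' With `shift = 0` the grid is tiled directly. With `shift = floor(M/2)` the
#' grid is first cyclically rolled by `(-shift, -shift)`; tokens that wrapped
#' across the original image boundary receive an attention mask so that pairs
#' from different original regions cannot attend to each other. Grids not
#' divisible by M are zero-padded on the right/bottom and pad positions are
#' masked out as attention targets.
#'
#' @param x A `lesiondet_fmap`.
#' @param M Window side, in grid positions.
#' @param shift 0 or `floor(M/2)`.
#' @return A list of class `lesiondet_winpart`: per window, `idx` (original
#'   1-based token indices, NA for padding) and `mask` (M^2 x M^2 additive
#'   attention mask), plus the grid bookkeeping needed by [window_merge()].
#' @export
window_partition <- function(x, M, shift = 0) {
  h <- x$h; w <- x$w
  if (!shift %in% c(0L, M %/% 2L)) stopf("shift must be 0 or floor(M/2)")
  if (M > max(h, w)) stopf("window size M=%d exceeds grid %dx%d", M, h, w)
  hp <- ceiling(h / M) * M
  wp <- ceiling(w / M) * M
  # original token index at each padded-grid position (NA = padding)
  idx_grid <- matrix(NA_integer_, hp, wp)
  idx_grid[seq_len(h), seq_len(w)] <- matrix(seq_len(h * w), h, w, byrow = TRUE)
  # region ids for the shift mask, computed on the original grid
  reg_r <- integer(hp); reg_c <- integer(wp)
  if (shift > 0) {
    roll <- function(n) ((seq_len(n) - 1 + shift) %% n) + 1
    idx_grid <- idx_grid[roll(hp), roll(wp), drop = FALSE]
    reg_r <- as.integer(seq_len(hp) > hp - shift)
    reg_c <- as.integer(seq_len(wp) > wp - shift)
  }
  windows <- list()
  for (wr in seq_len(hp %/% M)) {
    for (wc in seq_len(wp %/% M)) {
      rr <- (wr - 1) * M + seq_len(M)
      cc <- (wc - 1) * M + seq_len(M)
      idx <- as.vector(t(idx_grid[rr, cc, drop = FALSE]))  # row-major within window
      region <- as.vector(t(outer(reg_r[rr], reg_c[cc], function(a, b) a * 2L + b)))
      mask <- matrix(0, M * M, M * M)
      if (shift > 0) {
        diff <- outer(region, region, "!=")
        mask[diff] <- -1e9
      }
      pad <- is.na(idx)
      if (any(pad)) mask[, pad] <- -1e9
      windows[[length(windows) + 1L]] <- list(idx = idx, mask = mask,
                                              offset = c(wr - 1L, wc - 1L))
    }
  }
  structure(list(M = as.integer(M), shift = as.integer(shift), h = h, w = w,
                 hp = hp, wp = wp, windows = windows),
            class = "lesiondet_winpart")
}

#' Reassemble a feature map from per-window token blocks
#'
#' Exact inverse of [window_partition()]: scatters window tokens back to their
#' original grid positions, dropping padding.
#'
#' @param part A `lesiondet_winpart`.
#' @param window_tokens List of M^2 x C matrices, one per window, in partition
#'   order.
#' @return A `lesiondet_fmap` of the original grid shape.
#' @export
window_merge <- function(part, window_tokens) {
  C <- ncol(window_tokens[[1]])
  out <- matrix(0, part$h * part$w, C)
  for (k in seq_along(part$windows)) {
    idx <- part$windows[[k]]$idx
    keep <- !is.na(idx)
    out[idx[keep], ] <- window_tokens[[k]][keep, , drop = FALSE]
  }
  feature_map(out, part$h, part$w)
}

# Tape-level windowed attention (shared by w_msa / sw_msa). The query/key/value
# projections do not depend on window membership, so they are computed once on
# the full grid; each window then gathers its projected rows (padding drawn
# from an appended zero row — the projections are bias-free, so a zero token
# projects to zero), applies masked attention, and results are scattered back
# in original token order before the shared output map W_v.
window_attention_node <- function(x, h, w, M, params, shift) {
  x <- as_ad(x)
  # a window never needs to exceed the grid: clamp (and re-derive the shift)
  if (M > max(h, w)) {
    M <- max(h, w)
    if (shift > 0) shift <- M %/% 2L
  }
  part <- window_partition(feature_map(x$value, h, w), M, shift)
  C <- ncol(x$value)
  n <- h * w
  H <- params$heads
  d <- params$d_head
  scale <- if (params$attention_scale == "sqrt") 1 / sqrt(d) else 1 / d
  zrow <- ad_const(matrix(0, 1, C))
  f_all <- ad_rbind(list(ad_matmul(x, params$Wf), zrow))
  g_all <- ad_rbind(list(ad_matmul(x, params$Wg), zrow))
  h_all <- ad_rbind(list(ad_matmul(x, params$Wh), zrow))
  outs <- vector("list", length(part$windows))
  # position of each original token inside the concatenated window outputs
  gather_back <- integer(n)
  for (k in seq_along(part$windows)) {
    win <- part$windows[[k]]
    rows <- ifelse(is.na(win$idx), n + 1L, win$idx)
    fw <- ad_gather_rows(f_all, rows)
    gw <- ad_gather_rows(g_all, rows)
    vw <- ad_gather_rows(h_all, rows)
    mask <- if (any(win$mask != 0)) win$mask else NULL
    heads_out <- vector("list", H)
    for (hh in seq_len(H)) {
      cols <- (hh - 1) * d + seq_len(d)
      f <- if (H == 1) fw else ad_cols(fw, cols)
      g <- if (H == 1) gw else ad_cols(gw, cols)
      v <- if (H == 1) vw else ad_cols(vw, cols)
      e <- ad_scale(ad_matmul(f, ad_transpose(g)), scale)
      heads_out[[hh]] <- ad_matmul(ad_softmax_rows(e, mask = mask), v)
    }
    outs[[k]] <- if (H == 1) heads_out[[1]] else ad_cbind(heads_out)
    keep <- which(!is.na(win$idx))
    gather_back[win$idx[keep]] <- (k - 1L) * M * M + keep
  }
  allw <- if (length(outs) == 1) outs[[1]] else ad_rbind(outs)
  ad_matmul(ad_gather_rows(allw, gather_back), params$Wv)
}

#' Window multi-head self-attention (regular tiling)
#'
#' Self-attention applied independently inside each non-overlapping M x M
#' window; tokens in different windows cannot influence each other. With a
#' single window covering the whole grid this equals global [self_attention()].
#'
#' @param x A `lesiondet_fmap`.
#' @param M Window side.
#' @param params [attention_params()].
#' @return A `lesiondet_fmap`.
#' @export
w_msa <- function(x, M, params) {
  out <- ad_run(window_attention_node(ad_const(x$tokens), x$h, x$w, M, params,
                                        shift = 0L))
  feature_map(out, x$h, x$w)
}

#' Shifted-window multi-head self-attention
#'
#' Cyclically rolls the grid by `(-floor(M/2), -floor(M/2))`, applies windowed
#' attention with wrapped pairs masked out, and rolls back. Equivalent to
#' explicitly re-tiling the shifted layout and attending within each contiguous
#' sub-window.
#'
#' @inheritParams w_msa
#' @return A `lesiondet_fmap`.
#' @export
sw_msa <- function(x, M, params) {
  out <- ad_run(window_attention_node(ad_const(x$tokens), x$h, x$w, M, params,
                                        shift = M %/% 2L))
  feature_map(out, x$h, x$w)
}

#' Initialise one W-MSA/SW-MSA block pair
#'
#' @param C Channel dimension.
#' @param M Window side (default 4).
#' @param heads Attention heads.
#' @param mlp_ratio Hidden width of the MLPs as a multiple of C.
#' @param attention_scale See [attention_params()].
#' @return Parameter list for [block_pair()].
#' @export
block_pair_params <- function(C, M = 4, heads = 1, mlp_ratio = 2,
                              attention_scale = "sqrt") {
  hid <- max(1L, as.integer(round(mlp_ratio * C)))
  mk_mlp <- function() list(fc1 = linear_init(C, hid), fc2 = linear_init(hid, C))
  list(M = as.integer(M), C = as.integer(C),
       ln1 = layernorm_init(C), attn_w = attention_params(C, heads, attention_scale),
       ln2 = layernorm_init(C), mlp1 = mk_mlp(),
       ln3 = layernorm_init(C), attn_sw = attention_params(C, heads, attention_scale),
       ln4 = layernorm_init(C), mlp2 = mk_mlp())
}

mlp_apply <- function(mlp, x) linear_apply(mlp$fc2, ad_gelu(linear_apply(mlp$fc1, x)))

# Tape-level block pair: [LN -> W-MSA -> +] [LN -> MLP -> +]
#                        [LN -> SW-MSA -> +] [LN -> MLP -> +]
block_pair_node <- function(x, h, w, params) {
  x <- as_ad(x)
  M <- params$M
  z <- ad_add(x, window_attention_node(
    ad_layernorm(x, params$ln1$gamma, params$ln1$beta), h, w, M, params$attn_w, 0L))
  z <- ad_add(z, mlp_apply(params$mlp1,
    ad_layernorm(z, params$ln2$gamma, params$ln2$beta)))
  z <- ad_add(z, window_attention_node(
    ad_layernorm(z, params$ln3$gamma, params$ln3$beta), h, w, M, params$attn_sw,
    M %/% 2L))
  ad_add(z, mlp_apply(params$mlp2,
    ad_layernorm(z, params$ln4$gamma, params$ln4$beta)))
}

#' Apply one consecutive W-MSA / SW-MSA transformer block pair
#'
#' Two pre-norm residual sub-blocks: layer norm, window attention, residual,
#' then layer norm, MLP, residual — first with the regular window tiling
#' (W-MSA), then with the shifted tiling (SW-MSA). Shape preserving.
#'
#' @param x A `lesiondet_fmap`.
#' @param params From [block_pair_params()].
#' @return A `lesiondet_fmap` of identical shape.
#' @export
block_pair <- function(x, params) {
  out <- ad_run(block_pair_node(ad_const(x$tokens), x$h, x$w, params))
  feature_map(out, x$h, x$w)
}

#' Attention cost closed forms
#'
#' Floating-point operation counts of global multi-head self-attention and of
#' window attention with M x M windows on an `h x w`, C-channel feature map:
#' `omega_MSA = 4 h w C^2 + 2 (h w)^2 C` and
#' `omega_WMSA = 4 h w C^2 + 2 M^2 h w C`. When one window covers the whole
#' grid (`M^2 = h w`) the two coincide.
#'
#' @param h,w,C,M Positive integers.
#' @return Named numeric vector `c(omega_msa, omega_wmsa)`.
#' @export
attention_cost <- function(h, w, C, M) {
  stopifnot(h > 0, w > 0, C > 0, M > 0)
  hw <- as.numeric(h) * as.numeric(w)
  c(omega_msa = 4 * hw * C^2 + 2 * hw^2 * C,
    omega_wmsa = 4 * hw * C^2 + 2 * M^2 * hw * C)
}

#' Initialise patch-merging parameters (2x2 concat + linear to 2C)
#' @param C Input channel dimension.
#' @return Parameter list for the merge step.
#' @export
patch_merge_params <- function(C) {
  list(C = as.integer(C), proj = linear_init(4 * C, 2 * C))
}

# Tape-level 2x2 patch merging: concat each 2x2 neighborhood's channels and
# project 4C -> 2C; halves h and w.
patch_merge_node <- function(x, h, w, params) {
  if (h %% 2 != 0 || w %% 2 != 0 || h < 2 || w < 2) {
    stopf("grid %dx%d too small or odd for 2x2 patch merging", h, w)
  }
  x <- as_ad(x)
  idx <- matrix(seq_len(h * w), h, w, byrow = TRUE)
  tl <- as.vector(t(idx[seq(1, h, 2), seq(1, w, 2), drop = FALSE]))
  tr <- as.vector(t(idx[seq(1, h, 2), seq(2, w, 2), drop = FALSE]))
  bl <- as.vector(t(idx[seq(2, h, 2), seq(1, w, 2), drop = FALSE]))
  br <- as.vector(t(idx[seq(2, h, 2), seq(2, w, 2), drop = FALSE]))
  cat4 <- ad_cbind(list(ad_gather_rows(x, tl), ad_gather_rows(x, tr),
                        ad_gather_rows(x, bl), ad_gather_rows(x, br)))
  linear_apply(params$proj, cat4)
}

#' Initialise the hierarchical backbone
#'
#' @param patch_dim Flattened patch length (patch_size^2 * channels).
#' @param base_channels Channel width C of the first stage (doubles per stage).
#' @param stage_depths Integer vector: number of block pairs per stage
#'   (length = number of stages, default `c(1, 1, 1)`).
#' @param M Window side (default 4).
#' @param heads Attention heads per block.
#' @param attention_scale `"sqrt"` or `"linear"` score scaling.
#' @param grid_shape `(rows, cols)` of the input patch grid (for the fixed
#'   sin-cos position table).
#' @return Parameter list of class `lesiondet_backbone` for
#'   [hierarchical_forward()].
#' @export
backbone_params <- function(patch_dim, grid_shape, base_channels = 32,
                            stage_depths = c(1, 1, 1), M = 4, heads = 1,
                            attention_scale = "sqrt") {
  S <- length(stage_depths)
  C <- base_channels
  stages <- vector("list", S)
  for (s in seq_len(S)) {
    Cs <- base_channels * 2^(s - 1)
    blocks <- lapply(seq_len(stage_depths[s]), function(i) {
      block_pair_params(Cs, M = M, heads = heads, attention_scale = attention_scale)
    })
    merge <- if (s < S) patch_merge_params(Cs) else NULL
    stages[[s]] <- list(blocks = blocks, merge = merge)
  }
  structure(list(
    proj = linear_init(patch_dim, base_channels),
    pos = position_table(grid_shape[1], grid_shape[2], base_channels),
    grid_shape = as.integer(grid_shape),
    base_channels = as.integer(base_channels),
    stage_depths = as.integer(stage_depths), M = as.integer(M),
    heads = as.integer(heads), attention_scale = attention_scale
  ) |> c(list(stages = stages)), class = "lesiondet_backbone")
}

# Tape-level hierarchical forward; returns list of per-stage token nodes with
# their grid shapes.
hierarchical_forward_node <- function(tokens, params) {
  h <- params$grid_shape[1]; w <- params$grid_shape[2]
  x <- ad_add(linear_apply(params$proj, as_ad(tokens)), ad_const(params$pos))
  outs <- vector("list", length(params$stages))
  for (s in seq_along(params$stages)) {
    st <- params$stages[[s]]
    for (bp in st$blocks) x <- block_pair_node(x, h, w, bp)
    outs[[s]] <- list(node = x, h = h, w = w)
    if (!is.null(st$merge)) {
      x <- patch_merge_node(x, h, w, st$merge)
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  outs
}

#' Run the hierarchical backbone over a patch sequence
#'
#' Projects patch tokens to `base_channels`, adds fixed sin-cos positions, and
#' runs the configured stages of W-MSA/SW-MSA block pairs; after each stage but
#' the last, 2x2 patch merging halves the grid and doubles the channels. Emits
#' every stage's feature map for the detection neck.
#'
#' @param seq A `lesiondet_patchseq` from [patchify()].
#' @param params From [backbone_params()].
#' @return List of `lesiondet_fmap`, one per stage (coarsening resolution,
#'   growing channels).
#' @export
hierarchical_forward <- function(seq, params) {
  if (!identical(as.integer(seq$grid_shape), params$grid_shape)) {
    stopf("patch grid (%d,%d) does not match backbone grid (%d,%d)",
          seq$grid_shape[1], seq$grid_shape[2],
          params$grid_shape[1], params$grid_shape[2])
  }
  outs <- hierarchical_forward_node(ad_const(seq$tokens), params)
  res <- lapply(outs, function(o) feature_map(ad_value(o$node), o$h, o$w))
  ad_tape_reset()
  res
}
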