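# Masked-autoencoder reconstruction pretraining.
#
# Visible patches are embedded and encoded by a stack of standard transformer
# blocks (global attention); the decoder sees the full-length sequence in which
# every masked position holds one shared learnable mask token, adds positional
# embeddings for the whole sequence, and reconstructs pixel values under a mean
# squared error objective. The encoder never sees masked patches.

transformer_block_params <- function(C, heads = 1, mlp_ratio = 2) {
  hid <- max(1L, as.integer(round(mlp_ratio * C)))
  list(ln1 = layernorm_init(C), attn = attention_params(C, heads),
       ln2 = layernorm_init(C),
       mlp = list(fc1 = linear_init(C, hid), fc2 = linear_init(hid, C)))
}

transformer_block_node <- function(x, params) {
  z <- ad_add(x, self_attention_node(
    ad_layernorm(x, params$ln1$gamma, params$ln1$beta), params$attn))
  ad_add(z, mlp_apply(params$mlp, ad_layernorm(z, params$ln2$gamma, params$ln2$beta)))
}

#' Initialise masked-autoencoder parameters
#'
#' @param patch_dim Flattened patch length (patch_size^2 * channels).
#' @param grid_shape `(rows, cols)` patch grid.
#' @param enc_width,enc_depth Encoder width / number of transformer blocks.
#' @param dec_width,dec_depth Decoder width / depth (lighter than the encoder
#'   under the defaults).
#' @param heads Attention heads in both stacks.
#' @return A list of class `lesiondet_mae_params` containing the patch
#'   projection, encoder blocks, encoder-to-decoder projection, the learnable
#'   mask token, decoder blocks, output projection, and fixed position tables.
#' @export
mae_params <- function(patch_dim, grid_shape, enc_width = 64, enc_depth = 2,
                       dec_width = 32, dec_depth = 1, heads = 1) {
  n_pos <- grid_shape[1] * grid_shape[2]
  structure(list(
    patch_proj = linear_init(patch_dim, enc_width),
    enc_pos = position_table(grid_shape[1], grid_shape[2], enc_width),
    enc_blocks = lapply(seq_len(enc_depth), function(i) {
      transformer_block_params(enc_width, heads)
    }),
    enc_to_dec = linear_init(enc_width, dec_width),
    mask_token = ad_param(init_mat(1, dec_width, 0.02)),
    dec_pos = position_table(grid_shape[1], grid_shape[2], dec_width),
    dec_blocks = lapply(seq_len(dec_depth), function(i) {
      transformer_block_params(dec_width, heads)
    }),
    out_proj = linear_init(dec_width, patch_dim),
    grid_shape = as.integer(grid_shape), patch_dim = as.integer(patch_dim),
    enc_width = as.integer(enc_width), dec_width = as.integer(dec_width),
    enc_depth = as.integer(enc_depth), dec_depth = as.integer(dec_depth),
    heads = as.integer(heads)
  ), class = "lesiondet_mae_params")
}

# Tape-level encoder: gather visible rows, project, add their position rows,
# run the block stack. Masked patches cannot influence the output by
# construction (they are dropped before any computation).
encode_visible_node <- function(tokens, plan, params) {
  vis <- plan$visible_idx
  x <- ad_gather_rows(as_ad(tokens), vis)
  x <- linear_apply(params$patch_proj, x)
  x <- ad_add(x, ad_const(params$enc_pos[vis, , drop = FALSE]))
  for (blk in params$enc_blocks) x <- transformer_block_node(x, blk)
  x
}

#' Encode the visible patches of a masked sequence
#'
#' @param seq A `lesiondet_patchseq`.
#' @param plan A `lesiondet_maskplan` consistent with `seq`.
#' @param params From [mae_params()].
#' @return A `|visible_idx|` x `enc_width` latent token matrix.
#' @export
encode_visible <- function(seq, plan, params) {
  n <- nrow(seq$tokens)
  if (length(plan$visible_idx) + length(plan$masked_idx) != n) {
    stopf("mask plan covers %d patches but sequence has %d",
          length(plan$visible_idx) + length(plan$masked_idx), n)
  }
  ad_run(encode_visible_node(ad_const(seq$tokens), plan, params))
}

# Tape-level decoder: project latents to decoder width, fill masked positions
# with the shared mask token, add whole-sequence positions, decode, project to
# pixels.
decode_full_node <- function(latent, plan, params) {
  n <- length(plan$visible_idx) + length(plan$masked_idx)
  n_masked <- length(plan$masked_idx)
  vis_dec <- linear_apply(params$enc_to_dec, as_ad(latent))
  mask_rows <- ad_matmul(ad_const(matrix(1, n_masked, 1)), params$mask_token)
  stacked <- ad_rbind(list(vis_dec, mask_rows))
  # position i of the full sequence -> row in `stacked`
  perm <- integer(n)
  perm[plan$visible_idx] <- seq_along(plan$visible_idx)
  perm[plan$masked_idx] <- length(plan$visible_idx) + seq_len(n_masked)
  x <- ad_gather_rows(stacked, perm)
  x <- ad_add(x, ad_const(params$dec_pos))
  for (blk in params$dec_blocks) x <- transformer_block_node(x, blk)
  linear_apply(params$out_proj, x)
}

#' Decode the full patch sequence from visible latents
#'
#' @param latent `|visible_idx|` x `enc_width` matrix from [encode_visible()].
#' @param plan The `lesiondet_maskplan` used for encoding.
#' @param params From [mae_params()].
#' @return An `n_patches` x `patch_dim` matrix of reconstructed patch pixels.
#' @export
decode_full <- function(latent, plan, params) {
  if (nrow(latent) != length(plan$visible_idx)) {
    stopf("latent has %d rows but plan has %d visible patches",
          nrow(latent), length(plan$visible_idx))
  }
  ad_run(decode_full_node(ad_const(latent), plan, params))
}

#' Mean squared error between predicted and target pixels
#'
#' `value = (1/N) * sum((y - yhat)^2)` with N the total number of pixels.
#'
#' @param pred,target Numeric arrays of identical shape.
#' @return A list of class `lesiondet_recon_loss` with `value` (scalar >= 0)
#'   and `per_pixel` (the squared error components).
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    stopf("pred and target shapes differ")
  }
  per <- (pred - target)^2
  structure(list(value = mean(per), per_pixel = per), class = "lesiondet_recon_loss")
}

#' Count scalar parameters in a nested parameter structure
#' @param params Nested list of `ad` nodes.
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(params) {
  sum(vapply(ad_param_list(params), function(p) length(ad_value(p)), numeric(1)))
}

#' Pretrain a masked autoencoder on a dataset bundle
#'
#' Minimises the reconstruction MSE by Adam over minibatches; the mask is
#' resampled for every image at every epoch. Deterministic given the seed in
#' single-threaded mode.
#'
#' @param data A `lesiondet_bundle` (train split used).
#' @param config List of options; recognised fields (with defaults):
#'   `patch_size` (16), `mask_ratio` (0.75), `enc_width` (64), `enc_depth` (2),
#'   `dec_width` (32), `dec_depth` (1), `heads` (1), `epochs` (30),
#'   `batch_size` (32), `lr` (1e-4), `weight_decay` (5e-4),
#'   `loss_on` ("all" or "masked"; default "all", the literal all-pixels
#'   objective), `seed` (1).
#' @return A list of class `lesiondet_mae`: `params`, `loss_trace` (mean train
#'   loss per epoch), `config`.
#' @export
pretrain <- function(data, config = list()) {
  cfg <- utils::modifyList(list(
    patch_size = 16, mask_ratio = 0.75, enc_width = 64, enc_depth = 2,
    dec_width = 32, dec_depth = 1, heads = 1, epochs = 30, batch_size = 32,
    lr = 1e-4, weight_decay = 5e-4, loss_on = "all", seed = 1
  ), config)
  train <- data$train
  if (length(train) == 0) stopf("empty train split")
  seqs <- lapply(train, function(im) patchify(im$pixels, cfg$patch_size))
  grid <- seqs[[1]]$grid_shape
  n_patches <- nrow(seqs[[1]]$tokens)
  params <- with_seed(derive_seed(cfg$seed, 0), {
    mae_params(ncol(seqs[[1]]$tokens), grid, cfg$enc_width, cfg$enc_depth,
               cfg$dec_width, cfg$dec_depth, cfg$heads)
  })
  opt <- adam_init(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  loss_trace <- numeric(cfg$epochs)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 1000 + ep), sample(length(seqs)))
    ep_losses <- numeric(0)
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      ad_zero_grad(params)
      for (bi in batch) {
        step <- step + 1L
        # one fixed mask per image (deterministic in the image, not the epoch),
        # so a zero-learning-rate run has an exactly constant loss trace
        plan <- sample_mask(n_patches, cfg$mask_ratio,
                            seed = derive_seed(cfg$seed, 7919L + bi))
        latent <- encode_visible_node(ad_const(seqs[[bi]]$tokens), plan, params)
        pred <- decode_full_node(latent, plan, params)
        w <- NULL
        if (cfg$loss_on == "masked") {
          w <- matrix(0, n_patches, ncol(seqs[[bi]]$tokens))
          w[plan$masked_idx, ] <- 1
        }
        loss <- ad_scale(ad_mse(pred, seqs[[bi]]$tokens, weight = w),
                         1 / length(batch))
        if (!is.finite(ad_value(loss))) {
          stopf("pretraining diverged (non-finite loss) at epoch %d", ep)
        }
        ad_backward(loss)
        ep_losses <- c(ep_losses, ad_value(loss) * length(batch))
      }
      opt <- adam_step(opt)
    }
    loss_trace[ep] <- mean(ep_losses)
  }
  structure(list(params = params, loss_trace = loss_trace, config = cfg),
            class = "lesiondet_mae")
}

#' Reconstruct an image through the masked autoencoder
#'
#' Runs one encode/decode pass under a fresh mask and returns the
#' reconstructed pixels (the denoised-image wire-up between the pretraining
#' stage and the backbone).
#'
#' @param image A `lesiondet_image` (or plain pixel matrix).
#' @param mae A `lesiondet_mae` from [pretrain()].
#' @param seed Seed for the mask draw.
#' @return Pixel matrix of the reconstruction (same shape as the input).
#' @export
reconstruct_image <- function(image, mae, seed = 1) {
  px <- if (inherits(image, "lesiondet_image")) image$pixels else image
  seq <- patchify(px, mae$config$patch_size)
  plan <- sample_mask(nrow(seq$tokens), mae$config$mask_ratio, seed = seed)
  latent <- encode_visible(seq, plan, mae$params)
  rec <- decode_full(latent, plan, mae$params)
  seq$tokens <- rec
  unpatchify(seq)
}
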