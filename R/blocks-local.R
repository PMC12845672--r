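# Convolutional feature-extraction blocks: channel shuffle, Enhanced Spatial
# Attention (ESA), residual local feature extraction (RLFE) units, Reverse
# Residual Attention Fusion (RRAF) blocks, and Pixel-Channel Attention (PCA).
#
# A feature map is a numeric array [H, W, C] of normalized intensities.

#' Configuration for the local (convolutional) blocks
#'
#' @param channels Number of feature channels `C`.
#' @param rlfe_per_rraf Number of RLFE units aggregated by one RRAF block.
#' @param shuffle_groups Channel-shuffle group count; must divide `channels`.
#' @param esa_reduction Channel reduction factor inside ESA; must divide
#'   `channels`.
#' @param esa_dilations Two dilation rates for the ESA context convolutions.
#' @param rlfe_cascade If `TRUE` (default) the K RLFE units are applied as a
#'   cascade on the running state; if `FALSE` they act in parallel on the
#'   block input.
#' @return A `local_block_config` list.
#' @export
local_block_config <- function(channels = 64L, rlfe_per_rraf = 4L,
                               shuffle_groups = 2L, esa_reduction = 4L,
                               esa_dilations = c(1L, 2L), rlfe_cascade = TRUE) {
  stopifnot(channels >= 1, rlfe_per_rraf >= 1)
  if (channels %% shuffle_groups != 0)
    stop("shuffle_groups (", shuffle_groups, ") must divide channels (", channels, ")")
  if (channels %% esa_reduction != 0)
    stop("esa_reduction (", esa_reduction, ") must divide channels (", channels, ")")
  structure(list(channels = as.integer(channels),
                 rlfe_per_rraf = as.integer(rlfe_per_rraf),
                 shuffle_groups = as.integer(shuffle_groups),
                 esa_reduction = as.integer(esa_reduction),
                 esa_dilations = as.integer(esa_dilations),
                 rlfe_cascade = isTRUE(rlfe_cascade)),
            class = "local_block_config")
}

#' Forward pass through a network block
#'
#' @param block A block object created by one of the `*_block()` constructors
#'   or [charms_model()].
#' @param x Input: a `[H, W, C]` feature array (or, for a full model, an
#'   `[H, W]` slice).
#' @param ... Passed to methods.
#' @return The block output as a plain array.
#' @export
forward <- function(block, x, ...) UseMethod("forward")

# internal: forward on autograd nodes
node_fwd <- function(block, x) block$fwd(block, x)

run_block <- function(block, x) {
  if (length(dim(x)) != 3L) stop("expected a [H, W, C] feature array")
  if (any(!is.finite(x))) stop("non-finite values in block input")
  vof(block$fwd(block, ag_input(x)))
}

#' @export
forward.charms_block <- function(block, x, ...) run_block(block, x)

#' Channel shuffle
#'
#' Permutes the channel axis by reshaping `C = groups * (C/groups)`,
#' transposing, and flattening, so that channels from different groups are
#' interleaved. With `groups = 1` this is the identity; the permutation is a
#' bijection whose inverse is [channel_shuffle_perm()] with the complementary
#' grouping.
#'
#' @param x A `[H, W, C]` feature array.
#' @param groups Number of groups; must divide `C`.
#' @return The shuffled array, same shape, values permuted channelwise.
#' @export
channel_shuffle <- function(x, groups) {
  d <- dim(x)
  perm <- channel_shuffle_perm(d[3], groups)
  x[, , perm, drop = FALSE]
}

#' Channel-shuffle permutation
#'
#' @param channels Number of channels.
#' @param groups Group count; must divide `channels`.
#' @return An integer permutation `p` such that output channel `i` is input
#'   channel `p[i]`.
#' @export
channel_shuffle_perm <- function(channels, groups) {
  if (channels %% groups != 0)
    stop("groups (", groups, ") must divide the channel count (", channels, ")")
  as.vector(matrix(seq_len(channels), nrow = groups, byrow = TRUE))
}

# ---------------------------------------------------------------------------
# ESA: channel-reduce -> strided 3x3 max pooling -> dilated 3x3 convs
# (rates 1 and 2) -> bilinear interpolation back -> 1-channel recovery ->
# sigmoid. Yields a single-channel spatial gate in (0,1), broadcast over
# channels by the caller. Attention-branch convolutions are bias-free.
# ---------------------------------------------------------------------------

#' Enhanced Spatial Attention block
#'
#' @param cfg A [local_block_config()].
#' @return An `esa_block`; `forward()` maps `[H, W, C]` to a `[H, W, 1]`
#'   attention map with entries strictly inside (0, 1).
#' @export
esa_block <- function(cfg = local_block_config()) {
  C <- cfg$channels; Cr <- C %/% cfg$esa_reduction
  b <- list(
    cfg = cfg,
    reduce = layer_conv2d(C, Cr, k = 1L, pad = 0L, bias = FALSE, name = "esa.reduce"),
    d1 = layer_conv2d(Cr, Cr, k = 3L, dilation = cfg$esa_dilations[1], bias = FALSE, name = "esa.d1"),
    d2 = layer_conv2d(Cr, Cr, k = 3L, dilation = cfg$esa_dilations[2], bias = FALSE, name = "esa.d2"),
    recover = layer_conv2d(Cr, 1L, k = 1L, pad = 0L, bias = FALSE, name = "esa.recover"),
    fwd = function(self, x) {
      d <- dim(vof(x))
      if (d[1] < 4L || d[2] < 4L)
        stop("ESA requires spatial dims >= 4 (got ", d[1], "x", d[2],
             "); refusing to pool smaller inputs")
      h <- conv_fwd(self$reduce, x)
      h <- ag_maxpool(h)
      h <- conv_fwd(self$d1, h)
      h <- conv_fwd(self$d2, h)
      h <- ag_bilinear(h, d[1], d[2])
      h <- conv_fwd(self$recover, h)
      ag_sigmoid(h)
    }
  )
  class(b) <- c("esa_block", "charms_block")
  b
}

#' Residual local feature extraction (RLFE) unit
#'
#' Two 3x3 convolutions with a ReLU between them, gated by the ESA spatial
#' attention map: `eps(F) = A_s(F') ⊙ F'` with `F' = conv(relu(conv(F)))`.
#'
#' @param cfg A [local_block_config()].
#' @return An `rlfe_unit` block preserving the `[H, W, C]` shape.
#' @export
rlfe_unit <- function(cfg = local_block_config()) {
  C <- cfg$channels
  b <- list(
    cfg = cfg,
    conv1 = layer_conv2d(C, C, k = 3L, name = "rlfe.conv1"),
    conv2 = layer_conv2d(C, C, k = 3L, name = "rlfe.conv2"),
    esa = esa_block(cfg),
    fwd = function(self, x) {
      if (dim(vof(x))[3] != self$cfg$channels)
        stop("RLFE configured for ", self$cfg$channels, " channels, got ",
             dim(vof(x))[3])
      h <- conv_fwd(self$conv2, ag_relu(conv_fwd(self$conv1, x)))
      map <- self$esa$fwd(self$esa, h)
      ag_mul_spatial(h, map)
    }
  )
  class(b) <- c("rlfe_unit", "charms_block")
  b
}

#' Reverse Residual Attention Fusion (RRAF) block
#'
#' Aggregates K RLFE units over a residual trunk and finishes with a channel
#' shuffle: `F_out = Shuffle(F_in + sum_k eps_k(F_{k-1}))` with `F_0 = F_in`
#' in the cascaded form (default), or `eps_k(F_in)` in the parallel form.
#' With all RLFE weights zero the block reduces exactly to the channel
#' shuffle of its input.
#'
#' @param cfg A [local_block_config()].
#' @param shuffle Apply the channel shuffle (disabled in the ablation
#'   baseline).
#' @return An `rraf_block` preserving the `[H, W, C]` shape.
#' @export
rraf_block <- function(cfg = local_block_config(), shuffle = TRUE) {
  b <- list(
    cfg = cfg,
    units = lapply(seq_len(cfg$rlfe_per_rraf), function(i) rlfe_unit(cfg)),
    shuffle = isTRUE(shuffle),
    fwd = function(self, x) {
      acc <- x
      state <- x
      for (u in self$units) {
        eps <- u$fwd(u, state)
        acc <- ag_add(acc, eps)
        if (self$cfg$rlfe_cascade) state <- acc
      }
      if (self$shuffle)
        acc <- ag_permute_channels(acc, channel_shuffle_perm(self$cfg$channels,
                                                             self$cfg$shuffle_groups))
      acc
    }
  )
  class(b) <- c("rraf_block", "charms_block")
  b
}

# ---------------------------------------------------------------------------
# PCA: pixel attention (1x1 -> sigmoid, one spatial map) plus channel
# attention (global average pool -> two 1x1 layers -> sigmoid, one weight per
# channel), combined as the half-sum so the result stays in [0, 1].
# The module is residual: a 3x3 feature transform and a 1x1 fusion are wrapped
# around the gating, both additive, so a zero-weight module reduces to
# 0.5 * input exactly.
# ---------------------------------------------------------------------------

#' Pixel-Channel Attention (PCA) block
#'
#' Joint per-pixel and per-channel recalibration. The combined attention is
#' `A = (A_p + A_c) / 2`, guaranteed inside `[0, 1]` because both summands
#' are sigmoid outputs; the output is `G + fuse(G)` with
#' `G = (F + conv(F)) ⊙ A`.
#'
#' @param cfg A [local_block_config()].
#' @return A `pca_block` preserving the `[H, W, C]` shape.
#' @export
pca_block <- function(cfg = local_block_config()) {
  C <- cfg$channels
  b <- list(
    cfg = cfg,
    transform = layer_conv2d(C, C, k = 3L, name = "pca.transform"),
    pixel = layer_conv2d(C, 1L, k = 1L, pad = 0L, bias = FALSE, name = "pca.pixel"),
    ch1 = layer_conv2d(C, C, k = 1L, pad = 0L, bias = FALSE, name = "pca.ch1"),
    ch2 = layer_conv2d(C, C, k = 1L, pad = 0L, bias = FALSE, name = "pca.ch2"),
    fuse = layer_conv2d(C, C, k = 1L, pad = 0L, name = "pca.fuse"),
    fwd = function(self, x) {
      h <- ag_add(x, conv_fwd(self$transform, x))
      d <- dim(vof(h))
      ap <- ag_sigmoid(conv_fwd(self$pixel, h))                 # [H,W,1]
      s <- ag_gap(h)                                            # [1,1,C]
      ac <- ag_sigmoid(conv_fwd(self$ch2, ag_relu(conv_fwd(self$ch1, s))))
      a <- ag_scale(ag_add_maps(ap, ac, d[1], d[2], d[3]), 0.5) # [H,W,C] in [0,1]
      g <- ag_mul(h, a)
      ag_add(g, conv_fwd(self$fuse, g))
    }
  )
  class(b) <- c("pca_block", "charms_block")
  b
}

#' Pixel and channel attention maps of a PCA block
#'
#' Exposes the intermediate `A_p` (pixel, `[H, W, 1]`), `A_c` (channel,
#' `[1, 1, C]`) and combined `A = (A_p + A_c)/2` maps for inspection.
#'
#' @param block A [pca_block()].
#' @param x A `[H, W, C]` feature array.
#' @return A list with elements `pixel_map`, `channel_map`, `combined`.
#' @export
pca_attention_maps <- function(block, x) {
  h <- x + vof(conv_fwd(block$transform, ag_input(x)))
  d <- dim(h)
  ap <- vof(ag_sigmoid(conv_fwd(block$pixel, ag_input(h))))
  s <- vof(ag_gap(ag_input(h)))
  ac <- vof(ag_sigmoid(conv_fwd(block$ch2, ag_relu(conv_fwd(block$ch1, ag_input(s))))))
  comb <- 0.5 * (array(ap, dim = d) + array(rep(as.vector(ac), each = d[1] * d[2]), dim = d))
  list(pixel_map = ap, channel_map = ac, combined = comb)
}
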