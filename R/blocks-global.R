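# Lightweight Transformer stage: Multi-Depthwise Dilated Transformer
# Attention (MDDTA) and the Gated Depthwise Dilated Feed-Forward Network
# (GDDFN), composed with residual skips.
#
# Attention is computed channel-wise ("transposed" attention): queries and
# keys are reshaped to [H*W, C] and contracted over positions, giving a
# [C, C] row-stochastic matrix per dilation head. Cost is linear in the
# pixel count and quadratic in C, which is what makes the stage affordable
# at MRI slice resolutions.

#' Configuration for the MDDTA attention stage
#'
#' @param channels Feature channels `C`.
#' @param dilation_rates Dilations of the depthwise context convolutions,
#'   one attention head per rate.
#' @param temperature_init Initial softmax temperature; stored on a log
#'   scale so the learned temperature stays positive. Defaults to `sqrt(C)`.
#' @return An `mddta_config` list.
#' @export
mddta_config <- function(channels = 64L, dilation_rates = c(1L, 2L, 3L),
                         temperature_init = sqrt(channels)) {
  stopifnot(channels >= 1, length(dilation_rates) >= 1, temperature_init > 0)
  structure(list(channels = as.integer(channels),
                 dilation_rates = as.integer(dilation_rates),
                 temperature_init = temperature_init),
            class = "mddta_config")
}

#' Configuration for the GDDFN feed-forward stage
#'
#' @param channels Feature channels `C`.
#' @param expansion Width multiplier: the entry 1x1 convolution expands to
#'   `2 * expansion * C` channels before the gated split. `expansion * C`
#'   must be a whole number.
#' @param dilation Dilation of the depthwise 3x3 convolutions.
#' @return A `gddfn_config` list.
#' @export
gddfn_config <- function(channels = 64L, expansion = 0.5, dilation = 2L) {
  hidden <- channels * expansion
  if (abs(hidden - round(hidden)) > 1e-9)
    stop("expansion * channels must be an integer (got ", hidden, ")")
  structure(list(channels = as.integer(channels), expansion = expansion,
                 hidden = as.integer(round(hidden)), dilation = as.integer(dilation)),
            class = "gddfn_config")
}

#' Multi-Depthwise Dilated Transformer Attention (MDDTA) block
#'
#' A shared bias-free 1x1 projection produces query, key and value stacks;
#' each dilation head refines them with depthwise 3x3 convolutions at its
#' rate, then channel-wise attention `softmax(Q^T K / d)` (a `[C, C]`
#' matrix) reweights the values. Head outputs are combined with learned
#' scalar weights and passed through a 1x1 output projection, so a
#' zero-initialized output projection makes the block contribute nothing.
#'
#' @param cfg An [mddta_config()].
#' @return An `mddta_block` preserving the `[H, W, C]` shape.
#' @export
mddta_block <- function(cfg = mddta_config()) {
  C <- cfg$channels
  nr <- length(cfg$dilation_rates)
  heads <- lapply(cfg$dilation_rates, function(r) list(
    dq = layer_conv2d(C, C, k = 3L, dilation = r, groups = C, bias = FALSE,
                      name = sprintf("mddta.r%d.dq", r)),
    dk = layer_conv2d(C, C, k = 3L, dilation = r, groups = C, bias = FALSE,
                      name = sprintf("mddta.r%d.dk", r)),
    dv = layer_conv2d(C, C, k = 3L, dilation = r, groups = C, bias = FALSE,
                      name = sprintf("mddta.r%d.dv", r)),
    w = ag_param(array(1 / nr, 1L), sprintf("mddta.r%d.w", r))
  ))
  b <- list(
    cfg = cfg,
    qkv = layer_conv2d(C, 3L * C, k = 1L, pad = 0L, bias = FALSE, name = "mddta.qkv"),
    heads = heads,
    log_d = ag_param(array(log(cfg$temperature_init), 1L), "mddta.log_d"),
    out = layer_conv2d(C, C, k = 1L, pad = 0L, name = "mddta.out"),
    fwd = function(self, x) mddta_fwd(self, x)$out
  )
  class(b) <- c("mddta_block", "charms_block")
  b
}

mddta_fwd <- function(self, x) {
  C <- self$cfg$channels
  d <- dim(vof(x))
  qkv <- conv_fwd(self$qkv, x)
  q0 <- ag_slice_c(qkv, seq_len(C))
  k0 <- ag_slice_c(qkv, C + seq_len(C))
  v0 <- ag_slice_c(qkv, 2L * C + seq_len(C))
  temp <- ag_exp(self$log_d)
  acc <- NULL
  maps <- list()
  for (h in self$heads) {
    qm <- ag_as_matrix(conv_fwd(h$dq, q0))   # [HW, C]
    km <- ag_as_matrix(conv_fwd(h$dk, k0))
    vm <- ag_as_matrix(conv_fwd(h$dv, v0))
    logits <- ag_div_node(ag_mm(qm, km, ta = TRUE), temp)  # [C, C]
    if (any(!is.finite(vof(logits))))
      stop("non-finite attention logits; the learned temperature may have collapsed")
    a <- ag_softmax_rows(logits)
    maps[[length(maps) + 1L]] <- a
    o <- ag_scale_node(ag_mm(vm, a, tb = TRUE), h$w)       # [HW, C]
    acc <- if (is.null(acc)) o else ag_add(acc, o)
  }
  feat <- ag_as_fmap(acc, d[1], d[2])
  # maps holds the live post-softmax nodes; vof() detaches them for callers
  list(out = conv_fwd(self$out, feat), maps = maps)
}

#' Post-softmax attention matrices of an MDDTA block
#'
#' Returns one row-stochastic `[C, C]` matrix per dilation head, as used by
#' the attention regularizer and for visualization.
#'
#' @param block An [mddta_block()] (or a model containing transformer
#'   blocks, in which case all heads of all blocks are returned).
#' @param x The block input `[H, W, C]` array (or LR slice for a model).
#' @return List of `[C, C]` matrices.
#' @export
collect_attention_maps <- function(block, x) UseMethod("collect_attention_maps")

#' @export
collect_attention_maps.mddta_block <- function(block, x) {
  lapply(mddta_fwd(block, ag_input(x))$maps, vof)
}

#' Analytic FLOP count of the MDDTA stage
#'
#' Multiply-add = 2 FLOPs convention: shared projection and per-head
#' depthwise convolutions are linear in the pixel count; the two `[C, C]`
#' contractions cost `2 C^2 H W` each, also linear in pixels and quadratic
#' in channels.
#'
#' @param cfg An [mddta_config()].
#' @param height,width Feature-map size.
#' @return Total FLOPs (numeric).
#' @export
mddta_flops <- function(cfg, height, width) {
  C <- cfg$channels
  hw <- height * width
  nr <- length(cfg$dilation_rates)
  2 * C * 3 * C * hw +                 # shared 1x1 projection
    nr * 3 * 2 * 9 * C * hw +          # depthwise 3x3 refinements
    nr * 2 * (2 * C^2 * hw) +          # Q^T K and A V contractions
    2 * C * C * hw                     # output projection
}

#' Gated Depthwise Dilated Feed-Forward Network (GDDFN) block
#'
#' Expands with a 1x1 convolution to `2 * expansion * C` channels, splits
#' into two branches refined by dilated depthwise 3x3 convolutions, gates
#' one branch with GELU of the other, and projects back with a 1x1
#' convolution.
#'
#' @param cfg A [gddfn_config()].
#' @return A `gddfn_block` preserving the `[H, W, C]` shape.
#' @export
gddfn_block <- function(cfg = gddfn_config()) {
  C <- cfg$channels; Hd <- cfg$hidden
  b <- list(
    cfg = cfg,
    expand = layer_conv2d(C, 2L * Hd, k = 1L, pad = 0L, bias = FALSE, name = "gddfn.expand"),
    d1 = layer_conv2d(Hd, Hd, k = 3L, dilation = cfg$dilation, groups = Hd,
                      bias = FALSE, name = "gddfn.d1"),
    d2 = layer_conv2d(Hd, Hd, k = 3L, dilation = cfg$dilation, groups = Hd,
                      bias = FALSE, name = "gddfn.d2"),
    proj = layer_conv2d(Hd, C, k = 1L, pad = 0L, name = "gddfn.proj"),
    fwd = function(self, x) {
      h <- conv_fwd(self$expand, x)
      f1 <- ag_slice_c(h, seq_len(self$cfg$hidden))
      f2 <- ag_slice_c(h, self$cfg$hidden + seq_len(self$cfg$hidden))
      gated <- ag_mul(ag_gelu(conv_fwd(self$d1, f1)), conv_fwd(self$d2, f2))
      conv_fwd(self$proj, gated)
    }
  )
  class(b) <- c("gddfn_block", "charms_block")
  b
}

#' Transformer block: MDDTA + GDDFN with residual skips
#'
#' `F_t = MDDTA(F) + F; out = GDDFN(F_t) + F_t`. With zero-initialized
#' output projections the block is the identity map.
#'
#' @param mcfg An [mddta_config()].
#' @param gcfg A [gddfn_config()]; channel counts must agree.
#' @return A `transformer_block` preserving the `[H, W, C]` shape.
#' @export
transformer_block <- function(mcfg = mddta_config(), gcfg = gddfn_config(channels = mcfg$channels)) {
  stopifnot(mcfg$channels == gcfg$channels)
  b <- list(
    mddta = mddta_block(mcfg),
    gddfn = gddfn_block(gcfg),
    fwd = function(self, x) {
      ft <- ag_add(self$mddta$fwd(self$mddta, x), x)
      ag_add(self$gddfn$fwd(self$gddfn, ft), ft)
    }
  )
  class(b) <- c("transformer_block", "charms_block")
  b
}

#' @export
collect_attention_maps.transformer_block <- function(block, x) {
  lapply(mddta_fwd(block$mddta, ag_input(x))$maps, vof)
}
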