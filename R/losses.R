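# Training objectives: L1 reconstruction, SSIM term, attention
# regularization, and the composite fine-tuning loss
# L = lambda1 * L1 + lambda2 * (1 - SSIM) + lambda3 * L_AR.

#' Loss weights for the composite objective
#'
#' @param lambda1 Weight of the L1 reconstruction term (default 1).
#' @param lambda2 Weight of the `1 - SSIM` structural term (default 0.1).
#' @param lambda3 Weight of the attention-regularization penalty
#'   (default 0.005).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 0.1, lambda3 = 0.005) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Mean absolute error
#'
#' @param pred,target Numeric arrays of equal shape.
#' @return Non-negative scalar.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("l1_loss: shape mismatch")
  mean(abs(pred - target))
}

#' Structural-similarity loss term
#'
#' `1 - SSIM(pred, target)` using the package's windowed SSIM.
#'
#' @inheritParams l1_loss
#' @param data_range Dynamic range (1 after normalization).
#' @return Scalar in `[0, 2]`.
#' @export
ssim_term <- function(pred, target, data_range = 1) {
  1 - ssim(pred, target, data_range = data_range)
}

# -- attention-regularizer registry -----------------------------------------

.ar_registry <- new.env(parent = emptyenv())

#' Register or fetch an attention-regularizer variant
#'
#' Variants are functions taking a list of row-stochastic `[C, C]`
#' matrices and returning a non-negative scalar. The default
#' `"entropy_decor"` variant combines mean row entropy (penalizing diffuse
#' attention) and mean pairwise cosine similarity between heads
#' (penalizing redundant heads), equally weighted; `"entropy"` uses the
#' entropy term alone.
#'
#' @param name Variant name.
#' @param fn For `ar_register()`, the variant function.
#' @return `ar_get()` returns the registered function.
#' @export
ar_register <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .ar_registry)
  invisible(name)
}

#' @rdname ar_register
#' @export
ar_get <- function(name) {
  if (!exists(name, envir = .ar_registry, inherits = FALSE))
    stop("unknown attention-regularizer variant '", name, "'")
  get(name, envir = .ar_registry, inherits = FALSE)
}

check_stochastic <- function(maps) {
  for (m in maps) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-6))
      stop("attention matrices must be row-stochastic with non-negative entries")
  }
  invisible(TRUE)
}

row_entropy_mean <- function(maps) {
  mean(vapply(maps, function(m) {
    p <- pmax(m, 0)
    mean(rowSums(ifelse(p > 0, -p * log(p), 0)))
  }, numeric(1)))
}

head_cosine_mean <- function(maps) {
  if (length(maps) < 2L) return(0)
  pairs <- utils::combn(length(maps), 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- as.vector(maps[[ij[1]]]); b <- as.vector(maps[[ij[2]]])
    sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }))
}

#' Attention-regularization penalty
#'
#' Operationalizes two pressures on the transformer's channel-attention
#' matrices: sparsity (mean row entropy, zero for one-hot rows, `log C`
#' for uniform rows) and head diversity (mean pairwise cosine similarity
#' between flattened head matrices, 1 for identical heads). The default
#' variant sums the two with equal weight.
#'
#' @param maps List of row-stochastic `[C, C]` attention matrices (one per
#'   dilation head per transformer block), e.g. from
#'   [collect_attention_maps()].
#' @param variant Registered variant name (see [ar_register()]).
#' @return Non-negative scalar.
#' @export
attention_regularizer <- function(maps, variant = "entropy_decor") {
  check_stochastic(maps)
  ar_get(variant)(maps)
}

#' Composite training loss
#'
#' `lambda1 * L1 + lambda2 * (1 - SSIM) + lambda3 * L_AR`, with the
#' per-term breakdown returned for logging.
#'
#' @inheritParams l1_loss
#' @param maps Attention matrices for the regularizer (may be an empty
#'   list, in which case the AR term is 0).
#' @param w A [loss_weights()].
#' @param ar_variant Regularizer variant name.
#' @return A list with `total` and the `breakdown` vector
#'   `(l1, ssim, ar)`.
#' @export
composite_loss <- function(pred, target, maps = list(), w = loss_weights(),
                           ar_variant = "entropy_decor") {
  br <- c(l1 = l1_loss(pred, target),
          ssim = ssim_term(pred, target),
          ar = if (length(maps) && w$lambda3 > 0)
            attention_regularizer(maps, ar_variant) else 0)
  list(total = w$lambda1 * br[["l1"]] + w$lambda2 * br[["ssim"]] +
         w$lambda3 * br[["ar"]],
       breakdown = br)
}

# -- autograd twins (used by the trainer) -----------------------------------

loss_l1_node <- function(pred, target) {
  ag_mean(ag_abs(ag_sub(pred, ag_input(target))))
}

loss_ssim_node <- function(pred, target, data_range = 1) {
  win <- array(gaussian_window(), dim = c(11L, 11L, 1L, 1L))
  wlay <- list(kind = "conv2d", w = ag_param(win, "ssim.win"), b = NULL,
               k = 11L, stride = 1L, pad = 0L, dilation = 1L, groups = 1L)
  wlay$w$trainable <- FALSE
  cv <- function(z) ag_conv2d(z, wlay$w, NULL, stride = 1L, pad = 0L)
  tgt <- ag_input(array(target, dim = dim(vof(pred))))
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  mu_a <- cv(pred); mu_b <- cv(tgt)
  va <- ag_sub(cv(ag_mul(pred, pred)), ag_mul(mu_a, mu_a))
  vb <- ag_sub(cv(ag_mul(tgt, tgt)), ag_mul(mu_b, mu_b))
  vab <- ag_sub(cv(ag_mul(pred, tgt)), ag_mul(mu_a, mu_b))
  num <- ag_mul(ag_shift(ag_scale(ag_mul(mu_a, mu_b), 2), c1),
                ag_shift(ag_scale(vab, 2), c2))
  den <- ag_mul(ag_shift(ag_add(ag_mul(mu_a, mu_a), ag_mul(mu_b, mu_b)), c1),
                ag_shift(ag_add(va, vb), c2))
  ag_shift(ag_scale(ag_mean(ag_div(num, den)), -1), 1)   # 1 - mean SSIM
}

# entropy + head-decorrelation on live attention nodes
loss_ar_node <- function(map_nodes, variant = "entropy_decor") {
  eps <- 1e-12
  ent <- NULL
  for (m in map_nodes) {
    C <- nrow(vof(m))
    e <- ag_scale(ag_sum(ag_mul(m, ag_log(ag_shift(m, eps)))), -1 / C)
    ent <- if (is.null(ent)) e else ag_add(ent, e)
  }
  ent <- ag_scale(ent, 1 / length(map_nodes))
  if (variant == "entropy" || length(map_nodes) < 2L) return(ent)
  pairs <- utils::combn(length(map_nodes), 2L)
  cs <- NULL
  for (j in seq_len(ncol(pairs))) {
    a <- map_nodes[[pairs[1, j]]]; b <- map_nodes[[pairs[2, j]]]
    num <- ag_sum(ag_mul(a, b))
    den <- ag_mul(ag_sqrt(ag_sum(ag_mul(a, a))), ag_sqrt(ag_sum(ag_mul(b, b))))
    s <- ag_div(num, den)
    cs <- if (is.null(cs)) s else ag_add(cs, s)
  }
  ag_add(ent, ag_scale(cs, 1 / ncol(pairs)))
}

composite_loss_node <- function(pred, target, map_nodes, w,
                                ar_variant = "entropy_decor") {
  total <- ag_scale(loss_l1_node(pred, target), w$lambda1)
  if (w$lambda2 > 0)
    total <- ag_add(total, ag_scale(loss_ssim_node(pred, target), w$lambda2))
  if (w$lambda3 > 0 && length(map_nodes))
    total <- ag_add(total, ag_scale(loss_ar_node(map_nodes, ar_variant), w$lambda3))
  total
}

ar_register("entropy_decor", function(maps) row_entropy_mean(maps) + head_cosine_mean(maps))
ar_register("entropy", function(maps) row_entropy_mean(maps))
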