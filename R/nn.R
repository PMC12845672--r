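# Minimal layer library on top of the autograd engine. Layers are lists
# holding `ag_param` environments plus metadata; blocks compose them.

# Kaiming-uniform bound with a = sqrt(5), the standard convolution default;
# keeps activations O(1) through the deeply cascaded residual trunk.
kaiming_bound <- function(fan_in) 1 / sqrt(fan_in)

#' @keywords internal
layer_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                         dilation = 1L, groups = 1L, bias = TRUE, name = "conv") {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("groups (", groups, ") must divide both cin (", cin, ") and cout (", cout, ")")
  cing <- cin %/% groups
  fan_in <- k * k * cing
  w <- array(stats::runif(k * k * cing * cout, -kaiming_bound(fan_in), kaiming_bound(fan_in)),
             dim = c(k, k, cing, cout))
  lay <- list(
    kind = "conv2d", w = ag_param(w, paste0(name, ".w")),
    b = if (bias) ag_param(rep(0, cout), paste0(name, ".b")) else NULL,
    cin = cin, cout = cout, k = k, stride = stride, pad = pad,
    dilation = dilation, groups = groups, name = name
  )
  class(lay) <- "charms_layer"
  lay
}

conv_fwd <- function(lay, x) {
  pad <- if (lay$dilation > 1L) lay$dilation * (lay$k - 1L) %/% 2L else lay$pad
  ag_conv2d(x, lay$w, lay$b, stride = lay$stride, pad = pad,
            dilation = lay$dilation, groups = lay$groups)
}

#' Collect trainable parameters of a layer, block or model
#'
#' Walks a nested block structure and returns every `ag_param` environment
#' exactly once, in a stable order.
#'
#' @param x A layer, block, or assembled model.
#' @return A list of parameter environments.
#' @export
parameters <- function(x) {
  out <- list()
  walk <- function(el) {
    if (is_param(el)) {
      out[[length(out) + 1L]] <<- el
    } else if (is.list(el)) {
      for (sub in el) walk(sub)
    }
  }
  walk(x)
  out
}

#' Number of scalar weights in a block or model
#' @param x A layer, block, or model.
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(x) {
  sum(vapply(parameters(x), function(p) length(p$val), numeric(1)))
}

#' Set every weight of a block or model to zero
#'
#' Useful for verifying the closed-form behaviour of residual and gated
#' blocks (a zero-weight network reduces to its skip connections).
#'
#' @param x A layer, block, or model (modified in place).
#' @return `x`, invisibly.
#' @export
zero_parameters <- function(x) {
  for (p in parameters(x)) p$val <- array(0, dim = dim(p$val) %||% length(p$val))
  invisible(x)
}

set_trainable <- function(x, flag) {
  for (p in parameters(x)) p$trainable <- flag
  invisible(x)
}

# ---------------------------------------------------------------------------
# AdamW optimizer. State lives on the parameter environments.
# ---------------------------------------------------------------------------

adamw_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st <- list(params = params, lr = lr, beta1 = beta1, beta2 = beta2,
             eps = eps, weight_decay = weight_decay, t = 0L)
  for (p in params) { p$m <- NULL; p$v <- NULL }
  st
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (p in opt$params) {
    if (!p$trainable || is.null(p$grad)) next
    g <- p$grad
    p$m <- if (is.null(p$m)) (1 - b1) * g else b1 * p$m + (1 - b1) * g
    p$v <- if (is.null(p$v)) (1 - b2) * g^2 else b2 * p$v + (1 - b2) * g^2
    step <- (p$m / bc1) / (sqrt(p$v / bc2) + opt$eps)
    if (opt$weight_decay > 0) step <- step + opt$weight_decay * p$val
    p$val <- p$val - opt$lr * step
  }
  opt
}

# Flatten / restore weights (checkpointing)
get_state <- function(x) lapply(parameters(x), function(p) p$val)

set_state <- function(x, state) {
  ps <- parameters(x)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$val) == length(state[[i]]))
    ps[[i]]$val <- state[[i]]
  }
  invisible(x)
}

# Scale all gradients so their global L2 norm does not exceed max_norm.
clip_global_norm <- function(params, max_norm) {
  if (!is.finite(max_norm)) return(invisible(NULL))
  tot <- 0
  for (p in params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
  nrm <- sqrt(tot)
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(NULL)
}
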