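#' @useDynLib charms, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation over dense arrays.
#
# Feature maps are numeric arrays [H, W, C]; attention matrices are plain
# matrices; losses are length-1 arrays. A forward pass records every
# operation on a tape (creation order is a topological order), and
# ag_backward() replays it in reverse, accumulating gradients into the
# participating nodes. Model parameters are persistent `ag_param`
# environments that survive across passes; all other nodes are rebuilt each
# forward pass. When recording is off the ops short-circuit to plain value
# computation, which is what inference uses.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- vector("list", 1024L)
.ag$n <- 0L

ag_recording <- function() .ag$recording

ag_begin <- function() {
  .ag$recording <- TRUE
  .ag$n <- 0L
  invisible(NULL)
}

ag_end <- function() {
  .ag$recording <- FALSE
  if (.ag$n > 0L) .ag$tape[seq_len(.ag$n)] <- list(NULL)
  .ag$n <- 0L
  invisible(NULL)
}

ag_push <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

# A value node. `bw` receives the accumulated output gradient.
ag_node <- function(val, bw = NULL) {
  if (!.ag$recording) return(list(val = val))
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$bw <- bw
  class(node) <- "ag_node"
  ag_push(node)
}

#' @keywords internal
ag_param <- function(val, name = "") {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$name <- name
  p$trainable <- TRUE
  class(p) <- "ag_param"
  p
}

is_param <- function(x) inherits(x, "ag_param")
is_node <- function(x) inherits(x, "ag_node") || is_param(x)

# Wrap a constant / input value so ops can consume it uniformly.
ag_input <- function(val) {
  if (.ag$recording) ag_node(val) else list(val = val)
}

ag_accum <- function(x, g) {
  if (is.environment(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the whole tape.
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"))
  loss$grad <- array(1, dim = dim(loss$val) %||% 1L)
  for (i in rev(seq_len(.ag$n))) {
    node <- .ag$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$bw)) node$bw(node$grad)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vof <- function(x) if (is.environment(x) || is.list(x)) x$val else x

# -- elementwise ------------------------------------------------------------

ag_relu <- function(x) {
  v <- vof(x)
  y <- v * (v > 0)
  ag_node_with(y, x, function(g) ag_accum(x, g * (v > 0)))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-vof(x)))
  ag_node_with(s, x, function(g) ag_accum(x, g * s * (1 - s)))
}

ag_gelu <- function(x) {
  v <- vof(x)
  ph <- stats::pnorm(v)
  y <- v * ph
  ag_node_with(y, x, function(g) ag_accum(x, g * (ph + v * stats::dnorm(v))))
}

ag_node_with <- function(val, x, bw) {
  if (!.ag$recording) return(list(val = val))
  ag_node(val, bw)
}

ag_add <- function(a, b) {
  y <- vof(a) + vof(b)
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) { ag_accum(a, g); ag_accum(b, g) })
}

ag_sub <- function(a, b) {
  y <- vof(a) - vof(b)
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) { ag_accum(a, g); ag_accum(b, -g) })
}

ag_mul <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  y <- va * vb
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) { ag_accum(a, g * vb); ag_accum(b, g * va) })
}

ag_div <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  y <- va / vb
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) { ag_accum(a, g / vb); ag_accum(b, -g * va / (vb * vb)) })
}

ag_scale <- function(x, k) {  # k plain numeric
  y <- vof(x) * k
  ag_node_with(y, x, function(g) ag_accum(x, g * k))
}

ag_shift <- function(x, k) {  # x + plain numeric
  y <- vof(x) + k
  ag_node_with(y, x, function(g) ag_accum(x, g))
}

ag_abs <- function(x) {
  v <- vof(x)
  ag_node_with(abs(v), x, function(g) ag_accum(x, g * sign(v)))
}

ag_log <- function(x) {
  v <- vof(x)
  ag_node_with(log(v), x, function(g) ag_accum(x, g / v))
}

ag_sqrt <- function(x) {
  s <- sqrt(vof(x))
  ag_node_with(s, x, function(g) ag_accum(x, g / (2 * s)))
}

ag_exp <- function(x) {
  e <- exp(vof(x))
  ag_node_with(e, x, function(g) ag_accum(x, g * e))
}

ag_mean <- function(x) {
  v <- vof(x)
  n <- length(v)
  ag_node_with(array(mean(v), 1L), x, function(g) ag_accum(x, array(g[1] / n, dim(v) %||% n)))
}

ag_sum <- function(x) {
  v <- vof(x)
  ag_node_with(array(sum(v), 1L), x, function(g) ag_accum(x, array(g[1], dim(v) %||% length(v))))
}

# -- broadcast multiply -----------------------------------------------------

# x [H,W,C] * map [H,W,1] (spatial attention broadcast over channels)
ag_mul_spatial <- function(x, map) {
  vx <- vof(x); vm <- vof(map)
  d <- dim(vx)
  mr <- array(vm, dim = d)  # recycles the [H,W] plane across channels
  y <- vx * mr
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ag_accum(x, g * mr)
    gm <- array(rowSums(matrix(g * vx, d[1] * d[2], d[3])), dim = c(d[1], d[2], 1L))
    ag_accum(map, gm)
  })
}

# x [H,W,C] * s [1,1,C] (channel attention broadcast over positions)
ag_mul_channel <- function(x, s) {
  vx <- vof(x); vs <- vof(s)
  d <- dim(vx)
  sr <- array(rep(as.vector(vs), each = d[1] * d[2]), dim = d)
  y <- vx * sr
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ag_accum(x, g * sr)
    gs <- array(colSums(matrix(g * vx, d[1] * d[2], d[3])), dim = c(1L, 1L, d[3]))
    ag_accum(s, gs)
  })
}

# broadcast add of [H,W,1] and [1,1,C] style maps onto [H,W,C] not needed;
# pixel+channel attention combines a [H,W,1] and a [1,1,C] map directly:
ag_add_maps <- function(p, s, H, W, C) {
  vp <- vof(p); vs <- vof(s)
  y <- array(vp, dim = c(H, W, C)) +
    array(rep(as.vector(vs), each = H * W), dim = c(H, W, C))
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ag_accum(p, array(rowSums(matrix(g, H * W, C)), dim = c(H, W, 1L)))
    ag_accum(s, array(colSums(matrix(g, H * W, C)), dim = c(1L, 1L, C)))
  })
}

# -- structural ops ---------------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 1L, dilation = 1L, groups = 1L) {
  vx <- vof(x)
  y <- cpp_conv2d(vx, w$val, if (is.null(b)) NULL else b$val,
                  as.integer(stride), as.integer(pad), as.integer(dilation),
                  as.integer(groups))
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    need_gx <- inherits(x, "ag_node")
    need_gw <- w$trainable
    gr <- cpp_conv2d_bwd(vx, w$val, g, as.integer(stride), as.integer(pad),
                         as.integer(dilation), as.integer(groups),
                         need_gx, need_gw)
    if (need_gx) ag_accum(x, gr$gx)
    if (need_gw) {
      ag_accum(w, gr$gw)
      if (!is.null(b)) ag_accum(b, gr$gb)
    }
  })
}

ag_maxpool <- function(x) {
  vx <- vof(x)
  r <- cpp_maxpool(vx)
  if (!.ag$recording) return(list(val = r$y))
  d <- dim(vx)
  ag_node(r$y, function(g) ag_accum(x, cpp_maxpool_bwd(g, r$idx, d[1], d[2])))
}

ag_bilinear <- function(x, H, W) {
  vx <- vof(x)
  y <- cpp_bilinear(vx, as.integer(H), as.integer(W))
  if (!.ag$recording) return(list(val = y))
  d <- dim(vx)
  ag_node(y, function(g) ag_accum(x, cpp_bilinear_bwd(g, d[1], d[2])))
}

# Sub-pixel rearrangement [H,W,r^2*C] -> [rH,rW,C], row-major sub-pixel
# convention: output(h*r+i, w*r+j, c) <- input(h, w, (c-1)*r^2 + i*r + j + 1).
pixel_shuffle_val <- function(v, r) {
  d <- dim(v)
  H <- d[1]; W <- d[2]; C <- d[3] %/% (r * r)
  y <- array(0, dim = c(H * r, W * r, C))
  for (i in 0:(r - 1)) for (j in 0:(r - 1)) {
    y[seq.int(i + 1L, H * r, r), seq.int(j + 1L, W * r, r), ] <-
      v[, , (seq_len(C) - 1L) * r * r + i * r + j + 1L]
  }
  y
}

pixel_unshuffle_val <- function(v, r) {
  d <- dim(v)
  H <- d[1] %/% r; W <- d[2] %/% r; C <- d[3]
  y <- array(0, dim = c(H, W, C * r * r))
  for (i in 0:(r - 1)) for (j in 0:(r - 1)) {
    y[, , (seq_len(C) - 1L) * r * r + i * r + j + 1L] <-
      v[seq.int(i + 1L, H * r, r), seq.int(j + 1L, W * r, r), , drop = FALSE]
  }
  y
}

ag_pixel_shuffle <- function(x, r) {
  vx <- vof(x)
  if (r == 1L) return(x)
  y <- pixel_shuffle_val(vx, r)
  ag_node_with(y, x, function(g) ag_accum(x, pixel_unshuffle_val(g, r)))
}

ag_permute_channels <- function(x, perm) {
  vx <- vof(x)
  y <- vx[, , perm, drop = FALSE]
  if (!.ag$recording) return(list(val = y))
  inv <- order(perm)
  ag_node(y, function(g) ag_accum(x, g[, , inv, drop = FALSE]))
}

ag_gap <- function(x) {  # global average pool -> [1,1,C]
  vx <- vof(x)
  d <- dim(vx)
  y <- array(colMeans(matrix(vx, d[1] * d[2], d[3])), dim = c(1L, 1L, d[3]))
  ag_node_with(y, x, function(g)
    ag_accum(x, array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)))
}

ag_concat_c <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  da <- dim(va); db <- dim(vb)
  y <- array(c(va, vb), dim = c(da[1], da[2], da[3] + db[3]))
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ag_accum(a, g[, , seq_len(da[3]), drop = FALSE])
    ag_accum(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ag_slice_c <- function(x, idx) {
  vx <- vof(x)
  y <- vx[, , idx, drop = FALSE]
  if (!.ag$recording) return(list(val = y))
  d <- dim(vx)
  ag_node(y, function(g) {
    gx <- array(0, dim = d)
    gx[, , idx] <- g
    ag_accum(x, gx)
  })
}

# -- matrix ops (channel-wise attention) ------------------------------------

# reshape [H,W,C] -> [H*W, C]
ag_as_matrix <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  y <- matrix(vx, d[1] * d[2], d[3])
  ag_node_with(y, x, function(g) ag_accum(x, array(g, dim = d)))
}

ag_as_fmap <- function(x, H, W) {
  vx <- vof(x)
  y <- array(vx, dim = c(H, W, ncol(vx)))
  ag_node_with(y, x, function(g) ag_accum(x, matrix(g, H * W, dim(vx)[2])))
}

ag_mm <- function(a, b, ta = FALSE, tb = FALSE) {
  va <- vof(a); vb <- vof(b)
  A <- if (ta) t(va) else va
  B <- if (tb) t(vb) else vb
  y <- A %*% B
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ga <- g %*% t(B); if (ta) ga <- t(ga)
    gb <- t(A) %*% g; if (tb) gb <- t(gb)
    ag_accum(a, ga)
    ag_accum(b, gb)
  })
}

# multiply / divide a tensor by a length-1 node (learned scalar)
ag_scale_node <- function(x, s) {
  vx <- vof(x); sv <- as.numeric(vof(s))[1]
  y <- vx * sv
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ag_accum(x, g * sv)
    ag_accum(s, array(sum(g * vx), 1L))
  })
}

ag_div_node <- function(x, s) {
  vx <- vof(x); sv <- as.numeric(vof(s))[1]
  y <- vx / sv
  if (!.ag$recording) return(list(val = y))
  ag_node(y, function(g) {
    ag_accum(x, g / sv)
    ag_accum(s, array(-sum(g * vx) / sv^2, 1L))
  })
}

ag_softmax_rows <- function(x) {
  v <- vof(x)
  m <- v - apply(v, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ag_node_with(s, x, function(g) {
    dot <- rowSums(g * s)
    ag_accum(x, (g - dot) * s)
  })
}
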