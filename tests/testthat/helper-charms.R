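# Shared fixtures: tiny configurations and independent brute-force oracles.

tiny_cfg <- function(channels = 8L, ...) {
  charms_config(scale = 2L, channels = channels, head_channels = channels,
                n_rraf = 1L, rlfe_per_rraf = 1L, ...)
}

rand_fmap <- function(H, W, C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(H * W * C), dim = c(H, W, C))
}

make_pair <- function(hr, r = 2L, subject = "s0", slice = 0L) {
  structure(list(lr = degrade_bicubic(hr, r), hr = hr, scale = as.integer(r),
                 subject_id = subject, slice_index = as.integer(slice)),
            class = "slice_pair")
}

# Direct-summation 2D convolution oracle (zero padding), input [H,W,Cin],
# weights [k,k,Cin/groups,Cout]; deliberately naive.
conv2d_oracle <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1, groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; cing <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, Cout))
  coutg <- Cout %/% groups
  for (co in seq_len(Cout)) {
    g <- (co - 1) %/% coutg
    for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(cing)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        ih <- (oh - 1) * stride - pad + (kh - 1) * dil + 1
        iw <- (ow - 1) * stride - pad + (kw - 1) * dil + 1
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + x[ih, iw, g * cing + ci] * w[kh, kw, ci, co]
      }
      y[oh, ow, co] <- acc
    }
  }
  y
}

# Full (non-separable) antialiased bicubic downsampling oracle: for each LR
# pixel, sum over every HR pixel with the 2D product kernel, clamped edges,
# normalized. Independent of the package's separable matrix implementation.
bicubic_down_oracle <- function(hr, r) {
  cub <- function(t, a = -0.5) {
    at <- abs(t)
    ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
           ifelse(at < 2, a * (at^3 - 5 * at^2 + 8 * at - 4), 0))
  }
  H <- nrow(hr); W <- ncol(hr)
  out <- matrix(0, H %/% r, W %/% r)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    ci <- (i - 0.5) * r - 0.5; cj <- (j - 0.5) * r - 0.5
    ri <- floor(ci - 2 * r + 1):ceiling(ci + 2 * r - 1)
    rj <- floor(cj - 2 * r + 1):ceiling(cj + 2 * r - 1)
    wi <- cub((ri - ci) / r); wj <- cub((rj - cj) / r)
    ric <- pmin(pmax(ri, 0), H - 1) + 1
    rjc <- pmin(pmax(rj, 0), W - 1) + 1
    num <- 0; den <- 0
    for (a in seq_along(ri)) for (b in seq_along(rj)) {
      wgt <- wi[a] * wj[b]
      num <- num + wgt * hr[ric[a], rjc[b]]
      den <- den + wgt
    }
    out[i, j] <- num / den
  }
  out
}

zero_layer <- function(lay) {
  lay$w$val[] <- 0
  if (!is.null(lay$b)) lay$b$val[] <- 0
  invisible(lay)
}

make_identity_mddta <- function(C = 2L, rate = 1L, d = 1) {
  cfg <- mddta_config(channels = C, dilation_rates = rate, temperature_init = d)
  b <- mddta_block(cfg)
  # shared projection copies the input into Q, K and V stacks
  w <- array(0, dim = c(1, 1, C, 3 * C))
  for (c in seq_len(C)) for (s in 0:2) w[1, 1, c, s * C + c] <- 1
  b$qkv$w$val <- w
  # depthwise 3x3 refinements become identities (center tap 1)
  for (h in b$heads) {
    for (nm in c("dq", "dk", "dv")) {
      h[[nm]]$w$val[] <- 0
      h[[nm]]$w$val[2, 2, 1, ] <- 1
    }
    h$w$val[] <- 1
  }
  # output projection identity with zero bias
  b$out$w$val <- array(diag(C), dim = c(1, 1, C, C))
  b$out$b$val[] <- 0
  b
}

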