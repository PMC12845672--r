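# Channel shuffle, ESA, RLFE, RRAF and PCA blocks.

test_that("channel shuffle is the reshape-transpose-flatten permutation", {
  expect_equal(channel_shuffle_perm(4, 2), c(1L, 3L, 2L, 4L))  # (c0,c2,c1,c3)
  x <- rand_fmap(3, 3, 4, seed = 1)
  expect_identical(channel_shuffle(x, 1), x)
  y <- channel_shuffle(x, 2)
  expect_equal(y[, , 2], x[, , 3])
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))        # multiset preserved
  # for C=4, g=2 the permutation is an involution
  expect_identical(channel_shuffle(y, 2), x)
  expect_error(channel_shuffle(x, 3), "divide")
})

test_that("channel shuffle is a bijection invertible for all tested (C, groups)", {
  for (C in c(4, 6, 8, 12, 16)) for (g in c(2, 4)) {
    if (C %% g != 0) next
    x <- rand_fmap(4, 5, C)
    perm <- channel_shuffle_perm(C, g)
    expect_equal(sort(perm), seq_len(C))
    inv <- order(perm)
    y <- x[, , perm, drop = FALSE]
    expect_identical(y[, , inv, drop = FALSE], x)
  }
})

test_that("ESA produces an in-range single-channel sigmoid map", {
  cfg <- local_block_config(channels = 8, esa_reduction = 4)
  set.seed(2)
  b <- esa_block(cfg)
  m <- forward(b, rand_fmap(16, 16, 8))
  expect_equal(dim(m), c(16L, 16L, 1L))
  expect_true(all(m > 0 & m < 1))
  zero_parameters(b)
  m0 <- forward(b, rand_fmap(16, 16, 8))
  expect_equal(as.vector(m0), rep(0.5, 256))                  # sigmoid(0)
  expect_error(forward(b, rand_fmap(3, 3, 8)), "pool")
})

test_that("attention maps lie strictly inside (0,1) over many random inputs", {
  cfg <- local_block_config(channels = 4, esa_reduction = 2)
  set.seed(5)
  esa <- esa_block(cfg)
  pca <- pca_block(cfg)
  ok <- TRUE
  for (i in 1:334) {
    x <- array(rnorm(8 * 8 * 4, sd = 2), dim = c(8, 8, 4))
    m1 <- forward(esa, x)
    maps <- pca_attention_maps(pca, x)
    ok <- ok && all(m1 > 0 & m1 < 1) &&
      all(maps$pixel_map > 0 & maps$pixel_map < 1) &&
      all(maps$channel_map > 0 & maps$channel_map < 1) &&
      all(maps$combined >= 0 & maps$combined <= 1)
  }
  expect_true(ok)
})

test_that("RLFE matches hand-set kernels and propagates zeros", {
  cfg1 <- local_block_config(channels = 1, rlfe_per_rraf = 1,
                             shuffle_groups = 1, esa_reduction = 1)
  set.seed(4)
  u <- rlfe_unit(cfg1)
  x <- rand_fmap(6, 6, 1)
  # independent path: direct convolution oracle + the unit's own ESA map
  h <- conv2d_oracle(x, u$conv1$w$val, u$conv1$b$val, pad = 1)
  h <- h * (h > 0)
  h <- conv2d_oracle(h, u$conv2$w$val, u$conv2$b$val, pad = 1)
  map <- forward(u$esa, h)
  want <- h * array(map, dim = dim(h))
  expect_equal(forward(u, x), want, tolerance = 1e-12)

  zero_parameters(u)
  expect_equal(forward(u, x), array(0, dim = c(6, 6, 1)))
  cfg8 <- local_block_config(channels = 8)
  u8 <- rlfe_unit(cfg8)
  expect_equal(dim(forward(u8, rand_fmap(10, 12, 8))), c(10L, 12L, 8L))
  expect_error(forward(u8, rand_fmap(8, 8, 4)), "channels")
})

test_that("RRAF reduces to channel shuffle with zero weights and composes RLFE", {
  cfg <- local_block_config(channels = 8, rlfe_per_rraf = 4)
  set.seed(6)
  b <- rraf_block(cfg)
  expect_length(b$units, 4L)                         # default K = 4
  x <- rand_fmap(12, 12, 8)
  zero_parameters(b)
  expect_equal(forward(b, x), channel_shuffle(x, 2), tolerance = 0)

  cfg1 <- local_block_config(channels = 2, rlfe_per_rraf = 1,
                             shuffle_groups = 2, esa_reduction = 2)
  b1 <- rraf_block(cfg1)
  x1 <- rand_fmap(6, 6, 2)
  want <- channel_shuffle(x1 + forward(b1$units[[1]], x1), 2)
  expect_equal(forward(b1, x1), want, tolerance = 1e-12)
})

test_that("shape is preserved by every block over random sizes", {
  cfg <- local_block_config(channels = 4, esa_reduction = 2)
  set.seed(8)
  blocks <- list(rraf_block(cfg), pca_block(cfg))
  for (i in 1:6) {
    H <- sample(8:64, 1); W <- sample(8:64, 1)
    x <- rand_fmap(H, W, 4)
    for (b in blocks) expect_equal(dim(forward(b, x)), c(H, W, 4L))
  }
})

test_that("PCA halves the input at zero weights and pools constants uniformly", {
  cfg <- local_block_config(channels = 8)
  set.seed(9)
  b <- pca_block(cfg)
  x <- rand_fmap(10, 10, 8)
  zero_parameters(b)
  expect_equal(forward(b, x), 0.5 * x, tolerance = 1e-15)

  b2 <- pca_block(cfg)
  xc <- array(rep(runif(8), each = 100), dim = c(10, 10, 8))  # spatially constant
  maps <- pca_attention_maps(b2, xc)
  expect_equal(dim(maps$channel_map), c(1L, 1L, 8L))
  # channel attention of a spatially constant input is spatially uniform by
  # construction; combined map varies over channels only through A_c
  rng <- apply(maps$combined - 0.5 * array(maps$pixel_map, dim = dim(maps$combined)),
               3, function(s) diff(range(s)))
  expect_equal(rng, rep(0, 8))
})
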