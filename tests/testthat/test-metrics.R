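# PSNR, SSIM, SNR/CNR, paired testing and aggregation.

test_that("psnr closed forms and infinity flag", {
  a <- matrix(0, 10, 10)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 0.1), 20)        # MSE 0.01
  expect_equal(psnr(a, a + 0.01), 40)       # MSE 1e-4
  expect_error(psnr(a, matrix(0, 5, 5)), "shape")
  # strictly decreasing with noise level on a fixed phantom slice
  ph <- generate_phantom(phantom_spec(shape = c(4L, 48L, 48L), noise_sigma = 0,
                                      bias_field_amplitude = 0, seed = 3))
  sl <- ph$volume$voxels[, , 2]
  sigmas <- c(0.01, 0.02, 0.05, 0.1)
  vals <- vapply(sigmas, function(s) {
    mean(vapply(1:20, function(k) {
      set.seed(1000 * s + k)
      psnr(sl + matrix(rnorm(length(sl), 0, s), nrow(sl)), sl)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim closed forms, symmetry and separation", {
  set.seed(51)
  a <- matrix(runif(1024), 32, 32)
  expect_equal(ssim(a, a), 1)
  b <- matrix(runif(1024), 32, 32)
  expect_equal(ssim(a, b), ssim(b, a))
  # constant images: zero variance leaves only the luminance factor
  mx <- 0.3; my <- 0.5; c1 <- 0.01^2
  expect_equal(ssim(matrix(mx, 32, 32), matrix(my, 32, 32)),
               (2 * mx * my + c1) / (mx^2 + my^2 + c1), tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
  # down-up-sampled self sits between unrelated phantom and identity
  ph1 <- generate_phantom(phantom_spec(shape = c(2L, 48L, 48L), seed = 4))
  ph2 <- generate_phantom(phantom_spec(shape = c(2L, 48L, 48L), sulci_frequency = 12,
                                       seed = 99))
  s1 <- minmax_normalize(ph1$volume)$voxels[, , 1]
  s2 <- minmax_normalize(ph2$volume)$voxels[, , 2]
  du <- bicubic_resize(degrade_bicubic(s1, 2), 48, 48)
  expect_lt(ssim(s1, du), 1)
  expect_gt(ssim(s1, du), ssim(s1, s2))
})

test_that("snr and cnr follow their mask-based definitions", {
  img <- array(0, dim = c(4, 4, 2))
  wm <- array(FALSE, dim = dim(img)); gm <- wm; csf <- wm; bg <- wm
  wm[1:2, , ] <- TRUE; gm[3, , ] <- TRUE; csf[4, 1:2, ] <- TRUE
  bg[4, 3:4, ] <- TRUE
  img[wm] <- 8; img[gm] <- 8
  img[bg] <- rep(c(0, 1, 2, 0), 2)[seq_len(sum(bg))]
  masks <- tissue_mask_set(wm, gm, csf, bg)
  expect_equal(snr(img, masks), 8 / stats::sd(img[bg]))
  expect_equal(snr(img * 3, masks), snr(img, masks))   # scale invariance
  img2 <- img; img2[gm] <- 3; img2[wm] <- 1
  expect_equal(cnr(img2, masks), 2 / stats::sd(img[bg]))
  expect_equal(cnr(img2 + 0.7, masks), cnr(img2, masks))  # shift invariance
  img3 <- img2; img3[gm] <- 1
  expect_equal(cnr(img3, masks), 0)
  imgc <- img; imgc[bg] <- 0
  expect_error(snr(imgc, masks), "zero")
})

test_that("snr and cnr recover phantom ground truth within 5%", {
  # uncensored background via a noise-floor pedestal; tissue mean 0.5,
  # sigma 0.05 => true SNR 10; |gm - wm| = 0.3 => true CNR 6
  snrs <- numeric(25); cnrs <- numeric(25)
  for (k in 1:25) {
    sp <- phantom_spec(shape = c(4L, 48L, 48L),
                       tissue_means = c(wm = 0.5, gm = 0.5, csf = 0.2),
                       noise_sigma = 0.05, bias_field_amplitude = 0,
                       background_level = 0.3, seed = 500 + k)
    ph <- generate_phantom(sp)
    snrs[k] <- snr(ph$volume$voxels, ph$masks)
    sp2 <- phantom_spec(shape = c(4L, 48L, 48L),
                        tissue_means = c(wm = 0.6, gm = 0.3, csf = 0.2),
                        noise_sigma = 0.05, bias_field_amplitude = 0,
                        background_level = 0.3, seed = 900 + k)
    ph2 <- generate_phantom(sp2)
    cnrs[k] <- cnr(ph2$volume$voxels, ph2$masks)
  }
  expect_equal(mean(snrs), 10, tolerance = 0.05)
  expect_equal(mean(cnrs), 6, tolerance = 0.05)
})

test_that("paired Wilcoxon test: exact enumeration, conventions, symmetry", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(paired_test(a, a), 1)                    # all-zero differences
  b <- a - c(0.2, 0.1, 0.4, 0.3, 0.5)                   # all differences positive
  expect_equal(paired_test(a, b), 0.0625)               # 2 * 1/2^5
  set.seed(52)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(paired_test(x, y), paired_test(y, x))
  expect_error(paired_test(1:5, 1:4), "length")
  expect_error(paired_test(1:3, 2:4), "at least 5")
})

test_that("paired test holds its nominal type-I error under the null", {
  set.seed(53)
  rej <- 0L; nsim <- 2000L
  for (i in seq_len(nsim)) {
    x <- rnorm(10); y <- rnorm(10)
    if (paired_test(x, y) < 0.05) rej <- rej + 1L
  }
  rate <- rej / nsim
  expect_gte(rate, 0.01); expect_lte(rate, 0.10)
})

test_that("aggregation reproduces a two-pass oracle and is order-invariant", {
  rows <- data.frame(subject = rep(c("s1", "s2", "s3"), each = 2),
                     slice = rep(0:1, 3),
                     psnr = c(27.647, 28.1, 30.2, 29.8, 26.5, 27.0),
                     ssim = c(0.91, 0.92, 0.95, 0.94, 0.89, 0.90))
  rep1 <- aggregate_metrics(rows)
  subj_means <- tapply(rows$psnr, rows$subject, mean)
  m <- sum(subj_means) / 3
  s <- sqrt(sum((subj_means - m)^2) / 3)                # population sd
  expect_equal(rep1$overall$mean[rep1$overall$metric == "psnr"], m)
  expect_equal(rep1$overall$sd[rep1$overall$metric == "psnr"], s)
  rep2 <- aggregate_metrics(rows[sample(nrow(rows)), ])
  expect_equal(rep1$overall, rep2$overall)
  single <- aggregate_metrics(rows[1, ])
  expect_equal(single$overall$mean[1], rows$psnr[1])
  expect_equal(single$overall$sd[1], 0)
  expect_error(aggregate_metrics(rows[0, ]), "empty")
})

test_that("metric reports export to TSV and JSON", {
  rows <- data.frame(subject = "s1", slice = 0L, psnr = 30, ssim = 0.9)
  rep <- aggregate_metrics(rows)
  prefix <- tempfile()
  paths <- write_metric_report(rep, prefix)
  expect_true(all(file.exists(paste0(prefix, c("_slices.tsv", "_summary.tsv", ".json")))))
  back <- utils::read.delim(paste0(prefix, "_slices.tsv"))
  expect_equal(back$psnr, 30)
})
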