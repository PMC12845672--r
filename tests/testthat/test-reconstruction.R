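# Model assembly, upsampling head, HFIR, parameter/FLOP accounting,
# checkpoints.

test_that("HFIR gates residually: zero weights give 1.5x the input", {
  set.seed(31)
  b <- hfir_block(8)
  u <- rand_fmap(9, 9, 8)
  expect_equal(dim(forward(b, u)), dim(u))
  zero_parameters(b)
  expect_equal(forward(b, u), 1.5 * u, tolerance = 1e-15)
  # the gate is a positive multiplier: correction has the sign pattern of u
  b2 <- hfir_block(8)
  d <- forward(b2, u) - u
  expect_true(all(sign(d[u != 0]) == sign(u[u != 0])))
})

test_that("assembled model honors ablation flags and scale contract", {
  base <- charms_model("baseline_x2")
  expect_null(base$pcas); expect_null(base$cs_fuse)
  expect_null(base$transformers); expect_null(base$hfir)
  expect_false(base$rrafs[[1]]$shuffle)

  m <- charms_model(tiny_cfg(seed = 5L))
  x <- matrix(runif(64 * 64), 64, 64)
  y <- forward_sr(m, x)
  expect_equal(dim(y), c(128L, 128L))
  expect_identical(forward_sr(m, x), y)            # bitwise deterministic
  expect_error(forward_sr(m, matrix(c(NA, runif(255)), 16, 16)), "finite")

  m4 <- charms_model(charms_config(scale = 4L, channels = 8L, head_channels = 8L,
                                   n_rraf = 1L, rlfe_per_rraf = 1L))
  expect_equal(dim(forward_sr(m4, matrix(runif(256), 16, 16))), c(64L, 64L))
  expect_error(charms_config(scale = 3L), "scale")
})

test_that("output dims are exactly r x input dims across sizes", {
  m2 <- charms_model(tiny_cfg(channels = 4L, esa_reduction = 2L, seed = 2L))
  for (hw in list(c(16, 24), c(33, 17), c(40, 40))) {
    y <- forward_sr(m2, matrix(runif(prod(hw)), hw[1], hw[2]))
    expect_equal(dim(y), 2L * hw)
  }
})

test_that("parameter counts reproduce the published budgets per preset", {
  want <- c(baseline_x2 = 1.46, ablation_cs_x2 = 1.49, ablation_cs_pca_x2 = 1.69,
            ablation_cs_pca_tr_x2 = 1.72, full_x2 = 1.74,
            baseline_x4 = 1.61, ablation_cs_x4 = 1.64, ablation_cs_pca_x4 = 1.84,
            ablation_cs_pca_tr_x4 = 1.87, full_x4 = 1.89)
  got <- vapply(names(want), function(nm)
    count_parameters(charms_model(nm))$parameter_millions, numeric(1))
  expect_equal(got, want)
  # strictly increasing along the cumulative ablation order at both scales
  expect_true(all(diff(got[1:5]) > 0))
  expect_true(all(diff(got[6:10]) > 0))
})

test_that("the parameter count partitions exactly over stages", {
  m <- charms_model("full_x4")
  parts <- c(n_parameters(m$shallow), n_parameters(m$rrafs),
             n_parameters(m$pcas), n_parameters(m$cs_fuse),
             n_parameters(m$transformers), n_parameters(m$up_stages),
             n_parameters(m$refine), n_parameters(m$hfir), n_parameters(m$out))
  expect_equal(sum(parts), count_parameters(m)$parameter_count)
  # count is invariant to input size (pure function of the config)
  expect_equal(count_flops(m, 128, 128)$parameter_count,
               count_flops(m, 256, 256)$parameter_count)
  # the x4 - x2 difference is exactly the extra upsampling stage
  m2 <- charms_model("full_x2")
  expect_equal(count_parameters(m)$parameter_count -
                 count_parameters(m2)$parameter_count,
               n_parameters(m$up_stages[[2]]))
})

test_that("analytic FLOPs are linear in pixel count", {
  m <- charms_model("full_x4")
  f1 <- count_flops(m, 128, 128)$flops
  f2 <- count_flops(m, 256, 256)$flops
  expect_equal(f2 / f1, 4.0, tolerance = 0.01)
  expect_gt(count_flops(m, 256, 256)$gflops, 10)
})

test_that("checkpoints round-trip weights and verify their format", {
  m <- charms_model(tiny_cfg(seed = 77L))
  x <- matrix(runif(144), 12, 12)
  y <- forward_sr(m, x)
  path <- tempfile(fileext = ".rds")
  charms_save(m, path)
  m2 <- charms_load(path)
  expect_identical(forward_sr(m2, x), y)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(charms_load(bad), "checkpoint")
})

test_that("config files round-trip through YAML", {
  cfg <- charms_preset("ablation_cs_pca_x4")
  path <- tempfile(fileext = ".yaml")
  charms_config_write(cfg, path)
  cfg2 <- charms_config_read(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  writeLines("bogus_field: 3", path)
  expect_error(charms_config_read(path), "unknown config")
})
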