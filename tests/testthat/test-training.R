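# Training loop, fine-tuning with selective freezing, evaluation.

test_that("training configs carry the published protocol defaults", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 200L)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$lr, 1e-4)
  expect_equal(c(cfg$beta1, cfg$beta2, cfg$eps), c(0.9, 0.999, 1e-8))
  expect_equal(cfg$loss, "l1")
  ft <- finetune_config()
  expect_equal(ft$lr, 1e-5)
  expect_equal(unlist(ft$weights), c(lambda1 = 1, lambda2 = 0.1, lambda3 = 0.005))
  expect_equal(ft$freeze_policy, "backbone_frozen")
  expect_error(train_config(lr = -1))
})

test_that("a single pair is overfit within 200 steps", {
  ph <- generate_phantom(phantom_spec(shape = c(1L, 32L, 32L), seed = 71))
  hr <- minmax_normalize(ph$volume)$voxels[, , 1]
  pair <- make_pair(hr)
  m <- charms_model(tiny_cfg(seed = 71L))
  fit <- charms_train(m, list(pair),
                      train_config(lr = 1e-2, batch_size = 1, seed = 1,
                                   max_steps = 200L))
  h <- fit$record$history$loss
  expect_lt(mean(tail(h, 10)), 0.2 * h[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  ph <- generate_phantom(phantom_spec(shape = c(2L, 32L, 32L), seed = 72))
  pairs <- build_pairs(list(ph$volume), r = 2, n_central = 2)
  run <- function() {
    m <- charms_model(tiny_cfg(seed = 5L))
    charms_train(m, pairs, train_config(lr = 1e-3, batch_size = 2, seed = 9,
                                        max_steps = 10L))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$record$history$loss, r2$record$history$loss)
  expect_identical(charms:::get_state(r1$model), charms:::get_state(r2$model))
})

test_that("training aborts on divergence with the offending step", {
  ph <- generate_phantom(phantom_spec(shape = c(1L, 32L, 32L), seed = 73))
  pairs <- build_pairs(list(ph$volume), r = 2, n_central = 1)
  m <- charms_model(tiny_cfg(seed = 3L, enable_transformer = FALSE))
  p1 <- parameters(m)[[1]]
  p1$val[1] <- Inf
  expect_error(charms_train(m, pairs, train_config(max_steps = 3L)),
               "step 1")
})

test_that("fine-tuning freezes the backbone bit-exactly", {
  ph <- generate_phantom(phantom_spec(shape = c(2L, 32L, 32L), seed = 74))
  pairs <- build_pairs(list(ph$volume), r = 2, n_central = 2)
  m <- charms_model(tiny_cfg(seed = 6L))
  before <- charms:::get_state(m)
  names_all <- vapply(parameters(m), function(p) p$name, character(1))
  charms:::apply_freeze_policy(m, "backbone_frozen")
  trainable <- vapply(parameters(m), function(p) p$trainable, logical(1))
  expect_gt(sum(trainable), 0)
  expect_lt(sum(trainable), length(trainable))           # strictly fewer
  # union of frozen and trainable covers everything, intersection empty
  expect_equal(sum(trainable) + sum(!trainable), length(trainable))
  frozen_names <- names_all[!trainable]

  fit <- charms_finetune(m, pairs,
                         finetune_config(lr = 1e-3, epochs = 5L, batch_size = 2L,
                                         seed = 2L))
  after <- charms:::get_state(fit$model)
  for (i in seq_along(before)) {
    if (names_all[i] %in% frozen_names) {
      expect_identical(after[[i]], before[[i]])          # frozen: bitwise equal
    }
  }
  expect_false(identical(after, before))                 # something trained
  # a policy that matches nothing is rejected
  m2 <- charms_model(tiny_cfg(seed = 6L))
  expect_error(charms_finetune(m2, pairs,
                               finetune_config(freeze_policy = "no.such.layer",
                                               epochs = 1L)),
               "zero trainable")
})

test_that("the transformer stage stays trainable under the default policy", {
  m <- charms_model(tiny_cfg(seed = 8L))
  charms:::apply_freeze_policy(m, "backbone_frozen")
  tr_params <- parameters(m$transformers)
  expect_true(all(vapply(tr_params, function(p) p$trainable, logical(1))))
  expect_false(any(vapply(parameters(m$rrafs), function(p) p$trainable, logical(1))))
})

test_that("evaluation reproduces the bicubic reference path and aggregates", {
  ph <- generate_phantom(phantom_spec(shape = c(3L, 32L, 32L), seed = 75))
  pairs <- build_pairs(list(ph$volume), r = 2, n_central = 3)
  rep <- charms_evaluate("bicubic", pairs)
  direct <- vapply(pairs, function(p)
    psnr(bicubic_resize(p$lr, nrow(p$hr), ncol(p$hr)), p$hr), numeric(1))
  expect_equal(rep$per_slice$psnr, direct)
  # aggregates recompute from the rows
  expect_equal(rep$overall$mean[rep$overall$metric == "psnr"],
               mean(tapply(rep$per_slice$psnr, rep$per_slice$subject, mean)))
  m <- charms_model(tiny_cfg(seed = 4L))
  expect_identical(charms_evaluate(m, pairs)$per_slice,
                   charms_evaluate(m, pairs)$per_slice)
  sp <- list(train = "phantom-000", val = character(0), test = "someone-else")
  expect_error(charms_evaluate(m, pairs, split = sp), "leakage")
})

test_that("run records persist as line-delimited JSON", {
  ph <- generate_phantom(phantom_spec(shape = c(1L, 32L, 32L), seed = 76))
  pairs <- build_pairs(list(ph$volume), r = 2, n_central = 1)
  m <- charms_model(tiny_cfg(seed = 9L))
  fit <- charms_train(m, pairs, train_config(max_steps = 3L, batch_size = 1L))
  path <- tempfile(fileext = ".jsonl")
  write_run_record(fit$record, path)
  lines <- readLines(path)
  expect_length(lines, 4L)                               # header + 3 steps
  expect_equal(jsonlite::fromJSON(lines[2])$step, 1L)
})
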