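# Training (L1 pre-training), cross-field fine-tuning with selective layer
# freezing (composite L1 + SSIM + attention-regularization objective), and
# evaluation orchestration.

#' Training configuration
#'
#' @param lr Learning rate (AdamW).
#' @param epochs Training epochs.
#' @param batch_size Slices per optimization step.
#' @param beta1,beta2,eps AdamW moment parameters.
#' @param weight_decay Decoupled weight decay (0 disables).
#' @param loss `"l1"` (pre-training default) or `"composite"`.
#' @param weights [loss_weights()] used when `loss = "composite"`.
#' @param ar_variant Attention-regularizer variant name.
#' @param seed Seed controlling batch sampling and patch draws.
#' @param max_steps Optional hard cap on optimization steps (overrides
#'   `epochs`), used by scaled-down experiments.
#' @param patch_lr Optional LR-patch side; when set, each training sample
#'   is a random aligned LR/HR patch pair instead of the full slice.
#' @param val_every Validate every this many steps (default: 10 times per
#'   run).
#' @param checkpoint_every Optional checkpointing interval in steps.
#' @param checkpoint_dir Directory for checkpoints.
#' @param lr_schedule `"constant"` (default) or `"cosine"`.
#' @param clip_grad_norm Clip the global gradient norm to this value before
#'   each update (`Inf` disables). Stabilizes small-batch training.
#' @param verbose Print progress lines.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 200L, batch_size = 16L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0, loss = c("l1", "composite"),
                         weights = loss_weights(), ar_variant = "entropy_decor",
                         seed = 1L, max_steps = NULL, patch_lr = NULL,
                         val_every = NULL, checkpoint_every = 0L,
                         checkpoint_dir = NULL,
                         lr_schedule = c("constant", "cosine"),
                         clip_grad_norm = 1, verbose = FALSE) {
  loss <- match.arg(loss)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, eps = eps, weight_decay = weight_decay,
                 loss = loss, weights = weights, ar_variant = ar_variant,
                 seed = as.integer(seed), max_steps = max_steps,
                 patch_lr = patch_lr, val_every = val_every,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir, lr_schedule = lr_schedule,
                 clip_grad_norm = clip_grad_norm, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Fine-tuning configuration
#'
#' Defaults follow the cross-field adaptation protocol: reduced learning
#' rate 1e-5, composite loss with weights (1, 0.1, 0.005), and the early
#' CNN backbone frozen so only the last (up to) two transformer blocks and
#' the decoder adapt.
#'
#' @inheritParams train_config
#' @param freeze_policy `"backbone_frozen"` (default), `"none"`, or a
#'   character vector of parameter-name prefixes to keep trainable.
#' @return A `finetune_config` (a `train_config` subclass).
#' @export
finetune_config <- function(lr = 1e-5, epochs = 30L, batch_size = 16L,
                            weights = loss_weights(),
                            freeze_policy = "backbone_frozen",
                            ar_variant = "entropy_decor", seed = 1L,
                            max_steps = NULL, patch_lr = NULL,
                            val_every = NULL, verbose = FALSE) {
  cfg <- train_config(lr = lr, epochs = epochs, batch_size = batch_size,
                      loss = "composite", weights = weights,
                      ar_variant = ar_variant, seed = seed,
                      max_steps = max_steps, patch_lr = patch_lr,
                      val_every = val_every, verbose = verbose)
  cfg$freeze_policy <- freeze_policy
  class(cfg) <- c("finetune_config", "train_config")
  cfg
}

# Random aligned LR/HR crop, biased toward informative content: up to four
# candidate positions are drawn and the first whose LR patch carries
# appreciable foreground signal is kept (background-only crops teach
# nothing about reconstruction).
crop_patch <- function(pair, patch_lr) {
  hl <- nrow(pair$lr); wl <- ncol(pair$lr); r <- pair$scale
  if (is.null(patch_lr) || (hl <= patch_lr && wl <= patch_lr)) return(pair)
  for (try in 1:4) {
    i <- sample.int(hl - patch_lr + 1L, 1L)
    j <- sample.int(wl - patch_lr + 1L, 1L)
    lr <- pair$lr[i:(i + patch_lr - 1L), j:(j + patch_lr - 1L)]
    if (mean(lr) > 0.05) break
  }
  pair$lr <- lr
  pair$hr <- pair$hr[((i - 1L) * r + 1L):((i + patch_lr - 1L) * r),
                     ((j - 1L) * r + 1L):((j + patch_lr - 1L) * r)]
  pair
}

val_psnr <- function(model, pairs) {
  mean(vapply(pairs, function(p)
    psnr(forward_sr(model, p$lr), p$hr), numeric(1)))
}

# Shared seeded optimization loop over slice pairs.
train_loop <- function(model, pairs, cfg, val_pairs = NULL) {
  stopifnot(length(pairs) >= 1)
  params <- parameters(model)
  trainable <- Filter(function(p) p$trainable, params)
  if (length(trainable) == 0L) stop("freeze policy selected zero trainable parameters")
  opt <- adamw_new(params, lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2,
                   eps = cfg$eps, weight_decay = cfg$weight_decay)
  n <- length(pairs)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  total_steps <- if (!is.null(cfg$max_steps)) as.integer(cfg$max_steps)
                 else cfg$epochs * steps_per_epoch
  val_every <- cfg$val_every %||% max(1L, total_steps %/% 10L)
  hist <- vector("list", total_steps)
  best <- list(psnr = -Inf, state = NULL, step = 0L)

  with_seed(cfg$seed, {
    for (s in seq_len(total_steps)) {
      if (cfg$lr_schedule == "cosine")
        opt$lr <- cfg$lr * 0.5 * (1 + cos(pi * (s - 1) / total_steps))
      idx <- sample.int(n, cfg$batch_size, replace = cfg$batch_size > n)
      ag_zero_grads(params)
      step_loss <- 0
      for (i in idx) {
        p <- crop_patch(pairs[[i]], cfg$patch_lr)
        x <- array(p$lr, dim = c(nrow(p$lr), ncol(p$lr), 1L))
        tgt <- array(p$hr, dim = c(nrow(p$hr), ncol(p$hr), 1L))
        ag_begin()
        fw <- model_fwd_with_maps(model, ag_input(x))
        loss_node <- if (cfg$loss == "l1") loss_l1_node(fw$y, tgt)
          else composite_loss_node(fw$y, tgt, fw$maps, cfg$weights, cfg$ar_variant)
        loss_node <- ag_scale(loss_node, 1 / length(idx))
        lval <- as.numeric(vof(loss_node))
        if (!is.finite(lval))
          stop("training diverged (non-finite loss) at step ", s)
        ag_backward(loss_node)
        ag_end()
        step_loss <- step_loss + lval
      }
      clip_global_norm(params, cfg$clip_grad_norm %||% Inf)
      opt <- adamw_step(opt)
      vp <- NA_real_
      if (!is.null(val_pairs) && (s %% val_every == 0L || s == total_steps)) {
        vp <- val_psnr(model, val_pairs)
        if (vp > best$psnr) best <- list(psnr = vp, state = get_state(model), step = s)
      }
      hist[[s]] <- data.frame(step = s, loss = step_loss, val_psnr = vp)
      if (cfg$verbose && (s %% max(1L, total_steps %/% 20L) == 0L))
        message(sprintf("step %d/%d  loss %.5f  val PSNR %s", s, total_steps,
                        step_loss, ifelse(is.na(vp), "-", sprintf("%.2f", vp))))
      if (cfg$checkpoint_every > 0L && !is.null(cfg$checkpoint_dir) &&
          s %% cfg$checkpoint_every == 0L)
        charms_save(model, file.path(cfg$checkpoint_dir, sprintf("step%06d.rds", s)))
    }
  })
  if (!is.null(best$state)) set_state(model, best$state)
  record <- structure(list(history = do.call(rbind, hist),
                           config = unclass(cfg), seed = cfg$seed,
                           best_step = best$step,
                           best_val_psnr = best$psnr,
                           n_pairs = n),
                      class = "run_record")
  list(model = model, record = record)
}

#' Train a super-resolution model
#'
#' Seeded AdamW optimization of the configured loss over LR-HR pairs.
#' When validation pairs are given, the weights with the best validation
#' PSNR are restored at the end.
#'
#' @param model A [charms_model()] (modified in place and returned).
#' @param pairs Training pairs from [build_pairs()].
#' @param cfg A [train_config()].
#' @param val_pairs Optional validation pairs for model selection.
#' @return List with elements `model` and `record` (a `run_record`).
#' @export
charms_train <- function(model, pairs, cfg = train_config(), val_pairs = NULL) {
  set_trainable(model, TRUE)
  train_loop(model, pairs, cfg, val_pairs)
}

apply_freeze_policy <- function(model, policy) {
  if (identical(policy, "none")) {
    set_trainable(model, TRUE)
    return(invisible(model))
  }
  set_trainable(model, FALSE)
  if (identical(policy, "backbone_frozen")) {
    for (st in model$up_stages) set_trainable(st, TRUE)
    set_trainable(model$refine, TRUE)
    if (!is.null(model$hfir)) set_trainable(model$hfir, TRUE)
    set_trainable(model$out, TRUE)
    if (!is.null(model$transformers)) {
      nt <- length(model$transformers)
      keep <- seq.int(max(1L, nt - 1L), nt)
      for (i in keep) set_trainable(model$transformers[[i]], TRUE)
    }
  } else if (is.character(policy)) {
    for (p in parameters(model))
      if (any(startsWith(p$name, policy))) p$trainable <- TRUE
  } else stop("unknown freeze policy")
  invisible(model)
}

#' Cross-field fine-tuning with selective freezing
#'
#' Adapts a pre-trained model on paired (low-field input, high-field
#' target) slices using the composite loss. Under the default
#' `"backbone_frozen"` policy only the last `min(2, n_transformer)`
#' transformer blocks and the decoder (upsampling stages, refinement
#' convolution, HFIR and output convolution) are updated; every other
#' weight is bit-identical before and after.
#'
#' @param model A pre-trained [charms_model()].
#' @param pairs Paired slices: `lr` is the (degraded) low-field input,
#'   `hr` the high-field target.
#' @param cfg A [finetune_config()].
#' @param val_pairs Optional validation pairs.
#' @return List with elements `model` and `record`.
#' @export
charms_finetune <- function(model, pairs, cfg = finetune_config(), val_pairs = NULL) {
  apply_freeze_policy(model, cfg$freeze_policy)
  out <- train_loop(model, pairs, cfg, val_pairs)
  set_trainable(out$model, TRUE)
  out
}

#' Evaluate a model on test pairs
#'
#' Runs the model slice-wise, computes PSNR/SSIM (plus SNR/CNR when tissue
#' masks are provided), and aggregates per subject. Passing
#' `model = "bicubic"` evaluates plain bicubic upsampling as the reference
#' path. When a [subject_split()] is given, any test pair whose subject is
#' not in the test partition raises a leakage error.
#'
#' @param model A [charms_model()] or `"bicubic"`.
#' @param pairs Test pairs.
#' @param masks Optional list of [tissue_mask_set()] parallel to `pairs`
#'   (HR geometry), enabling SNR/CNR columns.
#' @param split Optional [subject_split()] for the leakage guard.
#' @return A `metric_report`.
#' @export
charms_evaluate <- function(model, pairs, masks = NULL, split = NULL) {
  if (!is.null(split)) {
    subj <- unique(vapply(pairs, function(p) p$subject_id, character(1)))
    bad <- setdiff(subj, split$test)
    if (length(bad))
      stop("split leakage: subjects ", paste(bad, collapse = ", "),
           " are not in the test partition")
  }
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sr <- if (identical(model, "bicubic"))
      bicubic_resize(p$lr, nrow(p$hr), ncol(p$hr))
    else forward_sr(model, p$lr)
    row <- data.frame(subject = p$subject_id, slice = p$slice_index,
                      psnr = psnr(sr, p$hr), ssim = ssim(sr, p$hr))
    if (!is.null(masks)) {
      row$snr <- snr(sr, masks[[i]])
      row$cnr <- cnr(sr, masks[[i]])
    }
    row
  })
  aggregate_metrics(do.call(rbind, rows))
}

#' Persist a run record as line-delimited JSON
#'
#' @param record A `run_record` from [charms_train()] / [charms_finetune()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- record$config
  cfg$weights <- unclass(cfg$weights)
  writeLines(jsonlite::toJSON(list(config = cfg, seed = record$seed,
                                   best_step = record$best_step,
                                   n_pairs = record$n_pairs),
                              auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(record$history)))
    writeLines(jsonlite::toJSON(as.list(record$history[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Desk-scale study protocols on phantoms. These are the package's own
# scaled-down analogues of the full training / cross-field studies; sizes
# are fixed here so tests, vignette and scripts share one protocol.
# ---------------------------------------------------------------------------

phantom_slices <- function(ph, n_slices) {
  v <- minmax_normalize(ph$volume)
  central_slices(v, n_slices)
}

#' Scaled-down learning-signal study
#'
#' Trains a width-16 model for a fixed number of steps on 32 phantom
#' slice pairs at x2 and compares held-out PSNR against bicubic
#' upsampling. The phantom geometry is 64 x 64 pixels, 4 central slices
#' per subject; training samples 16 x 16 LR patches.
#'
#' @param seed Master seed for phantom generation and training.
#' @param steps Optimization steps (default 500).
#' @param width Trunk and head width of the reduced model.
#' @param n_train_subjects,n_test_subjects Phantom subjects per split.
#' @param lr Learning rate for the scaled run.
#' @return List with mean held-out `psnr_sr`, `psnr_bicubic`, and the
#'   per-slice values.
#' @export
phantom_sr_study <- function(seed = 1L, steps = 500L, width = 16L,
                             n_train_subjects = 8L, n_val_subjects = 2L,
                             n_test_subjects = 4L, lr = 3e-3) {
  base <- phantom_spec(shape = c(4L, 64L, 64L), noise_sigma = 0.02,
                       bias_field_amplitude = 0.05, seed = seed)
  data <- phantom_dataset(n_train_subjects + n_val_subjects + n_test_subjects,
                          spec_ranges = list(sulci_frequency = c(6, 10)),
                          seed = seed, base_spec = base)
  vols <- lapply(data, function(d) d$volume)
  train_pairs <- build_pairs(vols[seq_len(n_train_subjects)], r = 2L, n_central = 4L)
  val_pairs <- build_pairs(vols[n_train_subjects + seq_len(n_val_subjects)],
                           r = 2L, n_central = 2L)
  test_pairs <- build_pairs(vols[n_train_subjects + n_val_subjects +
                                   seq_len(n_test_subjects)],
                            r = 2L, n_central = 4L)
  model <- charms_model(charms_config(scale = 2L, channels = width,
                                      head_channels = width, seed = seed))
  cfg <- train_config(lr = lr, batch_size = 1L, seed = seed,
                      max_steps = steps, patch_lr = 16L,
                      lr_schedule = "cosine", val_every = 100L)
  fit <- charms_train(model, train_pairs, cfg, val_pairs = val_pairs)
  sr <- vapply(test_pairs, function(p) psnr(forward_sr(fit$model, p$lr), p$hr),
               numeric(1))
  bi <- vapply(test_pairs, function(p)
    psnr(bicubic_resize(p$lr, nrow(p$hr), ncol(p$hr)), p$hr), numeric(1))
  list(psnr_sr = mean(sr), psnr_bicubic = mean(bi),
       per_slice_sr = sr, per_slice_bicubic = bi)
}

#' Scaled-down cross-field adaptation study
#'
#' Pre-trains a reduced-width model on standard bicubic SR pairs from
#' "7T-like" phantoms, fine-tunes it with the frozen-backbone composite
#' objective on paired "3T-like"/"7T-like" subjects, and evaluates on
#' held-out paired subjects: the super-resolved 3T inputs are compared
#' against the 7T-like references, versus the native 3T images.
#'
#' @param seed Master seed.
#' @param width Reduced model width.
#' @param n_finetune_subjects,n_test_subjects Paired subjects.
#' @param pretrain_steps,finetune_epochs Scaled protocol sizes.
#' @return List with mean `psnr_sr` (SR vs 7T-like) and `psnr_3t`
#'   (3T-like vs 7T-like) over held-out subjects, plus per-subject values.
#' @export
crossfield_study <- function(seed = 1L, width = 16L,
                             n_finetune_subjects = 20L, n_test_subjects = 5L,
                             pretrain_steps = 200L, finetune_epochs = 30L) {
  ntot <- n_finetune_subjects + n_test_subjects
  base <- phantom_spec(shape = c(1L, 64L, 64L), noise_sigma = 0.02,
                       bias_field_amplitude = 0.05, seed = seed)
  paired <- lapply(seq_len(ntot), function(i) {
    sp <- base
    sp$sulci_frequency <- 6 + 4 * ((i * 37) %% 11) / 10
    sp$seed <- (seed + 7919L * i) %% 2147483647L
    class(sp) <- "phantom_spec"
    paired_field_phantoms(sp, subject_id = sprintf("phantom-%03d", i - 1L))
  })
  norm_slices <- function(vol) {
    v <- minmax_normalize(vol)
    central_slices(v, dim(v$voxels)[3])
  }
  mk_pairs <- function(idx, input = c("self", "low")) {
    input <- match.arg(input)
    out <- list()
    for (i in idx) {
      hi <- norm_slices(paired[[i]]$high_field)
      lo <- if (input == "low") norm_slices(paired[[i]]$low_field) else hi
      for (j in seq_along(hi)) {
        out[[length(out) + 1L]] <- structure(
          list(lr = degrade_bicubic(lo[[j]], 2L), hr = hi[[j]], scale = 2L,
               native = lo[[j]],
               subject_id = paired[[i]]$high_field$subject_id,
               slice_index = j - 1L), class = "slice_pair")
      }
    }
    out
  }
  model <- charms_model(charms_config(scale = 2L, channels = width,
                                      head_channels = width, seed = seed))
  pre <- charms_train(model, mk_pairs(seq_len(n_finetune_subjects), "self"),
                      train_config(lr = 2e-3, batch_size = 2L, seed = seed,
                                   max_steps = pretrain_steps, patch_lr = 16L))
  ft_pairs <- mk_pairs(seq_len(n_finetune_subjects), "low")
  ft <- charms_finetune(pre$model, ft_pairs,
                        finetune_config(lr = 5e-4, epochs = finetune_epochs,
                                        batch_size = 8L, seed = seed,
                                        patch_lr = 16L))
  test_pairs <- mk_pairs(n_finetune_subjects + seq_len(n_test_subjects), "low")
  subj <- vapply(test_pairs, function(p) p$subject_id, character(1))
  sr <- vapply(test_pairs, function(p) psnr(forward_sr(ft$model, p$lr), p$hr),
               numeric(1))
  nat <- vapply(test_pairs, function(p) psnr(p$native, p$hr), numeric(1))
  list(psnr_sr = mean(tapply(sr, subj, mean)),
       psnr_3t = mean(tapply(nat, subj, mean)),
       per_subject_sr = tapply(sr, subj, mean),
       per_subject_3t = tapply(nat, subj, mean))
}
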