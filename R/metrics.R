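# Image-quality metrics: PSNR, windowed SSIM, mask-based SNR/CNR,
# subject-level aggregation and paired significance testing.

#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)`. Identical images (zero MSE) return
#' `Inf` rather than raising an error.
#'
#' @param a,b Numeric arrays of equal shape.
#' @param data_range Dynamic range of the data (1 after min-max
#'   normalization).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, data_range = 1) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("psnr: shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

filt2 <- function(img, win) {
  k <- nrow(win)
  x <- array(img, dim = c(nrow(img), ncol(img), 1L))
  w <- array(win, dim = c(k, k, 1L, 1L))
  y <- cpp_conv2d(x, w, NULL, 1L, 0L, 1L, 1L)
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Structural similarity index
#'
#' Standard windowed SSIM with an 11x11 Gaussian window (sigma 1.5),
#' `k1 = 0.01`, `k2 = 0.03`, averaged over valid window positions.
#'
#' @inheritParams psnr
#' @param k1,k2 Stabilization constants.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = 1, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  if (min(dim(a)[1:2]) < 11L)
    stop("ssim: image smaller than the 11x11 window")
  a <- as.matrix(a); b <- as.matrix(b)
  win <- gaussian_window()
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  mu_a <- filt2(a, win); mu_b <- filt2(b, win)
  va <- filt2(a * a, win) - mu_a^2
  vb <- filt2(b * b, win) - mu_b^2
  vab <- filt2(a * b, win) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
         ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
}

#' Tissue mask set
#'
#' Mutually exclusive boolean masks partitioning a slice or volume into
#' white matter, gray matter, CSF and background.
#'
#' @param wm,gm,csf,background Logical arrays of identical shape.
#' @return A `tissue_mask_set`.
#' @export
tissue_mask_set <- function(wm, gm, csf, background) {
  total <- wm + gm + csf + background
  if (any(total != 1))
    stop("tissue masks must be disjoint and cover every voxel")
  structure(list(wm = wm, gm = gm, csf = csf, background = background),
            class = "tissue_mask_set")
}

#' Signal-to-noise ratio over tissue masks
#'
#' Mean intensity over brain tissue (WM plus GM) divided by the standard
#' deviation of the background.
#'
#' @param img Numeric array.
#' @param masks A [tissue_mask_set()] matching `img` in shape.
#' @return Positive scalar.
#' @export
snr <- function(img, masks) {
  tissue <- masks$wm | masks$gm
  if (!any(tissue) || !any(masks$background))
    stop("snr: tissue or background mask is empty")
  s <- stats::sd(img[masks$background])
  if (s == 0) stop("snr: background standard deviation is zero")
  mean(img[tissue]) / s
}

#' Gray-white matter contrast-to-noise ratio
#'
#' `|mean(GM) - mean(WM)| / sd(background)`.
#'
#' @inheritParams snr
#' @return Non-negative scalar.
#' @export
cnr <- function(img, masks) {
  if (!any(masks$gm) || !any(masks$wm) || !any(masks$background))
    stop("cnr: required mask is empty")
  s <- stats::sd(img[masks$background])
  if (s == 0) stop("cnr: background standard deviation is zero")
  abs(mean(img[masks$gm]) - mean(img[masks$wm])) / s
}

#' Paired significance test on per-subject scores
#'
#' Two-sided Wilcoxon signed-rank test on paired differences (exact when
#' there are no ties). All-zero differences return `p = 1` by convention.
#'
#' @param scores_a,scores_b Equal-length numeric vectors paired by subject
#'   (length at least 5).
#' @param method `"wilcoxon"` (default) or `"t"` for a paired t-test.
#' @return The p-value.
#' @export
paired_test <- function(scores_a, scores_b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b))
    stop("paired_test: length mismatch")
  if (length(scores_a) < 5L) stop("paired_test: need at least 5 pairs")
  d <- scores_a - scores_b
  if (all(d == 0)) return(1)
  if (method == "t") return(stats::t.test(scores_a, scores_b, paired = TRUE)$p.value)
  suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, paired = TRUE, exact = TRUE)$p.value
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate per-slice metric rows into a report
#'
#' Computes per-subject means and the overall mean and population standard
#' deviation per metric, exactly recomputable from the per-slice rows.
#'
#' @param rows A data frame with columns `subject`, `slice`, and one or
#'   more metric columns (e.g. `psnr`, `ssim`, `snr`, `cnr`).
#' @return A `metric_report` with elements `per_slice`, `per_subject`,
#'   `overall`.
#' @export
aggregate_metrics <- function(rows) {
  if (nrow(rows) < 1L) stop("aggregate_metrics: empty input")
  mcols <- setdiff(names(rows), c("subject", "slice"))
  per_subject <- do.call(rbind, lapply(split(rows, rows$subject), function(g) {
    out <- data.frame(subject = g$subject[1], n_slices = nrow(g))
    for (m in mcols) out[[paste0(m, "_mean")]] <- mean(g[[m]])
    out
  }))
  rownames(per_subject) <- NULL
  overall <- do.call(rbind, lapply(mcols, function(m) {
    subj <- per_subject[[paste0(m, "_mean")]]
    data.frame(metric = m,
               mean = mean(subj), sd = pop_sd(subj),
               slice_mean = mean(rows[[m]]), slice_sd = pop_sd(rows[[m]]))
  }))
  structure(list(per_slice = rows, per_subject = per_subject, overall = overall),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report:", nrow(x$per_slice), "slices,",
      nrow(x$per_subject), "subjects\n")
  print(transform(x$overall, mean = round(mean, 3), sd = round(sd, 3),
                  slice_mean = round(slice_mean, 3), slice_sd = round(slice_sd, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Write a metric report to disk
#'
#' Writes a tab-delimited per-slice table, a summary block mirroring the
#' per-subject mean/std layout, and a machine-readable JSON twin.
#'
#' @param report A `metric_report`.
#' @param prefix Output path prefix; `<prefix>_slices.tsv`,
#'   `<prefix>_summary.tsv` and `<prefix>.json` are produced.
#' @return The paths, invisibly.
#' @export
write_metric_report <- function(report, prefix) {
  p1 <- paste0(prefix, "_slices.tsv")
  p2 <- paste0(prefix, "_summary.tsv")
  p3 <- paste0(prefix, ".json")
  utils::write.table(report$per_slice, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$per_subject, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(per_subject = report$per_subject,
                            overall = report$overall),
                       p3, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(p1, p2, p3))
}
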