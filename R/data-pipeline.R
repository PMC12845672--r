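# Volume I/O, per-volume min-max normalization, central-slice extraction,
# bicubic degradation into LR-HR pairs, subject-level splitting and
# foreground masking. Slices are taken along the third voxel axis after
# canonical reorientation.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct an image volume
#'
#' @param voxels Numeric 3D array (third axis = slice axis).
#' @param spacing Voxel spacing in mm, length 3.
#' @param subject_id Subject identifier.
#' @param contrast `"T1w"` or `"T2w"`.
#' @param orientation Optional orientation string recorded from the header.
#' @return An `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), subject_id = "unknown",
                         contrast = c("T1w", "T2w"), orientation = NA_character_) {
  contrast <- match.arg(contrast)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(!is.finite(voxels))) stop("non-finite voxels")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 subject_id = subject_id, contrast = contrast,
                 orientation = orientation),
            class = "image_volume")
}

#' Load a NIfTI volume
#'
#' Reads a NIfTI-1/2 file, canonicalizes the axis order to RAS (recorded in
#' the `orientation` field) and extracts voxel spacing from the header.
#' 4D inputs are rejected.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param subject_id Subject identifier (defaults to the file stem).
#' @param contrast `"T1w"` or `"T2w"`.
#' @return An [image_volume()].
#' @export
load_volume <- function(path, subject_id = NULL,
                        contrast = c("T1w", "T2w")) {
  contrast <- match.arg(contrast)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(img)) == 4L && dim(img)[4] == 1L) img <- img[, , , 1]
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)),
         "D; split 4D series into per-volume files first")
  orient <- tryCatch({
    o <- RNifti::orientation(img)
    if (!identical(o, "RAS")) RNifti::orientation(img) <- "RAS"
    o
  }, error = function(e) NA_character_)
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vox <- array(as.numeric(img), dim = dim(img))
  if (min(vox) < 0)
    warning("negative intensities in ", path, "; expected magnitude images")
  image_volume(vox, spacing, subject_id, contrast, orientation = orient)
}

#' Write a volume to NIfTI
#'
#' @param vol An [image_volume()] (or plain 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  voxels <- if (inherits(vol, "image_volume")) vol$voxels else vol
  spacing <- if (inherits(vol, "image_volume")) vol$spacing else c(1, 1, 1)
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max normalize a volume
#'
#' `(x - min) / (max - min)` computed independently per volume, mapping
#' intensities onto `[0, 1]`. A constant volume maps to all zeros with a
#' warning. The original min and max are stored as attributes so
#' [denormalize_volume()] can invert the map.
#'
#' @param v An [image_volume()].
#' @return The normalized volume.
#' @export
minmax_normalize <- function(v) {
  stopifnot(inherits(v, "image_volume"))
  lo <- min(v$voxels); hi <- max(v$voxels)
  if (hi == lo) {
    warning("constant volume for subject ", v$subject_id, "; normalized to zeros")
    v$voxels <- array(0, dim = dim(v$voxels))
  } else {
    v$voxels <- (v$voxels - lo) / (hi - lo)
  }
  attr(v, "norm_min") <- lo
  attr(v, "norm_max") <- hi
  v
}

#' @rdname minmax_normalize
#' @export
denormalize_volume <- function(v) {
  lo <- attr(v, "norm_min"); hi <- attr(v, "norm_max")
  if (is.null(lo)) stop("volume carries no normalization record")
  if (hi > lo) v$voxels <- v$voxels * (hi - lo) + lo
  attr(v, "norm_min") <- NULL; attr(v, "norm_max") <- NULL
  v
}

#' Extract the central slices of a volume
#'
#' Returns the `n` slices centered on the volume midpoint along the slice
#' axis (start index `floor((D - n) / 2)`, 0-based). Volumes with fewer
#' than `n` slices return all slices with a warning.
#'
#' @param v An [image_volume()].
#' @param n Number of slices (default 100, the standard protocol).
#' @return A list of 2D matrices; slice indices are attached as names.
#' @export
central_slices <- function(v, n = 100L) {
  stopifnot(n >= 1)
  D <- dim(v$voxels)[3]
  if (D < n) {
    warning("volume has ", D, " slices < n = ", n, "; using all slices")
    idx <- seq_len(D)
  } else {
    start <- floor((D - n) / 2)
    idx <- seq.int(start + 1L, start + n)
  }
  out <- lapply(idx, function(i) v$voxels[, , i])
  names(out) <- idx - 1L   # 0-based slice indices
  out
}

# -- bicubic resampling -----------------------------------------------------

cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * (at^3 - 5 * at^2 + 8 * at - 4), 0))
}

# Row-normalized 1D resampling matrix [n_out, n_in]; for downscaling the
# kernel is stretched by the scale factor (antialias prefilter), edges are
# handled by clamping sample positions (replicate padding).
resample_matrix <- function(n_in, n_out, a = -0.5) {
  scale <- n_in / n_out
  kwid <- max(1, scale)
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) * scale - 0.5          # 0-based source position
    j <- floor(center - 2 * kwid + 1):ceiling(center + 2 * kwid - 1)
    w <- cubic_kernel((j - center) / kwid)
    jc <- pmin(pmax(j, 0), n_in - 1)
    for (k in seq_along(j)) M[i, jc[k] + 1] <- M[i, jc[k] + 1] + w[k]
  }
  M / rowSums(M)
}

#' Bicubic resampling of a 2D image
#'
#' Separable Catmull-Rom bicubic interpolation (`a = -0.5`) with an
#' antialias prefilter when downscaling (the kernel is stretched by the
#' scale factor) and replicate edge handling. Row weights are normalized,
#' so constant images are reproduced exactly.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output size.
#' @return Numeric matrix `[out_h, out_w]`.
#' @export
bicubic_resize <- function(img, out_h, out_w) {
  Mh <- resample_matrix(nrow(img), out_h)
  Mw <- resample_matrix(ncol(img), out_w)
  Mh %*% img %*% t(Mw)
}

#' Bicubic degradation of a high-resolution slice
#'
#' Downsamples by the scale factor with the antialiased bicubic kernel,
#' producing the LR member of a training pair. If the input dimensions are
#' not divisible by `r` the slice is cropped (bottom/right) first, and the
#' crop is recorded in the `"crop"` attribute.
#'
#' @param hr Numeric matrix in `[0, 1]`.
#' @param r Scale factor, 2 or 4.
#' @return The LR matrix `[H/r, W/r]`.
#' @export
degrade_bicubic <- function(hr, r) {
  if (!r %in% c(2L, 4L)) stop("scale factor must be 2 or 4 (got ", r, ")")
  if (min(dim(hr)) < 4 * r) stop("image smaller than the bicubic kernel support")
  crop <- dim(hr) %% r
  if (any(crop > 0)) {
    hr <- hr[seq_len(nrow(hr) - crop[1]), seq_len(ncol(hr) - crop[2]), drop = FALSE]
  }
  lr <- bicubic_resize(hr, nrow(hr) %/% r, ncol(hr) %/% r)
  attr(lr, "crop") <- crop
  lr
}

#' Subject-level train/validation/test split
#'
#' Deterministically shuffles the subject ids with the given seed and
#' assigns counts by largest-remainder rounding of the ratios; the test
#' partition is guaranteed at least one subject. Every subject lands in
#' exactly one partition.
#'
#' @param ids Character vector of subject ids (at least 3).
#' @param ratios Train/val/test proportions (default 70:20:10).
#' @param seed Integer seed.
#' @return A `split_assignment` list with `train`, `val`, `test`.
#' @export
subject_split <- function(ids, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  ids <- unique(as.character(ids))
  if (length(ids) < 3L) stop("need at least 3 subjects to split")
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  ratios <- ratios / sum(ratios)
  n <- length(ids)
  exact <- n * ratios
  cnt <- floor(exact)
  rem <- n - sum(cnt)
  if (rem > 0) {
    order_rem <- order(exact - cnt, decreasing = TRUE)
    cnt[order_rem[seq_len(rem)]] <- cnt[order_rem[seq_len(rem)]] + 1
  }
  if (cnt[3] == 0) {             # guarantee a non-empty test partition
    donor <- which.max(cnt[1:2])
    cnt[donor] <- cnt[donor] - 1
    cnt[3] <- 1
  }
  shuffled <- with_seed(seed, sample(ids))
  structure(list(train = sort(shuffled[seq_len(cnt[1])]),
                 val = sort(shuffled[cnt[1] + seq_len(cnt[2])]),
                 test = sort(shuffled[cnt[1] + cnt[2] + seq_len(cnt[3])]),
                 seed = seed),
            class = "split_assignment")
}

# -- foreground masking -----------------------------------------------------

shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | shift_mat(m, dr, dc, FALSE)
  out
}

erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out & shift_mat(m, dr, dc, TRUE)
  out
}

# 4-connected component labels by iterative label propagation
label_components <- function(mask) {
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  repeat {
    nxt <- pmax(lab,
                shift_mat(lab, 1, 0), shift_mat(lab, -1, 0),
                shift_mat(lab, 0, 1), shift_mat(lab, 0, -1))
    nxt[!mask] <- 0
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}

#' Foreground (brain) mask of a slice
#'
#' Thresholds at `tau`, applies a one-pixel morphological opening (clearing
#' isolated noise pixels that cross the threshold) followed by a one-pixel
#' closing (sealing interior holes), and keeps the largest 4-connected
#' component. Returns an all-`FALSE` mask when no pixel exceeds the
#' threshold. The operation is idempotent: masking an already-masked slice
#' returns the same mask.
#'
#' @param slice Numeric matrix in `[0, 1]`.
#' @param tau Intensity threshold on normalized intensities.
#' @return Logical matrix.
#' @export
foreground_mask <- function(slice, tau = 0.01) {
  m <- slice > tau
  if (!any(m)) return(m)
  m <- dilate3(erode3(m))              # opening: drop threshold speckle
  m <- erode3(dilate3(m))              # closing: seal interior holes
  if (!any(m)) return(m)
  lab <- label_components(m)
  tab <- table(lab[lab > 0])
  lab == as.integer(names(tab)[which.max(tab)])
}

#' Build LR-HR slice pairs from volumes
#'
#' Normalizes each volume, extracts the central slices, and degrades each
#' slice bicubically, yielding one `slice_pair` per retained slice in a
#' deterministic (subject, slice-index) order.
#'
#' @param volumes List of [image_volume()] objects.
#' @param r Scale factor, 2 or 4.
#' @param n_central Central slices per volume (default 100).
#' @return A list of `slice_pair` objects with fields `lr`, `hr`, `scale`,
#'   `subject_id`, `slice_index`.
#' @export
build_pairs <- function(volumes, r, n_central = 100L) {
  ord <- order(vapply(volumes, function(v) v$subject_id, character(1)))
  out <- list()
  for (v in volumes[ord]) {
    nv <- minmax_normalize(v)
    sl <- central_slices(nv, n_central)
    for (j in seq_along(sl)) {
      hr <- sl[[j]]
      crop <- dim(hr) %% r
      if (any(crop > 0))
        hr <- hr[seq_len(nrow(hr) - crop[1]), seq_len(ncol(hr) - crop[2]), drop = FALSE]
      lr <- degrade_bicubic(hr, r)
      out[[length(out) + 1L]] <- structure(
        list(lr = lr, hr = hr, scale = as.integer(r),
             subject_id = v$subject_id,
             slice_index = as.integer(names(sl)[j])),
        class = "slice_pair")
    }
  }
  out
}

#' Write a pair manifest
#'
#' Records subject, slice index, scale and array dimensions for a list of
#' pairs as a tab-delimited table (one row per pair).
#'
#' @param pairs List of `slice_pair` objects.
#' @param path Output TSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_pair_manifest <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p) data.frame(
    subject = p$subject_id, slice = p$slice_index, scale = p$scale,
    lr_h = nrow(p$lr), lr_w = ncol(p$lr), hr_h = nrow(p$hr), hr_w = ncol(p$hr))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
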