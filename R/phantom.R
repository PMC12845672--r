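# Synthetic brain phantoms: nested ellipsoids (background / CSF / cortical
# GM ribbon / WM core) with sinusoidal boundary perturbation emulating
# sulci, an optional smooth multiplicative bias field, and additive noise.
# Ground-truth tissue masks are the noiseless generative labels, which makes
# every image-quality metric testable without external data.

#' Phantom specification
#'
#' @param shape Volume shape `(D, H, W)`: D slices of H x W pixels.
#' @param contrast `"T1w"` (WM > GM > CSF) or `"T2w"` (CSF > GM > WM); the
#'   intensity ordering is enforced.
#' @param tissue_means Named intensities in `[0, 1]` for `wm`, `gm`, `csf`.
#' @param noise_sigma Additive noise standard deviation (must be < 0.5).
#' @param cortical_thickness_px Thickness of the GM ribbon in pixels.
#' @param sulci_frequency Angular frequency of the boundary perturbation;
#'   higher values give finer cortical folding.
#' @param bias_field_amplitude Amplitude of the smooth multiplicative bias
#'   field, in `[0, 0.3]`.
#' @param background_level Air / noise-floor intensity of the background
#'   (default 0). A level of a few noise standard deviations keeps the
#'   additive background noise uncensored by the non-negativity clip,
#'   which is what mask-based noise estimation assumes.
#' @param noise_model `"gaussian"` (default; magnitude-like images far from
#'   the low-SNR regime) or `"rician"`.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 96L, 96L),
                         contrast = c("T1w", "T2w"),
                         tissue_means = NULL,
                         noise_sigma = 0.02,
                         cortical_thickness_px = 3L,
                         sulci_frequency = 8,
                         bias_field_amplitude = 0.05,
                         background_level = 0,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  contrast <- match.arg(contrast)
  noise_model <- match.arg(noise_model)
  if (is.null(tissue_means))
    tissue_means <- if (contrast == "T1w") c(wm = 0.8, gm = 0.5, csf = 0.2)
                    else c(wm = 0.35, gm = 0.55, csf = 0.85)
  tm <- tissue_means[c("wm", "gm", "csf")]
  if (any(is.na(tm))) stop("tissue_means must name wm, gm and csf")
  if (contrast == "T1w" && !(tm["wm"] >= tm["gm"] && tm["gm"] >= tm["csf"]))
    stop("T1w requires wm >= gm >= csf intensity ordering")
  if (contrast == "T2w" && !(tm["csf"] >= tm["gm"] && tm["gm"] >= tm["wm"]))
    stop("T2w requires csf >= gm >= wm intensity ordering")
  if (noise_sigma < 0 || noise_sigma >= 0.5) stop("noise_sigma must be in [0, 0.5)")
  if (bias_field_amplitude < 0 || bias_field_amplitude > 0.3)
    stop("bias_field_amplitude must be in [0, 0.3]")
  if (background_level < 0 || background_level > 0.4)
    stop("background_level must be in [0, 0.4]")
  stopifnot(length(shape) == 3L, all(shape >= 1), cortical_thickness_px >= 1,
            sulci_frequency > 0)
  structure(list(shape = as.integer(shape), contrast = contrast,
                 tissue_means = tm, noise_sigma = noise_sigma,
                 cortical_thickness_px = as.integer(cortical_thickness_px),
                 sulci_frequency = sulci_frequency,
                 bias_field_amplitude = bias_field_amplitude,
                 background_level = background_level,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Noiseless generative labels: 0 background, 1 WM, 2 GM, 3 CSF
phantom_labels <- function(spec, phase = 0) {
  D <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  ax <- 0.42 * H; ay <- 0.42 * W; az <- 0.46 * max(D, 2)
  t_norm <- spec$cortical_thickness_px / mean(c(ax, ay))
  r_csf_in <- 0.90
  sulci_amp <- 0.05
  if (t_norm + sulci_amp >= r_csf_in - 0.05)
    stop("degenerate phantom geometry: cortical ribbon thickness (",
         spec$cortical_thickness_px, " px) too large for the ellipsoid radius")
  cx <- (H + 1) / 2; cy <- (W + 1) / 2; cz <- (D + 1) / 2
  xs <- (seq_len(H) - cx) / ax
  ys <- (seq_len(W) - cy) / ay
  lab <- array(0L, dim = c(H, W, D))
  X <- matrix(xs, H, W); Y <- matrix(ys, H, W, byrow = TRUE)
  rho2d <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  for (z in seq_len(D)) {
    dz <- ((z - cz) / az)
    rho <- sqrt(rho2d^2 + dz^2)
    phi_z <- phase + 2 * pi * (z - 1) / max(D, 2)
    r_gm_in <- (r_csf_in - t_norm) *
      (1 + sulci_amp * sin(spec$sulci_frequency * theta + phi_z))
    sl <- matrix(0L, H, W)
    sl[rho < 1] <- 3L                       # CSF fills the head
    sl[rho < r_csf_in] <- 2L                # cortical GM ribbon
    sl[rho < r_gm_in] <- 1L                 # WM core
    lab[, , z] <- sl
  }
  lab
}

phantom_intensity <- function(spec, lab, tissue_means = spec$tissue_means) {
  H <- dim(lab)[1]; W <- dim(lab)[2]; D <- dim(lab)[3]
  img <- array(0, dim = dim(lab))
  img[lab == 0L] <- spec$background_level %||% 0
  img[lab == 1L] <- tissue_means["wm"]
  img[lab == 2L] <- tissue_means["gm"]
  img[lab == 3L] <- tissue_means["csf"]
  if (spec$bias_field_amplitude > 0) {
    bx <- cos(pi * (seq_len(H) - (H + 1) / 2) / H)
    by <- cos(pi * (seq_len(W) - (W + 1) / 2) / W)
    field <- 1 + spec$bias_field_amplitude * (outer(bx, by) - mean(outer(bx, by)))
    img <- img * array(rep(field, D), dim = dim(lab))
  }
  img
}

add_noise <- function(img, sigma, model) {
  if (sigma == 0) return(pmin(pmax(img, 0), 1.2))
  n1 <- array(stats::rnorm(length(img), 0, sigma), dim = dim(img))
  out <- if (model == "rician") {
    n2 <- array(stats::rnorm(length(img), 0, sigma), dim = dim(img))
    sqrt((img + n1)^2 + n2^2)
  } else img + n1
  pmin(pmax(out, 0), 1.2)
}

#' Generate a brain phantom
#'
#' Builds the tissue-label geometry, renders intensities with the optional
#' bias field, adds noise, and returns both the volume and the
#' ground-truth tissue masks (the noiseless labels). Deterministic for a
#' fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Subject identifier stored on the volume.
#' @return List with elements `volume` (an [image_volume()]) and `masks`
#'   (a [tissue_mask_set()]).
#' @export
generate_phantom <- function(spec, subject_id = "phantom-000") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    lab <- phantom_labels(spec, phase)
    img <- phantom_intensity(spec, lab)
    img <- add_noise(img, spec$noise_sigma, spec$noise_model)
    vol <- image_volume(img, spacing = c(1, 1, 1), subject_id = subject_id,
                        contrast = spec$contrast)
    masks <- tissue_mask_set(wm = lab == 1L, gm = lab == 2L,
                             csf = lab == 3L, background = lab == 0L)
    list(volume = vol, masks = masks, spec = spec)
  })
}

#' Generate a multi-subject phantom dataset
#'
#' Per-subject specs are drawn from the stated ranges with a derived
#' per-subject seed, so the whole dataset is reproducible from the master
#' seed. Subjects are named `phantom-000`, `phantom-001`, ...
#'
#' @param n_subjects Number of subjects.
#' @param spec_ranges Named list of `c(min, max)` ranges overriding
#'   `noise_sigma`, `sulci_frequency`, `cortical_thickness_px` or
#'   `bias_field_amplitude`.
#' @param seed Master seed.
#' @param base_spec Template [phantom_spec()] supplying all other fields.
#' @return A list of `generate_phantom()` results.
#' @export
phantom_dataset <- function(n_subjects, spec_ranges = list(), seed = 1L,
                            base_spec = phantom_spec()) {
  stopifnot(n_subjects >= 1)
  for (rg in spec_ranges)
    if (length(rg) != 2L || rg[2] < rg[1]) stop("spec_ranges entries must be c(min, max)")
  draws <- with_seed(seed, lapply(seq_len(n_subjects), function(i)
    stats::runif(length(spec_ranges) + 1L)))
  lapply(seq_len(n_subjects), function(i) {
    u <- draws[[i]]
    sp <- base_spec
    for (j in seq_along(spec_ranges)) {
      nm <- names(spec_ranges)[j]
      val <- spec_ranges[[j]][1] + u[j] * diff(spec_ranges[[j]])
      sp[[nm]] <- if (nm == "cortical_thickness_px") as.integer(round(val)) else val
    }
    sp$seed <- (base_spec$seed + 7919L * i) %% 2147483647L
    class(sp) <- "phantom_spec"
    generate_phantom(sp, subject_id = sprintf("phantom-%03d", i - 1L))
  })
}

gaussian_blur_slice <- function(img, sigma = 1.5) {
  k <- 9L
  x <- seq_len(k) - (k + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  w <- array(outer(g, g), dim = c(k, k, 1L, 1L))
  y <- cpp_conv2d(array(img, dim = c(nrow(img), ncol(img), 1L)), w, NULL,
                  1L, (k - 1L) %/% 2L, 1L, 1L)
  matrix(y, nrow(img), ncol(img))
}

#' Paired low-field / high-field phantoms
#'
#' Renders the same anatomy twice: a "7T-like" member (full resolution,
#' nominal noise and contrast) and a registered "3T-like" member with a
#' 1.5-pixel Gaussian blur, doubled noise, and the GM-WM contrast gap
#' shrunk to 70%. The shared tissue masks are returned once.
#'
#' @param spec A [phantom_spec()] describing the 7T-like member.
#' @param seed Seed for the noise draws (defaults to `spec$seed`).
#' @param subject_id Subject identifier.
#' @return List with `low_field`, `high_field` (both [image_volume()]) and
#'   `masks`.
#' @export
paired_field_phantoms <- function(spec, seed = spec$seed,
                                  subject_id = "phantom-000") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    lab <- phantom_labels(spec, phase)

    hi <- phantom_intensity(spec, lab)
    hi <- add_noise(hi, spec$noise_sigma, spec$noise_model)

    tm <- spec$tissue_means
    mid <- (tm["gm"] + tm["wm"]) / 2
    tm_lo <- tm
    tm_lo["gm"] <- mid + 0.7 * (tm["gm"] - mid)
    tm_lo["wm"] <- mid + 0.7 * (tm["wm"] - mid)
    lo <- phantom_intensity(spec, lab, tissue_means = tm_lo)
    for (z in seq_len(dim(lo)[3])) lo[, , z] <- gaussian_blur_slice(lo[, , z])
    lo <- add_noise(lo, 2 * spec$noise_sigma, spec$noise_model)

    masks <- tissue_mask_set(wm = lab == 1L, gm = lab == 2L,
                             csf = lab == 3L, background = lab == 0L)
    list(low_field = image_volume(lo, subject_id = subject_id,
                                  contrast = spec$contrast),
         high_field = image_volume(hi, subject_id = subject_id,
                                   contrast = spec$contrast),
         masks = masks)
  })
}

#' Write a phantom to disk as NIfTI plus sidecar metadata
#'
#' Writes the intensity volume, an integer label volume (0 background,
#' 1 WM, 2 GM, 3 CSF) and a JSON sidecar recording the generating spec.
#'
#' @param ph A [generate_phantom()] result.
#' @param dir Output directory.
#' @param name File stem (defaults to the subject id).
#' @return Paths of the three files, invisibly.
#' @export
write_phantom <- function(ph, dir, name = ph$volume$subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(name, ".nii.gz"))
  p2 <- file.path(dir, paste0(name, "_labels.nii.gz"))
  p3 <- file.path(dir, paste0(name, "_spec.json"))
  write_volume(ph$volume, p1)
  lab <- 1L * ph$masks$wm + 2L * ph$masks$gm + 3L * ph$masks$csf
  RNifti::writeNifti(RNifti::asNifti(lab), p2)
  sp <- ph$spec
  sp$tissue_means <- as.list(sp$tissue_means)
  jsonlite::write_json(unclass(sp), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
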