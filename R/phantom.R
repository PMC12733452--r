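#' Parameters for the synthetic brain phantom
#'
#' The phantom emulates the statistical structure of FLAIR MRI slices with
#' low-grade glioma annotations: a smooth brain ellipse on a dark
#' background, an optional hyperintense tumor (`tumor_level > brain_level >
#' background_level`), mild Gaussian texture, and a ground-truth mask equal
#' to the tumor support.  Tumor boundaries can be perturbed sinusoidally
#' (`boundary_jitter`) to produce the irregular, high-complexity shapes the
#' perceptual mappings react to.
#'
#' @param image_size side length in pixels (default 128; use 256 for
#'   paper-scale demos).
#' @param brain_axes ellipse semi-axes `(a_row, a_col)` in pixels; default
#'   `0.42 / 0.36` of the image size.
#' @param background_level,brain_level,tumor_level unit-interval intensities,
#'   strictly increasing.
#' @param tumor_center `(row, col)` center; default slightly off-center.
#'   Must lie inside the image.
#' @param tumor_radius radius in pixels; 0 disables the tumor.
#' @param boundary_jitter relative sinusoidal radius perturbation amplitude
#'   (0 = smooth disk).
#' @param jitter_waves number of sinusoidal lobes around the boundary.
#' @param texture_sd Gaussian texture standard deviation (unit interval).
#' @param seed integer seed; phantoms are bit-reproducible per seed.
#' @return an object of class `sonoseg_phantom_params`.
#' @export
phantom_params <- function(image_size = 128L,
                           brain_axes = NULL,
                           background_level = 0.05,
                           brain_level = 0.35,
                           tumor_level = 0.85,
                           tumor_center = NULL,
                           tumor_radius = 10,
                           boundary_jitter = 0,
                           jitter_waves = 5L,
                           texture_sd = 0.02,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(image_size >= 8L)
  if (!(tumor_level > brain_level && brain_level > background_level)) {
    abort_sonoseg("need tumor_level > brain_level > background_level (FLAIR hyperintensity)",
                  class = "sonoseg_phantom_error")
  }
  brain_axes <- brain_axes %||% c(0.42, 0.36) * image_size
  tumor_center <- tumor_center %||% (image_size * c(0.45, 0.55))
  if (any(tumor_center < 1) || any(tumor_center > image_size)) {
    abort_sonoseg("tumor_center lies outside the image",
                  class = "sonoseg_phantom_error")
  }
  structure(list(image_size = image_size, brain_axes = brain_axes,
                 background_level = background_level,
                 brain_level = brain_level, tumor_level = tumor_level,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 boundary_jitter = boundary_jitter,
                 jitter_waves = as.integer(jitter_waves),
                 texture_sd = texture_sd, seed = as.integer(seed)),
            class = "sonoseg_phantom_params")
}

#' Generate one phantom slice with its ground-truth mask
#'
#' @param params a [phantom_params()] object.
#' @return a list with `image` (`size x size` matrix in `[0, 1]`) and `mask`
#'   (`size x size` 0/1 matrix, the exact tumor support).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "sonoseg_phantom_params"))
  n <- params$image_size
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  # smooth-edged brain ellipse
  re <- sqrt(((rows - ctr) / params$brain_axes[1])^2 +
               ((cols - ctr) / params$brain_axes[2])^2)
  edge <- 1 / (1 + exp((re - 1) / 0.02))
  brain <- re <= 1
  image <- params$background_level +
    (params$brain_level - params$background_level) * edge
  mask <- matrix(0, n, n)
  with_seed(params$seed, {
    if (params$tumor_radius > 0) {
      dy <- rows - params$tumor_center[1]
      dx <- cols - params$tumor_center[2]
      rr <- sqrt(dy^2 + dx^2)
      radius <- params$tumor_radius
      if (params$boundary_jitter > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        theta <- atan2(dx, dy)
        radius <- radius * (1 + params$boundary_jitter *
                              sin(params$jitter_waves * theta + phase))
      }
      tumor <- (rr <= radius) & brain   # lesions live inside the brain
      mask[tumor] <- 1
      image[tumor] <- params$tumor_level
    }
    if (params$texture_sd > 0) {
      image <- image + stats::rnorm(n * n, sd = params$texture_sd) * (edge > 0.5)
    }
  })
  image[image < 0] <- 0
  image[image > 1] <- 1
  list(image = image, mask = mask)
}

#' Write a phantom dataset in the patient-wise image/mask folder layout
#'
#' Emits one folder per synthetic patient containing PNG slices and their
#' `_mask`-suffixed binary masks, plus a CSV manifest; the tree is directly
#' consumable by [index_dataset()].  A fixed fraction of slices per patient
#' carries a tumor; the remainder are tumor-free (empty masks).
#'
#' @param n_patients number of synthetic patients.
#' @param slices_per_patient slices written per patient.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling all phantom draws.
#' @param tumor_fraction fraction of slices with a tumor (default 0.7;
#'   rounded per patient).
#' @param image_size slice side length in pixels.
#' @return a tibble manifest (`patient_id`, `slice_index`, `image_path`,
#'   `mask_path`, `has_tumor`), also written as `manifest.csv`.
#' @export
generate_phantom_dataset <- function(n_patients, slices_per_patient, out_dir,
                                     seed = 1L, tumor_fraction = 0.7,
                                     image_size = 128L) {
  stopifnot(n_patients >= 1L, slices_per_patient >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_patients * slices_per_patient)
  with_seed(seed, {
    for (p in seq_len(n_patients)) {
      pid <- sprintf("phantom_%03d", p)
      pdir <- file.path(out_dir, pid)
      dir.create(pdir, showWarnings = FALSE)
      n_tumor <- round(tumor_fraction * slices_per_patient)
      has_tumor <- sample(rep(c(TRUE, FALSE),
                              c(n_tumor, slices_per_patient - n_tumor)))
      for (s in seq_len(slices_per_patient)) {
        pp <- phantom_params(
          image_size = image_size,
          tumor_center = image_size * stats::runif(2, 0.35, 0.65),
          tumor_radius = if (has_tumor[s])
            stats::runif(1, 0.05, 0.16) * image_size else 0,
          boundary_jitter = stats::runif(1, 0, 0.25),
          texture_sd = 0.02,
          seed = sample.int(.Machine$integer.max, 1L))
        ph <- generate_phantom(pp)
        img_path <- file.path(pdir, sprintf("%s_%d.png", pid, s))
        mask_path <- file.path(pdir, sprintf("%s_%d_mask.png", pid, s))
        png::writePNG(array(rep(ph$image, 3L),
                            c(image_size, image_size, 3L)), img_path)
        png::writePNG(ph$mask, mask_path)
        rows[[(p - 1L) * slices_per_patient + s]] <- tibble::tibble(
          patient_id = pid, slice_index = s,
          image_path = img_path, mask_path = mask_path,
          has_tumor = has_tumor[s])
      }
    }
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate an in-memory phantom slice stack
#'
#' Convenience wrapper used for desk-scale training runs: draws `n_slices`
#' phantoms (ignoring the on-disk layout) and returns arrays in the network
#' input contract.
#'
#' @param n_slices number of slices.
#' @param image_size slice side length.
#' @param tumor_fraction fraction of slices with a tumor.
#' @param seed integer seed.
#' @return list with `images` (`size x size x 3 x n`) and `masks`
#'   (`size x size x n`).
#' @export
phantom_slice_stack <- function(n_slices, image_size = 64L,
                                tumor_fraction = 0.7, seed = 1L) {
  images <- array(0, c(image_size, image_size, 3L, n_slices))
  masks <- array(0, c(image_size, image_size, n_slices))
  with_seed(seed, {
    n_tumor <- round(tumor_fraction * n_slices)
    has_tumor <- sample(rep(c(TRUE, FALSE), c(n_tumor, n_slices - n_tumor)))
    for (i in seq_len(n_slices)) {
      pp <- phantom_params(
        image_size = image_size,
        tumor_center = image_size * stats::runif(2, 0.35, 0.65),
        tumor_radius = if (has_tumor[i])
          stats::runif(1, 0.06, 0.18) * image_size else 0,
        boundary_jitter = stats::runif(1, 0, 0.25),
        texture_sd = 0.02,
        seed = sample.int(.Machine$integer.max, 1L))
      ph <- generate_phantom(pp)
      images[, , , i] <- rep(ph$image, 3L)
      masks[, , i] <- ph$mask
    }
  })
  list(images = images, masks = masks)
}
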