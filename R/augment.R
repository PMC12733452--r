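#' Training-time augmentation configuration
#'
#' Each transform is gated by its own independent Bernoulli draw.  Geometric
#' transforms (flip, rotation, elastic deformation) are applied identically
#' to image and mask, with nearest-neighbour resampling for the mask so it
#' stays strictly binary; photometric transforms (Gaussian noise, intensity
#' shift, motion blur) touch the image only.
#'
#' @param flip_probability probability of a horizontal mirror (default 0.5).
#' @param rotation_limit_degrees rotation angle drawn uniformly from
#'   `[-limit, limit]` (default 7).
#' @param elastic_amplitude peak random displacement in pixels (default 10).
#' @param elastic_sigma Gaussian smoothing width of the displacement field
#'   in pixels (default 4).
#' @param noise_sd additive Gaussian noise SD on the unit interval
#'   (default 0.02).
#' @param intensity_shift_limit relative intensity scale drawn from
#'   `[1 - limit, 1 + limit]` (default 0.10).
#' @param motion_blur_sizes integer kernel lengths sampled from (pixels,
#'   default `3:7`).
#' @param motion_blur_directions subset of
#'   `c("horizontal", "vertical", "diagonal")`.
#' @param p_rotation,p_elastic,p_noise,p_intensity,p_blur gate probabilities
#'   of the remaining transforms (default 0.5 each).
#' @return an object of class `sonoseg_augmentation_config`.
#' @export
augmentation_config <- function(flip_probability = 0.5,
                                rotation_limit_degrees = 7,
                                elastic_amplitude = 10,
                                elastic_sigma = 4,
                                noise_sd = 0.02,
                                intensity_shift_limit = 0.10,
                                motion_blur_sizes = 3:7,
                                motion_blur_directions = c("horizontal",
                                                           "vertical",
                                                           "diagonal"),
                                p_rotation = 0.5, p_elastic = 0.5,
                                p_noise = 0.5, p_intensity = 0.5,
                                p_blur = 0.5) {
  stopifnot(flip_probability >= 0, flip_probability <= 1,
            all(motion_blur_sizes %in% 3:7))
  motion_blur_directions <- match.arg(motion_blur_directions,
                                      several.ok = TRUE)
  structure(list(flip_probability = flip_probability,
                 rotation_limit_degrees = rotation_limit_degrees,
                 elastic_amplitude = elastic_amplitude,
                 elastic_sigma = elastic_sigma,
                 noise_sd = noise_sd,
                 intensity_shift_limit = intensity_shift_limit,
                 motion_blur_sizes = as.integer(motion_blur_sizes),
                 motion_blur_directions = motion_blur_directions,
                 p_rotation = p_rotation, p_elastic = p_elastic,
                 p_noise = p_noise, p_intensity = p_intensity,
                 p_blur = p_blur),
            class = "sonoseg_augmentation_config")
}

# package-local call audit so tests can assert which loaders augment
the_audit <- new.env(parent = emptyenv())
the_audit$augment_calls <- 0L

#' Augmentation call audit
#'
#' `augment_calls()` returns how many times [augment_slice()] has run since
#' the last [reset_augment_audit()]; used to verify that validation and test
#' data are never augmented.
#'
#' @return integer count.
#' @export
augment_calls <- function() the_audit$augment_calls

#' @rdname augment_calls
#' @export
reset_augment_audit <- function() {
  the_audit$augment_calls <- 0L
  invisible(NULL)
}

#' Augment one preprocessed slice pair
#'
#' @param pair list with `image` (`H x W (x C)`, unit interval) and `mask`
#'   (`H x W`, 0/1).
#' @param config an [augmentation_config()].
#' @return a pair of the same shapes; the image is clipped to `[0, 1]` and
#'   the mask remains strictly 0/1.  With all gate probabilities zero the
#'   input is returned unchanged.
#' @export
augment_slice <- function(pair, config = augmentation_config()) {
  stopifnot(inherits(config, "sonoseg_augmentation_config"))
  the_audit$augment_calls <- the_audit$augment_calls + 1L
  img <- pair$image
  msk <- pair$mask
  if (stats::runif(1) < config$flip_probability) {
    img <- flip_h(img)
    msk <- flip_h(msk)
  }
  if (stats::runif(1) < config$p_rotation && config$rotation_limit_degrees > 0) {
    ang <- stats::runif(1, -config$rotation_limit_degrees,
                        config$rotation_limit_degrees)
    img <- warp_rotate(img, ang, bilinear = TRUE)
    msk <- warp_rotate(msk, ang, bilinear = FALSE)
  }
  if (stats::runif(1) < config$p_elastic && config$elastic_amplitude > 0) {
    d <- dim(msk)
    fld <- elastic_field(d, config$elastic_amplitude, config$elastic_sigma)
    img <- warp_displace(img, fld, bilinear = TRUE)
    msk <- warp_displace(msk, fld, bilinear = FALSE)
  }
  if (stats::runif(1) < config$p_noise && config$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = config$noise_sd)
  }
  if (stats::runif(1) < config$p_intensity && config$intensity_shift_limit > 0) {
    img <- img * (1 + stats::runif(1, -config$intensity_shift_limit,
                                   config$intensity_shift_limit))
  }
  if (stats::runif(1) < config$p_blur) {
    size <- sample(config$motion_blur_sizes, 1L)
    dir <- sample(config$motion_blur_directions, 1L)
    img <- motion_blur(img, size, dir)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = msk)
}

flip_h <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) x[, d[2]:1, , drop = FALSE] else x[, d[2]:1, drop = FALSE]
}

# rotate about the image center by `degrees` (resampling the source at the
# inversely rotated target coordinates)
warp_rotate <- function(x, degrees, bilinear = TRUE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- degrees * pi / 180
  rows <- matrix(seq_len(H), H, W) - cy
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- cos(a) * rows - sin(a) * cols + cy
  sx <- sin(a) * rows + cos(a) * cols + cx
  sample_grid(x, sy, sx, bilinear)
}

# smoothed random displacement field (one field shared by image and mask)
elastic_field <- function(d, amplitude, sigma) {
  raw_y <- matrix(stats::rnorm(prod(d[1:2])), d[1], d[2])
  raw_x <- matrix(stats::rnorm(prod(d[1:2])), d[1], d[2])
  fy <- gaussian_smooth(raw_y, sigma)
  fx <- gaussian_smooth(raw_x, sigma)
  mx <- max(abs(c(fy, fx)), 1e-12)
  list(dy = fy / mx * amplitude, dx = fx / mx * amplitude)
}

warp_displace <- function(x, fld, bilinear = TRUE) {
  d <- dim(x)
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  sample_grid(x, rows + fld$dy, cols + fld$dx, bilinear)
}

# sample a (H, W (, C)) array at fractional source coordinates with border
# clamping; bilinear for intensities, nearest for labels
sample_grid <- function(x, sy, sx, bilinear = TRUE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  had_c <- length(d) == 3L
  if (!had_c) dim(x) <- c(H, W, 1L)
  C <- dim(x)[3]
  out <- array(0, dim(x))
  if (bilinear) {
    y0 <- pmin(pmax(floor(sy), 1), H); x0 <- pmin(pmax(floor(sx), 1), W)
    y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
    wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
    for (c in seq_len(C)) {
      xc <- x[, , c]
      out[, , c] <-
        xc[cbind(c(y0), c(x0))] * (1 - wy) * (1 - wx) +
        xc[cbind(c(y1), c(x0))] * wy * (1 - wx) +
        xc[cbind(c(y0), c(x1))] * (1 - wy) * wx +
        xc[cbind(c(y1), c(x1))] * wy * wx
    }
  } else {
    yn <- pmin(pmax(round(sy), 1), H)
    xn <- pmin(pmax(round(sx), 1), W)
    for (c in seq_len(C)) {
      xc <- x[, , c]
      out[, , c] <- xc[cbind(c(yn), c(xn))]
    }
  }
  if (!had_c) dim(out) <- c(H, W)
  out
}

# separable Gaussian smoothing with border replication
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sm_axis <- function(mm, along_rows) {
    n <- if (along_rows) nrow(mm) else ncol(mm)
    acc <- 0
    for (t in -r:r) {
      idx <- pmin(pmax(seq_len(n) + t, 1), n)
      acc <- acc + k[t + r + 1] * (if (along_rows) mm[idx, , drop = FALSE]
                                   else mm[, idx, drop = FALSE])
    }
    acc
  }
  sm_axis(sm_axis(m, TRUE), FALSE)
}

# mean filter along a line of `size` pixels (border replication)
motion_blur <- function(x, size, direction) {
  d <- dim(x)
  had_c <- length(d) == 3L
  if (!had_c) dim(x) <- c(d, 1L)
  H <- dim(x)[1]; W <- dim(x)[2]
  offs <- (0:(size - 1L)) - (size - 1L) %/% 2L
  step <- switch(direction,
                 horizontal = c(0L, 1L),
                 vertical = c(1L, 0L),
                 diagonal = c(1L, 1L))
  acc <- array(0, dim(x))
  for (t in offs) {
    yi <- pmin(pmax(seq_len(H) + t * step[1], 1L), H)
    xi <- pmin(pmax(seq_len(W) + t * step[2], 1L), W)
    acc <- acc + x[yi, xi, , drop = FALSE]
  }
  out <- acc / size
  if (!had_c) dim(out) <- dim(out)[1:2]
  out
}
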