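#' Render a scalar grid through a colormap
#'
#' The grid is min-max normalized to `[0, 1]` (a constant grid maps to 0),
#' then linearly interpolated into an ordered RGB table: the grid minimum
#' maps exactly to the first color and the maximum exactly to the last.
#'
#' @param grid finite numeric matrix.
#' @param colormap an `n x 3` matrix of RGB rows in `[0, 1]` (n >= 2), or a
#'   character vector of colors.  Default: a black-red-yellow-white "hot"
#'   ramp.
#' @return an 8-bit integer `H x W x 3` RGB array.
#' @export
render_colormap <- function(grid, colormap = sonoseg_colormap()) {
  stopifnot(all(is.finite(grid)))
  cm <- resolve_colormap(colormap)
  rng <- range(grid)
  t <- if (rng[2] > rng[1]) (grid - rng[1]) / (rng[2] - rng[1]) else grid * 0
  interp_colormap(t, cm)
}

sonoseg_colormap <- function() {
  c("black", "darkred", "red", "orange", "yellow", "white")
}

resolve_colormap <- function(colormap) {
  cm <- if (is.character(colormap)) {
    t(grDevices::col2rgb(colormap)) / 255
  } else colormap
  if (!is.matrix(cm) || nrow(cm) < 2L || ncol(cm) != 3L) {
    abort_sonoseg("colormap needs at least 2 RGB entries",
                  class = "sonoseg_color_error")
  }
  cm
}

# t in [0,1] (any shape) -> 8-bit RGB array via piecewise-linear interpolation
interp_colormap <- function(t, cm) {
  n <- nrow(cm)
  pos <- pmin(pmax(t, 0), 1) * (n - 1)
  lo <- pmin(floor(pos), n - 2)
  w <- pos - lo
  out <- array(0L, c(dim(t), 3L))
  for (c in 1:3) {
    v <- cm[lo + 1, c] * (1 - w) + cm[lo + 2, c] * w
    out[, , c] <- as.integer(round(v * 255))
  }
  out
}

#' Overlay a probability map on a grayscale base image
#'
#' The base is blended with the colormapped probabilities using an alpha
#' that scales with the probability itself, so zero-probability pixels show
#' the untouched anatomy and confident lesion pixels take the full map
#' color:
#' `out = base * (1 - alpha * p) + color(p) * alpha * p`.
#'
#' @param image unit-interval grayscale matrix (or `H x W x C`, averaged).
#' @param prob probability matrix in `[0, 1]`, same spatial size.
#' @param colormap as in [render_colormap()].
#' @param alpha maximum blend weight in `[0, 1]`.
#' @return an 8-bit integer `H x W x 3` RGB array.
#' @export
render_overlay <- function(image, prob, colormap = sonoseg_colormap(),
                           alpha = 0.6) {
  g <- to_gray(image)
  if (!identical(dim(g), dim(prob))) {
    abort_sonoseg("image and probability shapes differ",
                  class = "sonoseg_shape_error")
  }
  cm <- resolve_colormap(colormap)
  color <- interp_colormap(prob, cm)      # uses prob directly, not min-max
  w <- alpha * prob
  out <- array(0L, c(dim(g), 3L))
  base255 <- g * 255
  for (c in 1:3) {
    out[, , c] <- as.integer(round(base255 * (1 - w) + color[, , c] * w))
  }
  out
}

#' Write an 8-bit RGB array as PNG
#'
#' @param rgb integer `H x W x 3` array (0..255).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}
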