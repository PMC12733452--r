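#' Z-score map relative to a reference region
#'
#' Standardizes every pixel against the intensity distribution of the
#' reference region (normal-appearing brain: brain foreground minus the
#' predicted lesion).  A zero-variance reference yields an all-zero map with
#' a warning.
#'
#' @param image unit-interval intensity matrix (multi-channel arrays are
#'   averaged to one channel first).
#' @param reference_mask binary matrix marking reference pixels; needs at
#'   least 2.
#' @return matrix of z-scores, same spatial size.
#' @export
zscore_map <- function(image, reference_mask) {
  image <- to_gray(image)
  if (!identical(dim(image), dim(reference_mask))) {
    abort_sonoseg("image and reference_mask shapes differ",
                  class = "sonoseg_shape_error")
  }
  ref <- image[reference_mask > 0]
  if (length(ref) < 2L) {
    abort_sonoseg("reference region has fewer than 2 pixels",
                  class = "sonoseg_anomaly_error")
  }
  mu <- mean(ref)
  s <- stats::sd(ref)
  if (s == 0) {
    warning("reference region has zero variance; returning all-zero z map")
    return(image * 0)
  }
  (image - mu) / s
}

to_gray <- function(image) {
  d <- dim(image)
  if (length(d) == 3L) {
    g <- image[, , 1]
    if (d[3] > 1L) for (c in 2:d[3]) g <- g + image[, , c]
    g / d[3]
  } else image
}

#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance; used to
#' delineate brain foreground from background.
#'
#' @param image unit-interval matrix.
#' @param n_bins histogram resolution.
#' @return scalar threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- if (is.null(dim(image))) as.vector(image) else as.vector(to_gray(image))
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  which.max(sb) / n_bins
}

# label 8-connected components of a binary matrix (integer label matrix,
# 0 = background)
label_components <- function(mask) {
  d <- dim(mask)
  pos <- which(mask > 0)
  lab <- matrix(0L, d[1], d[2])
  if (length(pos) == 0L) return(lab)
  id <- matrix(0L, d[1], d[2])
  id[pos] <- seq_along(pos)
  H <- d[1]; W <- d[2]
  edges <- list()
  # connect each positive pixel to its E, S, SE and SW positive neighbors
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    yr <- seq_len(H); xr <- seq_len(W)
    ny <- yr + off[1]; nx <- xr + off[2]
    vy <- which(ny >= 1L & ny <= H); vx <- which(nx >= 1L & nx <= W)
    a1 <- id[vy, vx, drop = FALSE]
    a2 <- id[ny[vy], nx[vx], drop = FALSE]
    both <- a1 > 0L & a2 > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(a1[both], a2[both])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0L, 2L),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(pos) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[pos] <- as.integer(comp[seq_along(pos)])
  lab
}

#' Extract region-level features from a binary mask
#'
#' Connected components are 8-connected.  Per region: area (pixels),
#' centroid (mean pixel coordinates, row/col, 1-based, origin top-left),
#' perimeter (count of 4-neighbor pixel edges bordering background or the
#' image boundary), shape complexity `perimeter^2 / (4 pi area)` (1 for an
#' ideal disk, larger for irregular shapes -- used as the texture/morphology
#' proxy), intensity statistics, z-score statistics and a severity label
#' from [classify_severity()].
#'
#' @param mask binary matrix.
#' @param image optional unit-interval intensity matrix for intensity stats.
#' @param z_grid optional z-score map from [zscore_map()].
#' @param min_size regions smaller than this many pixels are discarded as
#'   speckle (default 5; use 1 to keep everything).
#' @param severity_thresholds `(moderate, high)` z thresholds, see
#'   [classify_severity()].
#' @return a tibble of class `sonoseg_regions`, one row per region, sorted
#'   by descending area (`region_id` reassigned after sorting).
#' @export
extract_regions <- function(mask, image = NULL, z_grid = NULL, min_size = 5L,
                            severity_thresholds = c(moderate = 2, high = 3)) {
  if (!is.null(image) && !identical(dim(mask), dim(to_gray(image)))) {
    abort_sonoseg("mask and image shapes differ", class = "sonoseg_shape_error")
  }
  if (!is.null(z_grid) && !identical(dim(mask), dim(z_grid))) {
    abort_sonoseg("mask and z_grid shapes differ", class = "sonoseg_shape_error")
  }
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) {
    return(empty_regions())
  }
  image <- if (!is.null(image)) to_gray(image)
  H <- nrow(mask); W <- ncol(mask)
  rows_i <- row(mask); cols_i <- col(mask)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    sel <- lab == r
    area <- sum(sel)
    if (area < min_size) next
    per <- region_perimeter(sel)
    zvals <- if (!is.null(z_grid)) z_grid[sel]
    ivals <- if (!is.null(image)) image[sel]
    mz <- if (is.null(zvals)) NA_real_ else max(zvals)
    out[[r]] <- tibble::tibble(
      region_id = r,
      area = area,
      centroid_row = mean(rows_i[sel]),
      centroid_col = mean(cols_i[sel]),
      perimeter = per,
      complexity = per^2 / (4 * pi * area),
      mean_intensity = if (is.null(ivals)) NA_real_ else mean(ivals),
      max_intensity = if (is.null(ivals)) NA_real_ else max(ivals),
      mean_zscore = if (is.null(zvals)) NA_real_ else mean(zvals),
      max_zscore = mz,
      severity = if (is.na(mz)) NA_character_
      else classify_severity(mz, severity_thresholds))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_regions())
  res <- dplyr::arrange(res, dplyr::desc(.data$area), .data$region_id)
  res$region_id <- seq_len(nrow(res))
  structure(res, class = c("sonoseg_regions", class(tibble::tibble())))
}

empty_regions <- function() {
  structure(tibble::tibble(
    region_id = integer(), area = integer(), centroid_row = numeric(),
    centroid_col = numeric(), perimeter = integer(), complexity = numeric(),
    mean_intensity = numeric(), max_intensity = numeric(),
    mean_zscore = numeric(), max_zscore = numeric(), severity = character()),
    class = c("sonoseg_regions", class(tibble::tibble())))
}

# count of pixel edges between the region and background / image border
region_perimeter <- function(sel) {
  H <- nrow(sel); W <- ncol(sel)
  p <- array(FALSE, c(H + 2L, W + 2L))
  p[2:(H + 1L), 2:(W + 1L)] <- sel
  core <- p[2:(H + 1L), 2:(W + 1L)]
  sum(core & !p[1:H, 2:(W + 1L)]) + sum(core & !p[3:(H + 2L), 2:(W + 1L)]) +
    sum(core & !p[2:(H + 1L), 1:W]) + sum(core & !p[2:(H + 1L), 3:(W + 2L)])
}

#' Classify anomaly severity from a peak z-score
#'
#' `high` when `max_zscore >= high` threshold, `moderate` when `>=
#' moderate`, otherwise `none`.  Thresholds must satisfy
#' `high > moderate > 0`.
#'
#' @param max_zscore numeric vector of peak z-scores.
#' @param thresholds named or positional numeric `(moderate, high)`,
#'   default `c(2, 3)` standard deviations.
#' @return character vector of severity labels.
#' @export
classify_severity <- function(max_zscore, thresholds = c(moderate = 2, high = 3)) {
  mod <- unname(thresholds[1]); hi <- unname(thresholds[2])
  if (!(hi > mod && mod > 0)) {
    abort_sonoseg("severity thresholds must satisfy high > moderate > 0",
                  class = "sonoseg_anomaly_error")
  }
  ifelse(max_zscore >= hi, "high",
         ifelse(max_zscore >= mod, "moderate", "none"))
}

#' Full anomaly analysis of a slice and its predicted mask
#'
#' Operationalizes "anomalies relative to normal brain": the reference
#' region is the Otsu-thresholded brain foreground minus the predicted
#' lesion; pixel z-scores are computed against it and region features are
#' extracted from the mask.
#'
#' @param image unit-interval intensity matrix (or `H x W x C` array).
#' @param mask binary predicted mask.
#' @param brain_mask optional explicit brain foreground; Otsu-derived when
#'   `NULL`.
#' @param min_size,severity_thresholds passed to [extract_regions()].
#' @return an object of class `sonoseg_anomaly_report`: list with `regions`
#'   (a [extract_regions()] tibble), `reference` (mean, sd, n_pixels),
#'   `image_size`, `parameters`.
#' @export
anomaly_report <- function(image, mask, brain_mask = NULL, min_size = 5L,
                           severity_thresholds = c(moderate = 2, high = 3)) {
  g <- to_gray(image)
  if (is.null(brain_mask)) {
    # threshold the non-lesion intensities so a large bright tumor cannot
    # drag the foreground cut above the normal-brain level
    thr <- otsu_threshold(g[mask == 0])
    brain_mask <- (g >= thr) * 1
  }
  ref_mask <- (brain_mask > 0 & mask == 0) * 1
  z <- zscore_map(g, ref_mask)
  ref <- g[ref_mask > 0]
  regions <- extract_regions(mask, image = g, z_grid = z, min_size = min_size,
                             severity_thresholds = severity_thresholds)
  structure(list(regions = regions,
                 reference = list(mean = mean(ref), sd = stats::sd(ref),
                                  n_pixels = length(ref)),
                 image_size = dim(g),
                 parameters = list(min_size = min_size,
                                   severity_thresholds = severity_thresholds)),
            class = "sonoseg_anomaly_report")
}

#' @export
print.sonoseg_anomaly_report <- function(x, ...) {
  cat(sprintf("<sonoseg_anomaly_report> %d region(s), reference mean %.3f sd %.3f\n",
              nrow(x$regions), x$reference$mean, x$reference$sd))
  invisible(x)
}

#' Serialize an anomaly report as JSON
#'
#' @param report a [anomaly_report()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anomaly_report <- function(report, path) {
  jsonlite::write_json(
    list(regions = as.data.frame(report$regions),
         reference = report$reference,
         image_size = report$image_size,
         parameters = report$parameters),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
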