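#' Index a patient-wise image/mask collection
#'
#' Scans `root_dir` for per-patient subdirectories containing 2-D slice
#' images (PNG or TIFF) paired with binary masks named
#' `<image basename>_mask.<ext>`.  Every image must have a mask partner;
#' an orphan image is an error naming the file.
#'
#' @param root_dir directory of per-patient folders.
#' @return a tibble with one row per slice pair, sorted by `patient_id` then
#'   `slice_index`: columns `patient_id`, `slice_index`, `image_path`,
#'   `mask_path`.
#' @export
index_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) {
    abort_sonoseg(sprintf("dataset root '%s' does not exist", root_dir),
                  class = "sonoseg_io_error")
  }
  patients <- list.dirs(root_dir, recursive = FALSE)
  rows <- list()
  for (pdir in patients) {
    pid <- basename(pdir)
    files <- list.files(pdir, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    is_mask <- grepl("_mask\\.[^.]+$", files, ignore.case = TRUE)
    imgs <- files[!is_mask]
    for (img in imgs) {
      ext <- tools::file_ext(img)
      mask <- sub(sprintf("\\.%s$", ext), sprintf("_mask.%s", ext), img)
      if (!file.exists(mask)) {
        abort_sonoseg(sprintf("image '%s' has no '_mask' partner", img),
                      class = "sonoseg_io_error")
      }
      base <- tools::file_path_sans_ext(basename(img))
      num <- regmatches(base, regexpr("[0-9]+$", base))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid,
        slice_index = if (length(num)) as.integer(num) else NA_integer_,
        image_path = img, mask_path = mask)
    }
  }
  if (length(rows) == 0L) {
    abort_sonoseg("no patients found", class = "sonoseg_io_error")
  }
  idx <- dplyr::bind_rows(rows)
  idx <- dplyr::group_by(idx, .data$patient_id)
  idx <- dplyr::mutate(idx, slice_index = ifelse(
    is.na(.data$slice_index), dplyr::row_number(), .data$slice_index))
  idx <- dplyr::ungroup(idx)
  dplyr::arrange(idx, .data$patient_id, .data$slice_index)
}

#' Patient-level train/validation/test split
#'
#' Patients (never slices) are assigned at random to the three partitions,
#' so no subject contributes slices to more than one of them.  Partition
#' sizes follow a floor-then-remainder rule: train and validation counts are
#' floored, the remainder goes to the test set (110 patients at
#' 0.90/0.05/0.05 gives 99/5/6).
#'
#' @param index a dataset index from [index_dataset()] (or any data frame
#'   with a `patient_id` column).
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed integer seed; the split is reproducible per seed.
#' @return an object of class `sonoseg_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`, `seed`.
#' @export
split_patients <- function(index, fractions = c(0.90, 0.05, 0.05), seed = 42L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  patients <- sort(unique(index$patient_id))
  n <- length(patients)
  if (n < 3L) {
    abort_sonoseg("need at least 3 patients (one per split part)",
                  class = "sonoseg_split_error")
  }
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    abort_sonoseg("split fractions leave an empty partition",
                  class = "sonoseg_split_error")
  }
  perm <- with_seed(seed, sample(patients))
  structure(list(train_ids = sort(perm[seq_len(n_train)]),
                 val_ids = sort(perm[n_train + seq_len(n_val)]),
                 test_ids = sort(perm[n_train + n_val + seq_len(n_test)]),
                 seed = as.integer(seed)),
            class = "sonoseg_split")
}

#' @export
print.sonoseg_split <- function(x, ...) {
  cat(sprintf("<sonoseg_split> %d train / %d val / %d test patients (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Attach split labels to a dataset index
#'
#' @param index a dataset index.
#' @param split a [split_patients()] result.
#' @return the index tibble with a `split` column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
assign_split <- function(index, split) {
  stopifnot(inherits(split, "sonoseg_split"))
  lab <- rep(NA_character_, nrow(index))
  lab[index$patient_id %in% split$train_ids] <- "train"
  lab[index$patient_id %in% split$val_ids] <- "val"
  lab[index$patient_id %in% split$test_ids] <- "test"
  dplyr::mutate(index, split = lab)
}

#' Write the dataset manifest CSV
#'
#' @param index a dataset index (with or without a `split` column).
#' @param path output CSV path.
#' @param split optional [split_patients()] result to attach first.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(index, path, split = NULL) {
  if (!is.null(split)) index <- assign_split(index, split)
  utils::write.csv(index, path, row.names = FALSE)
  invisible(path)
}

#' Load one slice pair from disk
#'
#' Images are returned as 8-bit-range arrays (`H x W x 3`, values 0..255);
#' grayscale inputs are replicated to three channels and alpha channels are
#' dropped.  Masks are binarized at > 127, so both 0/1 and 0/255 encodings
#' load to exact 0/1.
#'
#' @param image_path,mask_path file paths (PNG or TIFF).
#' @return list with `image` (`H x W x 3`, 0..255) and `mask` (`H x W`, 0/1).
#' @export
load_slice_pair <- function(image_path, mask_path) {
  img <- read_image_unit(image_path)
  msk <- read_image_unit(mask_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  if (!identical(dim(img)[1:2], dim(msk)[1:2])) {
    abort_sonoseg(sprintf("image and mask sizes differ for '%s'", image_path),
                  class = "sonoseg_io_error")
  }
  list(image = round(img * 255),
       mask = (round(msk * 255) > 127) * 1)
}

read_image_unit <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else abort_sonoseg(sprintf("unsupported image format '%s'", ext),
                     class = "sonoseg_io_error")
}

#' Preprocess a raw slice to the network input contract
#'
#' Intensities are scaled to `[0, 1]` with the fixed 8-bit divisor 255
#' (inputs whose maximum is already `<= 1` are taken as unit-scaled, which
#' makes the operation idempotent), then the slice is center-cropped or
#' zero-padded symmetrically to `size x size`.  The fixed divisor (rather
#' than per-image min-max) preserves intensity comparability across slices,
#' which the z-score anomaly stage relies on.
#'
#' @param image 2-D matrix or `H x W x C` array, 8-bit range.
#' @param size target side length (default 256).
#' @return array of shape `size x size (x C)`, values in `[0, 1]`.
#' @export
preprocess <- function(image, size = 256L) {
  d <- dim(image)
  if (is.null(d) || any(d == 0L)) {
    abort_sonoseg("zero-sized input image", class = "sonoseg_io_error")
  }
  if (max(image) > 1) image <- image / 255
  crop_pad(image, size)
}

#' @rdname preprocess
#' @param mask binary mask; cropped/padded with the same geometry, never
#'   rescaled.
#' @export
preprocess_mask <- function(mask, size = 256L) {
  d <- dim(mask)
  if (is.null(d) || any(d == 0L)) {
    abort_sonoseg("zero-sized input mask", class = "sonoseg_io_error")
  }
  crop_pad(mask, size)
}

# center crop / symmetric zero-pad each spatial axis to `size`
crop_pad <- function(x, size) {
  d <- dim(x)
  had_c <- length(d) == 3L
  if (!had_c) dim(x) <- c(d, 1L)
  d <- dim(x)
  out <- array(0, c(size, size, d[3]))
  src_r <- axis_window(d[1], size)
  src_c <- axis_window(d[2], size)
  out[src_r$dst, src_c$dst, ] <- x[src_r$src, src_c$src, , drop = FALSE]
  if (!had_c) dim(out) <- c(size, size)
  out
}

axis_window <- function(n, size) {
  if (n >= size) {
    off <- (n - size) %/% 2L
    list(src = (off + 1L):(off + size), dst = seq_len(size))
  } else {
    off <- (size - n) %/% 2L
    list(src = seq_len(n), dst = (off + 1L):(off + n))
  }
}

#' Load a split into preprocessed arrays
#'
#' Reads every slice of the requested partition, preprocesses images and
#' masks to `size x size`, and stacks them.
#'
#' @param index a dataset index.
#' @param split a [split_patients()] result.
#' @param partition `"train"`, `"val"`, or `"test"`.
#' @param size target side length.
#' @return list with `images` (`size x size x 3 x N`, unit interval),
#'   `masks` (`size x size x N`), and the row subset of the index.
#' @export
load_split <- function(index, split, partition = c("train", "val", "test"),
                       size = 256L) {
  partition <- match.arg(partition)
  ids <- switch(partition, train = split$train_ids, val = split$val_ids,
                test = split$test_ids)
  rows <- index[index$patient_id %in% ids, , drop = FALSE]
  n <- nrow(rows)
  images <- array(0, c(size, size, 3L, n))
  masks <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    sp <- load_slice_pair(rows$image_path[i], rows$mask_path[i])
    images[, , , i] <- preprocess(sp$image, size)
    masks[, , i] <- preprocess_mask(sp$mask, size)
  }
  list(images = images, masks = masks, index = rows)
}
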