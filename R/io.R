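#' Load an image set from a metadata table plus TIFF files
#'
#' The metadata table (CSV) must contain the columns `image_id`,
#' `compound_id`, `plate_id`, `well`, `site`, and either a single `path`
#' column pointing to one multi-page TIFF per image (one page per channel) or
#' several `path_<channel>` columns, one single-page TIFF per channel,
#' stacked in metadata column order. An optional logical `control` column
#' marks vehicle-control images. Intensities are returned exactly as stored
#' (the `tiff` reader maps integer samples to `[0, 1]`); no rescaling is
#' applied at load time.
#'
#' @param metadata_table_path Path to the metadata CSV.
#' @param image_root Directory that relative image paths are resolved
#'   against.
#' @return List of [image_record()] objects, one per metadata row, validated
#'   with [validate_image_set()].
#' @export
load_image_set <- function(metadata_table_path, image_root = dirname(metadata_table_path)) {
  md <- utils::read.csv(metadata_table_path, stringsAsFactors = FALSE)
  need <- c("image_id", "compound_id", "plate_id", "well", "site")
  if (!all(need %in% names(md))) {
    stop("metadata table requires columns: ", paste(need, collapse = ", "))
  }
  path_cols <- if ("path" %in% names(md)) {
    "path"
  } else {
    grep("^path_", names(md), value = TRUE)
  }
  if (length(path_cols) == 0L) {
    stop("metadata table needs a 'path' column or 'path_<channel>' columns")
  }
  has_ctrl <- "control" %in% names(md)
  records <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    chans <- list()
    for (pc in path_cols) {
      f <- file.path(image_root, md[[pc]][i])
      if (!file.exists(f)) {
        stop(sprintf("missing image file for image_id '%s': %s",
                     md$image_id[i], f))
      }
      pages <- tiff::readTIFF(f, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      chans <- c(chans, pages)
    }
    px <- array(0, c(dim(chans[[1L]])[1:2], length(chans)))
    for (k in seq_along(chans)) px[, , k] <- chans[[k]]
    cn <- if (length(path_cols) > 1L) {
      sub("^path_", "", path_cols)
    } else {
      paste0("ch", seq_along(chans))
    }
    records[[i]] <- image_record(
      image_id = md$image_id[i], compound_id = md$compound_id[i],
      plate_id = md$plate_id[i], well = md$well[i], site = md$site[i],
      pixels = px, channel_names = cn,
      control = if (has_ctrl) as.logical(md$control[i]) else FALSE
    )
  }
  validate_image_set(records)
  records
}

#' Write an image set as multi-page TIFFs plus a metadata CSV
#'
#' Inverse of [load_image_set()]: one 16-bit multi-page TIFF per image (one
#' page per channel) under `dir/images/`, and `dir/metadata.csv`. Pixel
#' values are assumed to lie in `[0, 1]`; values already quantized to 16-bit
#' levels (`k / 65535`) round-trip exactly.
#'
#' @param records List of image records.
#' @param dir Output directory (created if needed).
#' @return Path of the metadata CSV, invisibly.
#' @export
write_image_set <- function(records, dir) {
  validate_image_set(records)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rel <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    rel[i] <- file.path("images", paste0(r$image_id, ".tif"))
    pages <- lapply(seq_len(dim(r$pixels)[3]), function(k) r$pixels[, , k])
    tiff::writeTIFF(pages, file.path(dir, rel[i]), bits.per.sample = 16L)
  }
  md <- data.frame(
    image_id = image_ids(records),
    compound_id = compound_ids(records),
    plate_id = record_field(records, "plate_id"),
    well = record_field(records, "well"),
    site = vapply(records, `[[`, 0L, "site"),
    control = is_control(records),
    path = rel,
    stringsAsFactors = FALSE
  )
  out <- file.path(dir, "metadata.csv")
  utils::write.csv(md, out, row.names = FALSE)
  invisible(out)
}

#' Default channel-to-RGB mixing matrix
#'
#' Partitions the C fluorescence channels over the three RGB bands in channel
#' order; when several channels map to one band their weights average, so a
#' constant image stays constant after conversion.
#'
#' @param n_channels Number of input channels C.
#' @return A C x 3 non-negative weight matrix with columns `R`, `G`, `B`.
#' @export
default_mixing_matrix <- function(n_channels) {
  stopifnot(n_channels >= 1L)
  band <- cut(seq_len(n_channels) - 0.5, breaks = n_channels * c(0, 1, 2, 3) / 3,
              labels = FALSE)
  m <- matrix(0, n_channels, 3, dimnames = list(NULL, c("R", "G", "B")))
  for (b in 1:3) {
    idx <- which(band == b)
    if (length(idx)) m[idx, b] <- 1 / length(idx)
  }
  m
}

#' Convert a multi-channel record to 3-channel RGB
#'
#' Each output pixel is the input channel vector times a non-negative C x 3
#' mixing matrix, clipped to `[0, 1]`. The mixing matrix is attached to the
#' result as attribute `"mixing"` so runs are reproducible.
#'
#' @param record An [image_record()].
#' @param mixing C x 3 non-negative weight matrix; defaults to
#'   [default_mixing_matrix()].
#' @return An [image_record()] with C = 3 and channels `R`, `G`, `B`.
#' @export
convert_channels_to_rgb <- function(record, mixing = NULL) {
  stopifnot(inherits(record, "image_record"))
  d <- dim(record$pixels)
  if (is.null(mixing)) mixing <- default_mixing_matrix(d[3])
  mixing <- as.matrix(mixing)
  if (!identical(dim(mixing), c(d[3], 3L)) &&
      !identical(dim(mixing), as.integer(c(d[3], 3)))) {
    stop(sprintf("mixing must be %d x 3, got %d x %d",
                 d[3], nrow(mixing), ncol(mixing)))
  }
  if (any(mixing < 0)) stop("mixing weights must be non-negative")
  flat <- matrix(record$pixels, d[1] * d[2], d[3])
  rgb <- flat %*% mixing
  rgb[rgb > 1] <- 1
  out <- record
  out$pixels <- array(rgb, c(d[1], d[2], 3L))
  out$channel_names <- c("R", "G", "B")
  attr(out, "mixing") <- mixing
  out
}

#' Resize a record spatially (bilinear)
#'
#' Bilinear resampling of every channel to the target height and width
#' (default 224 x 224, the input size of the full-scale encoder). An image
#' already at the target size is returned unchanged.
#'
#' @param record An [image_record()].
#' @param target_hw Integer pair `(height, width)`.
#' @return An [image_record()] with resized pixels; channel count unchanged.
#' @export
resize_image <- function(record, target_hw = c(224L, 224L)) {
  stopifnot(inherits(record, "image_record"), length(target_hw) == 2L)
  target_hw <- as.integer(target_hw)
  if (any(target_hw < 1L)) stop("target size must be positive")
  d <- dim(record$pixels)
  if (identical(d[1:2], target_hw)) return(record)
  out <- array(0, c(target_hw, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- EBImage::imageData(EBImage::resize(
      EBImage::Image(record$pixels[, , k]),
      w = target_hw[1], h = target_hw[2], filter = "bilinear"
    ))
  }
  rec <- record
  rec$pixels <- out
  rec
}

#' Preprocess an image set for contrastive training
#'
#' Applies, in order: optional per-image max-reference normalization (divide
#' all channels by the image maximum so the brightest pixel maps to 1),
#' optional channel-to-RGB mixing, and optional spatial resizing. Each step
#' is a no-op when its argument is `NULL`/`FALSE`.
#'
#' @param records List of image records.
#' @param normalize Logical; per-image max normalization (default `TRUE`).
#' @param mixing `NULL` (keep channels), `TRUE` (default mixing matrix) or an
#'   explicit C x 3 matrix.
#' @param target_hw `NULL` (keep size) or integer pair for [resize_image()].
#' @return List of preprocessed image records.
#' @export
preprocess_records <- function(records, normalize = TRUE, mixing = NULL,
                               target_hw = NULL) {
  lapply(records, function(r) {
    if (isTRUE(normalize)) {
      mx <- max(r$pixels)
      if (mx > 0) r$pixels <- r$pixels / mx
    }
    if (!is.null(mixing) && !isFALSE(mixing)) {
      r <- convert_channels_to_rgb(
        r, if (isTRUE(mixing)) NULL else mixing
      )
    }
    if (!is.null(target_hw)) r <- resize_image(r, target_hw)
    r
  })
}
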