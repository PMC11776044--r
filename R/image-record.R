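#' Construct a single field-of-view image record
#'
#' An `image_record` holds one microscopy field of view: a pixel stack of
#' dimension H x W x C (intensities in `[0, 1]`) plus the plate/well/site
#' coordinates and the compound treatment it images. Vehicle controls (e.g.
#' DMSO wells) carry `control = TRUE` and are never annotated.
#'
#' @param image_id Unique opaque identifier.
#' @param compound_id Compound identifier, or the control sentinel (any id is
#'   allowed; `control` marks control records).
#' @param plate_id Plate (acquisition batch) identifier.
#' @param well Well coordinate, e.g. `"B07"`.
#' @param site Field-of-view site within the well, integer `>= 1`.
#' @param pixels Numeric H x W x C array of non-negative intensities. A bare
#'   H x W matrix is promoted to a single-channel array.
#' @param channel_names Character vector of length C naming the channels.
#' @param control Logical; `TRUE` for vehicle-control images.
#' @return An object of class `image_record`.
#' @export
image_record <- function(image_id, compound_id, plate_id, well, site,
                         pixels, channel_names = NULL, control = FALSE) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  nc <- dim(pixels)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("channel_names length must equal the number of channels")
  }
  structure(
    list(
      image_id = as.character(image_id),
      compound_id = as.character(compound_id),
      plate_id = as.character(plate_id),
      well = as.character(well),
      site = as.integer(site),
      pixels = pixels,
      channel_names = as.character(channel_names),
      control = isTRUE(control)
    ),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_record %s> compound=%s plate=%s well=%s site=%d  %dx%dx%d%s\n",
    x$image_id, x$compound_id, x$plate_id, x$well, x$site,
    d[1], d[2], d[3], if (x$control) "  [control]" else ""
  ))
  invisible(x)
}

#' Validate a collection of image records
#'
#' Checks that all records share channel count and channel names, that
#' image ids are unique, and that (plate, well, site) is unique per image.
#'
#' @param records List of [image_record()] objects.
#' @return The records, invisibly; errors on violation.
#' @export
validate_image_set <- function(records) {
  stopifnot(length(records) >= 1L)
  ids <- vapply(records, `[[`, "", "image_id")
  if (anyDuplicated(ids)) stop("duplicate image_id in image set")
  ccount <- vapply(records, function(r) dim(r$pixels)[3], 0)
  if (length(unique(ccount)) != 1L) {
    stop("inconsistent channel count across image records")
  }
  cn <- vapply(records, function(r) paste(r$channel_names, collapse = "|"), "")
  if (length(unique(cn)) != 1L) stop("inconsistent channel names")
  pws <- vapply(records, function(r) {
    paste(r$plate_id, r$well, r$site, sep = "/")
  }, "")
  if (anyDuplicated(pws)) stop("duplicate (plate_id, well, site) coordinates")
  invisible(records)
}

record_field <- function(records, field) {
  vapply(records, `[[`, vector(mode = "character", 1L), field)
}

#' Compound id of every record
#' @param records List of image records.
#' @return Character vector, one entry per record.
#' @export
compound_ids <- function(records) record_field(records, "compound_id")

#' Image id of every record
#' @param records List of image records.
#' @return Character vector, one entry per record.
#' @export
image_ids <- function(records) record_field(records, "image_id")

#' Logical control flag of every record
#' @param records List of image records.
#' @return Logical vector, one entry per record.
#' @export
is_control <- function(records) {
  vapply(records, function(r) isTRUE(r$control), TRUE)
}

#' Stack an image set into a B x H x W x C array
#'
#' All records must share identical pixel dimensions.
#'
#' @param records List of image records.
#' @return Numeric 4-d array, first dimension indexing records.
#' @export
stack_pixels <- function(records) {
  d <- dim(records[[1]]$pixels)
  out <- array(0, c(length(records), d))
  for (b in seq_along(records)) {
    if (!identical(dim(records[[b]]$pixels), d)) {
      stop("all records must share pixel dimensions to be stacked")
    }
    out[b, , , ] <- records[[b]]$pixels
  }
  out
}
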