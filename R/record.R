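#' Construct a single-cell IFC record
#'
#' A `cell_record` holds one imaging-flow-cytometry event: a multichannel
#' intensity stack (16-bit dynamic range, unitless counts), one binary
#' segmentation mask per channel, and acquisition metadata. Arrays are stored
#' H x W x C with 0-based (y, x) pixel coordinates implied row-major; masks are
#' logical with `TRUE` = inside the cell.
#'
#' @param record_id opaque string identifying the event.
#' @param channels character vector of unique channel names, one per slice.
#' @param image numeric H x W x C array of nonnegative intensities.
#' @param masks logical (or 0/1) H x W x C array, same shape as `image`.
#' @param meta list with `donor_id`, `experiment_id`, `condition`, and
#'   optionally `label` (a taxonomy class) and `probs` (length-9 simplex).
#' @return A validated object of class `cell_record`.
#' @examples
#' img <- array(0, c(8, 8, 2)); img[3:6, 3:6, 1] <- 100
#' msk <- img > 0
#' r <- cell_record("r1", c("BF", "CD3"), img, msk,
#'                  list(donor_id = "d1", experiment_id = "e1",
#'                       condition = "ctrl"))
#' @export
cell_record <- function(record_id, channels, image, masks, meta = list()) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (is.matrix(masks)) masks <- array(masks, c(dim(masks), 1L))
  storage.mode(image) <- "double"
  masks <- array(as.logical(masks), dim(masks))
  rec <- structure(
    list(record_id = as.character(record_id),
         channels = as.character(channels),
         image = image, masks = masks, meta = meta),
    class = "cell_record"
  )
  validate_cell_record(rec)
  rec
}

#' Validate a cell_record's invariants
#'
#' Checks shared image/mask shape, nonnegative intensities, unique channel
#' names matching the third dimension, and (when present) that `probs` is a
#' simplex summing to 1 within 1e-9.
#'
#' @param rec a `cell_record`.
#' @return `rec`, invisibly; stops with a descriptive error on violation.
#' @export
validate_cell_record <- function(rec) {
  if (!is.array(rec$image) || length(dim(rec$image)) != 3L)
    stop("image must be an H x W x C array")
  if (!identical(dim(rec$image), dim(rec$masks)))
    stop("image and masks must share shape: image ",
         paste(dim(rec$image), collapse = "x"), " vs masks ",
         paste(dim(rec$masks), collapse = "x"))
  if (anyNA(rec$image) || min(rec$image) < 0)
    stop("intensities must be nonnegative and non-missing")
  nch <- dim(rec$image)[3L]
  if (length(rec$channels) != nch)
    stop("channels length (", length(rec$channels),
         ") must equal number of slices (", nch, ")")
  if (anyDuplicated(rec$channels))
    stop("channel names must be unique")
  p <- rec$meta$probs
  if (!is.null(p)) {
    if (length(p) != 9L) stop("probs must have length 9")
    if (abs(sum(p) - 1) > 1e-9) stop("probs must sum to 1 within 1e-9")
  }
  lb <- rec$meta$label
  if (!is.null(lb) && !lb %in% class_taxonomy()$classes)
    stop("unknown class label: ", lb)
  invisible(rec)
}

#' @export
print.cell_record <- function(x, ...) {
  d <- dim(x$image)
  cat("cell_record ", x$record_id, ": ", d[1], "x", d[2], " px, ",
      d[3], " channels (", paste(x$channels, collapse = ", "), ")\n", sep = "")
  m <- x$meta
  cat("  donor ", m$donor_id %||% "?", ", experiment ",
      m$experiment_id %||% "?", ", condition ", m$condition %||% "?",
      if (!is.null(m$label)) paste0(", label '", m$label, "'") else "",
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one channel's image or mask
#' @param rec a `cell_record`.
#' @param channel channel name.
#' @return For `channel_image`, the H x W intensity matrix; for
#'   `channel_mask`, the logical H x W mask.
#' @export
channel_image <- function(rec, channel) {
  i <- match(channel, rec$channels)
  if (is.na(i)) stop("channel not in record: ", channel)
  rec$image[, , i]
}

#' @rdname channel_image
#' @export
channel_mask <- function(rec, channel) {
  i <- match(channel, rec$channels)
  if (is.na(i)) stop("channel not in record: ", channel)
  rec$masks[, , i]
}
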