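#' Write a cell_record to a single HDF5 file
#'
#' One record per file, enabling embarrassingly parallel feature extraction.
#' On-disk layout: dataset `image` (uint16, C x H x W), `masks` (uint8 0/1,
#' C x H x W), `channels` (strings), optional `probs` (float64, length 9), and
#' a group `meta` carrying donor_id / experiment_id / condition / label as
#' scalar string attributes. Integer intensity grids round-trip bit-exactly.
#'
#' @param record a validated [cell_record()].
#' @param path destination file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [read_record()]
#' @export
write_record <- function(record, path) {
  validate_cell_record(record)
  if (max(record$image) > 65535)
    stop("intensities exceed the 16-bit range")
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!ok) stop("cannot create HDF5 file at ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  img <- aperm(record$image, c(3L, 1L, 2L))   # C x H x W
  msk <- aperm(array(as.integer(record$masks), dim(record$masks)), c(3L, 1L, 2L))
  storage.mode(img) <- "integer"
  rhdf5::h5createDataset(path, "image", dims = dim(img), H5type = "H5T_STD_U16LE")
  rhdf5::h5write(img, path, "image")
  rhdf5::h5createDataset(path, "masks", dims = dim(msk), H5type = "H5T_STD_U8LE")
  rhdf5::h5write(msk, path, "masks")
  rhdf5::h5write(record$channels, path, "channels")
  if (!is.null(record$meta$probs))
    rhdf5::h5write(as.double(record$meta$probs), path, "probs")

  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  scalars <- c("record_id" = record$record_id,
               "donor_id" = record$meta$donor_id %||% NA_character_,
               "experiment_id" = record$meta$experiment_id %||% NA_character_,
               "condition" = record$meta$condition %||% NA_character_)
  for (nm in names(scalars)) {
    if (!is.na(scalars[[nm]]))
      rhdf5::h5writeAttribute(scalars[[nm]], gid, nm)
  }
  if (!is.null(record$meta$label))
    rhdf5::h5writeAttribute(record$meta$label, gid, "label")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a cell_record from an HDF5 file
#'
#' Expects the layout written by [write_record()]. Unknown extra top-level
#' datasets are ignored with a warning; a missing required dataset raises an
#' error naming it.
#'
#' @param path HDF5 file path.
#' @return A validated [cell_record()].
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  listing <- tryCatch(
    rhdf5::h5ls(path, recursive = FALSE),
    error = function(e) stop("cannot read HDF5 file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- listing$name
  for (req in c("image", "masks", "channels")) {
    if (!req %in% present)
      stop("file '", path, "' lacks required dataset '", req, "'")
  }
  known <- c("image", "masks", "channels", "probs", "meta")
  extra <- setdiff(present, known)
  if (length(extra))
    warning("ignoring unknown dataset(s) in '", path, "': ",
            paste(extra, collapse = ", "))

  img <- aperm(rhdf5::h5read(path, "image"), c(2L, 3L, 1L))
  msk <- aperm(rhdf5::h5read(path, "masks"), c(2L, 3L, 1L))
  channels <- as.character(rhdf5::h5read(path, "channels"))
  at <- rhdf5::h5readAttributes(path, "meta")
  meta <- list(donor_id = as.character(at$donor_id %||% NA),
               experiment_id = as.character(at$experiment_id %||% NA),
               condition = as.character(at$condition %||% NA))
  if (!is.null(at$label)) meta$label <- as.character(at$label)
  if ("probs" %in% present) meta$probs <- as.double(rhdf5::h5read(path, "probs"))
  cell_record(record_id = as.character(at$record_id %||% basename(path)),
              channels = channels,
              image = array(as.double(img), dim(img)),
              masks = msk > 0,
              meta = meta)
}
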