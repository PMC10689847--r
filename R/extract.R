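#' Extract an inventory's features from a set of records
#'
#' Computes one row of named features per record. Rows are independent, so
#' extraction can run on parallel workers (`parallel::mclapply`) with output
#' identical to serial execution. A per-record failure yields a missing row
#' plus a warning, never an aborted batch.
#'
#' @param records list of [cell_record()] objects, or a [dataset_index()]
#'   whose `path`s are read on the fly.
#' @param inventory a `feature_inventory`.
#' @param t_channel,b_channel channels defining the synapse mask (see
#'   [derive_synapse_mask()]).
#' @param dilation synapse-mask dilation radius.
#' @param workers number of parallel workers (default 1 = serial).
#' @return A `feature_table`: data.frame with rownames = record ids, one
#'   numeric column per inventory entry (inventory order), and attribute
#'   `inventory_hash`.
#' @export
extract_features <- function(records, inventory,
                             t_channel = "CD3", b_channel = "MHCII",
                             dilation = 3L, workers = 1L) {
  if (inherits(records, "dataset_index")) {
    paths <- records$path
    ids <- records$record_id
    getter <- function(i) read_record(paths[i])
    n <- length(paths)
  } else {
    ids <- vapply(records, function(r) r$record_id, character(1))
    getter <- function(i) records[[i]]
    n <- length(records)
  }
  one <- function(i) {
    tryCatch(
      compute_record_features(getter(i), inventory, t_channel, b_channel,
                              dilation),
      error = function(e) {
        warning("feature extraction failed for record '", ids[i], "': ",
                conditionMessage(e), call. = FALSE)
        stats::setNames(rep(NA_real_, nrow(inventory)), inventory$name)
      })
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(n), one, mc.cores = workers)
  } else {
    lapply(seq_len(n), one)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- ids
  attr(tab, "inventory_hash") <- inventory_hash(inventory)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# All features of one record, in inventory order.
compute_record_features <- function(rec, inventory, t_channel, b_channel,
                                    dilation) {
  out <- stats::setNames(rep(NA_real_, nrow(inventory)), inventory$name)

  need_syn <- any(inventory$family == "synaptic")
  syn <- if (need_syn) derive_synapse_mask(rec, t_channel, b_channel, dilation)
         else NULL

  qc_done <- FALSE
  per_channel <- split(seq_len(nrow(inventory)), inventory$channels)
  for (chspec in names(per_channel)) {
    idx <- per_channel[[chspec]]
    sub <- inventory[idx, , drop = FALSE]
    if (grepl("|", chspec, fixed = TRUE)) {                 # channel pair
      chs <- strsplit(chspec, "|", fixed = TRUE)[[1]]
      vals <- colocalization_features(channel_image(rec, chs[1]),
                                      channel_mask(rec, chs[1]),
                                      channel_image(rec, chs[2]),
                                      channel_mask(rec, chs[2]))
      out[idx] <- vals[sub$stat]
      next
    }
    ch <- chspec
    img <- channel_image(rec, ch)
    msk <- channel_mask(rec, ch)
    fams <- unique(sub$family)
    if (any(sub$stat %in% c("mean", "sum", "min", "max", "sd", "skewness",
                            "kurtosis", "entropy") |
            grepl("^p[0-9]+$", sub$stat))) {
      iv <- intensity_features(img, msk)
      hit <- sub$stat %in% names(iv)
      out[idx[hit]] <- iv[sub$stat[hit]]
    }
    if ("texture" %in% fams) {
      tv <- texture_features(img, msk)
      hit <- sub$stat %in% names(tv)
      out[idx[hit]] <- tv[sub$stat[hit]]
    }
    if ("synaptic" %in% fams) {
      sv <- synaptic_features(img, msk, syn)
      hit <- sub$stat %in% names(sv)
      out[idx[hit]] <- sv[sub$stat[hit]]
    }
    if (any(sub$stat == "area")) out[idx[sub$stat == "area"]] <- sum(msk)
    morph_stats <- sub$stat[!sub$stat %in% c("area", "bgmean", "grms") &
                            sub$family == "morphology"]
    if (length(morph_stats)) {
      mv <- morphology_features(msk, img)
      names(mv)[names(mv) == "area"] <- "area2"
      hit <- sub$stat %in% names(mv)
      out[idx[hit]] <- mv[sub$stat[hit]]
    }
    if ("qc" %in% fams) {
      if (!qc_done) { qcv <- qc_features(rec); qc_done <- TRUE }
      want <- paste0(ch, "_", sub$stat[sub$family == "qc"])
      out[idx[sub$family == "qc"]] <- qcv[want]
    }
  }
  out
}

#' Serialize / load a feature table as CSV
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly; the reader returns
#'   a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(record_id = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab <- df[, -1, drop = FALSE]
  rownames(tab) <- df$record_id
  class(tab) <- c("feature_table", "data.frame")
  tab
}
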