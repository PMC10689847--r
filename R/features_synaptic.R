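#' Derive the synapse (contact-zone) mask of a conjugate
#'
#' The synapse mask is the intersection of the T-cell and B-cell masks after
#' each has been dilated with a disk structuring element (default radius 3
#' pixels). An empty result is a valid "no contact" measurement. The
#' intersection-of-dilations form localizes the contact zone between the two
#' cells; a union would cover both cell bodies and flatten any enrichment
#' signal.
#'
#' @param record a [cell_record()].
#' @param t_channel channel whose mask marks the T cell (default `"CD3"`).
#' @param b_channel channel whose mask marks the B cell (default `"MHCII"`).
#' @param dilation disk radius in pixels.
#' @return Object of class `synapse_mask`: a logical matrix with attribute
#'   `dilation`.
#' @export
derive_synapse_mask <- function(record, t_channel = "CD3", b_channel = "MHCII",
                                dilation = 3L) {
  for (ch in c(t_channel, b_channel)) {
    if (!ch %in% record$channels)
      stop("required channel absent from record: ", ch)
  }
  mt <- channel_mask(record, t_channel)
  mb <- channel_mask(record, b_channel)
  syn <- dilate_mask(mt, dilation) & dilate_mask(mb, dilation)
  structure(syn, dilation = dilation, class = c("synapse_mask", class(syn)))
}

# Binary dilation with a disk structuring element of the given radius.
dilate_mask <- function(mask, radius) {
  if (!any(mask) || radius <= 0) return(mask > 0)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  as.matrix(EBImage::dilate(EBImage::Image((mask > 0) * 1), brush)) > 0
}

#' Synaptic enrichment of a channel
#'
#' Ratios of the channel's intensity inside the synapse mask to that over the
#' whole cell: `enrich_mean` = mean(in synapse)/mean(in cell), `enrich_sum` =
#' sum(in synapse)/sum(in cell), `enrich_max` = max(in synapse)/mean(in
#' cell). An empty synapse mask is a real "no contact" measurement and yields
#' all three equal to 0; an all-zero channel (zero denominator) yields
#' missing values.
#'
#' @param image numeric matrix (the channel).
#' @param cell_mask logical matrix (the channel's cell mask, non-empty).
#' @param synapse logical matrix from [derive_synapse_mask()].
#' @return Named numeric vector: `enrich_mean`, `enrich_sum`, `enrich_max`.
#' @export
synaptic_features <- function(image, cell_mask, synapse) {
  nm <- c("enrich_mean", "enrich_sum", "enrich_max")
  out <- stats::setNames(rep(NA_real_, 3L), nm)
  cm <- cell_mask > 0
  if (!any(cm)) return(out)
  if (!any(synapse > 0)) {
    out[] <- 0
    return(out)
  }
  cell_vals <- image[cm]
  syn_vals <- image[synapse > 0]
  mu_cell <- mean(cell_vals); s_cell <- sum(cell_vals)
  if (mu_cell > 0) {
    out["enrich_mean"] <- mean(syn_vals) / mu_cell
    out["enrich_max"] <- max(syn_vals) / mu_cell
  }
  if (s_cell > 0) out["enrich_sum"] <- sum(syn_vals) / s_cell
  out
}

#' Image quality-control features per channel
#'
#' `bgmean` is the mean intensity outside the union of all channel masks
#' (missing if the union covers the whole frame); `grms` is the
#' root-mean-square Sobel gradient magnitude within the channel's mask (or
#' over the whole valid interior if the mask is empty) — low values indicate
#' out-of-focus images.
#'
#' @param record a [cell_record()].
#' @return Named numeric vector `<channel>_bgmean`, `<channel>_grms` for each
#'   channel.
#' @export
qc_features <- function(record) {
  bg <- !apply(record$masks, c(1, 2), any)
  out <- numeric(0)
  for (i in seq_along(record$channels)) {
    ch <- record$channels[i]
    img <- record$image[, , i]
    v <- stats::setNames(rep(NA_real_, 2L), paste0(ch, c("_bgmean", "_grms")))
    if (any(bg)) v[1] <- mean(img[bg])
    v[2] <- gradient_rms(img, record$masks[, , i])
    out <- c(out, v)
  }
  out
}

# RMS of Sobel gradient magnitude within the mask (whole interior if empty).
# Computed on the valid interior (no padding).
gradient_rms <- function(img, mask = NULL) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3 || W < 3) return(0)
  ri <- 2:(H - 1); ci <- 2:(W - 1)
  sh <- function(dr, dc) img[ri + dr, ci + dc]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag2 <- gx^2 + gy^2
  if (!is.null(mask) && any(mask > 0)) {
    sel <- (mask > 0)[ri, ci]
    if (!any(sel)) return(0)
    sqrt(mean(mag2[sel]))
  } else {
    sqrt(mean(mag2))
  }
}
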