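#' Co-localization features between two channels
#'
#' Seventeen named values describing how two channels' masks and intensities
#' co-occur:
#' * mask overlap: `dice_dist`, `jaccard_dist`, `inter_area`, `union_area`,
#'   `inter_over_min` (intersection / smaller mask area);
#' * intensity agreement over the union-of-masks pixel set: `corr_dist`
#'   (1 - Pearson), `eucl_dist`, `cosine_dist`, `pearson`, `spearman`,
#'   `mutual_info` (16 x 16 joint histogram, natural log);
#' * co-occurrence coefficients over the union set: `manders_m1` (fraction of
#'   A's intensity on B's mask), `manders_m2` (converse), `overlap_coef`
#'   (Manders overlap coefficient), `icq` (intensity correlation quotient,
#'   in \[-0.5, 0.5\]);
#' * `ssim` (structural similarity of the full frames, single-window,
#'   data-range dynamic) and `hausdorff` (Hausdorff distance between the two
#'   mask point sets, in pixels).
#'
#' @param image_a,image_b numeric matrices (same extent).
#' @param mask_a,mask_b logical matrices.
#' @return Named numeric vector of length 17; all missing when both masks are
#'   empty.
#' @export
colocalization_features <- function(image_a, mask_a, image_b, mask_b) {
  nm <- c("dice_dist", "jaccard_dist", "inter_area", "union_area",
          "inter_over_min", "corr_dist", "eucl_dist", "cosine_dist",
          "pearson", "spearman", "mutual_info", "manders_m1", "manders_m2",
          "overlap_coef", "icq", "ssim", "hausdorff")
  out <- stats::setNames(rep(NA_real_, 17L), nm)
  ma <- mask_a > 0; mb <- mask_b > 0
  if (!any(ma) && !any(mb)) return(out)

  inter <- sum(ma & mb); uni <- sum(ma | mb)
  na <- sum(ma); nb <- sum(mb)
  out["inter_area"] <- inter
  out["union_area"] <- uni
  out["dice_dist"] <- if (na + nb > 0) 1 - 2 * inter / (na + nb) else NA_real_
  out["jaccard_dist"] <- 1 - inter / uni
  out["inter_over_min"] <- if (min(na, nb) > 0) inter / min(na, nb) else NA_real_

  u <- ma | mb
  a <- image_a[u]; b <- image_b[u]
  if (length(a) >= 2L) {
    if (stats::sd(a) > 0 && stats::sd(b) > 0) {
      r <- stats::cor(a, b)
      out["pearson"] <- r
      out["corr_dist"] <- 1 - r
      out["spearman"] <- stats::cor(a, b, method = "spearman")
    }
    out["eucl_dist"] <- sqrt(sum((a - b)^2))
    den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (den > 0) out["cosine_dist"] <- 1 - sum(a * b) / den
    out["mutual_info"] <- hist2d_mutual_information(a, b)
    # Manders split coefficients over the union set
    if (sum(a) > 0) out["manders_m1"] <- sum(a[mb[u]]) / sum(a)
    if (sum(b) > 0) out["manders_m2"] <- sum(b[ma[u]]) / sum(b)
    if (den > 0) out["overlap_coef"] <- sum(a * b) / den
    prod <- (a - mean(a)) * (b - mean(b))
    out["icq"] <- mean(prod > 0) - 0.5
  }
  out["ssim"] <- global_ssim(image_a, image_b)
  out["hausdorff"] <- hausdorff_distance(ma, mb)
  out
}

# Mutual information between two intensity vectors via a 16x16 joint
# histogram of min-max scaled values; natural log.
hist2d_mutual_information <- function(a, b, bins = 16L) {
  sc <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) pmin(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
    else rep(1L, length(v))
  }
  ia <- sc(a); ib <- sc(b)
  J <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins) / length(a)
  J <- matrix(J, bins, bins, byrow = TRUE)
  pa <- rowSums(J); pb <- colSums(J)
  nz <- J > 0
  sum(J[nz] * log(J[nz] / outer(pa, pb)[nz]))
}

# Single-window SSIM over the full frame; data range from the two images.
global_ssim <- function(A, B) {
  L <- max(A, B) - min(A, B)
  if (L <= 0) return(1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- mean(A); mu_b <- mean(B)
  va <- mean((A - mu_a)^2); vb <- mean((B - mu_b)^2)
  cab <- mean((A - mu_a) * (B - mu_b))
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

# Hausdorff distance between mask pixel coordinate sets (Euclidean, pixels).
hausdorff_distance <- function(ma, mb) {
  if (!any(ma) || !any(mb)) return(NA_real_)
  pa <- which(ma, arr.ind = TRUE)
  pb <- which(mb, arr.ind = TRUE)
  d_ab <- max(FNN::get.knnx(pb, pa, k = 1)$nn.dist)
  d_ba <- max(FNN::get.knnx(pa, pb, k = 1)$nn.dist)
  max(d_ab, d_ba)
}
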