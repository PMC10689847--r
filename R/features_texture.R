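#' Gray-level co-occurrence texture features
#'
#' Masked intensities are min-max rescaled and quantized to `levels` gray
#' levels; a single symmetric GLCM is accumulated at distance 1 over the
#' four standard angles (0, 45, 90, 135 degrees), counting only pixel pairs
#' that both lie inside the mask, then normalized. The six Haralick-style
#' statistics (contrast, dissimilarity, homogeneity, ASM, energy,
#' correlation) are computed from that angle-pooled matrix, so energy is
#' exactly sqrt(ASM). For a constant image (single gray level)
#' the matrix is degenerate: contrast and dissimilarity are 0, homogeneity,
#' ASM and energy are 1, and correlation is defined as 1.
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape.
#' @param levels number of quantization levels (default 32).
#' @return Named numeric vector: `glcm_contrast`, `glcm_dissimilarity`,
#'   `glcm_homogeneity`, `glcm_ASM`, `glcm_energy`, `glcm_correlation`.
#'   All missing if the mask is empty or no co-occurring pair exists.
#' @export
texture_features <- function(image, mask, levels = 32L) {
  nm <- paste0("glcm_", c("contrast", "dissimilarity", "homogeneity",
                          "ASM", "energy", "correlation"))
  out <- stats::setNames(rep(NA_real_, 6L), nm)
  m <- mask > 0
  if (!any(m)) return(out)
  q <- quantize_levels(image, m, levels)

  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))  # 0,45,90,135 deg
  P <- NULL
  for (off in offsets) {
    Pk <- glcm_matrix(q, m, off, levels, normalize = FALSE)
    if (!is.null(Pk)) P <- if (is.null(P)) Pk else P + Pk
  }
  if (is.null(P) || sum(P) == 0) return(out)
  out[] <- glcm_stats(P / sum(P), levels)
  out
}

# Quantize masked pixels to 1..levels by min-max rescaling (constant -> 1).
quantize_levels <- function(image, m, levels) {
  q <- matrix(0L, nrow(image), ncol(image))
  v <- image[m]
  rng <- range(v)
  if (rng[2] > rng[1]) {
    z <- (image[m] - rng[1]) / (rng[2] - rng[1])
    q[m] <- pmin(as.integer(floor(z * levels)) + 1L, levels)
  } else {
    q[m] <- 1L
  }
  q
}

# Symmetric co-occurrence matrix for one offset (dr, dc).
glcm_matrix <- function(q, m, off, levels, normalize = TRUE) {
  H <- nrow(q); W <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
  c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
  if (!length(r1) || !length(c1)) return(NULL)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- m[r1, c1, drop = FALSE] & m[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  counts <- tabulate((i - 1L) * levels + j, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)                       # symmetric
  if (normalize) P / sum(P) else P
}

glcm_stats <- function(P, levels) {
  idx <- seq_len(levels)
  I <- matrix(idx, levels, levels)
  J <- t(I)
  D <- I - J
  contrast <- sum(P * D^2)
  dissim <- sum(P * abs(D))
  homog <- sum(P / (1 + D^2))
  asm <- sum(P^2)
  energy <- sqrt(asm)
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  s_i <- sqrt(sum((I - mu_i)^2 * P)); s_j <- sqrt(sum((J - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0)
    sum((I - mu_i) * (J - mu_j) * P) / (s_i * s_j) else 1
  c(contrast, dissim, homog, asm, energy, corr)
}
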