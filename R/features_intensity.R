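#' Intensity statistics over masked pixels
#'
#' Eight moment/order statistics (min, sum, mean, population standard
#' deviation, skewness, excess kurtosis, max, Shannon entropy) plus the nine
#' deciles (10th..90th percentile, linear interpolation between closest
#' ranks). Only pixels inside the mask contribute; an empty mask yields all
#' missing. The Shannon entropy uses a 256-bin histogram of the intensities
#' rescaled by the 16-bit maximum (65535), natural log.
#'
#' @param image numeric matrix of intensities.
#' @param mask logical matrix, same shape.
#' @return Named numeric vector of length 17: `mean`, `sum`, `min`, `max`,
#'   `sd`, `skewness`, `kurtosis`, `entropy`, `p10` .. `p90`.
#' @export
intensity_features <- function(image, mask) {
  nm <- c("mean", "sum", "min", "max", "sd", "skewness", "kurtosis",
          "entropy", paste0("p", seq(10, 90, 10)))
  out <- stats::setNames(rep(NA_real_, 17L), nm)
  v <- image[mask > 0]
  if (length(v) == 0L) return(out)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  out["mean"] <- mu
  out["sum"] <- sum(v)
  out["min"] <- min(v)
  out["max"] <- max(v)
  out["sd"] <- sqrt(s2)
  if (s2 > 0) {
    out["skewness"] <- mean((v - mu)^3) / s2^1.5
    out["kurtosis"] <- mean((v - mu)^4) / s2^2 - 3
  } else {
    out["skewness"] <- 0
    out["kurtosis"] <- -3   # constant sample, Fisher convention
  }
  out["entropy"] <- shannon_entropy(v)
  out[paste0("p", seq(10, 90, 10))] <-
    stats::quantile(v, probs = seq(0.1, 0.9, 0.1), type = 7, names = FALSE)
  out
}

# Histogram Shannon entropy (natural log) on 256 bins over the 16-bit range.
shannon_entropy <- function(v, bins = 256L, range_max = 65535) {
  z <- pmin(pmax(v / range_max, 0), 1)
  h <- tabulate(pmin(floor(z * bins) + 1L, bins), nbins = bins)
  p <- h[h > 0] / length(z)
  -sum(p * log(p))
}
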