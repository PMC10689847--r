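#' Morphological shape descriptors of a binary mask
#'
#' Computes 30 named values: 16 scalar shape descriptors (area, bounding-box
#' area, convex area, eccentricity, equivalent diameter, Euler number, extent,
#' max/min Feret diameter, filled area, major/minor axis length, orientation,
#' perimeter, Crofton perimeter, solidity), the 7 Hu moment invariants of the
#' mask, and the 7 intensity-weighted Hu invariants (requires `image`;
#' otherwise missing). An empty mask yields all-missing values.
#'
#' Conventions: pixel coordinates are centers on an integer grid; the convex
#' hull, Feret diameters and axis lengths are computed from pixel centers;
#' perimeter counts exposed 4-neighbor pixel edges; the Crofton perimeter uses
#' intercept counts in 4 directions. Axis lengths derive from second central
#' moments (ellipse with matching moments).
#'
#' @param mask logical matrix.
#' @param image optional numeric matrix (same shape) for weighted Hu moments.
#' @return Named numeric vector of length 30.
#' @export
morphology_features <- function(mask, image = NULL) {
  nm <- c("area", "bbox_area", "convex_area", "eccentricity",
          "equivalent_diameter", "euler_number", "extent",
          "feret_diameter_max", "feret_diameter_min", "filled_area",
          "major_axis_length", "minor_axis_length", "orientation",
          "perimeter", "crofton_perimeter", "solidity",
          paste0("hu", 1:7), paste0("whu", 1:7))
  out <- stats::setNames(rep(NA_real_, 30L), nm)
  mask <- mask > 0
  A <- sum(mask)
  if (A == 0L) return(out)

  ij <- which(mask, arr.ind = TRUE)
  y <- ij[, 1] - 1; x <- ij[, 2] - 1
  out["area"] <- A
  out["bbox_area"] <- (diff(range(y)) + 1) * (diff(range(x)) + 1)
  out["extent"] <- A / out["bbox_area"]
  out["equivalent_diameter"] <- sqrt(4 * A / pi)

  hull <- convex_hull_points(x, y)
  out["convex_area"] <- convex_pixel_area(mask, hull)
  out["solidity"] <- A / out["convex_area"]
  fer <- feret_diameters(hull)
  out["feret_diameter_max"] <- fer[1]
  out["feret_diameter_min"] <- fer[2]

  filled <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  out["filled_area"] <- sum(filled)
  n_comp <- max(EBImage::bwlabel(EBImage::Image(mask * 1)))
  holes <- filled & !mask
  n_holes <- if (any(holes)) max(EBImage::bwlabel(EBImage::Image(holes * 1))) else 0
  out["euler_number"] <- n_comp - n_holes

  # central moments of the binary mask
  cm <- central_moments(x, y, rep(1, A))
  lam <- moment_axes(cm)
  out["major_axis_length"] <- 4 * sqrt(lam$l1)
  out["minor_axis_length"] <- 4 * sqrt(lam$l2)
  out["eccentricity"] <- if (lam$l1 > 0) sqrt(pmax(0, 1 - lam$l2 / lam$l1)) else 0
  out["orientation"] <- lam$theta

  out["perimeter"] <- edge_perimeter(mask)
  out["crofton_perimeter"] <- crofton_perimeter(mask)

  out[paste0("hu", 1:7)] <- hu_invariants(cm)
  if (!is.null(image)) {
    w <- image[ij]
    # weights normalized to mean 1 so the invariants ignore global
    # intensity scaling and reduce to the binary Hu set for flat images
    if (sum(w) > 0)
      out[paste0("whu", 1:7)] <-
        hu_invariants(central_moments(x, y, w / mean(w)))
  }
  out
}

# Pixel-center convex hull vertices (counter-clockwise), as a 2-column matrix.
convex_hull_points <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) <= 2L) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

# Number of pixels of the frame whose centers lie inside or on the hull.
convex_pixel_area <- function(mask, hull) {
  if (nrow(hull) <= 2L) return(sum(mask))
  ij <- which(!is.na(mask), arr.ind = TRUE)  # all pixels
  px <- ij[, 2] - 1; py <- ij[, 1] - 1
  # restrict to bounding box of hull for speed
  keep <- px >= min(hull[, 1]) & px <= max(hull[, 1]) &
          py >= min(hull[, 2]) & py <= max(hull[, 2])
  sum(points_in_convex(px[keep], py[keep], hull))
}

# Vectorized inside-or-on test for a convex polygon (vertices in hull order).
points_in_convex <- function(px, py, hull, tol = 1e-9) {
  n <- nrow(hull)
  inside <- rep(TRUE, length(px))
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hull[j, 1] - hull[i, 1]) * (py - hull[i, 2]) -
          (hull[j, 2] - hull[i, 2]) * (px - hull[i, 1])
    if (sgn == 0) {
      s <- sign(sum(sign(cr[abs(cr) > tol])))
      if (s != 0) sgn <- s
    }
    inside <- inside & (sgn * cr >= -tol | abs(cr) <= tol)
  }
  inside
}

# Max pairwise hull distance; min width by rotating calipers over hull edges.
feret_diameters <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) return(c(0, 0))
  d <- as.matrix(stats::dist(hull))
  fmax <- max(d)
  if (n == 2L) return(c(fmax, 0))
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    # distance of all hull points to the line through edge i-j
    max(abs((hull[, 1] - hull[i, 1]) * e[2] - (hull[, 2] - hull[i, 2]) * e[1]) / len)
  }, numeric(1))
  c(fmax, min(widths))
}

# Central moments mu_pq (p+q <= 3) of weighted points.
central_moments <- function(x, y, w) {
  m00 <- sum(w)
  xb <- sum(w * x) / m00; yb <- sum(w * y) / m00
  dx <- x - xb; dy <- y - yb
  mu <- function(p, q) sum(w * dx^p * dy^q)
  list(m00 = m00,
       mu20 = mu(2, 0), mu02 = mu(0, 2), mu11 = mu(1, 1),
       mu30 = mu(3, 0), mu03 = mu(0, 3), mu21 = mu(2, 1), mu12 = mu(1, 2))
}

# Eigenvalues of the normalized second-moment matrix and orientation.
moment_axes <- function(cm) {
  a <- cm$mu20 / cm$m00; b <- cm$mu11 / cm$m00; c <- cm$mu02 / cm$m00
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  l1 <- (a + c) / 2 + disc
  l2 <- (a + c) / 2 - disc
  theta <- 0.5 * atan2(2 * b, a - c)
  list(l1 = pmax(l1, 0), l2 = pmax(l2, 0), theta = theta)
}

# The seven Hu moment invariants from central moments.
hu_invariants <- function(cm) {
  m00 <- cm$m00
  eta <- function(mu, p, q) mu / m00^(1 + (p + q) / 2)
  n20 <- eta(cm$mu20, 2, 0); n02 <- eta(cm$mu02, 0, 2); n11 <- eta(cm$mu11, 1, 1)
  n30 <- eta(cm$mu30, 3, 0); n03 <- eta(cm$mu03, 0, 3)
  n21 <- eta(cm$mu21, 2, 1); n12 <- eta(cm$mu12, 1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
        ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
        (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
        ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
        (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# Count of mask pixel edges exposed to background (4-connectivity).
edge_perimeter <- function(mask) {
  m <- mask > 0
  pad <- function(m, dr, dc) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb <- pad(m, 1, 0) + pad(m, -1, 0) + pad(m, 0, 1) + pad(m, 0, -1)
  sum((4 - nb)[m])
}

# Crofton perimeter estimate from boundary intercepts in 4 directions.
crofton_perimeter <- function(mask) {
  m <- mask > 0
  transitions <- function(mat) sum(abs(diff(rbind(FALSE, mat, FALSE))))
  i0  <- transitions(t(m))                    # along rows
  i90 <- transitions(m)                       # along columns
  diag_transitions <- function(m) {
    H <- nrow(m); W <- ncol(m)
    tot <- 0
    for (k in (-(H - 1)):(W - 1)) {
      r <- seq_len(H); c <- r + k
      ok <- c >= 1 & c <= W
      if (!any(ok)) next
      v <- m[cbind(r[ok], c[ok])]
      tot <- tot + sum(abs(diff(c(FALSE, v, FALSE))))
    }
    tot
  }
  i45  <- diag_transitions(m)
  i135 <- diag_transitions(m[, rev(seq_len(ncol(m))), drop = FALSE])
  pi / 4 * (i0 + i90 + (i45 + i135) / sqrt(2))
}
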