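#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: sort ascending, multiply by
#' m/rank, take the running minimum from the largest down, cap at 1.
#' Implemented in-package so the profiling stack is self-contained; agrees
#' with the standard step-up procedure.
#'
#' @param p numeric vector of raw p-values (NAs propagate).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  ord <- order(pv, decreasing = TRUE)          # largest first
  adj <- pmin(1, cummin(pv[ord] * m / (m:1)))
  out[ok[ord]] <- adj
  out
}

#' Exact two-sided Wilcoxon signed-rank test against zero
#'
#' For n <= `exact_max` nonzero values the null distribution of the
#' positive-rank sum is built by enumerating all 2^n sign patterns (with the
#' observed tie structure), giving an exact two-sided p (doubled one-tail,
#' capped at 1). Larger n uses the normal approximation with tie correction
#' and continuity correction. Zeros are dropped; an all-zero sample gives
#' p = 1.
#'
#' @param x numeric vector of paired differences (here per-donor log2 fold
#'   changes).
#' @param exact_max largest n for which the exact enumeration is used.
#' @return List with `statistic` (positive-rank sum W+), `p_value`, `n`
#'   (nonzero values used).
#' @export
signed_rank_test <- function(x, exact_max = 12L) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) return(list(statistic = 0, p_value = 1, n = 0L))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    # distribution of W+ over all sign patterns with these ranks
    dist <- 0
    for (ri in r) dist <- c(dist, dist + ri)   # subset-sum enumeration
    p_ge <- mean(dist >= w - 1e-9)
    p_le <- mean(dist <= w + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, n = n)
}

#' Exact two-sided Mann-Whitney U test
#'
#' For arms of at most `exact_max` observations each (and no ties), the null
#' distribution of U is built by full enumeration of all
#' choose(n1 + n2, n1) group assignments; the two-sided p doubles the
#' smaller tail (capped at 1). Otherwise the tie-corrected normal
#' approximation with continuity correction is used. Identical constant arms
#' give p = 1.
#'
#' @param x,y the two arms.
#' @param exact_max per-arm size limit for exact enumeration.
#' @return List with `statistic` (U of arm `x`), `p_value`, `exact`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both arms must be non-empty")
  all_v <- c(x, y)
  if (stats::sd(all_v) == 0) return(list(statistic = n1 * n2 / 2,
                                         p_value = 1, exact = TRUE))
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (n1 <= exact_max && n2 <= exact_max && !has_ties) {
    combos <- utils::combn(n1 + n2, n1)
    rr <- rank(all_v)
    us <- colSums(matrix(rr[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p_ge <- mean(us >= u - 1e-9)
    p_le <- mean(us <= u + 1e-9)
    return(list(statistic = u, p_value = min(1, 2 * min(p_ge, p_le)),
                exact = TRUE))
  }
  mu <- n1 * n2 / 2
  ties <- table(all_v)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       exact = FALSE)
}

#' Per-class frequencies after cleaning
#'
#' `F_C` = (records predicted as C) / (total records), computed per donor x
#' condition over the non-artifact classes only (artifact predictions are
#' excluded from numerator and denominator).
#'
#' @param pred_class predicted class per retained record.
#' @param groups data.frame with `donor_id`, `condition` per record.
#' @param taxonomy a [class_taxonomy()].
#' @return data.frame with donor_id, condition, one frequency column per
#'   analysis class (rows sum to 1), and `n` (records counted).
#' @export
class_frequencies <- function(pred_class, groups,
                              taxonomy = class_taxonomy()) {
  keep_cls <- analysis_classes(taxonomy)
  ok <- pred_class %in% keep_cls
  pred_class <- pred_class[ok]
  groups <- groups[ok, , drop = FALSE]
  key <- interaction(groups$donor_id, groups$condition, drop = TRUE,
                     sep = "\r")
  rows <- lapply(levels(key), function(g) {
    idx <- key == g
    cnt <- table(factor(pred_class[idx], levels = keep_cls))
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    data.frame(donor_id = parts[1], condition = parts[2],
               as.list(cnt / sum(cnt)), n = sum(idx),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Class-frequency fold-change analysis between two conditions
#'
#' For each donor with both conditions, the per-class log2 fold change
#' log2(F_antibody / F_control) is computed; classes with a zero frequency
#' in either arm are excluded for that donor (log2FC undefined, no
#' pseudo-count). Each class's donor log2FCs are tested against zero with
#' the exact two-sided Wilcoxon signed-rank test (the design is donor-
#' paired), and p-values are BH-adjusted across the analysis classes within
#' this comparison. A rank-sum variant (two-sample Wilcoxon on the two
#' arms' frequencies) is available for strict literalism.
#'
#' @param freqs output of [class_frequencies()] containing both conditions.
#' @param antibody,control condition names.
#' @param alpha significance level.
#' @param test `"signed-rank"` (default) or `"rank-sum"`.
#' @return List with `log2fc` (donors x classes matrix), `tests`
#'   (data.frame: class, median_log2fc, p, p_adj, significant).
#' @export
frequency_test <- function(freqs, antibody, control, alpha = 0.05,
                           test = c("signed-rank", "rank-sum")) {
  test <- match.arg(test)
  classes <- setdiff(colnames(freqs),
                     c("donor_id", "condition", "n"))
  fa <- freqs[freqs$condition == antibody, , drop = FALSE]
  fc <- freqs[freqs$condition == control, , drop = FALSE]
  donors <- intersect(fa$donor_id, fc$donor_id)
  skipped <- setdiff(unique(freqs$donor_id), donors)
  if (length(skipped))
    warning("donor(s) missing a condition, dropped: ",
            paste(skipped, collapse = ", "))
  l2 <- matrix(NA_real_, length(donors), length(classes),
               dimnames = list(donors, classes))
  for (d in donors) {
    va <- as.numeric(fa[fa$donor_id == d, classes])
    vc <- as.numeric(fc[fc$donor_id == d, classes])
    ok <- va > 0 & vc > 0
    l2[d, ok] <- log2(va[ok] / vc[ok])
    if (any(!ok))
      warning("zero frequency for donor ", d, ", class(es) ",
              paste(classes[!ok], collapse = ", "), "; log2FC undefined")
  }
  p <- vapply(classes, function(cl) {
    v <- l2[, cl]
    if (test == "signed-rank") signed_rank_test(v)$p_value
    else {
      va <- as.numeric(fa[match(donors, fa$donor_id), cl])
      vc <- as.numeric(fc[match(donors, fc$donor_id), cl])
      mann_whitney_test(va, vc)$p_value
    }
  }, numeric(1))
  p_adj <- bh_adjust(p)
  med <- apply(l2, 2, stats::median, na.rm = TRUE)
  list(log2fc = l2,
       tests = data.frame(class = classes, median_log2fc = med, p = p,
                          p_adj = p_adj, significant = !is.na(p_adj) &
                            p_adj < alpha, row.names = NULL))
}

#' Per-donor feature difference map between two conditions
#'
#' For each donor and feature, a two-sided Mann-Whitney U test compares the
#' feature's values under the antibody vs the control arm; p-values are
#' BH-adjusted across features within that donor's comparison. The map entry
#' is +1 if significant (adjusted p < alpha) with a larger antibody median,
#' -1 if significant with a smaller median, else 0. Features constant across
#' both arms give p = 1 and entry 0.
#'
#' @param features feature data.frame (rownames = record ids), typically
#'   restricted to records predicted as 'synapse w/ signaling'.
#' @param groups data.frame with `donor_id`, `condition` per row.
#' @param antibody,control condition names.
#' @param alpha BH significance level.
#' @return Object of class `difference_map`: list with `map` (features x
#'   donors matrix in {-1, 0, +1}), `p`, `p_adj` (same shape),
#'   `consistency` (per feature: max number of donors sharing a nonzero
#'   sign, signed), `per_donor_counts` (+1/-1 counts per donor).
#' @export
feature_difference <- function(features, groups, antibody, control,
                               alpha = 0.05) {
  donors <- sort(unique(groups$donor_id))
  feats <- colnames(features)
  map <- matrix(0L, length(feats), length(donors),
                dimnames = list(feats, donors))
  praw <- matrix(NA_real_, length(feats), length(donors),
                 dimnames = list(feats, donors))
  padj <- praw
  for (d in donors) {
    ia <- groups$donor_id == d & groups$condition == antibody
    ic <- groups$donor_id == d & groups$condition == control
    if (!any(ia) || !any(ic))
      stop("donor ", d, " lacks one of the arms")
    for (fn in feats) {
      a <- features[ia, fn]; cvals <- features[ic, fn]
      a <- a[!is.na(a)]; cvals <- cvals[!is.na(cvals)]
      if (!length(a) || !length(cvals)) next
      praw[fn, d] <- mann_whitney_test(a, cvals)$p_value
    }
    padj[, d] <- bh_adjust(praw[, d])
    for (fn in feats) {
      if (is.na(padj[fn, d]) || padj[fn, d] >= alpha) next
      a <- features[ia, fn]; cvals <- features[ic, fn]
      dmed <- stats::median(a, na.rm = TRUE) -
        stats::median(cvals, na.rm = TRUE)
      map[fn, d] <- if (dmed > 0) 1L else if (dmed < 0) -1L else 0L
    }
  }
  cons <- apply(map, 1, function(row) {
    np <- sum(row == 1); nn <- sum(row == -1)
    if (np >= nn) np else -nn
  })
  counts <- data.frame(donor = donors,
                       increased = colSums(map == 1),
                       decreased = colSums(map == -1), row.names = NULL)
  structure(list(map = map, p = praw, p_adj = padj, consistency = cons,
                 per_donor_counts = counts, alpha = alpha),
            class = "difference_map")
}

#' Features changing consistently across donors
#'
#' @param dmap a [feature_difference()] result.
#' @param min_donors minimum number of donors sharing the same nonzero sign.
#' @return data.frame (feature, direction, n_donors), sorted by support.
#' @export
consistency_summary <- function(dmap, min_donors = 4L) {
  cons <- dmap$consistency
  sel <- abs(cons) >= min_donors
  out <- data.frame(feature = names(cons)[sel],
                    direction = sign(cons[sel]),
                    n_donors = abs(cons[sel]), row.names = NULL)
  out[order(-out$n_donors, out$feature), , drop = FALSE]
}

#' @export
print.difference_map <- function(x, ...) {
  cat("difference map:", nrow(x$map), "features x", ncol(x$map), "donors\n")
  print(x$per_donor_counts)
  invisible(x)
}

#' Render a difference map as a heatmap
#'
#' Features x donors, blue = significantly decreased, red = increased.
#'
#' @param dmap a [feature_difference()] result.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the matrix drawn.
#' @export
plot_difference_map <- function(dmap, ...) {
  M <- dmap$map
  graphics::image(t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = c("#2166AC", "#EEEEEE", "#B2182B"),
                  zlim = c(-1, 1), axes = FALSE, ...)
  invisible(M)
}
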