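#' Feature inventories
#'
#' A feature inventory is a declarative ordered list of feature definitions:
#' each entry has a unique `name`, a `family` (morphology, intensity, texture,
#' coloc, synaptic, qc), and the channel (or channel pair) it reads.
#'
#' `inventory_fluor_relevant()` builds the block used for population-level
#' comparisons: per fluorescent channel, 8 intensity statistics + 9 deciles +
#' 6 GLCM texture values + 3 synaptic enrichments + the mask area
#' (27 features), and per unordered channel pair the 17 co-localization
#' features. Four channels therefore give 4*27 + 6*17 = 210 columns and three
#' give 3*27 + 3*17 = 132.
#'
#' `inventory_full()` adds, for every panel channel, the 30 morphology
#' descriptors and the 2 QC features, plus the intensity block for the
#' non-fluorescent channels (so e.g. the viability mean needed by the
#' cleaning rules is available). Its total size depends on the panel and is
#' deliberately configurable rather than fixed.
#'
#' @param channels fluorescent channels to include.
#' @return A `feature_inventory`: data.frame with columns `name`, `family`,
#'   `channels`, `stat`.
#' @export
inventory_fluor_relevant <- function(channels) {
  stopifnot(length(channels) >= 1)
  ent <- list()
  int_stats <- c("mean", "sum", "min", "max", "sd", "skewness", "kurtosis",
                 "entropy", paste0("p", seq(10, 90, 10)))
  glcm_stats <- paste0("glcm_", c("contrast", "dissimilarity", "homogeneity",
                                  "ASM", "energy", "correlation"))
  syn_stats <- c("enrich_mean", "enrich_sum", "enrich_max")
  for (ch in channels) {
    ent[[length(ent) + 1L]] <- data.frame(
      name = paste0(ch, "_", c(int_stats, glcm_stats, syn_stats, "area")),
      family = c(rep("intensity", 17), rep("texture", 6),
                 rep("synaptic", 3), "morphology"),
      channels = ch,
      stat = c(int_stats, glcm_stats, syn_stats, "area"),
      stringsAsFactors = FALSE)
  }
  coloc_stats <- c("dice_dist", "jaccard_dist", "inter_area", "union_area",
                   "inter_over_min", "corr_dist", "eucl_dist", "cosine_dist",
                   "pearson", "spearman", "mutual_info", "manders_m1",
                   "manders_m2", "overlap_coef", "icq", "ssim", "hausdorff")
  if (length(channels) >= 2) {
    prs <- utils::combn(channels, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      ent[[length(ent) + 1L]] <- data.frame(
        name = paste0(a, "_", b, "_", coloc_stats),
        family = "coloc",
        channels = paste0(a, "|", b),
        stat = coloc_stats,
        stringsAsFactors = FALSE)
    }
  }
  inv <- do.call(rbind, ent)
  structure(inv, class = c("feature_inventory", "data.frame"))
}

#' @rdname inventory_fluor_relevant
#' @param panel full channel panel (see [default_panel()]).
#' @param fluor which panel channels are fluorescent markers.
#' @param morphology,qc include those families.
#' @export
inventory_full <- function(panel = default_panel(),
                           fluor = fluorescent_channels(panel),
                           morphology = TRUE, qc = TRUE) {
  inv <- inventory_fluor_relevant(fluor)
  extra <- list()
  int_stats <- c("mean", "sum", "min", "max", "sd", "skewness", "kurtosis",
                 "entropy", paste0("p", seq(10, 90, 10)))
  for (ch in setdiff(panel, fluor)) {
    extra[[length(extra) + 1L]] <- data.frame(
      name = paste0(ch, "_", c(int_stats, "area")),
      family = c(rep("intensity", 17), "morphology"),
      channels = ch, stat = c(int_stats, "area"), stringsAsFactors = FALSE)
  }
  morph_stats <- c("area2", "bbox_area", "convex_area", "eccentricity",
                   "equivalent_diameter", "euler_number", "extent",
                   "feret_diameter_max", "feret_diameter_min", "filled_area",
                   "major_axis_length", "minor_axis_length", "orientation",
                   "perimeter", "crofton_perimeter", "solidity",
                   paste0("hu", 1:7), paste0("whu", 1:7))
  if (morphology) {
    for (ch in panel) {
      extra[[length(extra) + 1L]] <- data.frame(
        name = paste0(ch, "_", sub("^area2$", "morph_area", morph_stats)),
        family = "morphology", channels = ch, stat = morph_stats,
        stringsAsFactors = FALSE)
    }
  }
  if (qc) {
    for (ch in panel) {
      extra[[length(extra) + 1L]] <- data.frame(
        name = paste0(ch, c("_bgmean", "_grms")),
        family = "qc", channels = ch, stat = c("bgmean", "grms"),
        stringsAsFactors = FALSE)
    }
  }
  inv <- rbind(as.data.frame(inv), do.call(rbind, extra))
  if (anyDuplicated(inv$name)) stop("duplicate feature names in inventory")
  structure(inv, class = c("feature_inventory", "data.frame"))
}

# Cheap stable fingerprint of an inventory (provenance stamp).
inventory_hash <- function(inv) {
  s <- paste(inv$name, collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x-%d", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291, nrow(inv))
}
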