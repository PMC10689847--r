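#' Parameters of the nine-rule cleaning pipeline
#'
#' Rule thresholds are percentiles of the sample being cleaned (computed per
#' donor x condition and frozen before any rule is applied), except the
#' fixed entropy cut. Rules, in order of application:
#' 1. dead cells: mean viability intensity >= its 90th percentile;
#' 2. focus: brightfield gradient RMS must lie strictly between its 2nd and
#'    90th percentiles;
#' 3. classifier uncertainty: prediction entropy > 1.0;
#' 4. predicted single B-LCL with MHCII mean intensity < 5th percentile;
#' 5. predicted single B-LCL with MHCII area < 10th percentile;
#' 6. predicted single T cells with CD3 mean intensity < 1st percentile;
#' 7. predicted B-LCL and T cell in one layer with MHCII area < 20th
#'    percentile;
#' 8. isolation-forest outliers (100 trees, subsample 256, 20 features per
#'    tree, score > 0.5) on the supplied outlier feature set;
#' 9. DBSCAN on a 2-D UMAP embedding of the standardized outlier features
#'    (eps 0.09, min_samples 5); noise points and clusters with frequency
#'    < 1e-4 are removed.
#'
#' @param viability_pct,grms_lo_pct,grms_hi_pct,entropy_max,mhcii_mean_pct,mhcii_area_pct,cd3_mean_pct,mhcii_area_layer_pct rule thresholds.
#' @param iforest_trees,iforest_max_features,iforest_score isolation-forest
#'   parameters.
#' @param dbscan_eps,dbscan_min_samples,min_cluster_freq,umap_neighbors,umap_min_dist rule-9 parameters.
#' @param embed `"umap"` (default) embeds the standardized outlier features
#'   to 2-D before DBSCAN; `"none"` clusters the standardized features
#'   directly.
#' @param viability_feature,grms_feature,mhcii_mean_feature,mhcii_area_feature,cd3_mean_feature names of the feature columns the rules read.
#' @return List of class `clean_params`.
#' @export
clean_params <- function(viability_pct = 90, grms_lo_pct = 2,
                         grms_hi_pct = 90, entropy_max = 1.0,
                         mhcii_mean_pct = 5, mhcii_area_pct = 10,
                         cd3_mean_pct = 1, mhcii_area_layer_pct = 20,
                         iforest_trees = 100L, iforest_max_features = 20L,
                         iforest_score = 0.5,
                         dbscan_eps = 0.09, dbscan_min_samples = 5L,
                         min_cluster_freq = 1e-4,
                         umap_neighbors = 15L, umap_min_dist = 0.1,
                         embed = c("umap", "none"),
                         viability_feature = "LiveDead_mean",
                         grms_feature = "BF_grms",
                         mhcii_mean_feature = "MHCII_mean",
                         mhcii_area_feature = "MHCII_area",
                         cd3_mean_feature = "CD3_mean") {
  embed <- match.arg(embed)
  structure(as.list(environment()), class = "clean_params")
}

pctl <- function(v, p) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  stats::quantile(v, p / 100, type = 7, names = FALSE)
}

#' Clean one donor x condition sample
#'
#' Applies the nine rules of [clean_params()] in order with first-match
#' attribution: each removed record is credited to the first rule that
#' matched it. Threshold percentiles are computed once on the full input
#' sample; the model-based rules (8, 9) are fitted on the records surviving
#' rules 1-7.
#'
#' @param features data.frame of features (rownames = record ids) containing
#'   the rule columns named in `params`.
#' @param pred_class predicted class per record.
#' @param entropy prediction entropy per record (see
#'   [predict_with_entropy()]).
#' @param outlier_features columns used by rules 8-9 (typically the top-30
#'   features by gain importance); `NULL` = all columns.
#' @param params a [clean_params()].
#' @param seed integer seed for rules 8-9.
#' @return List with `retained` (record ids) and `report` (a
#'   `cleaning_report`: per-rule removed ids and parameters, counts in/out).
#' @export
clean_sample <- function(features, pred_class, entropy,
                         outlier_features = NULL, params = clean_params(),
                         seed = 1L) {
  ids <- rownames(features)
  n <- nrow(features)
  report <- list()
  if (n == 0L) {
    return(list(retained = character(0),
                report = structure(list(rules = list(), n_input = 0L,
                                        n_retained = 0L,
                                        retained = character(0)),
                                   class = "cleaning_report")))
  }
  need <- c(params$viability_feature, params$grms_feature,
            params$mhcii_mean_feature, params$mhcii_area_feature,
            params$cd3_mean_feature)
  for (i in seq_along(need)) {
    if (!need[i] %in% colnames(features))
      stop("cleaning rule ", c(1, 2, 4, 5, 6)[i],
           " requires missing feature '", need[i], "'")
  }
  pred_class <- as.character(pred_class)
  t_classes <- c("single T cell w/o signaling", "single T cell w/ signaling")

  viab <- features[[params$viability_feature]]
  grms <- features[[params$grms_feature]]
  mh_mean <- features[[params$mhcii_mean_feature]]
  mh_area <- features[[params$mhcii_area_feature]]
  cd3_mean <- features[[params$cd3_mean_feature]]
  thr <- list(
    viab = pctl(viab, params$viability_pct),
    grms_lo = pctl(grms, params$grms_lo_pct),
    grms_hi = pctl(grms, params$grms_hi_pct),
    mh_mean = pctl(mh_mean[pred_class == "single B-LCL"], params$mhcii_mean_pct),
    mh_area = pctl(mh_area[pred_class == "single B-LCL"], params$mhcii_area_pct),
    cd3_mean = pctl(cd3_mean[pred_class %in% t_classes], params$cd3_mean_pct),
    mh_area_layer = pctl(mh_area[pred_class == "B-LCL and T cell in one layer"],
                         params$mhcii_area_layer_pct)
  )

  removed <- rep(FALSE, n)
  claim <- function(hit, id, name, pars) {
    hit[is.na(hit)] <- FALSE
    new <- hit & !removed
    removed <<- removed | new
    report[[length(report) + 1L]] <<-
      list(id = id, name = name, params = pars, removed = ids[new])
  }
  claim(viab >= thr$viab, 1L, "dead cells (viability >= 90th pct)",
        list(threshold = thr$viab))
  claim(!(grms > thr$grms_lo & grms < thr$grms_hi), 2L,
        "out of focus (BF gradient RMS outside (2nd, 90th) pct)",
        list(lo = thr$grms_lo, hi = thr$grms_hi))
  claim(entropy > params$entropy_max, 3L, "high prediction entropy",
        list(max = params$entropy_max))
  claim(pred_class == "single B-LCL" & mh_mean < thr$mh_mean, 4L,
        "predicted B-LCL with low MHCII mean", list(threshold = thr$mh_mean))
  claim(pred_class == "single B-LCL" & mh_area < thr$mh_area, 5L,
        "predicted B-LCL with small MHCII area", list(threshold = thr$mh_area))
  claim(pred_class %in% t_classes & cd3_mean < thr$cd3_mean, 6L,
        "predicted T cell with low CD3 mean", list(threshold = thr$cd3_mean))
  claim(pred_class == "B-LCL and T cell in one layer" &
          mh_area < thr$mh_area_layer, 7L,
        "one-layer doublet with small MHCII area",
        list(threshold = thr$mh_area_layer))

  of <- outlier_features %||% colnames(features)
  X <- as.matrix(impute_median(features[, of, drop = FALSE]))
  alive <- which(!removed)
  if (length(alive) >= 2L) {
    sc <- iforest_scores(X[alive, , drop = FALSE],
                         n_trees = params$iforest_trees,
                         max_features = params$iforest_max_features,
                         seed = derive_seed(seed, "iforest"))
    hit8 <- rep(FALSE, n); hit8[alive[sc > params$iforest_score]] <- TRUE
    claim(hit8, 8L, "isolation-forest outlier",
          list(trees = params$iforest_trees, score = params$iforest_score))
  } else {
    claim(rep(FALSE, n), 8L, "isolation-forest outlier", list())
  }

  alive <- which(!removed)
  min_n <- max(params$dbscan_min_samples + 1L, 5L)
  if (length(alive) > min_n) {
    Z <- scale(X[alive, , drop = FALSE])
    Z[, !is.finite(colSums(Z))] <- 0
    # embed = "none" runs the density rule on the standardized features
    # directly (useful for low-dimensional feature sets); default is the
    # 2-D UMAP embedding
    emb <- if (identical(params$embed, "none")) Z else
      with_seed(derive_seed(seed, "umap"),
        uwot::umap(Z, n_neighbors = min(params$umap_neighbors,
                                        length(alive) - 1L),
                   min_dist = params$umap_min_dist, n_threads = 1,
                   n_sgd_threads = 0))
    cl <- dbscan_cluster(emb, eps = params$dbscan_eps,
                         min_pts = params$dbscan_min_samples)
    freq <- table(cl[cl > 0]) / length(alive)
    bad_clusters <- as.integer(names(freq)[freq < params$min_cluster_freq])
    hit9 <- rep(FALSE, n)
    hit9[alive[cl == 0 | cl %in% bad_clusters]] <- TRUE
    claim(hit9, 9L, "low-density embedding outlier (UMAP + DBSCAN)",
          list(eps = params$dbscan_eps,
               min_samples = params$dbscan_min_samples,
               min_cluster_freq = params$min_cluster_freq))
  } else {
    claim(rep(FALSE, n), 9L, "low-density embedding outlier (UMAP + DBSCAN)",
          list())
  }

  retained <- ids[!removed]
  list(retained = retained,
       report = structure(list(rules = report, n_input = n,
                               n_retained = length(retained),
                               retained = retained),
                          class = "cleaning_report"))
}

#' Clean a cohort grouped by donor x condition
#'
#' Splits records by donor and condition, cleans each sample with
#' [clean_sample()] (percentile thresholds are per sample, keeping
#' conditions independent), and merges the reports.
#'
#' @param features feature data.frame (rownames = record ids).
#' @param groups data.frame with `donor_id` and `condition` per row.
#' @inheritParams clean_sample
#' @return List with `retained` ids and `reports` (one `cleaning_report` per
#'   donor x condition sample).
#' @export
clean_cohort <- function(features, groups, pred_class, entropy,
                         outlier_features = NULL, params = clean_params(),
                         seed = 1L) {
  key <- paste(groups$donor_id, groups$condition, sep = "\r")
  retained <- character(0)
  reports <- list()
  for (g in unique(key)) {
    idx <- which(key == g)
    res <- clean_sample(features[idx, , drop = FALSE], pred_class[idx],
                        entropy[idx], outlier_features, params,
                        seed = derive_seed(seed, g))
    retained <- c(retained, res$retained)
    reports[[sub("\r", ":", g)]] <- res$report
  }
  list(retained = retained, reports = reports)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning report:", x$n_input, "records in,", x$n_retained, "retained\n")
  for (r in x$rules)
    cat(sprintf("  rule %d (%s): removed %d\n", r$id, r$name,
                length(r$removed)))
  invisible(x)
}

# ---- isolation forest ------------------------------------------------------

# Anomaly scores in (0, 1): average random-partition path length relative to
# the expectation c(n) for the subsample size; higher = more isolated.
iforest_scores <- function(X, n_trees = 100L, sample_size = NULL,
                           max_features = 20L, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  sample_size <- min(sample_size %||% 256L, n)
  max_features <- min(max_features, p)
  depth_limit <- ceiling(log2(max(sample_size, 2)))
  rng <- make_rng(seed)
  paths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    rows <- rng$sample(n, sample_size)
    feats <- rng$sample(p, max_features)
    tree <- grow_itree(X[rows, feats, drop = FALSE], depth_limit, rng)
    paths[, t] <- itree_path(tree, X[, feats, drop = FALSE])
  }
  avg <- rowMeans(paths)
  2^(-avg / c_factor(sample_size))
}

c_factor <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

grow_itree <- function(X, depth_limit, rng, depth = 0L) {
  n <- nrow(X)
  if (n <= 1L || depth >= depth_limit)
    return(list(leaf = TRUE, size = n))
  rngs <- apply(X, 2, range)
  splittable <- which(rngs[2, ] > rngs[1, ])
  if (!length(splittable)) return(list(leaf = TRUE, size = n))
  q <- splittable[[max(1L, ceiling(rng$runif(1) * length(splittable)))]]
  u <- rngs[1, q] + rng$runif(1) * (rngs[2, q] - rngs[1, q])
  left <- X[, q] < u
  list(leaf = FALSE, feature = q, value = u,
       left = grow_itree(X[left, , drop = FALSE], depth_limit, rng, depth + 1L),
       right = grow_itree(X[!left, , drop = FALSE], depth_limit, rng, depth + 1L))
}

itree_path <- function(tree, X, depth = 0L) {
  n <- nrow(X)
  if (tree$leaf) return(rep(depth + c_factor(tree$size), n))
  out <- numeric(n)
  left <- X[, tree$feature] < tree$value
  if (any(left))
    out[left] <- itree_path(tree$left, X[left, , drop = FALSE], depth + 1L)
  if (any(!left))
    out[!left] <- itree_path(tree$right, X[!left, , drop = FALSE], depth + 1L)
  out
}

# ---- DBSCAN ----------------------------------------------------------------

# Density clustering; returns integer labels, 0 = noise. Core points have at
# least min_pts neighbors (self included) within eps; clusters are connected
# components of the core-core eps graph; border points join any neighboring
# core's cluster.
dbscan_cluster <- function(X, eps, min_pts) {
  n <- nrow(X)
  if (n == 0L) return(integer(0))
  nb <- radius_neighbors(X, eps)
  n_nb <- lengths(nb)                       # self included
  core <- n_nb >= min_pts
  labels <- integer(n)
  if (!any(core)) return(labels)
  core_idx <- which(core)
  edges <- do.call(rbind, lapply(core_idx, function(i) {
    j <- nb[[i]]
    j <- j[core[j] & j > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  g <- igraph::graph_from_edgelist(
    matrix(match(rbind(cbind(core_idx, core_idx), edges), core_idx), ncol = 2),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[core_idx] <- comp
  for (i in which(!core)) {
    cand <- nb[[i]]
    cand <- cand[core[cand]]
    if (length(cand)) labels[i] <- labels[cand[1]]
  }
  labels
}

# All-neighbor lists within eps via kNN queries with adaptive k.
radius_neighbors <- function(X, eps) {
  n <- nrow(X)
  k <- min(n, 32L)
  repeat {
    res <- RANN::nn2(X, k = k)
    truncated <- res$nn.dists[, k] <= eps & k < n
    if (!any(truncated)) break
    k <- min(n, k * 2L)
  }
  lapply(seq_len(n), function(i) {
    res$nn.idx[i, res$nn.dists[i, ] <= eps]
  })
}
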