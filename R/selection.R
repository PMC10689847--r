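#' Configuration for the ensemble feature pre-selection pipeline
#'
#' @param pearson_threshold pairwise |Pearson| above which one of a pair of
#'   features is eliminated (default 0.95).
#' @param methods ranking methods to use, a subset of `"mutual_info"`,
#'   `"svm"`, `"logistic_l1"`, `"logistic_l2"`, `"random_forest"`,
#'   `"xgboost"`.
#' @param top_k features kept per ranking method before the union.
#' @param m number of spectral clusters (= final number of features).
#' @param seed integer seed driving every random choice in the pipeline.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(pearson_threshold = 0.95,
                             methods = c("mutual_info", "svm", "logistic_l1",
                                         "logistic_l2", "random_forest",
                                         "xgboost"),
                             top_k = 50L, m = 50L, seed = 1L) {
  stopifnot(pearson_threshold > 0, pearson_threshold <= 1,
            top_k >= 1, m >= 1)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("mutual_info", "svm", "logistic_l1",
                                   "logistic_l2", "random_forest", "xgboost"))
  structure(list(pearson_threshold = pearson_threshold, methods = methods,
                 top_k = as.integer(top_k), m = as.integer(m),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Eliminate highly correlated features
#'
#' While any pair of features exceeds `|Pearson| > threshold`, one member of
#' the pair is kept (chosen by seeded RNG) and the other eliminated. Constant
#' columns, whose correlation is undefined, are dropped with a warning.
#'
#' @param table numeric feature data.frame/matrix (no missing values).
#' @param threshold correlation threshold.
#' @param seed integer seed for the random keep choice.
#' @return The table restricted to surviving columns, with attribute
#'   `dropped` (named list: `constant`, `correlated`).
#' @export
correlation_prune <- function(table, threshold = 0.95, seed = 1L) {
  X <- as.matrix(table)
  const <- colnames(X)[apply(X, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))]
  if (length(const)) {
    warning("dropping constant column(s): ", paste(const, collapse = ", "))
    X <- X[, setdiff(colnames(X), const), drop = FALSE]
  }
  rng <- make_rng(seed)
  dropped <- character(0)
  if (ncol(X) >= 2) {
    C <- abs(suppressWarnings(stats::cor(X)))
    diag(C) <- 0
    alive <- rep(TRUE, ncol(X))
    repeat {
      Ca <- C[alive, alive, drop = FALSE]
      if (!length(Ca) || max(Ca) <= threshold) break
      w <- which(Ca == max(Ca), arr.ind = TRUE)[1, ]
      pair <- colnames(Ca)[w]
      lose <- pair[[if (rng$runif(1) < 0.5) 1 else 2]]
      dropped <- c(dropped, lose)
      alive[match(lose, colnames(C))] <- FALSE
    }
    X <- X[, colnames(C)[alive], drop = FALSE]
  }
  out <- as.data.frame(X)
  attr(out, "dropped") <- list(constant = const, correlated = dropped)
  out
}

#' Rank features by six methods and take the union of the top k
#'
#' Methods: k-nearest-neighbor mutual information between each feature and
#' the class label; absolute weight magnitude of a linear SVM (one-vs-one
#' weights summed); coefficient magnitude along the L1 and L2 multinomial
#' logistic regularization paths; random-forest Gini importance; gradient-
#' boosting total gain. Per-method rankings are returned for provenance.
#' Rankings are tie-broken by feature name for determinism.
#'
#' @param table numeric feature data.frame (no missing values).
#' @param labels class labels (one per row).
#' @param config a [selection_config()].
#' @return Character vector of the union of the per-method top-k features,
#'   with attribute `rankings` (named list of full per-method rankings).
#' @export
rank_union <- function(table, labels, config = selection_config()) {
  X <- as.matrix(table)
  y <- factor(labels)
  k <- config$top_k
  if (k > ncol(X)) {
    warning("top_k exceeds the number of features; clamped to ", ncol(X))
    k <- ncol(X)
  }
  scorers <- list(
    mutual_info = function() mutual_info_scores(X, y, seed = config$seed),
    svm = function() svm_weight_scores(X, y),
    logistic_l1 = function() glmnet_path_scores(X, y, alpha = 1),
    logistic_l2 = function() glmnet_path_scores(X, y, alpha = 0),
    random_forest = function() rf_importance_scores(X, y, seed = config$seed),
    xgboost = function() xgb_gain_scores(X, y, seed = config$seed)
  )
  rankings <- list()
  union_set <- character(0)
  for (mth in config$methods) {
    sc <- scorers[[mth]]()
    ord <- order(-sc, names(sc))      # score desc, then name
    rankings[[mth]] <- names(sc)[ord]
    union_set <- union(union_set, rankings[[mth]][seq_len(k)])
  }
  structure(union_set, rankings = rankings)
}

# kNN mutual information between each continuous feature and a discrete
# label (Ross-type estimator, k = 3): digamma(N) - <digamma(n_label)> +
# digamma(k) - <digamma(m_i)> where m_i counts points within the distance of
# the k-th same-label neighbor. Tiny feature jitter breaks ties.
mutual_info_scores <- function(X, y, k = 3L, seed = 1L) {
  rng <- make_rng(seed)
  N <- nrow(X)
  counts <- table(y)
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    v <- v + rng$rnorm(N, 0, 1e-10 * max(stats::sd(v), 1e-12))
    radius <- numeric(N)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      kk <- min(k, length(idx) - 1L)
      if (kk < 1L) { radius[idx] <- 0; next }
      d <- FNN::get.knn(matrix(v[idx]), k = kk)$nn.dist[, kk]
      radius[idx] <- d
    }
    ord <- order(v)
    vs <- v[ord]
    lo <- findInterval(v - radius, vs, left.open = TRUE)       # strictly inside
    hi <- findInterval(v + radius, vs, rightmost.closed = FALSE, left.open = FALSE)
    # count points with |v_i - v_j| < r_i (strict), excluding i itself
    m <- pmax(hi - lo - 1L, 1L)
    nl <- as.numeric(counts[y])
    mi <- digamma(N) - mean(digamma(nl)) + digamma(k) - mean(digamma(m))
    out[j] <- max(mi, 0)
  }
  out
}

svm_weight_scores <- function(X, y) {
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = 1, scale = FALSE)
  W <- t(fit$coefs) %*% fit$SV        # one row per one-vs-one classifier
  stats::setNames(colSums(abs(W)), colnames(X))
}

# Mean |coefficient| along the multinomial regularization path.
glmnet_path_scores <- function(X, y, alpha) {
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                        nlambda = 30, standardize = TRUE)
  acc <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (cl in names(fit$beta)) {
    B <- abs(as.matrix(fit$beta[[cl]]))
    acc <- acc + rowMeans(B)
  }
  acc
}

rf_importance_scores <- function(X, y, ntree = 200L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = ntree, importance = FALSE)
  stats::setNames(fit$importance[, "MeanDecreaseGini"], colnames(X))
}

xgb_gain_scores <- function(X, y, nrounds = 50L, seed = 1L) {
  fit <- fit_xgboost(X, y, nrounds = nrounds, seed = seed)
  gains <- gain_importance(fit)
  stats::setNames(gains[colnames(X)], colnames(X))
}

#' Reduce a candidate set to m decorrelated features by spectral clustering
#'
#' Spectral clustering on the |Spearman| correlation affinity of the
#' candidate features; one feature per cluster is then drawn at random
#' (seeded). Accounts for residual multicollinearity after the ranking
#' union. With fewer candidates than `m`, all candidates are returned with a
#' warning.
#'
#' @param table numeric feature table restricted to the candidate features.
#' @param m number of clusters.
#' @param seed integer seed.
#' @return Character vector of `m` selected feature names, with attribute
#'   `clusters` (named cluster assignment).
#' @export
decorrelate_by_clustering <- function(table, m, seed = 1L) {
  X <- as.matrix(table)
  p <- ncol(X)
  if (p < m) {
    warning("fewer candidate features (", p, ") than clusters (", m,
            "); returning all candidates")
    return(structure(colnames(X),
                     clusters = stats::setNames(seq_len(p), colnames(X))))
  }
  if (m == p) {
    return(structure(colnames(X),
                     clusters = stats::setNames(seq_len(p), colnames(X))))
  }
  A <- abs(stats::cor(X, method = "spearman"))
  A[!is.finite(A)] <- 0
  diag(A) <- 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  cl <- if (m == 1L) rep(1L, p) else {
    sc <- kernlab::specc(kernlab::as.kernelMatrix(A), centers = m)
    as.integer(sc)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  names(cl) <- colnames(X)
  rng <- make_rng(seed)
  chosen <- vapply(sort(unique(cl)), function(g) {
    members <- sort(names(cl)[cl == g])
    members[[max(1L, ceiling(rng$runif(1) * length(members)))]]
  }, character(1))
  structure(unname(chosen), clusters = cl)
}

#' The full feature pre-selection pipeline
#'
#' Composition of [correlation_prune()], [rank_union()] and
#' [decorrelate_by_clustering()], with a provenance log of what was dropped
#' at every stage. Missing feature values are median-imputed first.
#'
#' @param table numeric feature data.frame.
#' @param labels class labels, one per row.
#' @param config a [selection_config()].
#' @return List with `features` (final character vector, length <= m) and
#'   `log` (per-stage provenance: constant/correlated drops, per-method
#'   rankings, candidate union, cluster assignment).
#' @export
preselect <- function(table, labels, config = selection_config()) {
  X <- impute_median(table)
  pruned <- correlation_prune(X, config$pearson_threshold,
                              seed = derive_seed(config$seed, "prune"))
  cand <- rank_union(pruned, labels, config)
  final <- decorrelate_by_clustering(pruned[, cand, drop = FALSE], config$m,
                                     seed = derive_seed(config$seed, "cluster"))
  list(features = as.character(final),
       log = list(dropped = attr(pruned, "dropped"),
                  rankings = attr(cand, "rankings"),
                  candidates = as.character(cand),
                  clusters = attr(final, "clusters")))
}

#' Median imputation of missing feature values
#' @param table numeric data.frame/matrix.
#' @return data.frame with each column's NAs replaced by the column median
#'   (all-NA columns become 0).
#' @export
impute_median <- function(table) {
  X <- as.data.frame(table)
  for (j in seq_along(X)) {
    v <- X[[j]]
    if (anyNA(v)) {
      med <- stats::median(v, na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      v[is.na(v)] <- med
      X[[j]] <- v
    }
  }
  X
}
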