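#' Classifier specification
#'
#' Registry of the classical supervised models used for conjugate-class
#' prediction. Gradient boosting (the reference model) uses an ensemble of
#' 100 trees by default.
#'
#' @param kind one of `"gradient-boosting"`, `"logistic-regression"`,
#'   `"linear-discriminant"`, `"linear-SVM"`, `"random-forest"`.
#' @param trees number of trees for the ensemble models.
#' @param seed integer seed used at fit time.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("gradient-boosting", "logistic-regression",
                                "linear-discriminant", "linear-SVM",
                                "random-forest"),
                       trees = 100L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(trees >= 1)
  structure(list(kind = kind, trees = as.integer(trees),
                 seed = as.integer(seed)),
            class = "model_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Fit a classifier
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix/data.frame of features (no missing values).
#' @param y class labels (>= 2 distinct).
#' @return A fitted model object of class `ifc_model` carrying the class
#'   levels and feature names.
#' @export
fit_model <- function(spec, X, y) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; impute upstream")
  y <- factor(y)
  if (nlevels(y) < 2) stop("y has a single class")
  fit <- switch(spec$kind,
    "gradient-boosting" = fit_xgboost(X, y, nrounds = spec$trees,
                                      seed = spec$seed),
    "logistic-regression" = with_seed(spec$seed, {
      df <- data.frame(.y = y, X, check.names = FALSE)
      nnet::multinom(.y ~ ., df, maxit = 300, MaxNWts = 1e5, trace = FALSE)
    }),
    "linear-discriminant" = MASS::lda(X, grouping = y),
    "linear-SVM" = with_seed(spec$seed,
      e1071::svm(X, y, kernel = "linear", probability = TRUE)),
    "random-forest" = with_seed(spec$seed,
      randomForest::randomForest(X, y, ntree = max(spec$trees, 100L)))
  )
  structure(list(kind = spec$kind, fit = fit, classes = levels(y),
                 features = colnames(X)),
            class = "ifc_model")
}

# Gradient boosting on a label factor; nthread = 1 for determinism.
fit_xgboost <- function(X, y, nrounds = 100L, seed = 1L, max_depth = 6L,
                        eta = 0.3) {
  X <- as.matrix(X)
  y <- factor(y)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  fit <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(y),
                  max_depth = max_depth, eta = eta, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
  attr(fit, "classes") <- levels(y)
  attr(fit, "feature_names") <- colnames(X)
  fit
}

#' Class-probability predictions
#'
#' @param model an `ifc_model` from [fit_model()].
#' @param X feature matrix with the training columns.
#' @return Matrix (rows = records, columns = classes) of probabilities; every
#'   row sums to 1 within 1e-9.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  P <- switch(model$kind,
    "gradient-boosting" = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(p))
        p <- matrix(p, ncol = length(model$classes), byrow = TRUE)
      dimnames(p) <- list(NULL, model$classes)
      p
    },
    "logistic-regression" = {
      p <- predict(model$fit, data.frame(X, check.names = FALSE), type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)   # 2-class case
      colnames(p) <- model$classes
      p
    },
    "linear-discriminant" = {
      p <- predict(model$fit, X)$posterior
      full <- matrix(0, nrow(X), length(model$classes),
                     dimnames = list(NULL, model$classes))
      full[, colnames(p)] <- p
      full
    },
    "linear-SVM" = {
      pr <- predict(model$fit, X, probability = TRUE)
      p <- attr(pr, "probabilities")[, model$classes, drop = FALSE]
      p
    },
    "random-forest" = predict(model$fit, X, type = "prob")[, model$classes,
                                                           drop = FALSE]
  )
  P / rowSums(P)
}

#' Hard class predictions (argmax of probabilities)
#' @inheritParams predict_proba
#' @return Character vector of predicted class names.
#' @export
predict_class <- function(model, X) {
  P <- predict_proba(model, X)
  colnames(P)[max.col(P, ties.method = "first")]
}

#' Predictions with the entropy of the class simplex
#'
#' The Shannon entropy (natural log) of the predicted probability vector,
#' used by the cleaning pipeline to drop records the classifier is uncertain
#' about. Ranges from 0 (one-hot) to ln(K) (uniform over K classes).
#'
#' @inheritParams predict_proba
#' @return List with `class` (character), `probs` (matrix), `entropy`
#'   (numeric vector).
#' @export
predict_with_entropy <- function(model, X) {
  P <- predict_proba(model, X)
  list(class = colnames(P)[max.col(P, ties.method = "first")],
       probs = P,
       entropy = simplex_entropy(P))
}

#' Shannon entropy of probability rows (natural log)
#' @param P probability matrix (rows sum to 1) or a single vector.
#' @return Numeric vector of entropies.
#' @export
simplex_entropy <- function(P) {
  if (is.null(dim(P))) P <- matrix(P, 1)
  apply(P, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in `y_true` or
#' `y_pred`. A class with undefined precision or recall contributes F1 = 0.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return F1-macro in \[0, 1\].
#' @export
f1_macro <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# Stratified fold assignment: within each class, seeded shuffle then
# round-robin fold labels.
stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  assign <- integer(length(y))
  rng <- make_rng(seed)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[order(rng$runif(length(idx)))]
    assign[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation
#'
#' The benchmark protocol: stratified 5-fold cross-validation repeated 10
#' times (50 fold scores). When a `selection` config is supplied, feature
#' pre-selection and median imputation are refit inside each training fold
#' so no information leaks from the held-out fold.
#'
#' @param X feature data.frame/matrix.
#' @param y class labels.
#' @param spec a [model_spec()].
#' @param folds,repeats protocol size.
#' @param seed integer seed (drives fold assignment and fits).
#' @param selection optional [selection_config()] applied within folds.
#' @return An `eval_result`: list with `fold_scores` (folds x repeats),
#'   `mean`, `sd`, `confusion` (classes x classes counts, first repeat),
#'   `per_class_f1` (first repeat).
#' @export
repeated_stratified_cv <- function(X, y, spec = model_spec(), folds = 5L,
                                   repeats = 10L, seed = 1L,
                                   selection = NULL) {
  X <- as.data.frame(X)
  y <- factor(y)
  scores <- numeric(0)
  confusion <- NULL; per_class <- NULL
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, derive_seed(seed, paste0("cv", r)))
    pred_all <- character(length(y))
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f); te <- which(fold_of == f)
      pred <- fit_predict_fold(X, y, tr, te, spec, selection,
                               derive_seed(seed, paste0("cv", r, "_", f)))
      pred_all[te] <- pred
      scores <- c(scores, f1_macro(y[te], pred))
    }
    if (r == 1L) {
      confusion <- table(truth = y, predicted = factor(pred_all,
                                                       levels = levels(y)))
      per_class <- vapply(levels(y), function(cl)
        f1_binary(y == cl, pred_all == cl), numeric(1))
    }
  }
  structure(list(fold_scores = scores, mean = mean(scores),
                 sd = stats::sd(scores), confusion = confusion,
                 per_class_f1 = per_class),
            class = "eval_result")
}

f1_binary <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

fit_predict_fold <- function(X, y, tr, te, spec, selection, seed) {
  Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
  Xtr <- impute_median(Xtr)
  meds <- vapply(Xtr, stats::median, numeric(1))
  for (j in seq_along(Xte)) {
    v <- Xte[[j]]; v[is.na(v)] <- meds[[j]]; Xte[[j]] <- v
  }
  if (!is.null(selection)) {
    selection$seed <- seed
    keep <- preselect(Xtr, y[tr], selection)$features
    Xtr <- Xtr[, keep, drop = FALSE]
    Xte <- Xte[, keep, drop = FALSE]
  }
  sp <- spec; sp$seed <- seed
  model <- fit_model(sp, Xtr, y[tr])
  predict_class(model, Xte)
}

#' Leave-one-donor-out cross-validation
#'
#' One fold per donor: the model is trained on all other donors' records and
#' scored on the held-out donor, probing inter-donor generalizability.
#'
#' @inheritParams repeated_stratified_cv
#' @param donors donor id per row of `X`.
#' @return An `eval_result` with `per_donor` F1 scores.
#' @export
leave_one_donor_out_cv <- function(X, y, donors, spec = model_spec(),
                                   seed = 1L, selection = NULL) {
  X <- as.data.frame(X); y <- factor(y); donors <- as.character(donors)
  ids <- sort(unique(donors))
  if (length(ids) < 2) stop("need at least 2 donors")
  per_donor <- stats::setNames(numeric(length(ids)), ids)
  pred_all <- character(length(y))
  for (d in ids) {
    te <- which(donors == d); tr <- which(donors != d)
    pred <- fit_predict_fold(X, y, tr, te, spec, selection,
                             derive_seed(seed, paste0("lodo_", d)))
    pred_all[te] <- pred
    per_donor[d] <- f1_macro(y[te], pred)
  }
  structure(list(fold_scores = unname(per_donor), per_donor = per_donor,
                 mean = mean(per_donor), sd = stats::sd(per_donor),
                 confusion = table(truth = y,
                                   predicted = factor(pred_all,
                                                      levels = levels(y))),
                 per_class_f1 = vapply(levels(y), function(cl)
                   f1_binary(y == cl, pred_all == cl), numeric(1))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("F1-macro = %.4f +/- %.4f over %d folds\n",
              x$mean, x$sd, length(x$fold_scores)))
  invisible(x)
}

#' Average-gain feature importance of a gradient-boosting model
#'
#' For every feature, all splits using it are enumerated across all trees;
#' the loss improvement (gain) of those splits is summed and divided by the
#' number of splits, and the resulting per-feature average gains are
#' normalized to sum to 1. Features never used in a split score 0.
#'
#' @param model an `ifc_model` of kind gradient-boosting, or a raw xgboost
#'   booster from `fit_xgboost`.
#' @return Named nonnegative numeric vector over all training features,
#'   summing to 1.
#' @export
gain_importance <- function(model) {
  booster <- if (inherits(model, "ifc_model")) {
    if (model$kind != "gradient-boosting")
      stop("gain importance is only defined for tree ensembles")
    model$fit
  } else model
  feats <- attr(booster, "feature_names")
  if (is.null(feats)) feats <- booster$feature_names
  tree <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  splits <- tree[tree$Feature != "Leaf", c("Feature", "Gain")]
  out <- stats::setNames(rep(0, length(feats)), feats)
  if (nrow(splits)) {
    sums <- tapply(splits$Gain, splits$Feature, sum)
    cnts <- tapply(splits$Gain, splits$Feature, length)
    avg <- sums / cnts
    out[names(avg)] <- pmax(avg, 0)
  }
  if (sum(out) > 0) out <- out / sum(out)
  out
}

#' Median-gain feature importance protocol
#'
#' Repeats a stratified k-fold split `n_repeats` times; each repeat draws a
#' random pre-selection size top-k uniformly from `k_range`, pre-selects
#' features on the training fold, and fits a gradient-boosting model, giving
#' folds x repeats models in total. Every feature's importance is the median
#' of its normalized average gain across the models in which it was
#' available; features never available rank last.
#'
#' @param X,y labeled feature table.
#' @param selection a [selection_config()]; its `top_k` is overridden per
#'   repeat by the random draw.
#' @param n_repeats,folds protocol size (the reference protocol is 100 x 5 =
#'   500 models).
#' @param k_range inclusive range for the random top-k.
#' @param seed integer seed.
#' @return data.frame (feature, median_gain, n_models), sorted by decreasing
#'   median gain (ties by name).
#' @export
importance_protocol <- function(X, y, selection = selection_config(),
                                n_repeats = 100L, folds = 5L,
                                k_range = c(30L, 200L), seed = 1L) {
  X <- as.data.frame(impute_median(X))
  y <- factor(y)
  gains <- list()
  rng <- make_rng(seed)
  for (r in seq_len(n_repeats)) {
    k <- k_range[1] + floor(rng$runif(1) * (k_range[2] - k_range[1] + 1))
    fold_of <- stratified_folds(y, folds, derive_seed(seed, paste0("imp", r)))
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f)
      cfg <- selection
      cfg$top_k <- as.integer(min(k, ncol(X)))
      cfg$m <- as.integer(min(cfg$m, cfg$top_k))
      cfg$seed <- derive_seed(seed, paste0("imp", r, "_", f))
      keep <- preselect(X[tr, , drop = FALSE], y[tr], cfg)$features
      fit <- fit_xgboost(X[tr, keep, drop = FALSE], y[tr],
                         nrounds = 50L, seed = cfg$seed)
      gains[[length(gains) + 1L]] <- gain_importance(fit)
    }
  }
  all_feats <- colnames(X)
  med <- vapply(all_feats, function(fn) {
    v <- unlist(lapply(gains, function(g) g[fn]))
    v <- v[!is.na(v)]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  n_mod <- vapply(all_feats, function(fn)
    sum(vapply(gains, function(g) fn %in% names(g), logical(1))), integer(1))
  ord <- order(-ifelse(is.na(med), -Inf, med), all_feats)
  data.frame(feature = all_feats[ord], median_gain = med[ord],
             n_models = n_mod[ord], row.names = NULL)
}

#' Recursive channel elimination (staining importance)
#'
#' Evaluates the classifier on every non-empty subset of the fluorescent
#' channels, always keeping the stain-free brightfield channel. The feature
#' inventory is rebuilt per subset by restricting the full-panel feature
#' table to the columns whose channels lie in BF plus the subset (pairs must
#' lie entirely inside the subset). For 4 fluorescent channels this yields
#' 15 evaluations.
#'
#' @param table full-panel `feature_table` (from [inventory_full()]).
#' @param labels class labels per row.
#' @param panel the channel panel used to build `table`.
#' @param spec a [model_spec()].
#' @param folds,repeats,seed CV protocol per subset.
#' @return Named list (subset label such as `"BF+CD3+MHCII"`) of
#'   `eval_result`s.
#' @export
channel_ablation <- function(table, labels, panel = default_panel(),
                             spec = model_spec(), folds = 3L, repeats = 1L,
                             seed = 1L) {
  if (!"BF" %in% panel) stop("panel must include BF")
  fluor <- fluorescent_channels(panel)
  inv_cols <- colnames(table)
  out <- list()
  for (sz in seq_along(fluor)) {
    combos <- utils::combn(fluor, sz, simplify = FALSE)
    for (S in combos) {
      keep_ch <- c("BF", S)
      keep <- vapply(inv_cols, function(cn) {
        chs <- feature_channels(cn, panel)
        length(chs) > 0 && all(chs %in% keep_ch) &&
          !(length(chs) == 2 && !all(chs %in% S))
      }, logical(1))
      sub <- table[, keep, drop = FALSE]
      lab <- paste(c("BF", S), collapse = "+")
      out[[lab]] <- repeated_stratified_cv(sub, labels, spec, folds = folds,
                                           repeats = repeats, seed = seed)
    }
  }
  out
}

# Channels referenced by a feature column name (prefix-based).
feature_channels <- function(name, panel) {
  hits <- panel[vapply(panel, function(ch)
    startsWith(name, paste0(ch, "_")), logical(1))]
  if (length(hits) == 1) {
    rest <- substring(name, nchar(hits) + 2)
    second <- panel[vapply(panel, function(ch)
      startsWith(rest, paste0(ch, "_")), logical(1))]
    return(c(hits, second))
  }
  hits
}

#' Learning curve over stratified training subsets
#'
#' Fits the model on stratified fractions of the training data and scores on
#' a fixed test set, repeated with different subsample seeds.
#'
#' @param X_train,y_train training table and labels.
#' @param X_test,y_test fixed held-out test set.
#' @param fractions training fractions in (0, 1\]; 1 means the full set.
#' @param spec a [model_spec()].
#' @param repeats subsample repeats per fraction.
#' @param seed integer seed.
#' @return data.frame (fraction, mean_f1, sd_f1, n_train).
#' @export
learning_curve <- function(X_train, y_train, X_test, y_test,
                           fractions = seq(0.05, 0.95, 0.10),
                           spec = model_spec(), repeats = 3L, seed = 1L) {
  X_train <- as.data.frame(impute_median(X_train))
  X_test <- as.data.frame(impute_median(X_test))
  rows <- list()
  for (fr in fractions) {
    sc <- numeric(repeats)
    ntr <- NA_integer_
    for (r in seq_len(repeats)) {
      s <- derive_seed(seed, sprintf("lc_%0.3f_%d", fr, r))
      idx <- if (fr >= 1) seq_along(y_train)
             else stratified_split(y_train, fr, s)$train
      ntr <- length(idx)
      sp <- spec; sp$seed <- s
      model <- fit_model(sp, X_train[idx, , drop = FALSE], y_train[idx])
      sc[r] <- f1_macro(y_test, predict_class(model, X_test))
    }
    rows[[length(rows) + 1L]] <- data.frame(fraction = fr, mean_f1 = mean(sc),
                                            sd_f1 = stats::sd(sc),
                                            n_train = ntr)
  }
  do.call(rbind, rows)
}
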