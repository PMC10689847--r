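test_that("every model kind emits valid probability simplexes", {
  pt <- planted_table(n = 120, p = 6, informative = 2, shift = 3, seed = 1)
  X <- as.matrix(pt$X)
  for (kind in c("gradient-boosting", "logistic-regression",
                 "linear-discriminant", "linear-SVM", "random-forest")) {
    m <- fit_model(model_spec(kind, trees = 50, seed = 3), X, pt$y)
    P <- predict_proba(m, X)
    expect_equal(dim(P), c(120L, 2L))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0))
    expect_gte(f1_macro(pt$y, predict_class(m, X)), 0.9)
  }
  expect_error(fit_model(model_spec(), X, rep("a", 120)), "single class")
})

test_that("tree-model predictions ignore feature column order", {
  pt <- planted_table(n = 100, p = 5, seed = 2)
  X <- as.matrix(pt$X)
  m <- fit_model(model_spec("gradient-boosting", seed = 4), X, pt$y)
  perm <- X[, c(3, 1, 5, 2, 4)]
  expect_equal(predict_proba(m, perm), predict_proba(m, X))
})

test_that("macro F1 matches hand-computed cases", {
  expect_equal(f1_macro(c("a", "b"), c("a", "b")), 1)
  expect_equal(f1_macro(c("a", "a", "b", "b"), c("a", "b", "b", "b")),
               (2 / 3 + 4 / 5) / 2)
  expect_equal(f1_macro(rep(c("a", "b"), 10), rep("a", 20)), 1 / 3)
  expect_error(f1_macro(character(0), character(0)), "empty")
})

test_that("macro F1 agrees with the brute-force oracle on random cases", {
  set.seed(7)
  for (i in 1:60) {
    k <- sample(2:5, 1); n <- sample(5:30, 1)
    y_true <- sample(letters[1:k], n, replace = TRUE)
    y_pred <- sample(letters[1:k], n, replace = TRUE)
    expect_equal(f1_macro(y_true, y_pred), brute_f1_macro(y_true, y_pred))
  }
})

test_that("repeated stratified CV partitions, is seeded, and scores null data at chance", {
  pt <- planted_table(n = 90, p = 4, informative = 0, seed = 5)
  y9 <- factor(rep(paste0("c", 1:3), 30))
  ev1 <- repeated_stratified_cv(pt$X, y9, model_spec("gradient-boosting",
                                                     trees = 30),
                                folds = 3, repeats = 2, seed = 6)
  ev2 <- repeated_stratified_cv(pt$X, y9, model_spec("gradient-boosting",
                                                     trees = 30),
                                folds = 3, repeats = 2, seed = 6)
  expect_identical(ev1$fold_scores, ev2$fold_scores)
  expect_length(ev1$fold_scores, 6)
  expect_equal(unname(rowSums(ev1$confusion)), as.vector(table(y9)))
  # pure-noise features: macro F1 near chance for 3 balanced classes
  expect_lt(ev1$mean, 0.55)
  expect_gt(ev1$mean, 0.15)
})

test_that("leave-one-donor-out yields one fold per donor", {
  pt <- planted_table(n = 120, p = 5, informative = 2, shift = 3, seed = 8)
  donors <- rep(paste0("d", 1:4), each = 30)
  ev <- leave_one_donor_out_cv(pt$X, pt$y, donors,
                               model_spec("gradient-boosting", trees = 30))
  expect_named(ev$per_donor, paste0("d", 1:4))
  expect_gte(ev$mean, 0.85)
  expect_error(leave_one_donor_out_cv(pt$X, pt$y, rep("d1", 120),
                                      model_spec()), "2 donors")
})

test_that("gain importance is a simplex concentrated on informative features", {
  pt <- planted_table(n = 200, p = 8, informative = 1, shift = 4, seed = 9)
  X <- as.matrix(pt$X)
  m <- fit_model(model_spec("gradient-boosting", trees = 40, seed = 2),
                 X, pt$y)
  g <- gain_importance(m)
  expect_equal(sum(g), 1)
  expect_true(all(g >= 0))
  expect_equal(names(sort(g, decreasing = TRUE))[1], "f01")
  expect_lt(sum(g[setdiff(names(g), "f01")]), 0.3)

  m1 <- fit_model(model_spec("gradient-boosting", trees = 20, seed = 2),
                  X[, "f01", drop = FALSE], pt$y)
  expect_equal(unname(gain_importance(m1)), 1)
  expect_error(gain_importance(fit_model(model_spec("random-forest"),
                                         X, pt$y)), "tree ensembles")
})

test_that("gain importance matches an independent tree-dump oracle", {
  set.seed(10)
  for (i in 1:15) {
    n <- 40; p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- factor(ifelse(X[, 1] + 0.5 * rnorm(n) > 0, "a", "b"))
    booster <- fit_xgboost(X, y, nrounds = 3, seed = i, max_depth = 3)
    expect_equal(gain_importance(booster), dump_gain_oracle(booster),
                 tolerance = 1e-6)
  }
})

test_that("prediction entropy spans its closed-form range", {
  expect_equal(simplex_entropy(c(1, rep(0, 8))), 0)
  expect_equal(simplex_entropy(rep(1 / 9, 9)), log(9))
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(9); p <- p / sum(p)
    h <- simplex_entropy(p)
    expect_gte(h, 0); expect_lte(h, log(9) + 1e-12)
  }
})

test_that("the median-gain importance protocol recovers planted features", {
  pt <- planted_table(n = 250, p = 12, informative = 2, shift = 3, seed = 12)
  cfg <- selection_config(methods = c("mutual_info", "xgboost"),
                          top_k = 6, m = 6, seed = 1)
  rk <- importance_protocol(pt$X, pt$y, cfg, n_repeats = 2, folds = 3,
                            k_range = c(4L, 8L), seed = 13)
  expect_true(all(c("f01", "f02") %in% rk$feature[1:4]))
  rk2 <- importance_protocol(pt$X, pt$y, cfg, n_repeats = 2, folds = 3,
                             k_range = c(4L, 8L), seed = 13)
  expect_identical(rk, rk2)
})

test_that("channel ablation evaluates every BF-plus-subset inventory", {
  skip_if_not_installed("xgboost")
  recs <- lapply(1:54, function(i)
    render_record(scene_spec(class_taxonomy()$classes[(i %% 9) + 1]),
                  i, record_id = paste0("r", i)))
  tab <- extract_features(recs, inventory_full())
  labels <- vapply(recs, function(r) r$meta$label, character(1))
  res <- channel_ablation(impute_median(tab), labels,
                          spec = model_spec("gradient-boosting", trees = 10),
                          folds = 2, seed = 3)
  expect_length(res, 15)                        # 2^4 - 1 subsets
  expect_true("BF+Factin+MHCII+CD3+PCD3z" %in% names(res))
  # the single-channel runs see only their own channels' columns
  expect_true(all(vapply(res, function(e) is.numeric(e$mean), logical(1))))
})

test_that("learning curves improve with data and are seeded", {
  pt <- planted_table(n = 240, p = 5, informative = 2, shift = 2, seed = 14)
  tr <- 1:160; te <- 161:240
  lc <- learning_curve(pt$X[tr, ], pt$y[tr], pt$X[te, ], pt$y[te],
                       fractions = c(0.1, 0.5, 1),
                       spec = model_spec("gradient-boosting", trees = 20),
                       repeats = 2, seed = 15)
  expect_equal(nrow(lc), 3)
  expect_gte(lc$mean_f1[3] + 0.05, lc$mean_f1[1])   # monotone in expectation
  lc2 <- learning_curve(pt$X[tr, ], pt$y[tr], pt$X[te, ], pt$y[te],
                        fractions = c(0.1, 0.5, 1),
                        spec = model_spec("gradient-boosting", trees = 20),
                        repeats = 2, seed = 15)
  expect_identical(lc, lc2)
})
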