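# A fixture sample where every threshold rule has known planted violators.
# Baseline values sit in narrow bands so the sample percentiles cleanly
# separate the planted tails.
rule_fixture <- function(n = 500, seed = 1) {
  set.seed(seed)
  feat <- data.frame(
    LiveDead_mean = runif(n, 100, 200),
    BF_grms = runif(n, 90, 110),
    MHCII_mean = runif(n, 50, 60),
    MHCII_area = runif(n, 280, 320),
    CD3_mean = runif(n, 40, 50),
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n)
  )
  rownames(feat) <- sprintf("r%03d", seq_len(n))
  list(features = feat,
       pred = rep("synapse w/ signaling", n),
       entropy = rep(0.2, n))
}

test_that("each threshold rule claims exactly its planted violators", {
  fx <- rule_fixture()
  n <- nrow(fx$features)
  # plant violators in disjoint record ranges
  dead <- 1:20;    fx$features$LiveDead_mean[dead] <- runif(20, 5000, 6000)
  blur <- 21:28;   fx$features$BF_grms[blur] <- runif(8, 1, 5)
  unsure <- 36:50; fx$entropy[unsure] <- 1.5
  fx$pred[51:150] <- "single B-LCL"
  dimb <- 51:55;   fx$features$MHCII_mean[dimb] <- runif(5, 1, 3)
  small_b <- 56:62; fx$features$MHCII_area[small_b] <- runif(7, 10, 30)
  fx$pred[151:250] <- "single T cell w/o signaling"
  dimt <- 151;     fx$features$CD3_mean[dimt] <- 0.5
  fx$pred[251:350] <- "B-LCL and T cell in one layer"
  small_l <- 251:270; fx$features$MHCII_area[small_l] <- runif(20, 10, 30)

  res <- clean_sample(fx$features, fx$pred, fx$entropy,
                      outlier_features = c("x1", "x2", "x3"),
                      params = clean_params(iforest_score = 1.01,
                                            embed = "none",
                                            dbscan_eps = 10),
                      seed = 2)
  ids <- rownames(fx$features)
  removed_by <- function(k) res$report$rules[[k]]$removed
  # rule 1: 90th percentile of the viability distribution -> the top 10%
  # (about 50 records) includes every planted dead cell
  expect_true(all(ids[dead] %in% removed_by(1)))
  # rule 2: all planted blurred records fall below the 2nd percentile; they
  # are claimed by rule 2 unless rule 1's percentile cut got them first
  expect_true(all(ids[blur] %in% c(removed_by(1), removed_by(2))))
  expect_true(all(ids[unsure] %in% c(removed_by(1), removed_by(2),
                                     removed_by(3))))
  left <- setdiff(ids[unsure], c(removed_by(1), removed_by(2)))
  expect_setequal(removed_by(3), left)
  expect_true(all(ids[dimb] %in% Reduce(c, lapply(1:4, removed_by))))
  expect_true(all(ids[small_b] %in% Reduce(c, lapply(1:5, removed_by))))
  expect_true(all(ids[dimt] %in% Reduce(c, lapply(1:6, removed_by))))
  expect_true(all(ids[small_l] %in% Reduce(c, lapply(1:7, removed_by))))
  # conservation and disjoint attribution
  all_removed <- unlist(lapply(res$report$rules, `[[`, "removed"))
  expect_false(anyDuplicated(all_removed) > 0)
  expect_equal(length(res$retained) + length(all_removed), n)
})

test_that("a uniform 9-class probability vector is removed by the entropy rule", {
  fx <- rule_fixture(n = 100, seed = 3)
  ent <- rep(0.1, 100)
  ent[7] <- simplex_entropy(rep(1 / 9, 9))        # ln 9 > 1.0
  # keep record 7 safely inside the viability and focus bands so the
  # entropy rule is the first to match
  fx$features$LiveDead_mean[7] <- 150
  fx$features$BF_grms[7] <- 100
  res <- clean_sample(fx$features, fx$pred, ent,
                      outlier_features = c("x1", "x2"),
                      params = clean_params(iforest_score = 1.01,
                                            embed = "none", dbscan_eps = 10),
                      seed = 1)
  expect_true("r007" %in% res$report$rules[[3]]$removed)
})

test_that("threshold rules are idempotent under frozen thresholds", {
  fx <- rule_fixture(n = 300, seed = 4)
  viab <- fx$features$LiveDead_mean
  thr <- quantile(viab, 0.9, type = 7)
  first <- viab >= thr
  # frozen threshold re-applied to the survivors removes nothing
  expect_false(any(viab[!first] >= thr))
})

test_that("empty input produces an empty report without error", {
  fx <- rule_fixture(n = 0)
  res <- clean_sample(fx$features[0, ], character(0), numeric(0))
  expect_length(res$retained, 0)
  expect_equal(res$report$n_input, 0)
})

test_that("a missing rule feature is reported with its rule", {
  fx <- rule_fixture(n = 20)
  fx$features$CD3_mean <- NULL
  expect_error(clean_sample(fx$features, fx$pred, fx$entropy),
               "CD3_mean")
})

test_that("isolation forest isolates planted extremes above every inlier", {
  set.seed(5)
  inliers <- matrix(rnorm(300 * 4), 300, 4)
  outliers <- matrix(rnorm(6 * 4, mean = 12, sd = 0.3), 6, 4)
  X <- rbind(inliers, outliers)
  sc <- iforest_scores(X, seed = 6)
  expect_gt(min(sc[301:306]), max(sc[1:300]))     # exact score separation
  expect_true(all(sc[301:306] > 0.5))             # all planted removed
})

test_that("the isolation-forest rule removes planted outliers in context", {
  fx <- rule_fixture(n = 400, seed = 7)
  out_rows <- 390:400
  fx$features$x1[out_rows] <- 50
  fx$features$x2[out_rows] <- -50
  res <- clean_sample(fx$features, fx$pred, fx$entropy,
                      outlier_features = c("x1", "x2", "x3"),
                      params = clean_params(embed = "none", dbscan_eps = 10),
                      seed = 8)
  removed8 <- res$report$rules[[8]]$removed
  expect_true(all(rownames(fx$features)[out_rows] %in% removed8))
})

test_that("the density rule drops noise points and rare clusters exactly", {
  set.seed(9)
  # two dense blobs (standardized spread ~0.02 << eps) plus far singletons
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.01), rnorm(n, cy, 0.01))
  X <- rbind(blob(0, 0, 240), blob(1, 1, 240),
             matrix(c(30, 30, -30, 25, 25, -30), 3, 2, byrow = TRUE))
  fx <- rule_fixture(n = nrow(X), seed = 10)
  fx$features$x1 <- X[, 1]; fx$features$x2 <- X[, 2]
  # keep the planted rows inside the threshold-rule bands so the density
  # rule is the first to match them
  fx$features$LiveDead_mean[481:483] <- 150
  fx$features$BF_grms[481:483] <- 100
  res <- clean_sample(fx$features, fx$pred, fx$entropy,
                      outlier_features = c("x1", "x2"),
                      params = clean_params(iforest_score = 1.01,
                                            embed = "none"),
                      seed = 11)
  removed9 <- res$report$rules[[9]]$removed
  expect_setequal(removed9, rownames(fx$features)[481:483])
})

test_that("model-based rules are reproducible for a fixed seed", {
  fx <- rule_fixture(n = 120, seed = 12)
  run <- function() clean_sample(fx$features, fx$pred, fx$entropy,
                                 outlier_features = c("x1", "x2", "x3"),
                                 params = clean_params(), seed = 13)
  r1 <- run(); r2 <- run()
  expect_identical(r1$retained, r2$retained)
  expect_identical(lapply(r1$report$rules, `[[`, "removed"),
                   lapply(r2$report$rules, `[[`, "removed"))
})

test_that("cohort cleaning computes thresholds within each donor x condition", {
  fx1 <- rule_fixture(n = 60, seed = 14)
  fx2 <- rule_fixture(n = 60, seed = 15)
  fx2$features$LiveDead_mean <- fx2$features$LiveDead_mean + 5000
  feats <- rbind(fx1$features, fx2$features)
  rownames(feats) <- sprintf("m%03d", 1:120)
  groups <- data.frame(donor_id = rep(c("d1", "d2"), each = 60),
                       condition = "ctrl")
  res <- clean_cohort(feats, groups, c(fx1$pred, fx2$pred),
                      c(fx1$entropy, fx2$entropy),
                      outlier_features = c("x1", "x2"),
                      params = clean_params(iforest_score = 1.01,
                                            embed = "none", dbscan_eps = 10),
                      seed = 16)
  # d2's uniformly shifted viability is not flagged wholesale: its own 90th
  # percentile governs, so each sample loses only its top tail
  n_d2 <- sum(startsWith(res$retained, "m1") |
                as.integer(substring(res$retained, 2)) > 60)
  expect_gt(n_d2, 40)
  expect_length(res$reports, 2)
})
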