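test_that("BH adjustment matches the reference step-up on random p-vectors", {
  set.seed(1)
  for (i in 1:200) {
    m <- sample(1:30, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # adjusted p monotone in raw p
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("exact signed-rank p-values match the reference implementation", {
  set.seed(2)
  for (i in 1:120) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), 2)
    x <- x[x != 0]
    if (length(x) < 2 || anyDuplicated(abs(x))) next
    ours <- signed_rank_test(x)
    ref <- suppressWarnings(wilcox.test(x, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  expect_equal(signed_rank_test(rep(0, 5))$p_value, 1)
})

test_that("six same-sign fold changes give the printed exact p-value", {
  x <- c(0.4, 0.7, 0.2, 0.9, 0.5, 0.3)
  expect_equal(signed_rank_test(x)$p_value, 2 / 2^6)      # 0.03125
  expect_equal(signed_rank_test(-x)$p_value, 2 / 2^6)
})

test_that("exact Mann-Whitney matches the reference and the closed form", {
  set.seed(3)
  for (i in 1:120) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    ours <- mann_whitney_test(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(mann_whitney_test(c(1, 2, 3), c(4, 5, 6))$p_value,
               2 / choose(6, 3))                          # 0.1
  expect_equal(mann_whitney_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
})

test_that("large-sample Mann-Whitney approximates the reference with ties", {
  set.seed(4)
  x <- sample(1:8, 30, replace = TRUE)
  y <- sample(3:10, 40, replace = TRUE)
  ours <- mann_whitney_test(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_false(ours$exact)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("class frequencies form a simplex over analysis classes", {
  pred <- c(rep("synapse w/ signaling", 50),
            rep("single B-LCL", 930),
            rep("no cell-cell interaction", 70),       # artifact, excluded
            rep("synapse w/o signaling", 20))
  groups <- data.frame(donor_id = "d1", condition = "ctrl")[rep(1, 1070), ]
  fr <- class_frequencies(pred, groups)
  expect_equal(fr$n, 1000)                              # artifacts dropped
  expect_equal(fr[["synapse w/ signaling"]], 0.05)
  cls <- analysis_classes()
  expect_equal(sum(unlist(fr[, cls])), 1)
})

test_that("frequency tests reproduce the printed adjusted p-values", {
  # six donors; six classes with a donor-consistent sign (five up, one
  # down — composition forces a decrease somewhere) and one mixed class
  set.seed(5)
  donors <- paste0("d", 1:6)
  cls <- analysis_classes()
  rows <- list()
  for (i in seq_along(donors)) {
    base <- stats::setNames(c(rep(0.12, 5), 0.3, 0.1), cls)
    up <- base
    up[1:5] <- base[1:5] * runif(5, 1.15, 1.25)            # consistently up
    up[7] <- base[7] * (if (i %% 2) runif(1, 1.25, 1.35)
                        else runif(1, 0.65, 0.75))         # mixed
    up[6] <- 1 - sum(up[-6])                               # consistently down
    rows[[2 * i - 1]] <- data.frame(donor_id = donors[i],
                                    condition = "ctrl",
                                    as.list(base),
                                    n = 1000, check.names = FALSE)
    rows[[2 * i]] <- data.frame(donor_id = donors[i], condition = "ab",
                                as.list(up),
                                n = 1000, check.names = FALSE)
  }
  freqs <- do.call(rbind, rows)
  res <- frequency_test(freqs, "ab", "ctrl")
  six <- res$tests[res$tests$class != cls[7], ]
  expect_equal(six$p, rep(0.03125, 6))
  expect_equal(round(six$p_adj, 3), rep(0.036, 6))      # 0.03125 * 7/6
  expect_true(all(six$significant))
})

test_that("log2 fold changes are antisymmetric in the condition order", {
  set.seed(6)
  cls <- analysis_classes()
  rows <- list()
  for (d in paste0("d", 1:5)) {
    for (cn in c("a", "b")) {
      f <- runif(7, 0.05, 0.3); f <- f / sum(f)
      rows[[length(rows) + 1]] <- data.frame(
        donor_id = d, condition = cn,
        as.list(stats::setNames(f, cls)), n = 500, check.names = FALSE)
    }
  }
  freqs <- do.call(rbind, rows)
  ab <- frequency_test(freqs, "a", "b")
  ba <- frequency_test(freqs, "b", "a")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$tests$p, ba$tests$p)
})

test_that("zero frequencies and missing conditions are handled explicitly", {
  cls <- analysis_classes()
  f1 <- stats::setNames(c(0.5, 0.5, 0, 0, 0, 0, 0), cls)
  f2 <- stats::setNames(c(0.4, 0.5, 0.1, 0, 0, 0, 0), cls)
  mk <- function(d, cn, f) data.frame(donor_id = d, condition = cn,
                                      as.list(f), n = 100,
                                      check.names = FALSE)
  freqs <- rbind(mk("d1", "ctrl", f1), mk("d1", "ab", f2),
                 mk("d2", "ctrl", f2), mk("d2", "ab", f1),
                 mk("d3", "ctrl", f1))                 # d3 lacks 'ab'
  ws <- capture_warnings(res <- frequency_test(freqs, "ab", "ctrl"))
  expect_true(any(grepl("d3", ws)))
  expect_false("d3" %in% rownames(res$log2fc))
  expect_true(is.na(res$log2fc["d1", cls[3]]))         # zero in control arm
})

test_that("identical arms give an all-zero difference map", {
  set.seed(7)
  vals <- matrix(rnorm(200 * 3), 200, 3,
                 dimnames = list(NULL, c("fa", "fb", "fc")))
  features <- as.data.frame(rbind(vals, vals))
  rownames(features) <- sprintf("r%03d", 1:400)
  groups <- data.frame(donor_id = "d1",
                       condition = rep(c("ab", "ctrl"), each = 200))
  dm <- feature_difference(features, groups, "ab", "ctrl")
  expect_true(all(dm$map == 0))
})

test_that("planted location shifts are recovered with the correct sign", {
  set.seed(8)
  donors <- paste0("d", 1:6)
  n_arm <- 300
  feats <- paste0("f", 1:10)
  up <- feats[1:3]; down <- feats[4:5]
  tabs <- list(); grp <- list()
  for (d in donors) {
    base <- matrix(rnorm(2 * n_arm * 10), 2 * n_arm, 10,
                   dimnames = list(NULL, feats))
    base[1:n_arm, up] <- base[1:n_arm, up] + 1        # +1 pooled sd
    base[1:n_arm, down] <- base[1:n_arm, down] - 1
    tabs[[d]] <- as.data.frame(base)
    grp[[d]] <- data.frame(donor_id = d,
                           condition = rep(c("ab", "ctrl"), each = n_arm))
  }
  features <- do.call(rbind, tabs)
  rownames(features) <- sprintf("r%04d", seq_len(nrow(features)))
  groups <- do.call(rbind, grp)
  dm <- feature_difference(features, groups, "ab", "ctrl")
  expect_true(all(dm$map[up, ] == 1))
  expect_true(all(dm$map[down, ] == -1))
  cs <- consistency_summary(dm, min_donors = 4)
  expect_setequal(cs$feature, c(up, down))
  expect_true(all(cs$n_donors == 6))
  # at/below threshold edges
  expect_equal(nrow(consistency_summary(dm, min_donors = 7)), 0)
})
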