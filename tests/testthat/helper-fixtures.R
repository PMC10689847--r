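# Shared fixture builders (everything generated in code at test time).

square_mask <- function(size = 20, from = 5, to = 14) {
  m <- matrix(FALSE, size, size)
  m[from:to, from:to] <- TRUE
  m
}

disk_mask <- function(size, cy, cx, r) {
  y <- matrix(seq_len(size) - 1, size, size)
  x <- t(y)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

# A minimal two-channel record for I/O tests.
tiny_record <- function(id = "r1", seed = 1) {
  set.seed(seed)
  img <- array(sample(0:4095, 5 * 32 * 32, replace = TRUE), c(32, 32, 5))
  msk <- array(FALSE, dim(img))
  for (i in 1:5) msk[8:24, 8:24, i] <- TRUE
  cell_record(id, c("BF", "Factin", "MHCII", "CD3", "PCD3z"), img, msk,
              list(donor_id = "d1", experiment_id = "e1",
                   condition = "ctrl", label = "synapse w/ signaling"))
}

# Feature table with planted class signal in the first `informative` columns.
planted_table <- function(n = 200, p = 20, informative = 1, shift = 2,
                          seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  y <- factor(rep(c("a", "b"), length.out = n))
  for (j in seq_len(informative))
    X[[j]] <- X[[j]] + ifelse(y == "a", shift, 0)
  list(X = X, y = y)
}

# Independent brute-force macro F1 (per-class precision/recall from scratch).
brute_f1_macro <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  f1s <- numeric(0)
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s <- c(f1s, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  mean(f1s)
}

# Independent gain-importance oracle: parse the booster's text dump and
# re-enumerate every split's gain.
dump_gain_oracle <- function(booster) {
  feats <- attr(booster, "feature_names")
  txt <- xgboost::xgb.dump(booster, with_stats = TRUE)
  splits <- grep("gain=", txt, value = TRUE)
  fname <- sub(".*\\[([^<]+)<.*", "\\1", splits)
  gains <- as.numeric(sub(".*gain=([-0-9.eE+]+),.*", "\\1", splits))
  out <- stats::setNames(rep(0, length(feats)), feats)
  for (u in unique(fname))
    out[u] <- mean(gains[fname == u])
  out <- pmax(out, 0)
  if (sum(out) > 0) out / sum(out) else out
}
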