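#' Restrict predictions to the synapse population
#'
#' The functional readout is assumed to be driven by conjugates that formed
#' a synapse, so only records predicted as 'synapse w/o signaling' or
#' 'synapse w/ signaling' (after cleaning) enter the regression.
#'
#' @param pred_class predicted class per record.
#' @return Logical vector selecting the synapse records.
#' @export
select_synapse_population <- function(pred_class) {
  pred_class %in% c("synapse w/o signaling", "synapse w/ signaling")
}

#' Percentile aggregation of single-record features per donor x condition
#'
#' Multiple-instance summary: each donor x condition group of records is
#' collapsed to the 5th, 50th and 95th percentile of every feature,
#' capturing the extremes and the average. Aggregation is permutation-
#' invariant over the records within a group; missing feature values
#' propagate as missing; a group with no records is dropped with a warning.
#'
#' @param features feature data.frame (rownames = record ids), typically
#'   restricted to the consistent features of the difference map.
#' @param groups data.frame with `donor_id`, `condition` per row.
#' @param percentiles integer percentiles (default 5, 50, 95).
#' @return List with `profile` (data.frame, columns `<feature>|p<q>`),
#'   `groups` (donor_id, condition per row), `n_images` per row.
#' @export
aggregate_percentiles <- function(features, groups,
                                  percentiles = c(5, 50, 95)) {
  key <- paste(groups$donor_id, groups$condition, sep = "\r")
  uk <- unique(key)
  feats <- colnames(features)
  cols <- as.vector(outer(feats, percentiles,
                          function(f, q) paste0(f, "|p", q)))
  prof <- matrix(NA_real_, length(uk), length(cols),
                 dimnames = list(NULL, cols))
  n_images <- integer(length(uk))
  for (i in seq_along(uk)) {
    idx <- which(key == uk[i])
    n_images[i] <- length(idx)
    for (j in seq_along(feats)) {
      v <- features[idx, j]
      v <- v[!is.na(v)]
      if (!length(v)) next
      q <- stats::quantile(v, percentiles / 100, type = 7, names = FALSE)
      prof[i, paste0(feats[j], "|p", percentiles)] <- q
    }
  }
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  list(profile = as.data.frame(prof),
       groups = data.frame(donor_id = parts[, 1], condition = parts[, 2],
                           stringsAsFactors = FALSE),
       n_images = n_images)
}

#' Leave-one-donor-out sparse linear regression of a functional readout
#'
#' For each held-out donor the design columns are standardized on the
#' training rows, an L1-penalized linear model is fitted along the lasso
#' regularization path, the penalty is chosen by inner leave-one-row-out
#' cross-validation on the training rows, and the held-out donor's rows are
#' predicted. Reported feature importance is the ordering of absolute
#' standardized coefficients of the final full-data fit at the
#' cross-validated penalty. An optional condition-holdout scheme restricts
#' the test rows to given conditions (e.g. train on controls plus one
#' activator, predict the other activator) while those conditions are also
#' removed from every training set.
#'
#' @param profile aggregated design (from [aggregate_percentiles()]:
#'   `$profile`), rows aligned with `groups`.
#' @param y functional readout per row.
#' @param groups data.frame with `donor_id`, `condition` per row.
#' @param holdout_conditions optional character vector of conditions to be
#'   predicted only (and excluded from training).
#' @param lambda optional fixed penalty overriding the inner CV choice.
#' @return Object of class `functional_model`: list with `coefficients`
#'   (standardized scale, named), `intercept`, `predictions` (data.frame
#'   donor_id, condition, observed, predicted), `spearman` (pooled rank
#'   correlation), `importance` (features ordered by |coefficient|).
#' @export
fit_predict_lodo <- function(profile, y, groups, holdout_conditions = NULL,
                             lambda = NULL) {
  X <- as.matrix(profile)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (length(y) != nrow(X)) stop("y must align with the profile rows")
  donors <- unique(groups$donor_id)
  if (length(donors) < 3) stop("need at least 3 donors")
  test_rows_of <- function(d) {
    te <- which(groups$donor_id == d)
    if (!is.null(holdout_conditions))
      te <- te[groups$condition[te] %in% holdout_conditions]
    te
  }
  preds <- data.frame()
  for (d in donors) {
    te <- test_rows_of(d)
    if (!length(te)) next
    tr <- setdiff(which(groups$donor_id != d),
                  which(groups$condition %in% holdout_conditions))
    fit <- lasso_std_fit(X[tr, , drop = FALSE], y[tr], lambda)
    yhat <- lasso_std_predict(fit, X[te, , drop = FALSE])
    preds <- rbind(preds, data.frame(donor_id = d,
                                     condition = groups$condition[te],
                                     observed = y[te], predicted = yhat,
                                     stringsAsFactors = FALSE))
  }
  rho <- if (nrow(preds) >= 3 && stats::sd(preds$predicted) > 0 &&
             stats::sd(preds$observed) > 0)
    stats::cor(preds$observed, preds$predicted, method = "spearman")
  else NA_real_
  tr_all <- setdiff(seq_len(nrow(X)),
                    if (is.null(holdout_conditions)) integer(0)
                    else which(groups$condition %in% holdout_conditions))
  final <- lasso_std_fit(X[tr_all, , drop = FALSE], y[tr_all], lambda)
  coefs <- final$beta
  imp <- names(sort(abs(coefs[coefs != 0]), decreasing = TRUE))
  structure(list(coefficients = coefs, intercept = final$a0,
                 scaling = list(center = final$center, scale = final$scale),
                 lambda = final$lambda, predictions = preds,
                 spearman = rho, importance = imp),
            class = "functional_model")
}

# Standardize columns on the given rows, fit the lasso path, choose lambda
# by leave-one-out CV (unless fixed), return standardized coefficients.
lasso_std_fit <- function(X, y, lambda = NULL) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (stats::sd(y) == 0) {
    beta <- stats::setNames(rep(0, ncol(Z)), colnames(Z))
    return(list(beta = beta, a0 = mean(y), center = ctr, scale = scl,
                lambda = Inf))
  }
  # explicit lambda grid down to an effectively unpenalized fit (glmnet's
  # own path can stop early once the deviance saturates)
  lmax <- max(abs(crossprod(Z, y - mean(y)))) / nrow(Z)
  lam_seq <- exp(seq(log(lmax), log(lmax * 1e-7), length.out = 60))
  if (is.null(lambda)) {
    n <- nrow(Z)
    errs <- matrix(NA_real_, n, length(lam_seq))
    for (i in seq_len(n)) {
      f <- glmnet::glmnet(Z[-i, , drop = FALSE], y[-i], alpha = 1,
                          standardize = FALSE, lambda = lam_seq)
      pred <- stats::predict(f, Z[i, , drop = FALSE], s = lam_seq)
      errs[i, seq_len(ncol(pred))] <- (pred - y[i])^2
    }
    cvm <- colMeans(errs, na.rm = TRUE)
    lambda <- lam_seq[which.min(cvm)]
  }
  fit <- glmnet::glmnet(Z, y, alpha = 1, standardize = FALSE,
                        lambda = sort(unique(c(lam_seq, lambda)),
                                      decreasing = TRUE))
  beta <- as.numeric(stats::coef(fit, s = lambda))[-1]
  a0 <- as.numeric(stats::coef(fit, s = lambda))[1]
  list(beta = stats::setNames(beta, colnames(Z)), a0 = a0, center = ctr,
       scale = scl, lambda = lambda)
}

lasso_std_predict <- function(fit, X) {
  Z <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  as.numeric(fit$a0 + Z %*% fit$beta)
}

#' Unstandardized coefficients of a functional model
#' @param model a `functional_model`.
#' @return Named vector of coefficients on the original feature scale.
#' @export
unstandardized_coefficients <- function(model) {
  model$coefficients / model$scaling$scale
}

#' @export
print.functional_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("functional model:", nz, "active of", length(x$coefficients),
      "aggregated features; pooled Spearman rho =",
      round(x$spearman, 3), "\n")
  invisible(x)
}
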