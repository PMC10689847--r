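#' Dataset index: a manifest of records on disk
#'
#' Thin wrapper around a data.frame with columns `record_id`, `path`,
#' `donor_id`, `experiment_id`, `condition` and optional `label`. Grouping is
#' by ordinary subsetting on those columns.
#'
#' @param records data.frame with at least the columns above (`label` may be
#'   absent or NA).
#' @return An object of class `dataset_index` (a data.frame).
#' @export
dataset_index <- function(records) {
  need <- c("record_id", "path", "donor_id", "experiment_id", "condition")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$record_id))
    stop("record_ids must be unique")
  if (!"label" %in% names(records)) records$label <- NA_character_
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  class(records) <- c("dataset_index", "data.frame")
  records
}

#' Read / write a dataset manifest CSV
#' @param path CSV path.
#' @return `read_manifest` returns a [dataset_index()]; `write_manifest`
#'   returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  dataset_index(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

#' @rdname read_manifest
#' @param index a [dataset_index()].
#' @export
write_manifest <- function(index, path) {
  utils::write.csv(as.data.frame(index), path, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits labeled records into train and test preserving per-class
#' proportions. Each class contributes floor(train_fraction * n_c) records to
#' the training set; the remainders needed to reach
#' floor(train_fraction * n_total) go to the classes with the largest
#' fractional parts (ties broken by class name). Record assignment within a
#' class is a seeded uniform draw, so reruns with the same seed are identical.
#'
#' @param labels character/factor vector of class labels, one per record.
#' @param train_fraction fraction in (0, 1) of records to train on.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test` (positions in
#'   `labels`), a partition of `seq_along(labels)`.
#' @examples
#' lab <- rep(c("a", "b"), c(5, 5))
#' sp <- stratified_split(lab, 0.6, seed = 1)
#' lengths(sp)  # 6 train, 4 test
#' @export
stratified_split <- function(labels, train_fraction, seed = 1L) {
  if (anyNA(labels)) stop("every record must be labeled")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("class(es) with fewer than 2 records: ", paste(small, collapse = ", "))

  n_total <- length(labels)
  target_total <- floor(train_fraction * n_total)
  base <- floor(train_fraction * as.numeric(counts))
  frac <- train_fraction * as.numeric(counts) - base
  extra <- target_total - sum(base)
  ord <- order(-frac, names(counts))           # largest remainder, then name
  take <- base
  if (extra > 0) take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
  names(take) <- names(counts)

  rng <- make_rng(seed)
  train_idx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    k <- take[[cl]]
    pick <- idx[order(rng$runif(length(idx)))][seq_len(k)]
    train_idx <- c(train_idx, pick)
  }
  train_idx <- sort(train_idx)
  list(train = train_idx, test = setdiff(seq_len(n_total), train_idx))
}

# Private RNG stream: isolates package randomness from the caller's .Random.seed.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    runif = function(n, ...) with_state(function() stats::runif(n, ...)),
    rnorm = function(n, ...) with_state(function() stats::rnorm(n, ...)),
    rpois = function(n, lambda) with_state(function() stats::rpois(n, lambda)),
    rlnorm = function(n, ...) with_state(function() stats::rlnorm(n, ...)),
    sample = function(x, size = length(x), replace = FALSE, prob = NULL)
      with_state(function() sample(x, size, replace, prob)),
    rint = function(n, max) with_state(function() sample.int(max, n, replace = TRUE))
  )
}

#' Derive a stage seed from a global seed
#'
#' Stages of the pipeline draw their own seeds from the global one via a
#' deterministic counter scheme, so each stage is independently reproducible.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 97 + 1) %% 2147483647)
}
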