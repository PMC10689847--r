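#' Assemble a run configuration
#'
#' Validates the nested stage blocks of a pipeline run. Every stage consumes
#' only its own block plus the global seed (stage seeds are derived with
#' [derive_seed()]). Unknown keys raise an error naming the key, so typos
#' never silently disable a stage.
#'
#' @param config named list; recognized blocks: `seed`, `manifest`,
#'   `out_dir`, `cohort` (arguments to [cohort_spec()]), `inventory`
#'   (`preset` = "fluor"/"full", `channels`), `selection` (arguments to
#'   [selection_config()]), `model` (arguments to [model_spec()]),
#'   `split` (`train_fraction`), `cleaning` (arguments to [clean_params()],
#'   plus `top_features`), `profiling` (`antibody`, `control`, `alpha`,
#'   `min_donors`), `functional` (`y_table` or `use_truth`), `workers`.
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  known <- c("seed", "manifest", "out_dir", "cohort", "inventory",
             "selection", "model", "split", "cleaning", "profiling",
             "functional", "workers")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$workers <- as.integer(config$workers %||% 1L)
  structure(config, class = c("run_config", "list"))
}

#' Read a run configuration from a YAML file
#' @param path YAML file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load) the cohort; extract features; split
#' the labeled records and train/evaluate the classifier; predict all
#' records with entropies; clean per donor x condition; class-frequency and
#' feature-difference profiling between the configured antibody and control
#' conditions; percentile aggregation and functional regression. Every
#' artifact is stamped with the config fingerprint and the seed; a rerun
#' with the same config and seed is identical.
#'
#' @param config a [run_config()] (or plain list passed through it).
#' @return Named list of artifacts: `index`, `features`, `eval`, `model`,
#'   `predictions`, `cleaning`, `frequencies`, `frequency_tests`,
#'   `difference_map`, `consistent_features`, `functional`, `stamp`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(unclass(config))
  seed <- config$seed
  art <- list()

  if (!is.null(config$manifest)) {
    index <- read_manifest(config$manifest)
    records <- lapply(index$path, read_record)
    truth <- NULL
  } else {
    if (is.null(config$cohort)) stop("config needs either manifest or cohort")
    cargs <- config$cohort
    cargs$seed <- derive_seed(seed, "simulate")
    cohort <- do.call(cohort_spec, cargs)
    sim <- generate_cohort(cohort)
    index <- sim$index; records <- sim$records; truth <- sim$truth
  }
  art$index <- index

  invcfg <- config$inventory %||% list(preset = "fluor")
  channels <- invcfg$channels %||% fluorescent_channels()
  inv <- if (identical(invcfg$preset, "full")) inventory_full()
         else inventory_fluor_relevant(channels)
  # cleaning always needs the viability / BF QC / MHCII-CD3 rule features
  rule_inv <- inventory_full()
  rule_cols <- c("LiveDead_mean", "BF_grms", "MHCII_mean", "MHCII_area",
                 "CD3_mean")
  rule_inv <- rule_inv[rule_inv$name %in% setdiff(rule_cols, inv$name), ,
                       drop = FALSE]
  features <- extract_features(records, inv, workers = config$workers)
  if (nrow(rule_inv)) {
    extra <- extract_features(records, rule_inv, workers = config$workers)
    features <- cbind(features, extra[rownames(features), , drop = FALSE])
  }
  art$features <- features

  labeled <- which(!is.na(index$label) & index$label != "")
  y <- index$label[labeled]
  Xl <- impute_median(features[labeled, , drop = FALSE])
  sp <- do.call(model_spec, config$model %||% list())
  sp$seed <- derive_seed(seed, "train")
  split <- stratified_split(y, (config$split$train_fraction) %||% 0.7,
                            derive_seed(seed, "split"))
  selection <- if (!is.null(config$selection))
    do.call(selection_config, config$selection) else NULL
  model <- fit_model(sp, Xl[split$train, , drop = FALSE], y[split$train])
  art$model <- model
  art$eval <- list(
    holdout_f1 = f1_macro(y[split$test],
                          predict_class(model, Xl[split$test, , drop = FALSE])),
    split = lengths(split))

  Xall <- impute_median(features)
  pe <- predict_with_entropy(model, Xall)
  art$predictions <- data.frame(record_id = rownames(features),
                                pred_class = pe$class, entropy = pe$entropy,
                                stringsAsFactors = FALSE)

  ccfg <- config$cleaning %||% list()
  top_feats <- ccfg$top_features %||% {
    g <- sort(gain_importance(model), decreasing = TRUE)
    names(g)[seq_len(min(30L, length(g)))]
  }
  ccfg$top_features <- NULL
  cparams <- do.call(clean_params, ccfg)
  cleaned <- clean_cohort(Xall, index[, c("donor_id", "condition")],
                          pe$class, pe$entropy, top_feats, cparams,
                          seed = derive_seed(seed, "clean"))
  art$cleaning <- cleaned
  keep <- rownames(features) %in% cleaned$retained

  pcfg <- config$profiling
  freqs <- class_frequencies(pe$class[keep],
                             index[keep, c("donor_id", "condition")])
  art$frequencies <- freqs
  if (!is.null(pcfg)) {
    art$frequency_tests <- frequency_test(freqs, pcfg$antibody, pcfg$control,
                                          alpha = pcfg$alpha %||% 0.05)
    sel <- keep & pe$class == "synapse w/ signaling" &
      index$condition %in% c(pcfg$antibody, pcfg$control)
    # only donors with retained synapse records in both arms can be compared
    arms <- table(index$donor_id[sel], index$condition[sel])
    ok_donors <- rownames(arms)[apply(arms > 0, 1, all)]
    dropped <- setdiff(unique(index$donor_id), ok_donors)
    if (length(dropped))
      warning("donor(s) without retained synapses in both arms dropped ",
              "from the feature-difference map: ",
              paste(dropped, collapse = ", "))
    sel <- sel & index$donor_id %in% ok_donors
    fluor_cols <- inv$name[inv$name %in% colnames(features)]
    dmap <- feature_difference(Xall[sel, fluor_cols, drop = FALSE],
                               index[sel, c("donor_id", "condition")],
                               pcfg$antibody, pcfg$control,
                               alpha = pcfg$alpha %||% 0.05)
    art$difference_map <- dmap
    art$consistent_features <-
      consistency_summary(dmap, pcfg$min_donors %||% 4L)
  }

  fcfg <- config$functional
  if (!is.null(fcfg)) {
    syn <- keep & select_synapse_population(pe$class)
    consist <- if (!is.null(art$consistent_features) &&
                   nrow(art$consistent_features) > 0)
      art$consistent_features$feature else colnames(features)
    agg <- aggregate_percentiles(Xall[syn, consist, drop = FALSE],
                                 index[syn, c("donor_id", "condition")])
    yfun <- if (!is.null(fcfg$y_table)) {
      yt <- fcfg$y_table
      yt$y[match(paste(agg$groups$donor_id, agg$groups$condition),
                 paste(yt$donor_id, yt$condition))]
    } else if (!is.null(truth$functional)) {
      tf <- truth$functional
      tf$y[match(paste(agg$groups$donor_id, agg$groups$condition),
                 paste(tf$donor_id, tf$condition))]
    } else NULL
    if (!is.null(yfun) && sum(!is.na(yfun)) >= 6) {
      ok <- !is.na(yfun)
      art$functional <- fit_predict_lodo(agg$profile[ok, , drop = FALSE],
                                         yfun[ok],
                                         agg$groups[ok, , drop = FALSE])
    }
  }

  art$stamp <- list(seed = seed,
                    config_hash = inventory_hash(
                      data.frame(name = utils::capture.output(utils::str(config)))),
                    inventory_hash = attr(features, "inventory_hash"))
  if (!is.null(config$out_dir)) write_artifacts(art, config$out_dir)
  art
}

# Serialize the tabular/JSON artifacts of a run.
write_artifacts <- function(art, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(art$features, file.path(dir, "features.csv"))
  utils::write.csv(art$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(art$frequencies, file.path(dir, "frequencies.csv"),
                   row.names = FALSE)
  if (!is.null(art$difference_map))
    utils::write.csv(art$difference_map$map,
                     file.path(dir, "difference_map.csv"))
  jsonlite::write_json(
    list(eval = art$eval,
         cleaning = lapply(art$cleaning$reports, function(r)
           list(n_input = r$n_input, n_retained = r$n_retained)),
         stamp = art$stamp),
    file.path(dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
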