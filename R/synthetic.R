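#' Scene specification for one synthetic conjugate image
#'
#' Describes how to render a single record of a given taxonomy class:
#' disk geometry of the cells, per-channel mean intensity levels (counts),
#' additive Gaussian noise sd on top of Poisson shot noise, the synaptic
#' enrichment factor `rho` (ratio of contact-zone to cell-body mean intensity
#' applied to F-actin, MHCII and P-CD3zeta), the viability-channel level, and
#' an optional defocus blur sd.
#'
#' @param class one of the nine taxonomy class names.
#' @param size image side length in pixels.
#' @param t_radius,b_radius,small_b_radius disk radii in pixels.
#' @param levels named per-channel mean intensity counts.
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param rho synaptic enrichment factor (>= 0; 1 = no enrichment).
#' @param viability_level mean of the Live/Dead channel on the cells.
#' @param blur_sd Gaussian defocus blur sd in pixels (0 = in focus).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(class,
                       size = 64L,
                       t_radius = 8, b_radius = 10, small_b_radius = 3,
                       levels = c(BF = 3000, Factin = 2500, MHCII = 3000,
                                  CD3 = 3000, PCD3z = 1500, LiveDead = 200),
                       noise_sd = 50,
                       rho = 2.5,
                       viability_level = NULL,
                       blur_sd = 0) {
  if (!class %in% class_taxonomy()$classes) stop("unknown class name: ", class)
  stopifnot(t_radius > 0, b_radius > 0, small_b_radius > 0,
            all(levels >= 0), rho >= 0, noise_sd >= 0, blur_sd >= 0)
  if (!is.null(viability_level)) levels[["LiveDead"]] <- viability_level
  structure(list(class = class, size = as.integer(size),
                 t_radius = t_radius, b_radius = b_radius,
                 small_b_radius = small_b_radius, levels = levels,
                 noise_sd = noise_sd, rho = rho, blur_sd = blur_sd),
            class = "scene_spec")
}

# Disk rasterization: pixels whose centers lie within radius of (cy, cx).
raster_disk <- function(size, cy, cx, r) {
  y <- matrix(seq_len(size) - 1, size, size)
  x <- t(y)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

# Cell layout per class: list of cells (type "T"/"B", center, radius).
scene_layout <- function(spec) {
  s <- spec$size; c0 <- (s - 1) / 2
  rt <- spec$t_radius; rb <- spec$b_radius
  touch <- rt + rb - 2            # centers at touching distance (2 px overlap)
  switch(spec$class,
    "single B-LCL" = list(list("B", c0, c0, rb)),
    "single T cell w/o signaling" = list(list("T", c0, c0, rt)),
    "single T cell w/ signaling"  = list(list("T", c0, c0, rt)),
    "T cell w/ small B-LCL" = list(
      list("T", c0, c0 - 3, rt),
      list("B", c0, c0 - 3 + rt + spec$small_b_radius - 1, spec$small_b_radius)),
    "B-LCL and T cell in one layer" = list(
      list("B", c0, c0 - 2, rb),
      list("T", c0, c0 + 2, rt)),
    "synapse w/o signaling" = list(
      list("B", c0, c0 - touch / 2, rb),
      list("T", c0, c0 + touch / 2, rt)),
    "synapse w/ signaling" = list(
      list("B", c0, c0 - touch / 2, rb),
      list("T", c0, c0 + touch / 2, rt)),
    "no cell-cell interaction" = list(
      list("B", c0, c0 - (rt + rb + 12) / 2, rb),
      list("T", c0, c0 + (rt + rb + 12) / 2, rt)),
    "multi-synapse" = list(
      list("B", c0, c0, rb),
      list("T", c0, c0 - touch, rt),
      list("T", c0, c0 + touch, rt)),
    stop("unknown class name: ", spec$class)
  )
}

#' Render one synthetic cell record
#'
#' Draws the class-specific cell layout, paints per-channel intensities,
#' applies the synaptic enrichment `rho` to F-actin, MHCII and P-CD3zeta in
#' the contact zone, optional Gaussian defocus blur, then Poisson shot noise
#' plus additive Gaussian noise. Masks are the noiseless intensity supports.
#'
#' @param spec a [scene_spec()].
#' @param rng an RNG stream from `make_rng()`, or an integer seed.
#' @param record_id,meta identity and metadata for the record.
#' @param level_scale optional named multiplicative factors on channel levels
#'   (donor or condition effects).
#' @return A [cell_record()] with `label` = the scene class.
#' @export
render_record <- function(spec, rng = 1L, record_id = "synthetic",
                          meta = list(donor_id = "d1", experiment_id = "e1",
                                      condition = "ctrl"),
                          level_scale = NULL) {
  if (is.numeric(rng)) rng <- make_rng(as.integer(rng))
  s <- spec$size
  panel <- default_panel()
  lev <- spec$levels
  if (!is.null(level_scale)) {
    for (ch in names(level_scale)) lev[[ch]] <- lev[[ch]] * level_scale[[ch]]
  }
  cells <- scene_layout(spec)
  t_mask <- matrix(FALSE, s, s); b_mask <- matrix(FALSE, s, s)
  for (cl in cells) {
    d <- raster_disk(s, cl[[2]], cl[[3]], cl[[4]])
    if (cl[[1]] == "T") t_mask <- t_mask | d else b_mask <- b_mask | d
  }
  all_mask <- t_mask | b_mask
  signaling <- spec$class %in% c("single T cell w/ signaling",
                                 "synapse w/ signaling", "multi-synapse")
  contact <- if (any(t_mask) && any(b_mask))
    dilate_mask(t_mask, 3L) & dilate_mask(b_mask, 3L) else matrix(FALSE, s, s)

  base <- list(
    BF = 0.25 * lev[["BF"]] + lev[["BF"]] * all_mask,   # dim background light
    Factin = lev[["Factin"]] * all_mask,
    MHCII = lev[["MHCII"]] * b_mask,
    CD3 = lev[["CD3"]] * t_mask,
    PCD3z = if (signaling) lev[["PCD3z"]] * t_mask else 0 * t_mask,
    LiveDead = lev[["LiveDead"]] * all_mask
  )
  if (spec$rho != 1 && any(contact)) {
    # signal accumulates at the cell-cell interface: the contact zone is
    # painted at rho x the channel's cell-body level
    enrich_ch <- c("Factin", "MHCII", if (signaling) "PCD3z")
    for (ch in enrich_ch) {
      img <- base[[ch]]
      img[contact] <- spec$rho * lev[[ch]]
      base[[ch]] <- img
    }
  }
  img <- array(0, c(s, s, length(panel)))
  msk <- array(FALSE, c(s, s, length(panel)))
  mask_of <- list(BF = all_mask, Factin = all_mask, MHCII = b_mask,
                  CD3 = t_mask,
                  PCD3z = if (signaling) t_mask else matrix(FALSE, s, s),
                  LiveDead = all_mask)
  for (i in seq_along(panel)) {
    ch <- panel[i]
    sig <- base[[ch]]
    if (spec$blur_sd > 0)
      sig <- as.matrix(EBImage::gblur(EBImage::Image(sig), spec$blur_sd))
    shot <- matrix(rng$rpois(length(sig), pmax(sig, 0)), s, s)
    noisy <- shot + matrix(rng$rnorm(length(sig), 0, spec$noise_sd), s, s)
    img[, , i] <- pmin(pmax(round(noisy), 0), 65535)
    msk[, , i] <- mask_of[[ch]]
  }
  cell_record(record_id, panel, img, msk,
              c(meta, list(label = spec$class)))
}

#' Cohort specification for the synthetic generator
#'
#' Defines the study conditions a synthetic cohort emulates: donors with a
#' shared multiplicative log-normal intensity effect, conditions each with a
#' class-frequency simplex and optional per-channel intensity scaling /
#' enrichment shift (the planted feature effects), the number of records per
#' donor x condition, an optional fraction of dead cells, and an optional
#' linear functional model over percentile-aggregated synapse features.
#'
#' @param donors character vector of donor ids.
#' @param conditions named list; each element a list with `freq` (named
#'   9-class simplex), and optional `level_scale` (named channel factors),
#'   `rho_delta` (added to the enrichment factor), `dead_fraction`.
#' @param n_per_group records per donor x condition.
#' @param donor_sd sd of the log-normal donor intensity factor.
#' @param functional optional list with `coef` (named vector over aggregated
#'   columns, names like `"PCD3z_enrich_mean|p50"`), `intercept`, `noise_sd`.
#' @param seed integer seed.
#' @param scene_args extra arguments passed to every [scene_spec()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(donors, conditions, n_per_group = 100L,
                        donor_sd = 0.1, functional = NULL, seed = 1L,
                        scene_args = list()) {
  if (!length(donors)) stop("empty donor list")
  if (!length(conditions)) stop("empty condition list")
  tax <- class_taxonomy()
  for (cn in names(conditions)) {
    f <- conditions[[cn]]$freq
    if (is.null(f)) stop("condition '", cn, "' lacks a class frequency simplex")
    f <- unlist(f)                      # tolerate YAML-style lists
    conditions[[cn]]$freq <- f
    if (!all(names(f) %in% tax$classes)) stop("unknown class in freq of ", cn)
    if (abs(sum(f) - 1) > 1e-9) stop("freq of '", cn, "' must sum to 1")
  }
  if (n_per_group < 1) stop("records per group must be >= 1")
  structure(list(donors = donors, conditions = conditions,
                 n_per_group = as.integer(n_per_group), donor_sd = donor_sd,
                 functional = functional, seed = as.integer(seed),
                 scene_args = scene_args),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_group` records per donor x condition, class sampled from the
#' condition's frequency simplex, with donor intensity effects and the
#' condition's planted feature shifts applied at render time. Fully
#' reproducible from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @return List with `records` (list of [cell_record()]), `index` (data.frame
#'   manifest with empty paths), and `truth`: `labels` (per record),
#'   `frequencies` (planted per-condition simplex), `donor_factors`, and, if
#'   a functional model was specified, `functional` (per donor x condition
#'   observed readout y plus the aggregated design columns used).
#' @export
generate_cohort <- function(spec) {
  rng <- make_rng(spec$seed)
  tax <- class_taxonomy()
  donor_factor <- stats::setNames(rng$rlnorm(length(spec$donors), 0, spec$donor_sd),
                                  spec$donors)
  experiments <- stats::setNames(
    paste0("e", (seq_along(spec$donors) - 1) %% 2 + 1), spec$donors)
  records <- list(); rows <- list()
  k <- 0L
  for (d in spec$donors) {
    for (cn in names(spec$conditions)) {
      cond <- spec$conditions[[cn]]
      freq <- stats::setNames(rep(0, 9), tax$classes)
      freq[names(cond$freq)] <- cond$freq
      classes <- rng$sample(tax$classes, spec$n_per_group, replace = TRUE,
                            prob = freq)
      n_dead <- round((cond$dead_fraction %||% 0) * spec$n_per_group)
      for (i in seq_along(classes)) {
        k <- k + 1L
        sargs <- spec$scene_args
        sargs$class <- classes[i]
        if (!is.null(cond$rho_delta))
          sargs$rho <- (sargs$rho %||% 2.5) + cond$rho_delta
        if (i <= n_dead) sargs$viability_level <- 4000
        sc <- do.call(scene_spec, sargs)
        scale <- stats::setNames(rep(donor_factor[[d]], 5),
                                 c("BF", "Factin", "MHCII", "CD3", "PCD3z"))
        if (!is.null(cond$level_scale)) {
          for (ch in names(cond$level_scale))
            scale[[ch]] <- scale[[ch]] * cond$level_scale[[ch]]
        }
        id <- sprintf("%s_%s_%05d", d, cn, i)
        records[[k]] <- render_record(
          sc, rng, record_id = id,
          meta = list(donor_id = d, experiment_id = experiments[[d]],
                      condition = cn),
          level_scale = scale)
        rows[[k]] <- data.frame(record_id = id, path = NA_character_,
                                donor_id = d, experiment_id = experiments[[d]],
                                condition = cn, label = classes[i],
                                stringsAsFactors = FALSE)
      }
    }
  }
  index <- do.call(rbind, rows)
  truth <- list(
    labels = stats::setNames(index$label, index$record_id),
    frequencies = lapply(spec$conditions, function(cc) cc$freq),
    donor_factors = donor_factor
  )
  out <- list(records = records, index = index, truth = truth)
  if (!is.null(spec$functional)) {
    out$truth$functional <- cohort_functional_truth(out, spec, rng)
  }
  out
}

# Planted linear functional readout: y = intercept + beta . aggregated
# percentile features of the synapse-class records, + Gaussian noise.
cohort_functional_truth <- function(cohort, spec, rng) {
  fun <- spec$functional
  cols <- names(fun$coef)
  feats <- unique(sub("\\|p[0-9]+$", "", cols))
  inv <- inventory_full()
  inv <- inv[inv$name %in% feats, , drop = FALSE]
  if (nrow(inv) == 0) stop("functional model names unknown features")
  syn_classes <- c("synapse w/o signaling", "synapse w/ signaling")
  sel <- cohort$index$label %in% syn_classes
  tab <- extract_features(cohort$records[sel], inv)
  groups <- cohort$index[sel, c("donor_id", "condition")]
  prof <- aggregate_percentiles(tab, groups, percentiles = c(5, 50, 95))
  X <- prof$profile
  miss <- setdiff(cols, colnames(X))
  if (length(miss)) stop("functional columns not available: ",
                         paste(miss, collapse = ", "))
  y <- (fun$intercept %||% 0) +
    as.matrix(X[, cols, drop = FALSE]) %*% fun$coef +
    rng$rnorm(nrow(X), 0, fun$noise_sd %||% 0)
  data.frame(prof$groups, y = as.numeric(y), X, check.names = FALSE)
}

#' Write a generated cohort to disk
#'
#' One HDF5 file per record plus a CSV manifest and ground-truth CSVs.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "records"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$records))
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    paths[i] <- file.path(dir, "records", paste0(r$record_id, ".h5"))
    write_record(r, paths[i])
  }
  cohort$index$path <- paths
  write_manifest(dataset_index(cohort$index), file.path(dir, "manifest.csv"))
  utils::write.csv(data.frame(record_id = names(cohort$truth$labels),
                              label = cohort$truth$labels),
                   file.path(dir, "truth_labels.csv"), row.names = FALSE)
  if (!is.null(cohort$truth$functional))
    utils::write.csv(cohort$truth$functional,
                     file.path(dir, "truth_functional.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
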