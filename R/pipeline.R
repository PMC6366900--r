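#' Quantify processing bodies across a set of image stacks
#'
#' Full in vivo pipeline for each image and timepoint: segment cells on the
#' first channel, detect foci in every channel, match foci across the first
#' two channels (colocalization), and report per-image counts plus
#' `PBs_per_cell` -- the colocalized focus count (or the single-channel focus
#' count for one-channel data) divided by the cell count. Per-timepoint
#' aggregates (mean +/- SEM across images) are computed over non-excluded
#' images; images with zero segmented cells are excluded and listed with a
#' reason.
#'
#' @param stacks list of `image_stack` objects (one per field of view).
#' @param config an `analysis_config`.
#' @return list of data.frames: `per_image` (image, timepoint, n_cells,
#'   per-channel focus counts, n_colocalized, PBs_per_cell), `per_timepoint`
#'   (mean, sem, n_images), `excluded` (image, timepoint, reason), and
#'   `foci` (all retained foci with image/timepoint/channel annotations).
#' @export
run_pb_quantification <- function(stacks, config = default_config()) {
  if (length(stacks) == 0) stop("empty dataset")
  validate_config(config)
  per_image <- list(); excluded <- list(); all_foci <- list()
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    cfg <- config; cfg$pixel_size_um <- st$pixel_size_um
    for (tp in seq_len(n_timepoints(st))) {
      seg_img <- get_frame(st, 1, tp)
      label_map <- segment_cells(seg_img, cfg)
      ncell <- count_cells(label_map)
      foci_ch <- lapply(seq_len(n_channels(st)), function(ch) {
        f <- detect_foci(get_frame(st, ch, tp), cfg)
        f <- assign_foci_to_cells(f, label_map)
        if (nrow(f)) { f$image <- i; f$timepoint <- tp; f$channel <- ch }
        f
      })
      n_foci <- vapply(foci_ch, nrow, integer(1))
      n_match <- if (n_channels(st) >= 2)
        nrow(match_foci_channels(foci_ch[[1]], foci_ch[[2]],
                                 cfg$coloc$d_max_um, st$pixel_size_um))
      else n_foci[1]
      if (ncell == 0) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          image = i, timepoint = tp, reason = "n_cells = 0")
        next
      }
      row <- data.frame(image = i, timepoint = tp, n_cells = ncell)
      for (ch in seq_len(n_channels(st)))
        row[[paste0("n_foci_", st$channel_names[ch])]] <- n_foci[ch]
      row$n_colocalized <- n_match
      row$PBs_per_cell <- foci_per_cell(n_match, ncell)
      per_image[[length(per_image) + 1L]] <- row
      all_foci <- c(all_foci, foci_ch[n_foci > 0])
    }
  }
  per_image <- if (length(per_image)) do.call(rbind, per_image) else
    stop("all images excluded (no cells segmented)")
  per_tp <- do.call(rbind, lapply(split(per_image, per_image$timepoint),
    function(d) data.frame(
      timepoint = d$timepoint[1], n_images = nrow(d),
      mean_PBs_per_cell = mean(d$PBs_per_cell),
      sem_PBs_per_cell = if (nrow(d) > 1)
        stats::sd(d$PBs_per_cell) / sqrt(nrow(d)) else NA_real_)))
  rownames(per_tp) <- NULL
  list(per_image = per_image, per_timepoint = per_tp,
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(image = integer(0), timepoint = integer(0),
                    reason = character(0)),
       foci = if (length(all_foci)) do.call(rbind, all_foci) else NULL)
}

#' Quantify droplet fields across conditions
#'
#' For each condition (a list of droplet `image_stack`s, i.e. replicates):
#' segment droplets, compute the area-times-intensity metric per channel and
#' replicate, and normalize each channel by the named reference condition's
#' mean metric. When calibration curves are supplied, per-droplet
#' concentrations and the two-channel stoichiometric ratio are reported.
#'
#' @param conditions named list; each element a list of `image_stack`s.
#' @param config an `analysis_config`.
#' @param reference named character vector `channel -> condition` giving the
#'   normalization reference per channel, or a single condition name for all
#'   channels; `NULL` skips normalization.
#' @param curves named list of `calibration_curve` per channel; optional.
#' @param ratio_channels length-2 character vector (numerator, denominator)
#'   for the stoichiometric ratio; requires both curves.
#' @return list: `droplets` (per-droplet table with condition/replicate),
#'   `metrics` (condition x channel raw and normalized metric, mean +/- sd
#'   over replicates), `stoichiometry` (ratio summary or NULL).
#' @export
run_droplet_quantification <- function(conditions, config = default_config("confocal"),
                                       reference = NULL, curves = NULL,
                                       ratio_channels = NULL) {
  stopifnot(length(conditions) > 0, !is.null(names(conditions)))
  validate_config(config)
  d <- config$droplet
  droplets <- list(); metrics <- list()
  channels <- NULL
  for (cond in names(conditions)) {
    reps <- conditions[[cond]]
    for (r in seq_along(reps)) {
      seg <- segment_droplets(reps[[r]], channel = 1L,
                              threshold_method = d$threshold_method,
                              min_droplet_area_px = d$min_droplet_area_px)
      rec <- seg$records
      channels <- reps[[r]]$channel_names
      if (nrow(rec)) { rec$condition <- cond; rec$replicate <- r }
      droplets[[length(droplets) + 1L]] <- rec
      for (ch in channels)
        metrics[[length(metrics) + 1L]] <- data.frame(
          condition = cond, replicate = r, channel = ch,
          metric = droplet_metric(seg$records, ch))
    }
  }
  droplets <- do.call(rbind, droplets[vapply(droplets, nrow, integer(1)) > 0])
  metrics <- do.call(rbind, metrics)
  summ <- do.call(rbind, lapply(split(metrics, metrics[c("condition", "channel")], drop = TRUE),
    function(x) data.frame(condition = x$condition[1], channel = x$channel[1],
                           mean_metric = mean(x$metric),
                           sd_metric = if (nrow(x) > 1) stats::sd(x$metric) else 0,
                           n_replicates = nrow(x))))
  rownames(summ) <- NULL
  if (!is.null(reference)) {
    if (is.null(names(reference)))
      reference <- stats::setNames(rep(reference, length(unique(summ$channel))),
                                   unique(summ$channel))
    summ$normalized_metric <- NA_real_
    for (ch in unique(summ$channel)) {
      refcond <- reference[[ch]]
      if (is.null(refcond) || !refcond %in% summ$condition)
        stop("reference condition `", refcond, "` absent for channel ", ch)
      refval <- summ$mean_metric[summ$condition == refcond & summ$channel == ch]
      sel <- summ$channel == ch
      summ$normalized_metric[sel] <- normalize_metric(summ$mean_metric[sel], refval)
    }
  }
  stoich <- NULL
  if (!is.null(ratio_channels)) {
    stopifnot(length(ratio_channels) == 2, !is.null(curves))
    ca <- curves[[ratio_channels[1]]]; cb <- curves[[ratio_channels[2]]]
    if (is.null(ca) || is.null(cb)) stop("calibration curves required for both ratio channels")
    stoich <- droplet_stoichiometry(droplets, ca, cb,
                                    ratio_channels[1], ratio_channels[2])
    for (ch in ratio_channels) {
      cc <- droplet_concentration(droplets[[paste0("mean_intensity_", ch)]],
                                  curves[[ch]], background_subtracted = TRUE)
      droplets[[paste0("concentration_uM_", ch)]] <- cc$concentration_uM
    }
  }
  list(droplets = droplets, metrics = summ, stoichiometry = stoich)
}

#' End-to-end self test
#'
#' Generates small synthetic fixtures, runs every pipeline stage, and checks
#' the core recovery properties: cell-count recovery, focus
#' precision/recall, colocalization matching, in vivo ratio recovery,
#' calibration round trip, in vitro ratio recovery, and determinism.
#' Failures are reported, not raised.
#'
#' @param seed integer seed; the whole report is deterministic given it.
#' @return data.frame with columns property, value, pass.
#' @export
run_end_to_end_selftest <- function(seed = 1L) {
  res <- list()
  add <- function(property, value, pass)
    res[[length(res) + 1L]] <<- data.frame(property = property,
                                           value = value, pass = pass)
  cfg <- default_config()

  sim <- generate_cell_field(n_cells = 8, foci_per_cell = 2, n_channels = 2,
                             seed = derive_seed(seed, "cells"))
  lm1 <- segment_cells(get_frame(sim$stack, 1, 1), cfg)
  add("cell_count_recovery", count_cells(lm1),
      count_cells(lm1) == nrow(sim$truth$cells))

  f1 <- detect_foci(get_frame(sim$stack, 1, 1), cfg)
  tr <- sim$truth$foci[sim$truth$foci$channel == 1, ]
  pr <- match_foci_channels(f1, data.frame(centroid_row = tr$row,
                                           centroid_col = tr$col),
                            d_max_um = 0.26, sim$stack$pixel_size_um)
  recall <- nrow(pr) / nrow(tr)
  precision <- nrow(pr) / max(nrow(f1), 1)
  add("focus_recall", recall, recall >= 0.95)
  add("focus_precision", precision, precision >= 0.95)

  f2 <- detect_foci(get_frame(sim$stack, 2, 1), cfg)
  mm <- match_foci_channels(f1, f2, cfg$coloc$d_max_um, sim$stack$pixel_size_um)
  add("coloc_matches", nrow(mm), nrow(mm) >= 0.9 * nrow(tr))

  rho <- invivo_ratio_experiment(rho = 2, n_images = 4, foci_per_image = 12,
                                 seed = derive_seed(seed, "invivo"))
  add("invivo_ratio_rho2", rho, abs(rho - 2) / 2 <= 0.1)

  cal <- calibration_roundtrip(seed = derive_seed(seed, "cal"))
  add("calibration_roundtrip_uM", cal, abs(cal - 2) / 2 <= 0.05)

  iv <- invitro_ratio_experiment(rho = 2.7, n_droplets = 25, noise_frac = 0.05,
                                 seed = derive_seed(seed, "invitro"))
  add("invitro_ratio_rho2.7", iv, abs(iv - 2.7) / 2.7 <= 0.1)

  sim2 <- generate_cell_field(n_cells = 8, foci_per_cell = 2, n_channels = 2,
                              seed = derive_seed(seed, "cells"))
  add("determinism", 1,
      identical(sim$stack$frames, sim2$stack$frames))
  do.call(rbind, res)
}
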