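# Validation experiments: seeded, self-contained recovery studies that
# exercise the pipeline end to end against planted ground truth. They back
# the selftest, the test suite and the acceptance report, and are exported
# so analyses can rerun them at other settings.

#' Cell-count recovery experiment
#'
#' Generates fields of well-separated cells (with foci, at the default
#' shot-noise level) and segments them; reports the fraction of trials in
#' which the recovered count equals the planted count.
#'
#' @param n_values vector of planted cell counts to test.
#' @param n_trials seeded trials per count.
#' @param foci_per_cell foci planted per cell.
#' @param seed base seed.
#' @return data.frame: n_cells, n_trials, n_correct, recovery_rate.
#' @export
cell_count_experiment <- function(n_values = c(1, 5, 20, 50), n_trials = 20,
                                  foci_per_cell = 2, seed = 1L) {
  cfg <- default_config()
  do.call(rbind, lapply(n_values, function(n) {
    correct <- 0L
    for (t in seq_len(n_trials)) {
      sim <- generate_cell_field(
        n_cells = n, foci_per_cell = foci_per_cell, n_channels = 1,
        seed = derive_seed(seed, paste0("count", n, "_", t)))
      cnt <- count_cells(segment_cells(get_frame(sim$stack, 1, 1), cfg))
      if (cnt == n) correct <- correct + 1L
    }
    data.frame(n_cells = n, n_trials = n_trials, n_correct = correct,
               recovery_rate = correct / n_trials)
  }))
}

#' Focus detection precision/recall experiment
#'
#' Plants resolvable foci of fixed amplitude in cell fields and detects them
#' at default thresholds; a detection within 2 px of a planted centre is a
#' true positive.
#'
#' @param n_fields number of seeded fields.
#' @param focus_amplitude planted peak amplitude, counts (110 is peak
#'   SNR ~ 5 over the default cytoplasm shot noise; 400 is SNR ~ 20).
#' @param n_cells,foci_per_cell field composition.
#' @param seed base seed.
#' @return list: precision, recall (means over fields), per_field data.frame.
#' @export
focus_detection_experiment <- function(n_fields = 20, focus_amplitude = 110,
                                       n_cells = 6, foci_per_cell = 3,
                                       seed = 1L) {
  cfg <- default_config()
  rows <- lapply(seq_len(n_fields), function(i) {
    sim <- generate_cell_field(
      n_cells = n_cells, foci_per_cell = foci_per_cell, n_channels = 1,
      focus_amplitude = focus_amplitude, focus_amplitude_cv = 0,
      seed = derive_seed(seed, paste0("fdet", i)))
    f <- detect_foci(get_frame(sim$stack, 1, 1), cfg)
    tr <- sim$truth$foci
    if (nrow(f) == 0)
      return(data.frame(field = i, recall = 0, precision = NA_real_))
    d <- sqrt(outer(f$centroid_row, tr$row, "-")^2 +
                outer(f$centroid_col, tr$col, "-")^2)
    data.frame(field = i,
               recall = sum(apply(d, 2, min) <= 2) / nrow(tr),
               precision = sum(apply(d, 1, min) <= 2) / nrow(f))
  })
  per_field <- do.call(rbind, rows)
  list(precision = mean(per_field$precision, na.rm = TRUE),
       recall = mean(per_field$recall), per_field = per_field)
}

#' Colocalization matching experiment
#'
#' Builds coordinate instances of true focus pairs (jittered by 0.5 px,
#' placed on a coarse grid so pairs are well separated) plus unpaired decoys
#' in each channel, and checks that greedy matching returns exactly the
#' optimal assignment: every planted pair within `d_max` matched, no
#' decoy matches.
#'
#' @param n_fields instances.
#' @param n_pairs true pairs per instance.
#' @param n_decoys unpaired foci per channel.
#' @param d_max_um,pixel_size_um matching scale.
#' @param jitter_px planted partner jitter sd.
#' @param seed base seed.
#' @return list: fraction_optimal, fraction_all_matched, per_field.
#' @export
coloc_matching_experiment <- function(n_fields = 20, n_pairs = 20,
                                      n_decoys = 5, d_max_um = 0.25,
                                      pixel_size_um = 0.13, jitter_px = 0.5,
                                      seed = 1L) {
  rows <- lapply(seq_len(n_fields), function(i) {
    with_seed(derive_seed(seed, paste0("coloc", i)), {
      # pair bases on a jittered grid, >= 8 px apart
      g <- expand.grid(r = seq(10, 10 + 8 * ceiling(sqrt(n_pairs) - 1), by = 8),
                       c = seq(10, 10 + 8 * ceiling(sqrt(n_pairs) - 1), by = 8))
      g <- g[sample(nrow(g), n_pairs), ]
      base <- as.matrix(g) + matrix(stats::runif(2 * n_pairs, -2, 2), ncol = 2)
      partner <- base + matrix(stats::rnorm(2 * n_pairs, 0, jitter_px), ncol = 2)
      far <- max(base) + 30
      dec_a <- cbind(stats::runif(n_decoys, far, far + 40),
                     stats::runif(n_decoys, far, far + 40))
      dec_b <- cbind(stats::runif(n_decoys, far + 50, far + 90),
                     stats::runif(n_decoys, far + 50, far + 90))
      pa <- rbind(base, dec_a); pb <- rbind(partner, dec_b)
      mm <- match_foci_channels(
        data.frame(centroid_row = pa[, 1], centroid_col = pa[, 2]),
        data.frame(centroid_row = pb[, 1], centroid_col = pb[, 2]),
        d_max_um = d_max_um, pixel_size_um = pixel_size_um)
      # the optimum: pair i <-> i for every pair within d_max, nothing else
      within <- which(sqrt(rowSums((base - partner)^2)) * pixel_size_um <=
                        d_max_um)
      optimal <- nrow(mm) == length(within) &&
        all(sort(mm$a) == within) && all(mm$a == mm$b)
      data.frame(field = i, n_within = length(within),
                 n_matched = nrow(mm), optimal = optimal,
                 all_true_matched = all(within %in% mm$a[mm$a == mm$b]))
    })
  })
  per_field <- do.call(rbind, rows)
  list(fraction_optimal = mean(per_field$optimal),
       fraction_all_matched = mean(per_field$all_true_matched),
       per_field = per_field)
}

#' In vivo stoichiometry recovery experiment
#'
#' Plants colocalized focus pairs with a channel-1 : channel-2 amplitude
#' ratio `rho` across a set of images, runs detection in both channels, and
#' recovers the ratio by the top-k-median procedure.
#'
#' @param rho planted intensity ratio.
#' @param n_images images per condition.
#' @param foci_per_image planted foci per image.
#' @param k foci ranked per image.
#' @param seed base seed.
#' @param snr_amplitude planted channel-1 amplitude, counts.
#' @param n_cells cells per image.
#' @return recovered ratio (channel 1 / channel 2).
#' @export
invivo_ratio_experiment <- function(rho, n_images = 10, foci_per_image = 15,
                                    k = 10, seed = 1L, snr_amplitude = 400,
                                    n_cells = 6) {
  cfg <- default_config()
  rows_a <- list(); rows_b <- list()
  for (i in seq_len(n_images)) {
    sim <- generate_cell_field(
      n_cells = n_cells,
      foci_per_cell = ceiling(foci_per_image / n_cells),
      channel_ratio = rho, coloc_fraction = 1, n_channels = 2,
      focus_amplitude = snr_amplitude, seed = derive_seed(seed, paste0("img", i)))
    fa <- detect_foci(get_frame(sim$stack, 1, 1), cfg)
    fb <- detect_foci(get_frame(sim$stack, 2, 1), cfg)
    if (nrow(fa)) { fa$timepoint <- 1; fa$image <- i; rows_a[[i]] <- fa }
    if (nrow(fb)) { fb$timepoint <- 1; fb$image <- i; rows_b[[i]] <- fb }
  }
  tc <- ratio_timecourse(do.call(rbind, rows_a), do.call(rbind, rows_b),
                         k = k, use_all = TRUE)
  tc$ratio[1]
}

#' Calibration round-trip experiment
#'
#' Fits a calibration curve on a generated homogeneous-solution series,
#' simulates droplets at a known concentration on the same intensity scale,
#' measures them, and inverts the curve.
#'
#' @param conc planted droplet concentration, uM.
#' @param slope,intercept planted calibration line.
#' @param seed base seed.
#' @return mean recovered concentration over droplets, uM.
#' @export
calibration_roundtrip <- function(conc = 2, slope = 100, intercept = 50,
                                  seed = 1L) {
  cal <- generate_calibration_series(c(0, 1, 2, 4, 8), slope, intercept,
                                     noise = noise_spec(0, 1, FALSE),
                                     seed = derive_seed(seed, "series"))
  fit <- fit_calibration(
    vapply(cal, `[[`, numeric(1), "concentration"),
    vapply(cal, function(x) mean(get_frame(x$stack, 1, 1)), numeric(1)))
  sim <- generate_droplet_image(n_droplets = 10, concentration_uM = list(conc),
                                slope = slope, intercept = intercept,
                                noise = noise_spec(0, 1, FALSE),
                                seed = derive_seed(seed, "field"))
  seg <- segment_droplets(sim$stack)
  mean(droplet_concentration(seg$records$mean_intensity_mCherry, fit,
                             background_subtracted = TRUE)$concentration_uM)
}

#' In vitro stoichiometry recovery experiment
#'
#' Plants droplets whose two-channel concentrations stand in ratio `rho`,
#' images them through the linear intensity model with additive noise at a
#' given fraction of the channel-1 droplet signal, segments, converts to
#' concentrations via the known calibration lines, and reports the mean
#' per-droplet ratio.
#'
#' @param rho planted per-droplet concentration ratio.
#' @param n_droplets droplets per field.
#' @param conc_b channel-2 concentration, uM.
#' @param noise_frac noise sd as a fraction of the channel-1 droplet signal.
#' @param seed seed.
#' @param slope,intercept per-channel calibration lines.
#' @return recovered mean ratio.
#' @export
invitro_ratio_experiment <- function(rho, n_droplets = 50, conc_b = 2,
                                     noise_frac = 0.05, seed = 1L,
                                     slope = c(100, 120), intercept = c(50, 40)) {
  read_sd <- noise_frac * slope[1] * conc_b * rho
  sim <- generate_droplet_image(
    n_droplets = n_droplets,
    concentration_uM = list(conc_b * rho, conc_b),
    slope = slope, intercept = intercept,
    noise = noise_spec(0, read_sd, FALSE),
    field_size = c(384, 384), seed = seed)
  seg <- segment_droplets(sim$stack)
  curve_a <- structure(list(slope = slope[1], intercept = intercept[1],
                            r_squared = 1, n_points = 2,
                            concentration_range = c(0, 20)),
                       class = "calibration_curve")
  curve_b <- structure(list(slope = slope[2], intercept = intercept[2],
                            r_squared = 1, n_points = 2,
                            concentration_range = c(0, 20)),
                       class = "calibration_curve")
  droplet_stoichiometry(seg$records, curve_a, curve_b,
                        "mCherry", "GFP")$mean_ratio
}

#' Condensation-metric doubling experiment
#'
#' Builds a reference condition and a condition with twice as many planted
#' droplets (fixed radius and concentration, two replicates each) and
#' reports the normalized metric of the doubled condition (expected: 2).
#'
#' @param n_ref droplets in the reference condition.
#' @param seed base seed.
#' @return normalized metric of the doubled condition.
#' @export
metric_doubling_experiment <- function(n_ref = 10, seed = 1L) {
  mk <- function(n, s) generate_droplet_image(
    n_droplets = n, radius_px_range = c(6, 6), concentration_uM = list(2),
    slope = 100, intercept = 50, field_size = c(420, 420),
    seed = derive_seed(seed, paste0("fld", s)))$stack
  conds <- list(ref = list(mk(n_ref, 1), mk(n_ref, 2)),
                dbl = list(mk(2 * n_ref, 3), mk(2 * n_ref, 4)))
  res <- run_droplet_quantification(conds, reference = "ref")
  res$metrics$normalized_metric[res$metrics$condition == "dbl"]
}
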