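# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a small union-find pass.
label_components_8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment phase-separated droplets
#'
#' Thresholds one channel (Otsu by default), labels 8-connected foreground
#' components, removes components below the minimum area, and measures every
#' droplet on all channels of the field. The per-channel background is the
#' median of non-foreground pixels and is subtracted from the droplet mean
#' intensities, so the measurements sit on the same background-free scale as
#' `slope * concentration` in the calibration model.
#'
#' @param stack an `image_stack` (confocal droplet field).
#' @param channel channel (index or name) used for thresholding.
#' @param threshold_method `"otsu"` or `"fixed:<value>"`.
#' @param min_droplet_area_px smallest retained component, pixels.
#' @param timepoint frame index.
#' @return list: `labels` (integer matrix) and `records` (data.frame with
#'   label, area_px, area_um2, equivalent_diameter_um and one
#'   `mean_intensity_<channel>` column per channel).
#' @export
segment_droplets <- function(stack, channel = 1L, threshold_method = "otsu",
                             min_droplet_area_px = 9, timepoint = 1L) {
  img <- get_frame(stack, channel, timepoint)
  thr <- if (identical(threshold_method, "otsu")) {
    if (diff(range(img)) == 0) Inf
    else EBImage::otsu(EBImage::as.Image(img / max(img)), range = c(0, 1)) * max(img)
  } else if (grepl("^fixed:", threshold_method)) {
    as.numeric(sub("^fixed:", "", threshold_method))
  } else stop("threshold_method must be 'otsu' or 'fixed:<value>'")
  mask <- img > thr
  empty <- {
    rec <- data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0))
    for (ch in stack$channel_names)
      rec[[paste0("mean_intensity_", ch)]] <- numeric(0)
    list(labels = matrix(0L, nrow(img), ncol(img)), records = rec)
  }
  if (!any(mask)) return(empty)
  lab <- label_components_8(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_droplet_area_px)
  if (length(keep) == 0) return(empty)
  relab <- integer(length(areas)); relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  out[lab > 0] <- relab[lab[lab > 0]]
  px_area_um2 <- stack$pixel_size_um^2
  rec <- data.frame(label = seq_along(keep), area_px = areas[keep])
  rec$area_um2 <- rec$area_px * px_area_um2
  rec$equivalent_diameter_um <- 2 * sqrt(rec$area_um2 / pi)
  fg <- out > 0
  for (ch in seq_along(stack$channel_names)) {
    chimg <- get_frame(stack, ch, timepoint)
    bg <- stats::median(chimg[!fg])
    sums <- vapply(seq_along(keep), function(l) sum(chimg[out == l]),
                   numeric(1))
    rec[[paste0("mean_intensity_", stack$channel_names[ch])]] <-
      sums / rec$area_px - bg
  }
  list(labels = out, records = rec)
}

#' Area-times-intensity condensation metric
#'
#' Sum over droplets of background-subtracted mean intensity times area in
#' pixels -- the integrated excess fluorescence in the dense phase. Additive
#' over disjoint fields and invariant to intensity offsets.
#'
#' @param records droplet data.frame from [segment_droplets()].
#' @param channel channel name (suffix of the `mean_intensity_` column).
#' @return metric value, counts * px (0 for an empty record set).
#' @export
droplet_metric <- function(records, channel) {
  col <- paste0("mean_intensity_", channel)
  if (!col %in% names(records)) stop("no intensity column for channel ", channel)
  if (nrow(records) == 0) return(0)
  sum(records[[col]] * records$area_px)
}

#' Normalize condensation metrics to a reference condition
#'
#' @param values numeric metric values.
#' @param reference_value metric of the reference condition (> 0); the
#'   reference maps to 1.0.
#' @return `values / reference_value`.
#' @export
normalize_metric <- function(values, reference_value) {
  if (!is.numeric(reference_value) || reference_value <= 0)
    stop("reference_value must be > 0")
  values / reference_value
}

#' Fit a fluorescence calibration curve
#'
#' Ordinary least squares line `intensity = slope * concentration +
#' intercept` over homogeneous-solution measurements; exact on noiseless
#' collinear input.
#'
#' @param concentration_uM,mean_intensity paired measurements (>= 2 distinct
#'   concentrations).
#' @return a `calibration_curve`: slope, intercept, r_squared, n_points,
#'   concentration_range.
#' @export
fit_calibration <- function(concentration_uM, mean_intensity) {
  stopifnot(length(concentration_uM) == length(mean_intensity))
  if (length(unique(concentration_uM)) < 2)
    stop("calibration requires at least 2 distinct concentrations")
  fit <- stats::lm(mean_intensity ~ concentration_uM)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_intensity - mean(mean_intensity))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n_points = length(concentration_uM),
    concentration_range = range(concentration_uM)),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: intensity = %.6g * c + %.6g (r2 = %.4f, n = %d, range %.3g-%.3g uM)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              x$concentration_range[1], x$concentration_range[2]))
  invisible(x)
}

#' Convert droplet intensity to protein concentration
#'
#' Inverts the calibration line: `c = (intensity - intercept) / slope`.
#' Values outside the calibrated concentration range are flagged as
#' extrapolated.
#'
#' @param mean_intensity droplet mean intensity, counts.
#' @param curve a `calibration_curve` with slope > 0.
#' @param background_subtracted set `TRUE` for intensities that already had
#'   the background removed (as [segment_droplets()] reports them, where the
#'   background estimate plays the intercept's role); the intercept is then
#'   not subtracted again.
#' @return data.frame: concentration_uM, extrapolated.
#' @export
droplet_concentration <- function(mean_intensity, curve,
                                  background_subtracted = FALSE) {
  if (!inherits(curve, "calibration_curve") || curve$slope <= 0)
    stop("calibration curve with positive slope required")
  conc <- if (background_subtracted) mean_intensity / curve$slope
          else (mean_intensity - curve$intercept) / curve$slope
  data.frame(concentration_uM = conc,
             extrapolated = conc < curve$concentration_range[1] |
               conc > curve$concentration_range[2])
}

#' Per-droplet stoichiometric ratio between two channels
#'
#' Converts each droplet's mean intensity in both channels to a protein
#' concentration via the channel calibration curves and reports the mean and
#' sd over droplets of the per-droplet concentration ratio a/b. Droplets with
#' non-positive channel-b concentration are excluded and counted.
#'
#' @param records droplet data.frame from [segment_droplets()].
#' @param curve_a,curve_b `calibration_curve` for each channel.
#' @param channel_a,channel_b channel names.
#' @return list: mean_ratio, sd_ratio, n, n_excluded, ratios.
#' @export
droplet_stoichiometry <- function(records, curve_a, curve_b,
                                  channel_a, channel_b) {
  ca <- droplet_concentration(records[[paste0("mean_intensity_", channel_a)]],
                              curve_a, background_subtracted = TRUE)$concentration_uM
  cb <- droplet_concentration(records[[paste0("mean_intensity_", channel_b)]],
                              curve_b, background_subtracted = TRUE)$concentration_uM
  valid <- cb > 0
  if (!any(valid)) stop("no droplets with positive channel-b concentration")
  ratios <- ca[valid] / cb[valid]
  list(mean_ratio = mean(ratios),
       sd_ratio = if (sum(valid) > 1) stats::sd(ratios) else 0,
       n = sum(valid), n_excluded = sum(!valid), ratios = ratios)
}

#' Droplet size distribution
#'
#' Histogram of equivalent diameters over half-open bins
#' `[i*w, (i+1)*w)`; counts sum to the number of droplets.
#'
#' @param records droplet data.frame.
#' @param bin_width_um bin width, micrometres (> 0).
#' @return data.frame: bin_lo_um, bin_hi_um, count.
#' @export
size_distribution <- function(records, bin_width_um = 0.5) {
  stopifnot(bin_width_um > 0)
  if (nrow(records) == 0)
    return(data.frame(bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                      count = integer(0)))
  bins <- floor(records$equivalent_diameter_um / bin_width_um)
  tab <- table(bins)
  data.frame(bin_lo_um = as.numeric(names(tab)) * bin_width_um,
             bin_hi_um = (as.numeric(names(tab)) + 1) * bin_width_um,
             count = as.integer(tab))
}
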