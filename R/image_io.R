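#' Multi-channel, multi-timepoint image stack
#'
#' Container for raw fluorescence microscopy data: a grid of intensity frames
#' indexed by (channel, timepoint), a physical pixel size, and optional frame
#' interval. Intensities are kept as raw counts (real numbers); no rescaling
#' is ever applied, because the calibration math downstream requires raw
#' camera counts.
#'
#' @param frames list of numeric matrices, all of identical dimension, in
#'   channel-fastest page order: page index = (t - 1) * n_channels + c.
#' @param channel_names character vector of unique channel labels, e.g.
#'   `c("GFP", "mCherry")`.
#' @param pixel_size_um micrometres per pixel edge; must be > 0.
#' @param time_interval_s seconds between frames, or `NA` for single
#'   timepoints.
#' @param bit_depth integer bit depth the data were (or will be) stored at.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, channel_names = "ch1", pixel_size_um = 0.13,
                        time_interval_s = NA_real_, bit_depth = 16L) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices")
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical height/width")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  nc <- length(channel_names)
  if (length(frames) %% nc != 0L)
    stop("frame count (", length(frames), ") is not a multiple of channel count (", nc, ")")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("intensities must be non-negative")
  frames <- lapply(frames, function(f) { storage.mode(f) <- "double"; f })
  structure(
    list(frames = frames, channel_names = channel_names,
         pixel_size_um = pixel_size_um, time_interval_s = time_interval_s,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d x %d px, %d channel(s) [%s], %d timepoint(s), %.3f um/px\n",
              d[1], d[2], n_channels(x), paste(x$channel_names, collapse = ", "),
              n_timepoints(x), x$pixel_size_um))
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `image_stack`.
#' @export
n_channels <- function(stack) length(stack$channel_names)

#' @rdname image_stack
#' @export
n_timepoints <- function(stack) length(stack$frames) %/% n_channels(stack)

#' Extract one frame from an image stack
#'
#' @param stack an `image_stack`.
#' @param channel channel index or name.
#' @param timepoint timepoint index (1-based).
#' @return numeric intensity matrix.
#' @export
get_frame <- function(stack, channel = 1L, timepoint = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  nc <- n_channels(stack)
  if (channel < 1L || channel > nc) stop("channel index out of range")
  if (timepoint < 1L || timepoint > n_timepoints(stack))
    stop("timepoint index out of range")
  stack$frames[[(timepoint - 1L) * nc + channel]]
}

#' Read a grayscale TIFF into an image stack
#'
#' Pages of a multi-page TIFF are mapped to (channel, timepoint) in
#' channel-fastest order: page `(t-1)*n_channels + c` holds channel `c` at
#' timepoint `t`. Pixel values are read as raw integer counts (no [0,1]
#' normalisation).
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param channel_names channel labels; their number fixes `n_channels`.
#' @param n_timepoints expected number of timepoints; the page count must
#'   equal `length(channel_names) * n_timepoints`.
#' @param pixel_size_um,time_interval_s physical metadata (TIFFs written by
#'   this package do not carry them).
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, channel_names = "ch1", n_timepoints = 1L,
                             pixel_size_um = 0.13, time_interval_s = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  expected <- length(channel_names) * n_timepoints
  if (length(pages) != expected)
    stop("page count (", length(pages), ") inconsistent with layout (",
         length(channel_names), " channels x ", n_timepoints, " timepoints)")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("non-grayscale TIFF pages are not supported")
  image_stack(pages, channel_names = channel_names,
              pixel_size_um = pixel_size_um, time_interval_s = time_interval_s)
}

#' Write an image stack to a grayscale TIFF
#'
#' Inverse of [read_image_stack()]: pages are written in channel-fastest
#' order. Values are rounded to integers and stored at the stack's bit depth;
#' the write/read round trip is the identity on integer-valued 8/16-bit data.
#'
#' @param stack an `image_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(stack$frames, function(f) {
    f <- round(f)
    if (any(f > maxval))
      stop("intensity exceeds bit depth ", stack$bit_depth, " maximum ", maxval)
    f / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' Write a results table as tab-separated text
#'
#' Header row of keys, one row per record, numeric fields rendered at full
#' double precision so the table round-trips losslessly through
#' [read_results_table()].
#'
#' @param records a data.frame, or a list of uniform keyed lists.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    if (length(records) == 0L) stop("empty table: no records to write")
    keys <- names(records[[1]])
    ok <- vapply(records, function(r) identical(names(r), keys), logical(1))
    if (!all(ok)) stop("records have heterogeneous keys")
    records <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty table: no records to write")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path path to a tab-separated table with header.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

# ---- analysis configuration -------------------------------------------------

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline, grouped by stage. Field defaults:
#' the focus contrast cutoff is 0.05 (foci whose peak exceeds local background
#' by less than 5\% are discarded) and the in vivo stoichiometry uses the 10
#' brightest foci per image. `NULL` entries are derived at run time:
#' `min_votes` from the voting geometry (0.3 * 2*pi*r_min in pixels),
#' `nms_radius_px` from r_min, and `intensity_min` from the image background
#' plus 3 robust (MAD-based) noise standard deviations.
#'
#' @param profile optical profile fixing the default pixel size:
#'   `"widefield"` (0.13 um/px, 100x objective with 2x2 camera binning) or
#'   `"confocal"` (0.18 um/px, 63x oil objective).
#' @return a named list of class `analysis_config`.
#' @export
default_config <- function(profile = c("widefield", "confocal")) {
  profile <- match.arg(profile)
  cfg <- list(
    pixel_size_um = if (profile == "widefield") 0.13 else 0.18,
    segmentation = list(
      edge_sigma_px = 3,
      magnitude_quantile = 0.85,
      r_min_um = 1.5,
      r_max_um = 3.2,
      min_votes = NULL,          # derived: 0.3 perimeter fraction, see below
      nms_radius_px = NULL,      # derived: (r_min_px + r_max_px) / 2
      min_cell_area_um2 = 3,
      max_cell_area_um2 = 40,
      exclude_border = TRUE
    ),
    focus = list(
      smooth_sigma_px = 1.5,     # matched filter before maxima detection
      maxima_radius_px = 2,
      intensity_min = NULL,      # derived: background + 3 * MAD-based sd
      contrast_min = 0.05,
      r_int_px = 2.5,
      r_bg_in_px = 3,
      r_bg_out_px = 5
    ),
    coloc = list(d_max_um = 0.25),
    stoichiometry = list(k_brightest = 10),
    droplet = list(
      threshold_method = "otsu",
      min_droplet_area_px = 9,
      background_mode = "median"
    ),
    rng_seed = 1L
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Validate an analysis configuration
#'
#' @param cfg a configuration list.
#' @return `cfg`, invisibly, or an error naming the offending key.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, key, why) if (!ok) stop("invalid config key `", key, "`: ", why)
  chk(cfg$pixel_size_um > 0, "pixel_size_um", "must be > 0")
  s <- cfg$segmentation
  chk(s$edge_sigma_px > 0, "segmentation.edge_sigma_px", "must be > 0")
  chk(s$magnitude_quantile > 0 && s$magnitude_quantile < 1,
      "segmentation.magnitude_quantile", "must lie in (0, 1)")
  chk(s$r_min_um > 0, "segmentation.r_min_um", "must be > 0")
  chk(s$r_max_um > s$r_min_um, "segmentation.r_max_um", "must exceed r_min_um")
  chk(is.null(s$min_votes) || s$min_votes > 0, "segmentation.min_votes", "must be > 0")
  chk(is.null(s$nms_radius_px) || s$nms_radius_px >= 1,
      "segmentation.nms_radius_px", "must be >= 1")
  chk(s$min_cell_area_um2 > 0 && s$max_cell_area_um2 > s$min_cell_area_um2,
      "segmentation.max_cell_area_um2", "must exceed min_cell_area_um2 > 0")
  f <- cfg$focus
  chk(f$contrast_min >= 0, "focus.contrast_min", "must be >= 0")
  chk(f$maxima_radius_px >= 1, "focus.maxima_radius_px", "must be >= 1")
  chk(f$r_int_px > 0, "focus.r_int_px", "must be > 0")
  chk(f$r_bg_in_px >= f$r_int_px, "focus.r_bg_in_px", "must be >= r_int_px")
  chk(f$r_bg_out_px > f$r_bg_in_px, "focus.r_bg_out_px", "must exceed r_bg_in_px")
  chk(cfg$coloc$d_max_um > 0, "coloc.d_max_um", "must be > 0")
  chk(cfg$stoichiometry$k_brightest >= 1, "stoichiometry.k_brightest", "must be >= 1")
  d <- cfg$droplet
  chk(identical(d$threshold_method, "otsu") ||
        grepl("^fixed:", d$threshold_method),
      "droplet.threshold_method", "must be 'otsu' or 'fixed:<value>'")
  chk(d$min_droplet_area_px >= 1, "droplet.min_droplet_area_px", "must be >= 1")
  invisible(cfg)
}

#' Load an analysis configuration from a YAML file
#'
#' Missing keys are filled with the documented defaults (see
#' [default_config()]); unknown keys are rejected. Loading a dumped
#' configuration reproduces it exactly.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @param profile optical profile passed to [default_config()].
#' @return validated `analysis_config`.
#' @export
load_config <- function(path = NULL, profile = "widefield") {
  cfg <- default_config(profile)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user, prefix = "")
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg an `analysis_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base))
      stop("unknown config key: `", full, "`")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key `", full, "` must be a block")
      base[[key]] <- merge_config(base[[key]], user[[key]], paste0(full, "."))
    } else {
      base[key] <- list(user[[key]])   # keeps NULL-valued keys in place
    }
  }
  base
}

# Derived defaults, resolved against pixel size at run time.
resolve_segmentation <- function(cfg) {
  s <- cfg$segmentation
  s$r_min_px <- s$r_min_um / cfg$pixel_size_um
  s$r_max_px <- s$r_max_um / cfg$pixel_size_um
  # a perimeter pixel voting near the centre lands ~6 accumulator counts
  # (double LoG edge x ~3 ray steps inside the smoothing window); require
  # 30% of the r_min perimeter to vote
  if (is.null(s$min_votes)) s$min_votes <- 0.3 * 6 * 2 * pi * s$r_min_px
  if (is.null(s$nms_radius_px)) s$nms_radius_px <- (s$r_min_px + s$r_max_px) / 2
  s
}
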