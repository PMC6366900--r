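# Offsets (drow, dcol) of the pixel disc d <= radius, excluding the origin.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 & !(g$dr == 0 & g$dc == 0), ]
  as.matrix(g)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill = -Inf) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Detect focus candidates as local intensity maxima
#'
#' A pixel is a candidate when no pixel within Euclidean distance
#' `maxima_radius_px` exceeds it and its value is strictly above the image
#' minimum (so a flat field yields no candidates). Plateaus -- equal-valued
#' candidates within the radius -- are collapsed to their lexicographically
#' smallest (row, col) member.
#'
#' @param image intensity matrix.
#' @param maxima_radius_px neighbourhood radius, pixels (>= 1).
#' @return n x 2 matrix of candidate (row, col), sorted by descending pixel
#'   value (ties by ascending row, col).
#' @export
detect_local_maxima <- function(image, maxima_radius_px = 2) {
  stopifnot(maxima_radius_px >= 1)
  offs <- disc_offsets(maxima_radius_px)
  is_max <- matrix(TRUE, nrow(image), ncol(image))
  for (k in seq_len(nrow(offs)))
    is_max <- is_max & (image >= shift_matrix(image, offs[k, 1], offs[k, 2]))
  is_max <- is_max & (image > min(image))
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), 0, 2))
  v <- image[idx]
  ord <- order(-v, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; v <- v[ord]
  # collapse plateaus: drop a candidate if an equal-valued candidate with
  # smaller (row, col) lies within the radius
  keep <- rep(TRUE, nrow(idx))
  r2 <- maxima_radius_px^2
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    same <- which(keep & v == v[i])
    same <- same[same > i]
    if (length(same)) {
      d2 <- (idx[same, 1] - idx[i, 1])^2 + (idx[same, 2] - idx[i, 2])^2
      keep[same[d2 <= r2]] <- FALSE
    }
  }
  unname(idx[keep, , drop = FALSE])
}

#' Measure a focus at a candidate position
#'
#' Local background is the median intensity in the annulus
#' `[r_bg_in, r_bg_out)` around the candidate; the peak is the maximum in the
#' disc of radius `r_int` (half-open `< r_int` convention); the integrated
#' intensity is the background-corrected sum over that disc; contrast is
#' `(peak - background) / background`. The subpixel centroid is the centre of
#' mass of the background-subtracted (negative values clamped to zero) disc
#' pixels. A candidate whose annulus is clipped by the image border is
#' flagged (`border = TRUE`) and excluded from ranking downstream.
#'
#' @param image intensity matrix.
#' @param point `c(row, col)` candidate pixel.
#' @param r_int_px measurement disc radius.
#' @param r_bg_in_px,r_bg_out_px background annulus radii,
#'   `r_bg_out > r_bg_in >= r_int`.
#' @return one-row data.frame: centroid_row, centroid_col, peak_intensity,
#'   background, integrated_intensity, contrast, border.
#' @export
measure_focus <- function(image, point, r_int_px = 3, r_bg_in_px = 4,
                          r_bg_out_px = 7) {
  stopifnot(r_int_px > 0, r_bg_in_px >= r_int_px, r_bg_out_px > r_bg_in_px)
  h <- nrow(image); w <- ncol(image)
  r0 <- point[1]; c0 <- point[2]
  rmax <- ceiling(r_bg_out_px)
  border <- r0 - rmax < 1 || r0 + rmax > h || c0 - rmax < 1 || c0 + rmax > w
  rr <- max(1, r0 - rmax):min(h, r0 + rmax)
  cc <- max(1, c0 - rmax):min(w, c0 + rmax)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sub <- image[rr, cc, drop = FALSE]
  disc <- d2 < r_int_px^2
  ann <- d2 >= r_bg_in_px^2 & d2 < r_bg_out_px^2
  bg <- stats::median(sub[ann])
  peak <- max(sub[disc])
  integrated <- sum(sub[disc] - bg)
  contrast <- if (bg > 0) (peak - bg) / bg else NA_real_
  wgt <- pmax(sub - bg, 0) * disc
  tot <- sum(wgt)
  if (tot > 0) {
    cr <- sum(outer(rr, rep(1, length(cc))) * wgt) / tot
    cc0 <- sum(outer(rep(1, length(rr)), cc) * wgt) / tot
  } else {
    cr <- r0; cc0 <- c0
  }
  data.frame(centroid_row = cr, centroid_col = cc0, peak_intensity = peak,
             background = bg, integrated_intensity = integrated,
             contrast = contrast, border = border)
}

# Robust intensity floor: background median + 3 MAD-based noise sd.
default_intensity_min <- function(image) {
  stats::median(image) + 3 * stats::mad(image)
}

#' Filter focus candidates by intensity and contrast thresholds
#'
#' Candidates are measured with [measure_focus()] and retained when
#' `peak_intensity >= intensity_min` AND `contrast >= contrast_min` (both
#' boundaries inclusive: a focus at exactly 5\% contrast is kept). Candidates
#' with a border-clipped annulus are dropped.
#'
#' @param candidates n x 2 matrix from [detect_local_maxima()].
#' @param image intensity matrix.
#' @param intensity_min minimum peak intensity, counts; `NULL` derives
#'   image median + 3 robust (MAD) noise sd.
#' @param contrast_min minimum contrast (default 0.05, i.e. 5\%).
#' @param r_int_px,r_bg_in_px,r_bg_out_px measurement geometry.
#' @return data.frame of retained foci (columns of [measure_focus()] plus
#'   `peak_row`, `peak_col`), sorted by descending integrated intensity.
#' @export
filter_foci <- function(candidates, image, intensity_min = NULL,
                        contrast_min = 0.05, r_int_px = 3, r_bg_in_px = 4,
                        r_bg_out_px = 7) {
  stopifnot(contrast_min >= 0)
  if (is.null(intensity_min)) intensity_min <- default_intensity_min(image)
  stopifnot(intensity_min >= 0)
  empty <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                      peak_intensity = numeric(0), background = numeric(0),
                      integrated_intensity = numeric(0), contrast = numeric(0),
                      border = logical(0), peak_row = integer(0),
                      peak_col = integer(0))
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  # cheap pre-filter on raw pixel value before the full measurement
  pre <- image[candidates] >= intensity_min
  candidates <- candidates[pre, , drop = FALSE]
  if (nrow(candidates) == 0) return(empty)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    f <- measure_focus(image, candidates[i, ], r_int_px, r_bg_in_px,
                       r_bg_out_px)
    f$peak_row <- candidates[i, 1]; f$peak_col <- candidates[i, 2]
    f
  })
  foci <- do.call(rbind, rows)
  foci <- foci[!foci$border &
                 foci$peak_intensity >= intensity_min &
                 !is.na(foci$contrast) & foci$contrast >= contrast_min &
                 foci$integrated_intensity > 0, , drop = FALSE]
  foci <- foci[order(-foci$integrated_intensity,
                     foci$peak_row, foci$peak_col), , drop = FALSE]
  rownames(foci) <- NULL
  foci
}

#' Detect and measure foci in one frame
#'
#' Wrapper: [detect_local_maxima()] then [filter_foci()] with the focus block
#' of an `analysis_config`. The frame is first smoothed with a small Gaussian
#' (`smooth_sigma_px`, default 1 px) as an approximate matched filter for the
#' diffraction-limited spot; candidates, thresholds and measurements all use
#' the smoothed frame, which suppresses shot-noise bumps inside bright cell
#' interiors without shifting true focus positions.
#'
#' @param image intensity matrix.
#' @param config an `analysis_config`.
#' @return data.frame of retained foci.
#' @export
detect_foci <- function(image, config = default_config()) {
  f <- config$focus
  sm <- if (!is.null(f$smooth_sigma_px) && f$smooth_sigma_px > 0)
    as.matrix(EBImage::gblur(image, f$smooth_sigma_px)) else image
  cand <- detect_local_maxima(sm, f$maxima_radius_px)
  filter_foci(cand, sm, intensity_min = f$intensity_min,
              contrast_min = f$contrast_min, r_int_px = f$r_int_px,
              r_bg_in_px = f$r_bg_in_px, r_bg_out_px = f$r_bg_out_px)
}

#' Match foci across two channels (colocalization)
#'
#' Greedy one-to-one matching: all cross-channel pairs are sorted by
#' ascending centroid distance (ties by channel-a centroid, then channel-b),
#' and a pair is accepted when both foci are still unmatched and their
#' distance is at most `d_max_um`. Swapping the two inputs yields the same
#' pair set.
#'
#' @param set_a,set_b focus data.frames from [filter_foci()].
#' @param d_max_um maximum centroid distance, micrometres.
#' @param pixel_size_um micrometres per pixel.
#' @return data.frame with one row per match: `a` and `b` row indices into
#'   the input sets and `distance_um`.
#' @export
match_foci_channels <- function(set_a, set_b, d_max_um = 0.25,
                                pixel_size_um = 0.13) {
  empty <- data.frame(a = integer(0), b = integer(0), distance_um = numeric(0))
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  dr <- outer(set_a$centroid_row, set_b$centroid_row, "-")
  dc <- outer(set_a$centroid_col, set_b$centroid_col, "-")
  d <- sqrt(dr^2 + dc^2) * pixel_size_um
  ok <- which(d <= d_max_um, arr.ind = TRUE)
  if (nrow(ok) == 0) return(empty)
  ia <- ok[, 1]; ib <- ok[, 2]
  ord <- order(d[ok], set_a$centroid_row[ia], set_a$centroid_col[ia],
               set_b$centroid_row[ib], set_b$centroid_col[ib])
  ia <- ia[ord]; ib <- ib[ord]; dd <- d[ok][ord]
  used_a <- logical(nrow(set_a)); used_b <- logical(nrow(set_b))
  out <- list()
  for (k in seq_along(ia)) {
    if (used_a[ia[k]] || used_b[ib[k]]) next
    used_a[ia[k]] <- TRUE; used_b[ib[k]] <- TRUE
    out[[length(out) + 1L]] <- data.frame(a = ia[k], b = ib[k],
                                          distance_um = dd[k])
  }
  do.call(rbind, out)
}

#' Assign foci to segmented cells
#'
#' Sets `cell_label` to the label-map value at the rounded focus centroid;
#' background (label 0) gives `NA`.
#'
#' @param foci focus data.frame.
#' @param label_map a `cell_label_map`.
#' @return `foci` with a `cell_label` column.
#' @export
assign_foci_to_cells <- function(foci, label_map) {
  if (nrow(foci) == 0) { foci$cell_label <- integer(0); return(foci) }
  rr <- pmin(pmax(round(foci$centroid_row), 1), nrow(label_map$labels))
  cc <- pmin(pmax(round(foci$centroid_col), 1), ncol(label_map$labels))
  lab <- label_map$labels[cbind(rr, cc)]
  foci$cell_label <- ifelse(lab == 0L, NA_integer_, lab)
  foci
}

#' Foci per cell
#'
#' The headline per-image statistic: number of detected foci divided by the
#' number of cells. With zero cells the rate is undefined; `NA` is returned
#' with a warning and such images are excluded from aggregates.
#'
#' @param n_foci,n_cells counts.
#' @return numeric rate, or `NA_real_` when `n_cells == 0`.
#' @export
foci_per_cell <- function(n_foci, n_cells) {
  stopifnot(n_foci >= 0, n_cells >= 0)
  if (n_cells == 0) {
    warning("n_cells is 0: foci-per-cell undefined, image flagged")
    return(NA_real_)
  }
  n_foci / n_cells
}
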