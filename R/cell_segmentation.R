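#' Detect cell edges by Laplacian-of-Gaussian zero crossings
#'
#' The image is smoothed with a Gaussian of sd `edge_sigma_px`, its Laplacian
#' computed, and edge pixels taken as zero crossings of the response. At each
#' zero crossing the local gradient of the smoothed image gives the edge
#' normal, oriented from dark to bright; crossings whose gradient magnitude
#' falls below the given quantile of all crossing magnitudes are discarded,
#' suppressing noise edges.
#'
#' @param image intensity matrix.
#' @param edge_sigma_px Gaussian smoothing sd, pixels (> 0).
#' @param magnitude_quantile quantile in (0, 1) of zero-crossing gradient
#'   magnitudes below which edges are dropped.
#' @return an `edge_map`: `pixels` (n x 2 matrix of row, col),
#'   `direction` (n x 2 unit vectors, dark-to-bright), `magnitude` (length n).
#'   A constant image yields an empty edge map.
#' @export
detect_edges <- function(image, edge_sigma_px = 2, magnitude_quantile = 0.7) {
  stopifnot(length(image) > 0, edge_sigma_px > 0,
            magnitude_quantile > 0, magnitude_quantile < 1)
  empty <- structure(list(pixels = matrix(integer(0), 0, 2),
                          direction = matrix(numeric(0), 0, 2),
                          magnitude = numeric(0), dim = dim(image)),
                     class = "edge_map")
  if (diff(range(image)) == 0) return(empty)
  sm <- as.matrix(EBImage::gblur(image, sigma = edge_sigma_px))
  h <- nrow(sm); w <- ncol(sm)
  # 4-neighbour Laplacian
  lap <- matrix(0, h, w)
  lap[2:(h - 1), 2:(w - 1)] <-
    sm[1:(h - 2), 2:(w - 1)] + sm[3:h, 2:(w - 1)] +
    sm[2:(h - 1), 1:(w - 2)] + sm[2:(h - 1), 3:w] -
    4 * sm[2:(h - 1), 2:(w - 1)]
  # zero crossings: sign change towards right or down neighbour; mark the
  # pixel on the smaller-|lap| side of the crossing
  zc <- matrix(FALSE, h, w)
  right <- lap[, -w] * lap[, -1] < 0
  pick_left <- abs(lap[, -w]) <= abs(lap[, -1])
  zc[, -w] <- zc[, -w] | (right & pick_left)
  zc[, -1] <- zc[, -1] | (right & !pick_left)
  down <- lap[-h, ] * lap[-1, ] < 0
  pick_up <- abs(lap[-h, ]) <= abs(lap[-1, ])
  zc[-h, ] <- zc[-h, ] | (down & pick_up)
  zc[-1, ] <- zc[-1, ] | (down & !pick_up)
  zc[c(1, h), ] <- FALSE; zc[, c(1, w)] <- FALSE
  idx <- which(zc, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  # central-difference gradient of the smoothed image (dark -> bright)
  gr <- (sm[cbind(idx[, 1] + 1L, idx[, 2])] - sm[cbind(idx[, 1] - 1L, idx[, 2])]) / 2
  gc <- (sm[cbind(idx[, 1], idx[, 2] + 1L)] - sm[cbind(idx[, 1], idx[, 2] - 1L)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  # numerical zero crossings in flat regions (machine-epsilon Laplacian
  # ripple) carry essentially no gradient; drop them before the quantile
  real <- mag > 1e-9 * diff(range(image))
  idx <- idx[real, , drop = FALSE]
  gr <- gr[real]; gc <- gc[real]; mag <- mag[real]
  if (length(mag) == 0) return(empty)
  keep <- mag > stats::quantile(mag, magnitude_quantile) & mag > 0
  idx <- idx[keep, , drop = FALSE]
  gr <- gr[keep]; gc <- gc[keep]; mag <- mag[keep]
  structure(list(pixels = unname(idx),
                 direction = cbind(gr, gc, deparse.level = 0) / mag,
                 magnitude = unname(mag), dim = dim(image)),
            class = "edge_map")
}

#' Cast votes along edge normals to locate cell centres
#'
#' Each edge pixel casts one vote into every accumulator pixel along the ray
#' from its position in its dark-to-bright gradient direction, at integer
#' distances in `[r_min_px, r_max_px]`. For a bright convex cell the normals
#' converge at the cell centre, so the accumulator peaks there. The raw vote
#' image is smoothed with a Gaussian (sd 2 px) and rescaled by `2*pi*sd^2`,
#' so values remain on a local-vote-count scale and the scale-aware
#' `min_votes` default (0.3 * perimeter votes at r_min) applies directly.
#'
#' @param edges an `edge_map` from [detect_edges()].
#' @param r_min_px,r_max_px radius search range, pixels, `r_max > r_min > 0`.
#' @param smooth_sigma_px accumulator smoothing sd.
#' @return non-negative accumulator matrix of the image's dimensions.
#' @export
vote_cell_centres <- function(edges, r_min_px, r_max_px, smooth_sigma_px = 2) {
  stopifnot(inherits(edges, "edge_map"), r_min_px > 0, r_max_px > r_min_px)
  h <- edges$dim[1]; w <- edges$dim[2]
  acc <- matrix(0, h, w)
  n <- nrow(edges$pixels)
  if (n == 0) return(acc)
  dists <- seq(ceiling(r_min_px), floor(r_max_px), by = 1)
  for (d in dists) {
    rr <- round(edges$pixels[, 1] + d * edges$direction[, 1])
    cc <- round(edges$pixels[, 2] + d * edges$direction[, 2])
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (any(ok)) {
      lin <- (cc[ok] - 1L) * h + rr[ok]
      tab <- tabulate(lin, nbins = h * w)
      acc <- acc + tab
    }
  }
  if (smooth_sigma_px > 0)
    acc <- as.matrix(EBImage::gblur(acc, smooth_sigma_px)) *
      (2 * pi * smooth_sigma_px^2)
  pmax(acc, 0)
}

#' Find cell seeds in a vote accumulator
#'
#' Greedy non-maximum suppression: accumulator pixels with at least
#' `min_votes` are visited in order of descending value (ties broken by
#' ascending row, then column); each accepted seed suppresses all weaker
#' candidates within Euclidean distance `nms_radius_px`.
#'
#' @param accumulator vote matrix from [vote_cell_centres()].
#' @param min_votes minimum accumulator value for a seed (> 0).
#' @param nms_radius_px suppression radius, pixels (>= 1).
#' @return n x 2 matrix of seed (row, col), ordered by descending vote count.
#' @export
find_seeds <- function(accumulator, min_votes, nms_radius_px) {
  stopifnot(min_votes > 0, nms_radius_px >= 1)
  # candidates: above threshold and an 8-neighbourhood local maximum
  locmax <- matrix(TRUE, nrow(accumulator), ncol(accumulator))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    locmax <- locmax & (accumulator >= shift_matrix(accumulator, dr, dc))
  }
  cand <- which(locmax & accumulator >= min_votes)
  if (length(cand) == 0) return(matrix(integer(0), 0, 2))
  rr <- (cand - 1L) %% nrow(accumulator) + 1L
  cc <- (cand - 1L) %/% nrow(accumulator) + 1L
  v <- accumulator[cand]
  ord <- order(-v, rr, cc)
  rr <- rr[ord]; cc <- cc[ord]; v <- v[ord]
  alive <- rep(TRUE, length(v))
  seeds <- matrix(integer(0), 0, 2)
  for (i in seq_along(v)) {
    if (!alive[i]) next
    seeds <- rbind(seeds, c(rr[i], cc[i]))
    alive <- alive & ((rr - rr[i])^2 + (cc - cc[i])^2 > nms_radius_px^2)
  }
  seeds
}

# Histogram mode of an image: the dominant (background) intensity level.
background_mode <- function(image, nbins = 256) {
  rg <- range(image)
  if (diff(rg) == 0) return(rg[1])
  br <- seq(rg[1], rg[2], length.out = nbins + 1)
  hh <- graphics::hist(image, breaks = br, plot = FALSE)
  hh$mids[which.max(hh$counts)]
}

#' Reconstruct cells from seeds by edge-bounded region growing
#'
#' Each seed grows over pixels brighter than its threshold -- the midpoint of
#' the seed's intensity and the image's background mode -- and is halted at
#' edge pixels. Pixels claimed by several seeds are resolved by geodesic
#' distance to the seed (via [EBImage::propagate()]). Regions outside the
#' configured area range are discarded; regions touching the image border are
#' flagged and, when `exclude_border` is set, dropped from counting.
#'
#' @param image intensity matrix.
#' @param seeds n x 2 matrix of (row, col) seeds, as from [find_seeds()].
#' @param edges `edge_map` used as growth barrier.
#' @param config an `analysis_config` (segmentation block used).
#' @return a `cell_label_map`: `labels` (integer matrix, 0 background,
#'   1..n cells), `cells` (data.frame: label, area_px, area_um2,
#'   centroid_row, centroid_col, touches_border), `exclude_border` flag.
#' @export
reconstruct_cells <- function(image, seeds, edges, config = default_config()) {
  h <- nrow(image); w <- ncol(image)
  s <- resolve_segmentation(config)
  px_area <- config$pixel_size_um^2
  min_area_px <- s$min_cell_area_um2 / px_area
  max_area_px <- s$max_cell_area_um2 / px_area
  empty <- structure(list(labels = matrix(0L, h, w),
                          cells = data.frame(label = integer(0),
                                             area_px = integer(0),
                                             area_um2 = numeric(0),
                                             centroid_row = numeric(0),
                                             centroid_col = numeric(0),
                                             touches_border = logical(0)),
                          exclude_border = isTRUE(s$exclude_border),
                          pixel_size_um = config$pixel_size_um),
                     class = "cell_label_map")
  if (is.null(seeds) || nrow(seeds) == 0) return(empty)
  stopifnot(all(seeds[, 1] >= 1 & seeds[, 1] <= h &
                  seeds[, 2] >= 1 & seeds[, 2] <= w))
  bg <- background_mode(image)
  # seed level = median in a 5 px disc, robust to a bright focus sitting on
  # the seed pixel itself
  seed_level <- vapply(seq_len(nrow(seeds)), function(i) {
    rr <- max(1, seeds[i, 1] - 5):min(h, seeds[i, 1] + 5)
    cc <- max(1, seeds[i, 2] - 5):min(w, seeds[i, 2] + 5)
    d2 <- outer((rr - seeds[i, 1])^2, (cc - seeds[i, 2])^2, "+")
    stats::median(image[rr, cc][d2 <= 25])
  }, numeric(1))
  thr <- (seed_level + bg) / 2
  mask <- image > min(thr)
  if (nrow(edges$pixels) > 0) mask[edges$pixels] <- FALSE
  seed_img <- matrix(0L, h, w)
  seed_img[seeds] <- seq_len(nrow(seeds))
  mask[seeds] <- TRUE   # a seed always belongs to its own region
  prop <- as.matrix(EBImage::propagate(EBImage::as.Image(image),
                                       seeds = seed_img, mask = mask,
                                       lambda = 100))
  labels <- matrix(0L, h, w)
  recs <- list()
  next_label <- 0L
  for (i in seq_len(nrow(seeds))) {
    m <- prop == i & image > thr[i]
    m[seeds[i, , drop = FALSE]] <- TRUE
    # keep only the (8-connected) component containing the seed
    comp <- label_components_8(m)
    keep_id <- comp[seeds[i, 1], seeds[i, 2]]
    if (keep_id == 0) next
    m <- comp == keep_id
    area <- sum(m)
    if (area < min_area_px || area > max_area_px) next
    idx <- which(m, arr.ind = TRUE)
    touches <- any(idx[, 1] %in% c(1L, h)) || any(idx[, 2] %in% c(1L, w))
    next_label <- next_label + 1L
    labels[m] <- next_label
    recs[[next_label]] <- data.frame(
      label = next_label, area_px = area, area_um2 = area * px_area,
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
      touches_border = touches)
  }
  if (next_label == 0L) return(empty)
  # edge pixels halted the growth but sit on the cell boundary itself;
  # fold them into the adjacent region so areas are not ring-depleted
  if (nrow(edges$pixels) > 0) {
    for (pass in 1:2) {
      nb <- matrix(0L, h, w)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nb <- pmax(nb, shift_matrix(labels, dr, dc, fill = 0L))
      }
      fill <- edges$pixels[labels[edges$pixels] == 0L &
                             nb[edges$pixels] > 0L, , drop = FALSE]
      if (nrow(fill) == 0) break
      labels[fill] <- nb[fill]
    }
    for (i in seq_len(next_label)) {
      idx <- which(labels == i, arr.ind = TRUE)
      recs[[i]]$area_px <- nrow(idx)
      recs[[i]]$area_um2 <- nrow(idx) * px_area
      recs[[i]]$centroid_row <- mean(idx[, 1])
      recs[[i]]$centroid_col <- mean(idx[, 2])
      recs[[i]]$touches_border <- any(idx[, 1] %in% c(1L, h)) ||
        any(idx[, 2] %in% c(1L, w))
    }
    # re-apply the area filter after boundary completion
    keep <- vapply(recs, function(r)
      r$area_px >= min_area_px && r$area_px <= max_area_px, logical(1))
    if (!all(keep)) {
      drop <- which(!keep)
      labels[labels %in% drop] <- 0L
      recs <- recs[keep]
      if (length(recs) == 0L) return(empty)
      old <- vapply(recs, function(r) r$label, integer(1))
      for (k in seq_along(recs)) recs[[k]]$label <- k
      relab <- integer(next_label); relab[old] <- seq_along(recs)
      labels[labels > 0L] <- relab[labels[labels > 0L]]
      next_label <- length(recs)
    }
  }
  structure(list(labels = labels, cells = do.call(rbind, recs),
                 exclude_border = isTRUE(s$exclude_border),
                 pixel_size_um = config$pixel_size_um),
            class = "cell_label_map")
}

#' Count retained cells in a label map
#'
#' Border-touching cells are excluded when the map was built with
#' `exclude_border` set.
#'
#' @param label_map a `cell_label_map`.
#' @return integer cell count.
#' @export
count_cells <- function(label_map) {
  stopifnot(inherits(label_map, "cell_label_map"))
  cells <- label_map$cells
  if (nrow(cells) == 0) return(0L)
  if (label_map$exclude_border) sum(!cells$touches_border) else nrow(cells)
}

#' Segment a cell field end to end
#'
#' Convenience wrapper: [detect_edges()] -> [vote_cell_centres()] ->
#' [find_seeds()] -> [reconstruct_cells()].
#'
#' @param image intensity matrix.
#' @param config an `analysis_config`.
#' @return a `cell_label_map`.
#' @export
segment_cells <- function(image, config = default_config()) {
  s <- resolve_segmentation(config)
  edges <- detect_edges(image, s$edge_sigma_px, s$magnitude_quantile)
  acc <- vote_cell_centres(edges, s$r_min_px, s$r_max_px)
  # when min_votes is derived (not user-set), cap it at half the strongest
  # peak: on very clean images the magnitude quantile keeps few (all strong)
  # edge pixels, and absolute vote counts sit below the noisy-image scale
  mv <- s$min_votes
  if (is.null(config$segmentation$min_votes) && max(acc) > 0)
    mv <- min(mv, 0.5 * max(acc))
  seeds <- find_seeds(acc, mv, s$nms_radius_px)
  reconstruct_cells(image, seeds, edges, config)
}
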