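#' Noise specification for synthetic scenes
#'
#' Models an sCMOS-like camera: Poisson shot noise on the expected photon
#' count of each pixel, followed by additive Gaussian read noise. Both
#' components can be switched off for exact, noiseless scenes.
#'
#' @param background_level expected background counts per pixel.
#' @param read_noise_sd standard deviation of the additive read noise, counts.
#' @param shot_noise logical; apply Poisson resampling of expected counts.
#' @return a named list used by all generators.
#' @export
noise_spec <- function(background_level = 100, read_noise_sd = 2,
                       shot_noise = TRUE) {
  stopifnot(background_level >= 0, read_noise_sd >= 0)
  list(background_level = background_level, read_noise_sd = read_noise_sd,
       shot_noise = shot_noise)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Stable named sub-seed so each pipeline stage has its own stream.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

apply_noise <- function(expected, noise) {
  img <- expected
  if (isTRUE(noise$shot_noise)) {
    img[] <- stats::rpois(length(img), lambda = pmax(expected, 0))
  }
  if (noise$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = noise$read_noise_sd)
  }
  pmax(img, 0)
}

# Add an analytic Gaussian spot of amplitude `a`, sd `s` px, in a +/- 6s window.
add_gaussian_spot <- function(img, row, col, a, s) {
  w <- ceiling(6 * s)
  rr <- max(1L, floor(row - w)):min(nrow(img), ceiling(row + w))
  cc <- max(1L, floor(col - w)):min(ncol(img), ceiling(col + w))
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  img[rr, cc] <- img[rr, cc] + a * exp(-d2 / (2 * s^2))
  img
}

# Rejection-sample n centres with pairwise separation >= min_sep and a margin.
place_centres <- function(n, height, width, min_sep, margin, max_tries = 20000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    p <- c(stats::runif(1, margin, height - margin),
           stats::runif(1, margin, width - margin))
    if (placed == 0L ||
        all((pts[seq_len(placed), 1] - p[1])^2 +
              (pts[seq_len(placed), 2] - p[2])^2 >= min_sep^2)) {
      placed <- placed + 1L
      pts[placed, ] <- p
      if (placed == n) return(pts)
    }
  }
  stop("field too small to place ", n, " objects without overlap")
}

# Pixel mask of a rotated ellipse; returns linear indices.
ellipse_indices <- function(height, width, row, col, a, b, theta) {
  w <- ceiling(max(a, b)) + 1L
  rr <- max(1L, floor(row - w)):min(height, ceiling(row + w))
  cc <- max(1L, floor(col - w)):min(width, ceiling(col + w))
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 < 1
  idx <- which(inside)
  cbind(row = rr[(idx - 1) %% length(rr) + 1],
        col = cc[(idx - 1) %/% length(rr) + 1])
}

#' Generate a synthetic yeast cell field with fluorescent foci
#'
#' Emulates a dark-background widefield image of yeast cells with bright
#' cytoplasmic fluorescence and diffraction-limited foci (processing bodies)
#' inside the cells, in one or two channels. A fraction of foci is planted in
#' both channels at (nearly) the same position -- colocalized foci -- with the
#' channel-1 : channel-2 amplitude ratio fixed by `channel_ratio`. The scene
#' (background + elliptical cell interiors) is blurred with a Gaussian PSF,
#' foci are added as analytic Gaussian spots, and camera noise is applied.
#'
#' @param n_cells number of cells to place (rejection sampling, no overlap).
#' @param foci_per_cell either a fixed count or `list(mean = m)` for a
#'   Poisson-distributed count per cell.
#' @param channel_ratio planted amplitude ratio channel 1 / channel 2 for
#'   colocalized focus pairs.
#' @param coloc_fraction fraction of focus slots planted in both channels; the
#'   remainder are planted as independent single-channel foci in each channel.
#' @param noise a [noise_spec()].
#' @param field_size `c(height, width)` in pixels, or `NULL` to size the field
#'   to the requested cell count.
#' @param n_channels 1 or 2.
#' @param pixel_size_um physical pixel size (default 0.13: 100x objective,
#'   2x2 camera binning).
#' @param cell_radius_um range of cell semi-major axes (yeast: 4-6 um
#'   diameter).
#' @param interior_level range of cytoplasmic intensity levels, counts.
#' @param focus_amplitude mean peak amplitude of channel-1 foci above the
#'   local cell interior, counts.
#' @param focus_amplitude_cv coefficient of variation of focus amplitudes.
#' @param psf_sigma_px Gaussian PSF sigma in pixels (0 disables blurring).
#' @param coloc_jitter_px sd of the sub-resolution positional jitter between
#'   colocalized partners.
#' @param seed RNG seed; identical seed and parameters give bit-identical
#'   output.
#' @return `list(stack = image_stack, truth = ground_truth)`; the truth holds
#'   per-cell geometry (`$cells`), per-focus records (`$foci`: position,
#'   channel, amplitude, sigma, owning cell, pair id), the noise spec and the
#'   seed.
#' @export
generate_cell_field <- function(n_cells = 20, foci_per_cell = 2,
                                channel_ratio = 1, coloc_fraction = 1,
                                noise = noise_spec(), field_size = NULL,
                                n_channels = 2, pixel_size_um = 0.13,
                                cell_radius_um = c(2, 3),
                                interior_level = c(300, 500),
                                focus_amplitude = 400,
                                focus_amplitude_cv = 0.2,
                                psf_sigma_px = 1.3,
                                coloc_jitter_px = 0.5,
                                seed = 1L) {
  stopifnot(n_cells >= 0, coloc_fraction >= 0, coloc_fraction <= 1,
            channel_ratio > 0, n_channels %in% 1:2)
  r_max_px <- max(cell_radius_um) / pixel_size_um
  if (is.null(field_size)) {
    side <- max(192, ceiling(sqrt(max(n_cells, 1) * (2.6 * r_max_px)^2 * 1.6)))
    field_size <- c(side, side)
  }
  h <- field_size[1]; w <- field_size[2]
  with_seed(seed, {
    centres <- place_centres(n_cells, h, w, min_sep = 2.2 * r_max_px,
                             margin = r_max_px + 2)
    cells <- data.frame(cell = seq_len(n_cells),
                        row = centres[, 1], col = centres[, 2],
                        a_px = numeric(n_cells), b_px = numeric(n_cells),
                        theta = numeric(n_cells),
                        interior_level = numeric(n_cells),
                        area_px = numeric(n_cells))
    scene <- matrix(noise$background_level, h, w)
    if (n_cells > 0) {
      for (i in seq_len(n_cells)) {
        a <- stats::runif(1, cell_radius_um[1], cell_radius_um[2]) / pixel_size_um
        ratio <- stats::runif(1, 1, 1.3)
        b <- a / ratio
        theta <- stats::runif(1, 0, pi)
        lev <- stats::runif(1, interior_level[1], interior_level[2])
        idx <- ellipse_indices(h, w, centres[i, 1], centres[i, 2], a, b, theta)
        scene[idx] <- lev
        cells$a_px[i] <- a; cells$b_px[i] <- b; cells$theta[i] <- theta
        cells$interior_level[i] <- lev; cells$area_px[i] <- nrow(idx)
      }
    }
    # plant foci strictly inside cells
    foci <- list()
    pair_id <- 0L
    for (i in seq_len(n_cells)) {
      nf <- if (is.list(foci_per_cell)) stats::rpois(1, foci_per_cell$mean)
            else as.integer(foci_per_cell)
      placed <- matrix(numeric(0), 0, 2)
      for (j in seq_len(nf)) {
        pos <- focus_position(cells[i, ], placed)
        if (is.null(pos)) break
        placed <- rbind(placed, pos)
        amp <- focus_amplitude *
          max(stats::rnorm(1, 1, focus_amplitude_cv), 0.3)
        pair_id <- pair_id + 1L
        if (n_channels == 2 && stats::runif(1) < coloc_fraction) {
          jit <- stats::rnorm(2, 0, coloc_jitter_px)
          foci[[length(foci) + 1L]] <- data.frame(
            row = pos[1], col = pos[2], channel = 1L, amplitude = amp,
            sigma_px = max(psf_sigma_px, 1), cell = i, pair = pair_id)
          foci[[length(foci) + 1L]] <- data.frame(
            row = pos[1] + jit[1], col = pos[2] + jit[2], channel = 2L,
            amplitude = amp / channel_ratio,
            sigma_px = max(psf_sigma_px, 1), cell = i, pair = pair_id)
        } else {
          foci[[length(foci) + 1L]] <- data.frame(
            row = pos[1], col = pos[2], channel = 1L, amplitude = amp,
            sigma_px = max(psf_sigma_px, 1), cell = i, pair = NA_integer_)
          if (n_channels == 2) {
            pos2 <- focus_position(cells[i, ], placed)
            if (is.null(pos2)) next
            placed <- rbind(placed, pos2)
            foci[[length(foci) + 1L]] <- data.frame(
              row = pos2[1], col = pos2[2], channel = 2L,
              amplitude = amp / channel_ratio,
              sigma_px = max(psf_sigma_px, 1), cell = i, pair = NA_integer_)
          }
        }
      }
    }
    foci <- if (length(foci)) do.call(rbind, foci) else
      data.frame(row = numeric(0), col = numeric(0), channel = integer(0),
                 amplitude = numeric(0), sigma_px = numeric(0),
                 cell = integer(0), pair = integer(0))
    blurred <- if (psf_sigma_px > 0 && n_cells > 0)
      as.matrix(EBImage::gblur(scene, sigma = psf_sigma_px)) else scene
    frames <- lapply(seq_len(n_channels), function(ch) {
      img <- blurred
      fs <- foci[foci$channel == ch, , drop = FALSE]
      for (k in seq_len(nrow(fs)))
        img <- add_gaussian_spot(img, fs$row[k], fs$col[k],
                                 fs$amplitude[k], fs$sigma_px[k])
      apply_noise(img, noise)
    })
    truth <- structure(
      list(cells = cells, foci = foci, droplets = NULL, calibration = NULL,
           noise = noise, seed = seed, psf_sigma_px = psf_sigma_px,
           scene_unblurred = scene),
      class = "ground_truth")
    list(stack = image_stack(frames,
                             channel_names = c("GFP", "mCherry")[seq_len(n_channels)],
                             pixel_size_um = pixel_size_um),
         truth = truth)
  })
}

# Uniform position strictly inside the central 60% of a cell's ellipse,
# rejected until at least `min_sep` px from every position in `existing`
# (two diffraction-limited spots closer than ~2 FWHM are one focus to any
# detector, so the generator never plants them).
focus_position <- function(cell, existing = NULL, min_sep = 6) {
  for (i in 1:200) {
    repeat {
      u <- stats::runif(1, -0.6, 0.6); v <- stats::runif(1, -0.6, 0.6)
      if (u^2 + v^2 < 0.36) break
    }
    du <- u * cell$a_px; dv <- v * cell$b_px
    pos <- c(cell$row + du * cos(cell$theta) - dv * sin(cell$theta),
             cell$col + du * sin(cell$theta) + dv * cos(cell$theta))
    if (is.null(existing) || nrow(existing) == 0 ||
        all((existing[, 1] - pos[1])^2 + (existing[, 2] - pos[2])^2 >= min_sep^2))
      return(pos)
  }
  NULL   # cell too crowded; caller plants fewer foci there
}

#' Generate a synthetic phase-separated droplet field
#'
#' Circular liquid droplets on a uniform dilute-phase background, imitating a
#' confocal image of an in vitro phase separation reaction. The noiseless
#' interior intensity of droplet d in channel c is
#' `slope[c] * concentration[d, c] + intercept[c]`, and the background equals
#' `intercept[c]`, so intensities are on the same linear scale as the
#' matching calibration series.
#'
#' @param n_droplets number of droplets (non-overlapping discs).
#' @param radius_px_range uniform sampling range of droplet radii, pixels.
#' @param concentration_uM per-channel planted concentration(s), uM: a list
#'   with one entry per channel, each a scalar or a length-`n_droplets`
#'   vector.
#' @param slope,intercept calibration line per channel (counts/uM, counts);
#'   recycled across channels.
#' @param noise a [noise_spec()]; its `background_level` is ignored (the
#'   background is `intercept`).
#' @param field_size `c(height, width)` pixels.
#' @param pixel_size_um physical pixel size (default 0.18, confocal profile).
#' @param psf_sigma_px Gaussian blur sigma (0 = sharp discs).
#' @param channel_names labels, one per channel.
#' @param seed RNG seed.
#' @return `list(stack, truth)`; `truth$droplets` has one row per droplet
#'   (centre, radius, per-channel concentration).
#' @export
generate_droplet_image <- function(n_droplets = 30,
                                   radius_px_range = c(4, 10),
                                   concentration_uM = list(2),
                                   slope = 100, intercept = 50,
                                   noise = noise_spec(shot_noise = FALSE,
                                                      read_noise_sd = 0),
                                   field_size = c(256, 256),
                                   pixel_size_um = 0.18,
                                   psf_sigma_px = 0,
                                   channel_names = NULL,
                                   seed = 1L) {
  n_ch <- length(concentration_uM)
  slope <- rep_len(slope, n_ch); intercept <- rep_len(intercept, n_ch)
  if (is.null(channel_names))
    channel_names <- c("mCherry", "GFP", paste0("ch", seq_len(max(0, n_ch - 2)) + 2))[seq_len(n_ch)]
  conc <- vapply(concentration_uM, function(x) rep_len(as.numeric(x), max(n_droplets, 1)),
                 numeric(max(n_droplets, 1)))
  conc <- matrix(conc, nrow = max(n_droplets, 1))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  h <- field_size[1]; w <- field_size[2]
  with_seed(seed, {
    rmax <- max(radius_px_range)
    centres <- place_centres(n_droplets, h, w, min_sep = 2.2 * rmax,
                             margin = rmax + 2)
    radii <- if (n_droplets > 0)
      stats::runif(n_droplets, radius_px_range[1], radius_px_range[2]) else numeric(0)
    frames <- lapply(seq_len(n_ch), function(ch) {
      img <- matrix(intercept[ch], h, w)
      for (d in seq_len(n_droplets)) {
        idx <- ellipse_indices(h, w, centres[d, 1], centres[d, 2],
                               radii[d], radii[d], 0)
        img[idx] <- slope[ch] * conc[d, ch] + intercept[ch]
      }
      if (psf_sigma_px > 0) img <- as.matrix(EBImage::gblur(img, psf_sigma_px))
      apply_noise(img, noise)
    })
    droplets <- data.frame(
      droplet = seq_len(n_droplets),
      row = if (n_droplets) centres[, 1] else numeric(0),
      col = if (n_droplets) centres[, 2] else numeric(0),
      radius_px = radii)
    for (ch in seq_len(n_ch))
      droplets[[paste0("conc_", channel_names[ch])]] <-
        if (n_droplets) conc[seq_len(n_droplets), ch] else numeric(0)
    truth <- structure(
      list(cells = NULL, foci = NULL, droplets = droplets,
           calibration = data.frame(channel = channel_names,
                                    slope = slope, intercept = intercept),
           noise = noise, seed = seed, psf_sigma_px = psf_sigma_px),
      class = "ground_truth")
    list(stack = image_stack(frames, channel_names = channel_names,
                             pixel_size_um = pixel_size_um),
         truth = truth)
  })
}

#' Generate a fluorescence calibration series
#'
#' Homogeneous (spatially uniform) fields at known protein concentrations,
#' imitating the calibration acquisitions used to map droplet intensity to
#' concentration: each image is uniform at `slope * c + intercept` plus noise.
#'
#' @param concentrations vector of at least 2 distinct non-negative values, uM.
#' @param slope,intercept planted calibration line.
#' @param noise a [noise_spec()] (`background_level` unused).
#' @param field_size image dimensions.
#' @param pixel_size_um physical pixel size.
#' @param seed RNG seed.
#' @return list with one element per concentration:
#'   `list(stack, concentration, true_mean_intensity)`.
#' @export
generate_calibration_series <- function(concentrations, slope = 100,
                                        intercept = 50,
                                        noise = noise_spec(shot_noise = FALSE,
                                                           read_noise_sd = 0),
                                        field_size = c(128, 128),
                                        pixel_size_um = 0.18, seed = 1L) {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (length(unique(concentrations)) < 2)
    stop("need at least 2 distinct concentrations")
  with_seed(seed, {
    lapply(concentrations, function(cc) {
      mu <- slope * cc + intercept
      img <- apply_noise(matrix(mu, field_size[1], field_size[2]), noise)
      list(stack = image_stack(list(img), channel_names = "cal",
                               pixel_size_um = pixel_size_um),
           concentration = cc, true_mean_intensity = mu)
    })
  })
}

#' Generate a synthetic time lapse of focus formation/dissolution
#'
#' Cells are static across frames; at frame t each cell receives a Poisson
#' number of foci with mean `schedule[t]`, emulating the per-frame focus
#' counts behind stress/drug time courses.
#'
#' @param schedule per-frame expected foci per cell (length = number of
#'   frames), values >= 0.
#' @param n_cells number of cells.
#' @param noise,field_size,pixel_size_um,focus_amplitude,psf_sigma_px as in
#'   [generate_cell_field()].
#' @param seed RNG seed.
#' @return `list(stack, truth)`; the stack has 1 channel and
#'   `length(schedule)` timepoints, `truth$foci` carries a `frame` column.
#' @export
generate_timelapse <- function(schedule, n_cells = 20,
                               noise = noise_spec(), field_size = NULL,
                               pixel_size_um = 0.13, focus_amplitude = 400,
                               psf_sigma_px = 1.3, seed = 1L) {
  stopifnot(length(schedule) >= 1, all(schedule >= 0))
  base <- generate_cell_field(n_cells = n_cells, foci_per_cell = 0,
                              n_channels = 1, noise = noise_spec(
                                noise$background_level, 0, FALSE),
                              field_size = field_size,
                              pixel_size_um = pixel_size_um,
                              psf_sigma_px = psf_sigma_px, seed = seed)
  cells <- base$truth$cells
  blurred <- get_frame(base$stack, 1, 1)
  with_seed(derive_seed(seed, "timelapse"), {
    frames <- vector("list", length(schedule))
    foci_all <- list()
    for (t in seq_along(schedule)) {
      img <- blurred
      for (i in seq_len(n_cells)) {
        nf <- stats::rpois(1, schedule[t])
        placed <- matrix(numeric(0), 0, 2)
        for (j in seq_len(nf)) {
          pos <- focus_position(cells[i, ], placed)
          if (is.null(pos)) break
          placed <- rbind(placed, pos)
          amp <- focus_amplitude * max(stats::rnorm(1, 1, 0.2), 0.3)
          img <- add_gaussian_spot(img, pos[1], pos[2], amp,
                                   max(psf_sigma_px, 1))
          foci_all[[length(foci_all) + 1L]] <- data.frame(
            frame = t, row = pos[1], col = pos[2], channel = 1L,
            amplitude = amp, sigma_px = max(psf_sigma_px, 1), cell = i)
        }
      }
      frames[[t]] <- apply_noise(img, noise)
    }
    foci <- if (length(foci_all)) do.call(rbind, foci_all) else
      data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                 channel = integer(0), amplitude = numeric(0),
                 sigma_px = numeric(0), cell = integer(0))
    truth <- structure(
      list(cells = cells, foci = foci, droplets = NULL, calibration = NULL,
           noise = noise, seed = seed, schedule = schedule,
           psf_sigma_px = psf_sigma_px),
      class = "ground_truth")
    list(stack = image_stack(frames, channel_names = "GFP",
                             pixel_size_um = pixel_size_um,
                             time_interval_s = 60),
         truth = truth)
  })
}
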