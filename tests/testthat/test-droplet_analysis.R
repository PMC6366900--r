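test_that("blank fields segment to zero droplets", {
  st <- image_stack(list(matrix(50, 64, 64)), channel_names = "mCherry",
                    pixel_size_um = 0.18)
  seg <- segment_droplets(st)
  expect_equal(nrow(seg$records), 0)
  expect_equal(droplet_metric(seg$records, "mCherry"), 0)
})

test_that("planted discs are segmented with faithful areas", {
  sim <- generate_droplet_image(n_droplets = 12, radius_px_range = c(5, 9),
                                concentration_uM = list(2), slope = 100,
                                intercept = 50, field_size = c(320, 320),
                                seed = 61)
  seg <- segment_droplets(sim$stack)
  expect_equal(nrow(seg$records), 12)
  tr <- sim$truth$droplets
  lab_at <- seg$labels[cbind(round(tr$row), round(tr$col))]
  expect_true(all(lab_at > 0))
  for (i in seq_len(12)) {
    planted <- pi * tr$radius_px[i]^2
    expect_lt(abs(seg$records$area_px[lab_at[i]] - planted) / planted, 0.10)
  }
  # equivalent diameter identity
  expect_equal(seg$records$equivalent_diameter_um,
               2 * sqrt(seg$records$area_um2 / pi))
})

test_that("components below the minimum area are discarded", {
  img <- matrix(50, 64, 64)
  img[30:31, 30:31] <- 500            # 4 px, below default min 9
  img[10:14, 10:14] <- 500            # 25 px, kept
  st <- image_stack(list(img), channel_names = "a", pixel_size_um = 0.18)
  seg <- segment_droplets(st, threshold_method = "fixed:200")
  expect_equal(nrow(seg$records), 1)
  expect_equal(seg$records$area_px, 25)
})

test_that("diagonally-touching foreground is one 8-connected droplet", {
  img <- matrix(0, 20, 20)
  img[cbind(5:10, 5:10)] <- 10      # pure diagonal line
  img[cbind(5:10, 6:11)] <- 10
  st <- image_stack(list(img), channel_names = "a", pixel_size_um = 0.18)
  seg <- segment_droplets(st, threshold_method = "fixed:5",
                          min_droplet_area_px = 1)
  expect_equal(nrow(seg$records), 1)
})

test_that("the area-times-intensity metric is linear and additive", {
  rec <- data.frame(label = 1L, area_px = 50,
                    mean_intensity_mCherry = 200)
  expect_equal(droplet_metric(rec, "mCherry"), 10000)
  rec2 <- rec; rec2$mean_intensity_mCherry <- 400
  expect_equal(droplet_metric(rec2, "mCherry"),
               2 * droplet_metric(rec, "mCherry"))

  # additivity over disjoint fields
  sims <- lapply(1:3, function(s)
    generate_droplet_image(n_droplets = 6, concentration_uM = list(2),
                           field_size = c(200, 200), seed = 70 + s))
  parts <- vapply(sims, function(s)
    droplet_metric(segment_droplets(s$stack)$records, "mCherry"), numeric(1))
  pooled <- do.call(rbind, lapply(sims, function(s)
    segment_droplets(s$stack)$records))
  expect_equal(droplet_metric(pooled, "mCherry"), sum(parts))
})

test_that("metric normalization maps the reference to one", {
  expect_equal(normalize_metric(c(5, 10), 5), c(1, 2))
  expect_equal(normalize_metric(7, 7), 1)
  expect_error(normalize_metric(c(1, 2), 0), "reference_value")
})

test_that("calibration fits are exact on collinear data and accurate under noise", {
  fit <- fit_calibration(c(0, 1, 2), c(5, 15, 25))
  expect_equal(fit$slope, 10)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "distinct")

  set.seed(26)
  cc <- seq(0, 7)
  for (i in 1:5) {
    y <- 100 * cc + 50 + stats::rnorm(8, 0, 1)
    f <- fit_calibration(cc, y)
    expect_lt(abs(f$slope - 100) / 100, 0.03)
  }
})

test_that("concentration inversion is the inverse of the fitted line", {
  curve <- fit_calibration(c(0, 5, 10, 20), c(10, 20, 30, 50))
  expect_equal(curve$slope, 2)
  cc <- droplet_concentration(30, curve)
  expect_equal(cc$concentration_uM, 10)
  expect_false(cc$extrapolated)
  expect_equal(droplet_concentration(10, curve)$concentration_uM, 0)
  expect_true(droplet_concentration(100, curve)$extrapolated)
  # forward-inverse identity across the range
  conc <- c(0, 1.3, 7.7, 20)
  expect_equal(droplet_concentration(curve$slope * conc + curve$intercept,
                                     curve)$concentration_uM, conc)
})

test_that("simulate-measure-invert returns the planted concentration", {
  val <- pbquant:::calibration_roundtrip(conc = 2, seed = 81)
  expect_lt(abs(val - 2) / 2, 0.05)
})

test_that("planted stoichiometric ratios are recovered", {
  # noiseless: exact
  iv0 <- pbquant:::invitro_ratio_experiment(rho = 2.7, n_droplets = 20,
                                            noise_frac = 0, seed = 82)
  expect_lt(abs(iv0 - 2.7), 1e-6)
  # 5% noise: within 10%
  iv <- pbquant:::invitro_ratio_experiment(rho = 2.0, n_droplets = 50,
                                           noise_frac = 0.05, seed = 83)
  expect_lt(abs(iv - 2.0) / 2.0, 0.1)
})

test_that("droplet stoichiometry excludes non-positive denominators", {
  rec <- data.frame(label = 1:3, area_px = 20,
                    mean_intensity_a = c(200, 100, 300),
                    mean_intensity_b = c(100, -5, 100))
  cv <- function(s) structure(list(slope = s, intercept = 0, r_squared = 1,
                                   n_points = 2, concentration_range = c(0, 10)),
                              class = "calibration_curve")
  st <- droplet_stoichiometry(rec, cv(100), cv(100), "a", "b")
  expect_equal(st$n, 2)
  expect_equal(st$n_excluded, 1)
  expect_equal(st$ratios, c(2, 3))
  one <- droplet_stoichiometry(rec[1, ], cv(100), cv(100), "a", "b")
  expect_equal(one$mean_ratio, 2)
  expect_equal(one$sd_ratio, 0)
})

test_that("size distributions bin half-open and conserve counts", {
  rec <- data.frame(equivalent_diameter_um = c(1.0, 1.4, 2.1))
  h <- size_distribution(rec, 1)
  expect_equal(h$count, c(2, 1))
  expect_equal(h$bin_lo_um, c(1, 2))
  expect_equal(nrow(size_distribution(rec[0, , drop = FALSE], 1)), 0)

  set.seed(27)
  d <- stats::rlnorm(200, log(1.5), 0.3)
  h2 <- size_distribution(data.frame(equivalent_diameter_um = d), 0.25)
  expect_equal(sum(h2$count), 200)
  hist_mean <- sum((h2$bin_lo_um + 0.125) * h2$count) / 200
  expect_lt(abs(hist_mean - mean(d)) / mean(d), 0.1)
})

test_that("raising a fixed threshold never grows droplet areas", {
  sim <- generate_droplet_image(n_droplets = 8, concentration_uM = list(2),
                                noise = noise_spec(0, 5, FALSE),
                                psf_sigma_px = 1, field_size = c(240, 240),
                                seed = 84)
  prev <- NULL
  for (thr in c(80, 120, 160, 200)) {
    seg <- segment_droplets(sim$stack,
                            threshold_method = paste0("fixed:", thr),
                            min_droplet_area_px = 1)
    tot <- sum(seg$records$area_px)
    if (!is.null(prev)) expect_lte(tot, prev)
    prev <- tot
  }
})
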