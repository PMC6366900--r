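test_that("empty scenes are uniform background", {
  sim <- generate_cell_field(n_cells = 0, noise = noise_spec(100, 0, FALSE),
                             field_size = c(64, 64), n_channels = 1, seed = 1)
  expect_true(all(get_frame(sim$stack, 1, 1) == 100))
  expect_equal(nrow(sim$truth$cells), 0)

  d0 <- generate_droplet_image(n_droplets = 0, intercept = 50,
                               field_size = c(64, 64), seed = 1)
  expect_true(all(get_frame(d0$stack, 1, 1) == 50))
})

test_that("planted bookkeeping matches requested parameters", {
  sim <- generate_cell_field(n_cells = 5, foci_per_cell = 2,
                             coloc_fraction = 1, n_channels = 2, seed = 3)
  expect_equal(nrow(sim$truth$cells), 5)
  expect_equal(sum(sim$truth$foci$channel == 1), 10)
  expect_equal(sum(sim$truth$foci$channel == 2), 10)
  expect_true(all(!is.na(sim$truth$foci$pair)))
  # every focus lies strictly inside its cell's ellipse
  for (i in seq_len(nrow(sim$truth$foci))) {
    f <- sim$truth$foci[i, ]
    cl <- sim$truth$cells[f$cell, ]
    dr <- f$row - cl$row; dc <- f$col - cl$col
    u <- dr * cos(cl$theta) + dc * sin(cl$theta)
    v <- -dr * sin(cl$theta) + dc * cos(cl$theta)
    expect_lt((u / cl$a_px)^2 + (v / cl$b_px)^2, 1)
  }
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_cell_field(n_cells = 4, foci_per_cell = 2, seed = 11)
  b <- generate_cell_field(n_cells = 4, foci_per_cell = 2, seed = 11)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$foci, b$truth$foci)
  c <- generate_cell_field(n_cells = 4, foci_per_cell = 2, seed = 12)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("droplet interiors follow the planted linear intensity model", {
  sim <- generate_droplet_image(n_droplets = 1, radius_px_range = c(8, 8),
                                concentration_uM = list(2), slope = 100,
                                intercept = 50, psf_sigma_px = 0,
                                field_size = c(96, 96), seed = 2)
  img <- get_frame(sim$stack, 1, 1)
  tr <- sim$truth$droplets
  centre_val <- img[round(tr$row), round(tr$col)]
  expect_equal(centre_val, 100 * 2 + 50)
  expect_equal(img[1, 1], 50)
  expect_error(generate_droplet_image(n_droplets = 1,
                                      concentration_uM = list(-1)),
               "concentrations")
})

test_that("planted per-droplet channel ratios are exact in the ground truth", {
  sim <- generate_droplet_image(n_droplets = 12,
                                concentration_uM = list(5.4, 2),
                                slope = c(100, 120), intercept = c(50, 40),
                                field_size = c(300, 300), seed = 5)
  r <- sim$truth$droplets$conc_mCherry / sim$truth$droplets$conc_GFP
  expect_equal(r, rep(2.7, 12))
})

test_that("calibration series are uniform at slope*c + intercept", {
  cal <- generate_calibration_series(c(0, 1, 2), slope = 10, intercept = 5,
                                     noise = noise_spec(0, 0, FALSE),
                                     field_size = c(32, 32), seed = 1)
  means <- vapply(cal, function(x) mean(get_frame(x$stack, 1, 1)), numeric(1))
  expect_equal(means, c(5, 15, 25))
  expect_error(generate_calibration_series(c(2, 2), 10, 5), "distinct")

  # sample mean of a noisy 256x256 field is within 12 standard errors
  cal2 <- generate_calibration_series(c(0, 2), slope = 10, intercept = 5,
                                      noise = noise_spec(0, 1, FALSE),
                                      field_size = c(256, 256), seed = 4)
  expect_lt(abs(mean(get_frame(cal2[[2]]$stack, 1, 1)) - 25), 0.05)
})

test_that("noiseless unblurred scene conserves planted total intensity", {
  sim <- generate_cell_field(n_cells = 4, foci_per_cell = 2, n_channels = 1,
                             noise = noise_spec(100, 0, FALSE),
                             psf_sigma_px = 0, seed = 6)
  img <- get_frame(sim$stack, 1, 1)
  cells <- sim$truth$cells
  foci <- sim$truth$foci
  expected <- 100 * length(img) +
    sum((cells$interior_level - 100) * cells$area_px) +
    sum(2 * pi * foci$amplitude * foci$sigma_px^2)
  expect_lt(abs(sum(img) - expected) / expected, 0.005)
})

test_that("brightest pixel of an isolated focus sits at its planted centre", {
  sim <- generate_cell_field(n_cells = 1, foci_per_cell = 1, n_channels = 1,
                             noise = noise_spec(100, 0, FALSE), seed = 8)
  img <- get_frame(sim$stack, 1, 1)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  f <- sim$truth$foci
  expect_lt(sqrt((pk[1] - f$row)^2 + (pk[2] - f$col)^2), 1.01)
})

test_that("time lapses follow the per-frame focus schedule", {
  tl0 <- generate_timelapse(schedule = c(0, 0, 0), n_cells = 5, seed = 1)
  expect_equal(nrow(tl0$truth$foci), 0)
  expect_equal(n_timepoints(tl0$stack), 3)

  tl <- generate_timelapse(schedule = rep(2, 20), n_cells = 50, seed = 2)
  per_cell <- nrow(tl$truth$foci) / (50 * 20)
  expect_lt(abs(per_cell - 2), 0.2)
})

test_that("increasing schedules give non-decreasing expected focus totals", {
  sched <- c(0.3, 1, 2.5)
  totals <- matrix(0, 25, length(sched))
  for (s in 1:25) {
    tl <- generate_timelapse(schedule = sched, n_cells = 8, seed = s)
    totals[s, ] <- vapply(seq_along(sched),
                          function(t) sum(tl$truth$foci$frame == t), numeric(1))
  }
  m <- colMeans(totals)
  expect_true(all(diff(m) > 0))
})

test_that("overfull fields fail placement cleanly", {
  expect_error(generate_cell_field(n_cells = 60, field_size = c(100, 100),
                                   seed = 1),
               "field too small")
})
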