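test_that("flat fields yield no local maxima", {
  expect_equal(nrow(detect_local_maxima(matrix(5, 30, 30))), 0)
})

test_that("a single planted spot gives one candidate at its centre", {
  img <- matrix(100, 41, 41)
  img <- pbquant:::add_gaussian_spot(img, 20.6, 22.3, 400, 1.3)
  cand <- detect_local_maxima(img, 2)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand[1, 1] - 20.6)^2 + (cand[1, 2] - 22.3)^2), 1.01)
})

test_that("local maxima agree with the all-pairs brute-force oracle", {
  set.seed(7)
  for (i in 1:8) {
    img <- matrix(stats::runif(1600), 40, 40)
    r <- sample(c(1, 2, 3), 1)
    expect_equal(unname(detect_local_maxima(img, r)),
                 unname(oracle_local_maxima(img, r)))
  }
  # plateau: two equal maxima within the radius collapse to the smaller (row, col)
  img <- matrix(0, 20, 20)
  img[10, 10] <- 5; img[10, 11] <- 5
  cand <- detect_local_maxima(img, 2)
  expect_equal(unname(cand), matrix(c(10L, 10L), 1, 2), ignore_attr = TRUE)
})

test_that("focus measurement follows the disc/annulus recipe", {
  u <- matrix(100, 31, 31)
  m0 <- measure_focus(u, c(16, 16), 3, 4, 7)
  expect_equal(m0$peak_intensity, 100)
  expect_equal(m0$background, 100)
  expect_equal(m0$contrast, 0)
  expect_equal(m0$integrated_intensity, 0)

  # 13-pixel disc (d^2 < 4.41) raised by 5 counts on background 100
  img <- matrix(100, 31, 31)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[offs$dr^2 + offs$dc^2 < 4.41, ]
  img[cbind(16 + offs$dr, 16 + offs$dc)] <- 105
  m <- measure_focus(img, c(16, 16), 2.1, 4, 7)
  expect_equal(m$contrast, 0.05)
  expect_equal(m$integrated_intensity, 65)

  # annulus clipped by the border is flagged
  mb <- measure_focus(u, c(3, 3), 2, 3, 5)
  expect_true(mb$border)
})

test_that("integrated intensity matches the Gaussian integral", {
  img <- matrix(50, 41, 41)
  img <- pbquant:::add_gaussian_spot(img, 21, 21, 300, 1.0)
  m <- measure_focus(img, c(21, 21), 3.5, 5, 8)
  expect_lt(abs(m$integrated_intensity - 2 * pi * 300 * 1^2) /
              (2 * pi * 300), 0.02)
})

test_that("the 5% contrast boundary is inclusive", {
  mk <- function(level) {
    img <- matrix(100, 31, 31)
    offs <- expand.grid(dr = -2:2, dc = -2:2)
    offs <- offs[offs$dr^2 + offs$dc^2 < 4.41, ]
    img[cbind(16 + offs$dr, 16 + offs$dc)] <- level
    img
  }
  cand <- matrix(c(16L, 16L), 1, 2)
  kept <- filter_foci(cand, mk(105), intensity_min = 0, contrast_min = 0.05,
                      r_int_px = 2.1, r_bg_in_px = 4, r_bg_out_px = 7)
  expect_equal(nrow(kept), 1)   # contrast exactly 0.05 retained
  rejected <- filter_foci(cand, mk(104.9), intensity_min = 0,
                          contrast_min = 0.05, r_int_px = 2.1,
                          r_bg_in_px = 4, r_bg_out_px = 7)
  expect_equal(nrow(rejected), 0)  # contrast 0.049 rejected
})

test_that("planted foci are recovered without extras at high SNR", {
  sim <- generate_cell_field(n_cells = 5, foci_per_cell = 2, n_channels = 1,
                             seed = 31)
  f <- detect_foci(get_frame(sim$stack, 1, 1), default_config())
  mt <- match_truth(f, sim$truth$foci)
  expect_equal(mt$recall, 1)
  expect_equal(mt$precision, 1)
})

test_that("a focus-free low-noise field yields zero retained foci", {
  sim <- generate_cell_field(n_cells = 5, foci_per_cell = 0, n_channels = 1,
                             noise = noise_spec(100, 2, FALSE), seed = 32)
  f <- detect_foci(get_frame(sim$stack, 1, 1), default_config())
  expect_equal(nrow(f), 0)
})

test_that("raising thresholds never increases the retained count", {
  sim <- generate_cell_field(n_cells = 4, foci_per_cell = 3, n_channels = 1,
                             seed = 33)
  img <- get_frame(sim$stack, 1, 1)
  cand <- detect_local_maxima(img, 2)
  prev <- Inf
  for (cmin in c(0, 0.05, 0.2, 0.5, 1)) {
    n <- nrow(filter_foci(cand, img, intensity_min = 0, contrast_min = cmin))
    expect_lte(n, prev); prev <- n
  }
  prev <- Inf
  for (imin in c(0, 150, 300, 500, 800)) {
    n <- nrow(filter_foci(cand, img, intensity_min = imin, contrast_min = 0))
    expect_lte(n, prev); prev <- n
  }
})

test_that("channel matching is one-to-one, symmetric, and bounded by d_max", {
  empty <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0))
  one <- data.frame(centroid_row = 10, centroid_col = 10)
  expect_equal(nrow(match_foci_channels(empty, one, 0.25, 0.13)), 0)
  m1 <- match_foci_channels(one, one, 0.25, 0.13)
  expect_equal(m1$distance_um, 0)

  set.seed(5)
  for (rep in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pa <- data.frame(centroid_row = stats::runif(na, 0, 40),
                     centroid_col = stats::runif(na, 0, 40))
    pb <- data.frame(centroid_row = stats::runif(nb, 0, 40),
                     centroid_col = stats::runif(nb, 0, 40))
    mm <- match_foci_channels(pa, pb, d_max_um = 1, pixel_size_um = 0.13)
    expect_equal(anyDuplicated(mm$a), 0)
    expect_equal(anyDuplicated(mm$b), 0)
    expect_true(all(mm$distance_um <= 1))
    sw <- match_foci_channels(pb, pa, d_max_um = 1, pixel_size_um = 0.13)
    expect_equal(nrow(sw), nrow(mm))
    expect_setequal(paste(mm$a, mm$b), paste(sw$b, sw$a))
  }
})

test_that("matching attains the exhaustive optimum on well-separated instances", {
  set.seed(9)
  agree <- 0; n_inst <- 12
  for (rep in 1:n_inst) {
    # 4 true pairs on a coarse grid (>= 3 d_max apart) with sub-d_max jitter,
    # plus an unpaired decoy in each channel
    centres <- cbind(sample(seq(5, 45, by = 10), 4),
                     sample(seq(5, 45, by = 10), 4))
    pa <- rbind(centres, c(60, 60))
    pb <- rbind(centres + matrix(stats::rnorm(8, 0, 0.4), 4, 2), c(70, 70))
    dmax_px <- 2
    mm <- match_foci_channels(
      data.frame(centroid_row = pa[, 1], centroid_col = pa[, 2]),
      data.frame(centroid_row = pb[, 1], centroid_col = pb[, 2]),
      d_max_um = dmax_px * 0.13, pixel_size_um = 0.13)
    opt <- oracle_match(pa, pb, dmax_px)
    same <- nrow(mm) == opt$n &&
      abs(sum(mm$distance_um) / 0.13 - opt$cost) < 1e-9
    if (same) agree <- agree + 1
    # greedy is always a valid one-to-one matching no better than the optimum
    expect_lte(nrow(mm), opt$n)
  }
  expect_gte(agree / n_inst, 0.95)
})

test_that("well-separated jittered pairs are all recovered among decoys", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 20
    base <- cbind(stats::runif(n, 10, 190), stats::runif(n, 10, 190))
    keep <- which(!duplicated(round(base / 8)))[seq_len(min(n, 15))]
    base <- base[keep, , drop = FALSE]
    jit <- base + matrix(stats::rnorm(length(base), 0, 0.5), ncol = 2)
    dec_a <- cbind(stats::runif(5, 200, 250), stats::runif(5, 200, 250))
    dec_b <- cbind(stats::runif(5, 260, 300), stats::runif(5, 260, 300))
    pa <- rbind(base, dec_a); pb <- rbind(jit, dec_b)
    mm <- match_foci_channels(
      data.frame(centroid_row = pa[, 1], centroid_col = pa[, 2]),
      data.frame(centroid_row = pb[, 1], centroid_col = pb[, 2]),
      d_max_um = 0.25, pixel_size_um = 0.13)
    expect_equal(nrow(mm), nrow(base))
    expect_true(all(mm$a == mm$b))   # true pairing recovered
  }
})

test_that("foci are assigned to the cells that contain them", {
  sim <- generate_cell_field(n_cells = 5, foci_per_cell = 2, n_channels = 1,
                             noise = noise_spec(100, 0, FALSE), seed = 35)
  img <- get_frame(sim$stack, 1, 1)
  cfg <- default_config()
  cfg$segmentation$magnitude_quantile <- 0.15  # clean image: no noise edges
  cfg$segmentation$min_votes <- 60
  lm <- segment_cells(img, cfg)
  f <- detect_foci(img, cfg)
  f <- assign_foci_to_cells(f, lm)
  expect_true(all(!is.na(f$cell_label)))
  # each focus's assigned segmented cell must contain its planting cell centre
  tr <- sim$truth$foci
  for (i in seq_len(nrow(f))) {
    j <- which.min((tr$row - f$centroid_row[i])^2 +
                     (tr$col - f$centroid_col[i])^2)
    cl <- sim$truth$cells[tr$cell[j], ]
    expect_equal(f$cell_label[i],
                 lm$labels[round(cl$row), round(cl$col)])
  }
  # background focus gets NA
  fb <- data.frame(centroid_row = 1.4, centroid_col = 1.4)
  expect_true(is.na(assign_foci_to_cells(fb, lm)$cell_label))
})

test_that("foci per cell divides counts and guards the zero-cell case", {
  expect_equal(foci_per_cell(12, 6), 2)
  expect_equal(foci_per_cell(0, 10), 0)
  expect_warning(r <- foci_per_cell(3, 0), "undefined")
  expect_true(is.na(r))
})
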