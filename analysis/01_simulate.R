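#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analyses: a
# two-channel yeast cell field with colocalized foci, a starvation-style
# time lapse, an in vitro droplet field with a planted 2.7:1 channel
# ratio, and a homogeneous calibration series. Images are written as
# 16-bit TIFF stacks with their ground truth alongside.

suppressMessages(library(pbquant))

outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

# two-channel cell field: 12 cells, 2 foci/cell, all colocalized, Dhh1-like
# channel twice as bright as the Pat1-like channel
cells <- generate_cell_field(n_cells = 12, foci_per_cell = 2,
                             channel_ratio = 2, coloc_fraction = 1,
                             n_channels = 2, seed = seed)
write_image_stack(cells$stack, file.path(outdir, "cell_field.tif"))
write_results_table(cells$truth$cells, file.path(outdir, "cell_field_cells.tsv"))
write_results_table(cells$truth$foci, file.path(outdir, "cell_field_foci.tsv"))
message("cell field: ", nrow(cells$truth$cells), " cells, ",
        nrow(cells$truth$foci), " planted foci")

# time lapse: focus formation then dissolution (e.g. stress then release)
tl <- generate_timelapse(schedule = c(0.2, 1, 2, 2, 0.5, 0), n_cells = 15,
                         seed = seed + 1L)
write_image_stack(tl$stack, file.path(outdir, "timelapse.tif"))
write_results_table(tl$truth$foci, file.path(outdir, "timelapse_foci.tsv"))
message("time lapse: 6 frames, schedule 0.2 -> 2 -> 0 foci/cell")

# droplet field at planted 2.7:1 concentration ratio (5.4 uM : 2 uM)
dr <- generate_droplet_image(n_droplets = 40,
                             concentration_uM = list(5.4, 2),
                             slope = c(100, 120), intercept = c(50, 40),
                             noise = noise_spec(0, 27, FALSE),
                             field_size = c(512, 512), seed = seed + 2L)
write_image_stack(dr$stack, file.path(outdir, "droplet_field.tif"))
write_results_table(dr$truth$droplets, file.path(outdir, "droplet_truth.tsv"))
message("droplet field: ", nrow(dr$truth$droplets),
        " droplets at planted ratio 2.7")

# calibration series for the mCherry-like channel
cal <- generate_calibration_series(c(0, 0.5, 1, 2, 4, 8), slope = 100,
                                   intercept = 50,
                                   noise = noise_spec(0, 1, FALSE),
                                   seed = seed + 3L)
caltab <- data.frame(
  concentration_uM = vapply(cal, `[[`, numeric(1), "concentration"),
  mean_intensity = vapply(cal, function(x) mean(get_frame(x$stack, 1, 1)),
                          numeric(1)))
write_results_table(caltab, file.path(outdir, "calibration_series.tsv"))
message("calibration series: ", nrow(caltab), " concentrations")
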