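test_that("noiseless traces place translocation peaks at the configured times", {
  cfg <- sim_config(seed = 1, n_cells = 5, noise_sd = 0,
                    oscillation = list(desync_sd_min = 0))
  sim <- simulate_ratio_traces(cfg)
  for (pt in sim$truth$peak_times_min)
    expect_equal(pt, c(30, 150, 270))
  # trace value at a true peak equals baseline + damped amplitude (up to
  # overlap with neighbouring bumps, negligible at 120-min spacing)
  i30 <- which(sim$traces$times == 30)
  expect_equal(sim$traces$values[1, i30], 2, tolerance = 1e-3)
})

test_that("treatment delay shifts every peak after the first", {
  cfg <- sim_config(seed = 1, n_cells = 4, noise_sd = 0,
                    oscillation = list(desync_sd_min = 0,
                                       treatment_delay_min = 26))
  sim <- simulate_ratio_traces(cfg)
  for (pt in sim$truth$peak_times_min) {
    expect_equal(pt[1], 30)
    expect_equal(pt[2], 176)
  }
})

test_that("trace simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_cells = 20)
  a <- simulate_ratio_traces(cfg)
  b <- simulate_ratio_traces(cfg)
  expect_identical(a$traces$values, b$traces$values)
  expect_identical(a$truth, b$truth)
})

test_that("true peak times are strictly increasing and within the movie", {
  cfg <- sim_config(seed = 9, n_cells = 50,
                    oscillation = list(desync_sd_min = 10))
  sim <- simulate_ratio_traces(cfg)
  for (pt in sim$truth$peak_times_min) {
    expect_true(all(diff(pt) > 0))
    expect_true(all(pt >= 0 & pt <= cfg$duration_min))
  }
})

test_that("non-finite oscillation parameters are rejected", {
  expect_error(sim_config(oscillation = list(amplitude = NaN)), "finite")
  expect_error(sim_config(oscillation = list(damping = 0)), "damping")
  expect_error(sim_config(frame_interval_min = 0), "frame_interval")
})

test_that("rendered nuclear/cytoplasmic ratio inverts to the input trace", {
  cfg <- sim_config(seed = 2, n_cells = 1, image_size = 64,
                    duration_min = 6, noise_sd = 0,
                    nucleus_radius_px = 8, ring_width_px = 4)
  tr <- ratio_traces(c(0, 6), matrix(2, 1, 2))
  st <- render_p65_stack(tr, cfg, poisson_noise = FALSE)
  img <- get_frame(st, "reporter", 1)
  ctr <- st$meta$centers
  d2 <- outer(seq_len(64), rep(1, 64)) * 0  # placeholder
  rows <- matrix(seq_len(64), 64, 64)
  cols <- t(rows)
  d2 <- (rows - ctr$row[1])^2 + (cols - ctr$col[1])^2
  nuc_mean <- mean(img[d2 <= 6^2]) - cfg$background_level
  ring_mean <- mean(img[d2 > 9^2 & d2 <= 12^2]) - cfg$background_level
  expect_equal(nuc_mean / ring_mean, 2, tolerance = 0.05)
})

test_that("rendering zero cells yields a blank stack", {
  cfg <- sim_config(seed = 2, n_cells = 0, image_size = 32, duration_min = 6)
  tr <- ratio_traces(c(0, 6), matrix(numeric(0), 0, 2))
  st <- render_p65_stack(tr, cfg, poisson_noise = FALSE)
  expect_true(all(st$channels$nuclei == cfg$background_level))
  expect_true(all(st$channels$reporter == cfg$background_level))
})

test_that("rendered non-overlapping nuclei match a flood-fill component count", {
  cfg <- sim_config(seed = 5, n_cells = 25, image_size = 256,
                    duration_min = 6, noise_sd = 0,
                    nucleus_radius_px = 6, ring_width_px = 3)
  sim <- simulate_ratio_traces(cfg)
  st <- render_p65_stack(sim$traces, cfg, poisson_noise = FALSE)
  for (f in 1:2) {
    bw <- get_frame(st, "nuclei", f) > cfg$background_level + 1
    expect_equal(flood_fill_components(bw), 25)
  }
})

test_that("Srxn1 stack is background-only when onset is beyond the movie", {
  cfg <- sim_config(seed = 3, n_cells = 4, image_size = 96,
                    frame_interval_min = 30, duration_min = 240,
                    noise_sd = 0, nucleus_radius_px = 4,
                    srxn1 = list(onset_min = 5000, onset_sd_min = 0,
                                 plateau = 600, rate = 2.5))
  sim <- simulate_srxn1_stack(cfg)
  rep_ch <- sim$stack$channels$reporter
  expect_lt(max(rep_ch) - cfg$background_level, 1)
})

test_that("noiseless Srxn1 end frame covers exactly the rendered cell area", {
  cfg <- sim_config(seed = 3, n_cells = 1, image_size = 64,
                    frame_interval_min = 30, duration_min = 1440,
                    noise_sd = 0, nucleus_radius_px = 5,
                    srxn1 = list(onset_min = 240, onset_sd_min = 0))
  sim <- simulate_srxn1_stack(cfg, cell_radius_px = 8)
  last <- get_frame(sim$stack, "reporter", n_frames(sim$stack))
  area <- sum(last > cfg$background_level + 1)
  # analytic disk area within pixel-discretisation error
  expect_equal(area, pi * 8^2, tolerance = 0.1)
})

test_that("two Srxn1 onset groups are recovered from the truth trajectories", {
  half_rise <- function(cfg) {
    sim <- simulate_srxn1_stack(cfg)
    times <- frame_times(cfg)
    mean(apply(sim$truth$trajectories, 1, function(tr)
      times[which.min(abs(tr - cfg$srxn1$plateau / 2))]))
  }
  base <- list(n_cells = 20, image_size = 512, frame_interval_min = 30,
               duration_min = 1440, noise_sd = 0, nucleus_radius_px = 4)
  fast <- do.call(sim_config, c(base, list(
    seed = 4, srxn1 = list(onset_min = 240, onset_sd_min = 30))))
  slow <- do.call(sim_config, c(base, list(
    seed = 5, srxn1 = list(onset_min = 960, onset_sd_min = 30))))
  expect_lt(abs(half_rise(fast) - 240), 30)
  expect_lt(abs(half_rise(slow) - 960), 30)
})

test_that("zero hazard produces no Annexin-positive pixels", {
  cfg <- sim_config(seed = 6, n_cells = 4, image_size = 96,
                    frame_interval_min = 30, duration_min = 240,
                    nucleus_radius_px = 4,
                    death = list(baseline_hazard_per_h = 0))
  sim <- simulate_death_series(cfg, with_tnf = TRUE)
  expect_true(all(is.na(sim$truth$death_time_min)))
  expect_true(all(sim$stack$channels$death <= cfg$background_level))
})

test_that("dead fraction follows exponential survival under constant hazard", {
  h <- 0.05  # per hour over 24 h: 1 - exp(-1.2) = 0.699
  cfg <- sim_config(seed = 7, n_cells = 900, image_size = 512,
                    frame_interval_min = 720, duration_min = 1440,
                    nucleus_radius_px = 2,
                    death = list(baseline_hazard_per_h = h,
                                 tnf_multiplier = 1))
  sim <- simulate_death_series(cfg, with_tnf = FALSE)
  frac <- mean(!is.na(sim$truth$death_time_min))
  expected <- 1 - exp(-h * 24)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 900))
})

test_that("a unit TNFa multiplier leaves death kinetics unchanged", {
  mk <- function(seed, with_tnf) {
    cfg <- sim_config(seed = seed, n_cells = 500, image_size = 512,
                      frame_interval_min = 720, duration_min = 1440,
                      nucleus_radius_px = 2,
                      death = list(baseline_hazard_per_h = 0.02,
                                   tnf_multiplier = 1, tnf_add_min = 480))
    sim <- simulate_death_series(cfg, with_tnf = with_tnf)
    !is.na(sim$truth$death_time_min)
  }
  dead_a <- mk(11, FALSE)
  dead_b <- mk(12, TRUE)
  p <- stats::prop.test(c(sum(dead_a), sum(dead_b)), c(500, 500))$p.value
  expect_gt(p, 0.01)
})

test_that("Annexin labelling is cumulative after death", {
  cfg <- sim_config(seed = 8, n_cells = 9, image_size = 160,
                    frame_interval_min = 60, duration_min = 1440,
                    nucleus_radius_px = 4,
                    death = list(baseline_hazard_per_h = 0.1))
  sim <- simulate_death_series(cfg)
  pos <- sapply(seq_len(n_frames(sim$stack)), function(f)
    sum(get_frame(sim$stack, "death", f) > cfg$background_level))
  expect_true(all(diff(pos) >= 0))
})

test_that("the DEG generator plants recoverable structure deterministically", {
  cfg <- sim_config(seed = 21)
  deg <- simulate_deg_table(cfg, n_genes_per_block = 10, n_background = 30)
  # same seed, byte-identical TSV
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_deg_table(deg$table, f1)
  write_deg_table(simulate_deg_table(cfg, n_genes_per_block = 10,
                                     n_background = 30)$table, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # severe hepatotoxicant signature: Nrf2 block up, NF-kB block down
  tab <- deg$table
  sev <- tab[tab$treatment == "dili_severe", ]
  expect_gt(mean(sev$log2fc[grepl("^NRF2T", sev$gene)]), 1)
  expect_lt(mean(sev$log2fc[grepl("^NFKBT", sev$gene)]), -1)
})

test_that("with zero planted effects almost nothing passes the filter", {
  cfg <- sim_config(seed = 22)
  deg <- simulate_deg_table(cfg, n_genes_per_block = 25, n_background = 150,
                            effect_nrf2 = 0, effect_nfkb = 0)
  kept <- suppressWarnings(
    filter_responsive(deg$table, unique(deg$table$gene), filter_spec(),
                      category = "oxidative"))
  expect_lt(length(kept), 0.05 * length(unique(deg$table$gene)))
})

test_that("stacks round-trip through 16-bit multi-page TIFF", {
  cfg <- sim_config(seed = 2, n_cells = 4, image_size = 96, duration_min = 12,
                    noise_sd = 0, nucleus_radius_px = 5, ring_width_px = 3)
  sim <- simulate_ratio_traces(cfg)
  st <- render_p65_stack(sim$traces, cfg, poisson_noise = FALSE)
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(st, f)
  back <- read_stack_tiff(f, c("nuclei", "reporter"),
                          frame_interval_min = cfg$frame_interval_min)
  expect_equal(n_frames(back), n_frames(st))
  expect_equal(back$channels$reporter, round(st$channels$reporter),
               tolerance = 1e-6)
})
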