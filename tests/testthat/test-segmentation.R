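test_that("blank or constant images segment to zero labels", {
  expect_equal(max(segment_nuclei(matrix(0, 32, 32))), 0)
  expect_equal(max(segment_nuclei(matrix(7.5, 32, 32))), 0)
})

test_that("well-separated disks yield one label each with accurate centroids", {
  img <- matrix(100, 64, 64)
  img <- draw_disk(img, 16, 16, 6, 600)
  img <- draw_disk(img, 45, 48, 6, 600)
  labels <- segment_nuclei(img, min_area_px = 20)
  cen <- label_centroids(labels)
  expect_equal(nrow(cen), 2)
  cen <- cen[order(cen$row), ]
  expect_lt(abs(cen$row[1] - 16), 1)
  expect_lt(abs(cen$col[1] - 16), 1)
  expect_lt(abs(cen$row[2] - 45), 1)
  expect_lt(abs(cen$col[2] - 48), 1)
})

test_that("watershed splits overlapping nuclei that flood fill merges", {
  img <- matrix(100, 64, 64)
  r <- 8
  # centres 1.7 r apart: overlap ~30% of the radius
  img <- draw_disk(img, 32, 24, r, 600)
  img <- draw_disk(img, 32, 24 + round(1.7 * r), r, 600)
  bw <- img > 300
  expect_equal(flood_fill_components(bw), 1)  # touching: one component
  labels <- segment_nuclei(img, min_area_px = 20)
  expect_equal(max(labels), 2)
})

test_that("small components are removed and labels renumbered", {
  img <- matrix(100, 48, 48)
  img <- draw_disk(img, 12, 12, 6, 600)   # area ~113
  img <- draw_disk(img, 36, 36, 2, 600)   # area ~13, below min
  labels <- segment_nuclei(img, min_area_px = 30)
  expect_equal(sort(unique(as.vector(labels))), c(0, 1))
})

test_that("cytoplasmic ring area matches the analytic annulus", {
  labels <- matrix(0L, 64, 64)
  idx <- which((matrix(seq_len(64), 64, 64) - 32)^2 +
                 (t(matrix(seq_len(64), 64, 64)) - 32)^2 <= 10^2)
  labels[idx] <- 1L
  ring <- segment_cytoplasm(labels, ring_width_px = 5)
  analytic <- pi * ((10 + 5)^2 - 10^2)
  expect_equal(sum(ring == 1), analytic, tolerance = 0.15)
  expect_true(all(ring[labels == 1] == 0))  # ring excludes the nucleus
})

test_that("rings of adjacent nuclei partition the shared territory", {
  img <- matrix(100, 64, 64)
  img <- draw_disk(img, 32, 22, 7, 600)
  img <- draw_disk(img, 32, 42, 7, 600)
  labels <- segment_nuclei(img, min_area_px = 20)
  ring <- segment_cytoplasm(labels, ring_width_px = 6)
  # disjoint by construction (single label per pixel); both rings present
  expect_setequal(setdiff(unique(as.vector(ring)), 0), 1:2)
  # no ring pixel on any nucleus
  expect_true(all(ring[labels > 0] == 0))
})

test_that("ring width zero flags downstream ratios as missing", {
  img <- matrix(100, 48, 48)
  img <- draw_disk(img, 24, 24, 7, 600)
  labels <- segment_nuclei(img, min_area_px = 20)
  ring <- segment_cytoplasm(labels, ring_width_px = 0)
  expect_true(all(ring == 0))
  stack <- timelapse_stack(list(reporter = array(img, c(48, 48, 1))), 6)
  track <- data.frame(track_id = 1L, frame = 1L, label = 1L,
                      row = 24, col = 24)
  m <- measure_ratio(track, stack, list(labels), list(ring))
  expect_true(is.na(m$ratio))
})

static_label_movie <- function(n_frames, drift = 0) {
  lapply(seq_len(n_frames), function(f) {
    img <- matrix(100, 72, 72)
    img <- draw_disk(img, 18, 18 + (f - 1) * drift, 6, 600)
    img <- draw_disk(img, 50, 40 + (f - 1) * drift, 6, 600)
    segment_nuclei(img, min_area_px = 20)
  })
}

test_that("static nuclei give one full-length track each", {
  tracks <- track_nuclei(static_label_movie(6), max_disp_px = 10)
  expect_equal(length(unique(tracks$track_id)), 2)
  expect_true(all(table(tracks$track_id) == 6))
})

test_that("drifting nuclei stay on their tracks under a generous gate", {
  tracks <- track_nuclei(static_label_movie(6, drift = 2), max_disp_px = 10)
  expect_equal(length(unique(tracks$track_id)), 2)
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    expect_equal(tr$frame, 1:6)
    expect_true(all(diff(tr$col) > 0))  # follows the drift
  }
})

test_that("a disappearing nucleus ends its track at last detection", {
  movie <- static_label_movie(6)
  # remove the first nucleus from frames 4..6
  for (f in 4:6) {
    lab <- movie[[f]]
    cen <- label_centroids(lab)
    drop <- cen$label[which.min(cen$row)]
    lab[lab == drop] <- 0L
    movie[[f]] <- lab
  }
  tracks <- track_nuclei(movie, max_disp_px = 10, min_coverage = 0)
  lens <- sort(as.integer(table(tracks$track_id)))
  expect_equal(lens, c(3L, 6L))
})

test_that("no label is claimed by two tracks in one frame", {
  movie <- static_label_movie(6, drift = 1)
  tracks <- track_nuclei(movie, max_disp_px = 10, min_coverage = 0)
  key <- paste(tracks$frame, tracks$label)
  expect_false(any(duplicated(key)))
  # all referenced labels exist
  for (i in seq_len(nrow(tracks)))
    expect_true(tracks$label[i] %in% movie[[tracks$frame[i]]])
})

test_that("measured ratios follow the background-subtracted level ratio", {
  labels <- matrix(0L, 48, 48)
  labels <- draw_disk(labels, 24, 24, 7, 1L)
  ring <- segment_cytoplasm(labels, ring_width_px = 4)
  track <- data.frame(track_id = 1L, frame = 1L, label = 1L,
                      row = 24, col = 24)
  # uniform image: after background subtraction the cytoplasm level is 0,
  # so the ratio is undefined by design
  st1 <- timelapse_stack(list(reporter = array(50, c(48, 48, 1))), 6)
  m1 <- measure_ratio(track, st1, list(labels), list(ring))
  expect_true(is.na(m1$ratio))
  # equal nucleus and cytoplasm levels above background: ratio 1
  img <- matrix(100, 48, 48)
  img[ring == 1] <- 100 + 200
  img[labels == 1] <- 100 + 200
  st <- timelapse_stack(list(reporter = array(img, c(48, 48, 1))), 6)
  expect_equal(measure_ratio(track, st, list(labels), list(ring))$ratio, 1,
               tolerance = 1e-6)
  # nucleus 2x the cytoplasm above background: ratio 2
  img[labels == 1] <- 100 + 400
  st2 <- timelapse_stack(list(reporter = array(img, c(48, 48, 1))), 6)
  m2 <- measure_ratio(track, st2, list(labels), list(ring))
  expect_equal(m2$ratio, 2, tolerance = 1e-6)
})

test_that("render -> segment -> track -> measure recovers the input traces", {
  cfg <- sim_config(seed = 13, n_cells = 9, image_size = 176,
                    duration_min = 120, noise_sd = 0.05,
                    nucleus_radius_px = 8, ring_width_px = 4)
  sim <- simulate_ratio_traces(cfg)
  st <- render_p65_stack(sim$traces, cfg)
  tr <- extract_ratio_traces(st, ring_width_px = cfg$ring_width_px)
  expect_equal(nrow(tr$values), 9)
  err <- vapply(seq_len(nrow(tr$values)), function(i)
    min(rowMeans(abs(sweep(sim$traces$values, 2, tr$values[i, ], "-")),
                 na.rm = TRUE)), numeric(1))
  expect_lt(mean(err), 0.1 * mean(sim$traces$values))
})
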