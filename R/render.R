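#' Time-lapse image stack
#'
#' Multi-channel time-lapse container. Channels are stored as numeric arrays
#' `dim = c(rows, cols, frames)` under role names (`nuclei`, `reporter`,
#' `death`, `transmission`). Frame 0 corresponds to `t0_min` minutes after
#' stimulation (0 = time of TNFa addition for the p65 assay).
#'
#' @param channels named list of 3-d arrays with identical dimensions.
#' @param frame_interval_min minutes between frames (> 0).
#' @param t0_min time of the first frame, minutes after stimulation.
#' @param meta optional list of generator metadata (e.g. cell centres).
#' @return A `timelapse_stack` object.
#' @export
timelapse_stack <- function(channels, frame_interval_min, t0_min = 0,
                            meta = list()) {
  if (length(channels) < 1 || is.null(names(channels)))
    stop("timelapse_stack: channels must be a named list")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stop("timelapse_stack: each channel must be a rows x cols x frames array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("timelapse_stack: all channels must share dimensions")
  if (dims[[1]][3] < 1) stop("timelapse_stack: need >= 1 frame")
  if (frame_interval_min <= 0)
    stop("timelapse_stack: frame_interval_min must be > 0")
  structure(list(channels = channels,
                 frame_interval_min = frame_interval_min,
                 t0_min = t0_min, meta = meta),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("timelapse_stack:", d[1], "x", d[2], "px,", d[3], "frames every",
      x$frame_interval_min, "min; channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `timelapse_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$channels[[1]])[3]

#' Frame times of a stack, minutes after stimulation
#' @param stack a `timelapse_stack`.
#' @return Numeric vector of length [n_frames()].
#' @export
stack_times <- function(stack) {
  stack$t0_min + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval_min
}

#' Extract one channel frame
#' @param stack a `timelapse_stack`.
#' @param channel channel role name.
#' @param frame 1-based frame index.
#' @return Numeric matrix.
#' @export
get_frame <- function(stack, channel, frame) {
  if (!channel %in% names(stack$channels))
    stop("get_frame: no channel '", channel, "'")
  stack$channels[[channel]][, , frame]
}

# Deterministic non-overlapping cell placement on a jittered grid.
# Returns data.frame(row, col) of centres; errors if cells cannot fit.
place_cells <- function(n_cells, image_size, cell_radius, jitter_frac = 0.25) {
  if (n_cells == 0)
    return(data.frame(row = numeric(0), col = numeric(0)))
  side <- ceiling(sqrt(n_cells))
  spacing <- image_size / side
  max_jit <- jitter_frac * spacing / 2
  if (spacing / 2 - max_jit < cell_radius + 1)
    stop("place_cells: cells exceed image bounds; reduce n_cells or radii")
  idx <- seq_len(n_cells) - 1L
  gr <- idx %/% side
  gc <- idx %% side
  jit_r <- stats::runif(n_cells, -max_jit, max_jit)
  jit_c <- stats::runif(n_cells, -max_jit, max_jit)
  data.frame(row = (gr + 0.5) * spacing + jit_r,
             col = (gc + 0.5) * spacing + jit_c)
}

# Pixel indices (into an n x n matrix) of a disk / annulus around a centre.
disk_idx <- function(centre_row, centre_col, r_outer, image_size,
                     r_inner = -1) {
  rr <- max(1L, floor(centre_row - r_outer)):min(image_size, ceiling(centre_row + r_outer))
  cc <- max(1L, floor(centre_col - r_outer)):min(image_size, ceiling(centre_col + r_outer))
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - centre_row)^2 + (g$col - centre_col)^2
  keep <- d2 <= r_outer^2 & d2 > r_inner^2
  (g$col[keep] - 1L) * image_size + g$row[keep]
}

#' Render a GFP-p65 two-channel stack from ratio traces
#'
#' Draws each cell as a nuclear disk (nuclei channel) surrounded by a
#' cytoplasmic ring (reporter channel). The cytoplasmic reporter intensity is
#' held constant while the nuclear reporter intensity scales with the input
#' trace, so the rendered nuclear:cytoplasmic ratio above background equals
#' the trace value exactly at zero noise. Cells are placed on a jittered grid
#' with no overlap.
#'
#' @param traces a [ratio_traces()] collection.
#' @param cfg the [sim_config()] used to generate the traces.
#' @param cyto_level cytoplasmic reporter intensity above background.
#' @param nuclei_level Hoechst nuclear intensity above background.
#' @param poisson_noise if `TRUE`, pixel values are Poisson draws around their
#'   noiseless means (shot noise); if `FALSE` the rendering is exact.
#' @return A `timelapse_stack` with `nuclei` and `reporter` channels;
#'   `meta$centers` holds the true cell centres and `meta$cell_ids` their
#'   trace row indices.
#' @export
render_p65_stack <- function(traces, cfg, cyto_level = 200,
                             nuclei_level = 500, poisson_noise = TRUE) {
  stopifnot(inherits(traces, "ratio_traces"), inherits(cfg, "sim_config"))
  n <- nrow(traces$values)
  nt <- length(traces$times)
  sz <- cfg$image_size
  set.seed(cfg$seed + 10L)
  # cytoplasm is rendered wider than the measurement ring so that rings
  # segmented around the nucleus stay inside cytoplasm, as in real cells
  cyto_outer <- cfg$nucleus_radius_px + 2 * cfg$ring_width_px + 2
  centers <- place_cells(n, sz, cyto_outer)
  nuc <- array(cfg$background_level, dim = c(sz, sz, nt))
  rep_ch <- array(cfg$background_level, dim = c(sz, sz, nt))
  nuc_idx <- ring_idx <- vector("list", n)
  for (i in seq_len(n)) {
    nuc_idx[[i]] <- disk_idx(centers$row[i], centers$col[i],
                             cfg$nucleus_radius_px, sz)
    ring_idx[[i]] <- disk_idx(centers$row[i], centers$col[i], cyto_outer, sz,
                              r_inner = cfg$nucleus_radius_px)
  }
  for (f in seq_len(nt)) {
    nf <- nuc[, , f]
    rf <- rep_ch[, , f]
    for (i in seq_len(n)) {
      nf[nuc_idx[[i]]] <- cfg$background_level + nuclei_level
      rf[ring_idx[[i]]] <- cfg$background_level + cyto_level
      rf[nuc_idx[[i]]] <- cfg$background_level +
        max(traces$values[i, f], 0) * cyto_level
    }
    if (poisson_noise) {
      nf[] <- stats::rpois(length(nf), lambda = nf)
      rf[] <- stats::rpois(length(rf), lambda = rf)
    }
    nuc[, , f] <- nf
    rep_ch[, , f] <- rf
  }
  timelapse_stack(list(nuclei = nuc, reporter = rep_ch),
                  cfg$frame_interval_min, t0_min = 0,
                  meta = list(centers = centers,
                              cell_ids = traces$cell_ids))
}

#' Simulate an Srxn1-GFP induction stack
#'
#' Per-cell GFP accumulation follows a logistic sigmoid
#' \eqn{P / (1 + \exp(-(t - o_i)/\tau))} with plateau `P = srxn1$plateau`,
#' per-cell onset \eqn{o_i \sim N(\mathrm{onset\_min}, \mathrm{onset\_sd\_min}^2)}
#' and \eqn{\tau = P / (4\,\mathrm{rate})} so the maximal slope equals
#' `srxn1$rate` intensity units per minute. Cells render as uniform disks of
#' roughly cell size over a flat background; the nuclei channel marks one
#' nucleus per cell.
#'
#' @param cfg a [sim_config()] (use `frame_interval_min = 30`,
#'   `duration_min = 1440` for the standard 24-h assay).
#' @param cell_radius_px rendered cell blob radius; default twice the nucleus
#'   radius.
#' @param gaussian_noise_sd additive pixel noise s.d. (0 = exact rendering).
#' @return List with `stack` (channels `reporter`, `nuclei`) and `truth`
#'   (`onset_min` per cell, `trajectories` cells x frames matrix of noiseless
#'   above-background intensities, `centers`).
#' @export
simulate_srxn1_stack <- function(cfg, cell_radius_px = 2 * cfg$nucleus_radius_px,
                                 gaussian_noise_sd = cfg$noise_sd) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  times <- frame_times(cfg)
  nt <- length(times)
  sz <- cfg$image_size
  set.seed(cfg$seed + 20L)
  centers <- place_cells(cfg$n_cells, sz, cell_radius_px)
  onset <- stats::rnorm(cfg$n_cells, cfg$srxn1$onset_min, cfg$srxn1$onset_sd_min)
  tau <- cfg$srxn1$plateau / (4 * cfg$srxn1$rate)
  traj <- t(vapply(seq_len(cfg$n_cells), function(i) {
    cfg$srxn1$plateau / (1 + exp(-(times - onset[i]) / tau))
  }, numeric(nt)))
  if (cfg$n_cells == 0) traj <- matrix(0, 0, nt)
  rep_ch <- array(cfg$background_level, dim = c(sz, sz, nt))
  nuc <- array(cfg$background_level, dim = c(sz, sz, nt))
  cell_idx <- lapply(seq_len(cfg$n_cells), function(i)
    disk_idx(centers$row[i], centers$col[i], cell_radius_px, sz))
  nuc_idx <- lapply(seq_len(cfg$n_cells), function(i)
    disk_idx(centers$row[i], centers$col[i], cfg$nucleus_radius_px, sz))
  for (f in seq_len(nt)) {
    rf <- rep_ch[, , f]
    nf <- nuc[, , f]
    for (i in seq_len(cfg$n_cells)) {
      rf[cell_idx[[i]]] <- cfg$background_level + traj[i, f]
      nf[nuc_idx[[i]]] <- cfg$background_level + 500
    }
    if (gaussian_noise_sd > 0)
      rf <- rf + stats::rnorm(length(rf), sd = gaussian_noise_sd)
    rep_ch[, , f] <- rf
    nuc[, , f] <- nf
  }
  stack <- timelapse_stack(list(reporter = rep_ch, nuclei = nuc),
                           cfg$frame_interval_min, t0_min = 0,
                           meta = list(centers = centers))
  list(stack = stack,
       truth = list(onset_min = onset, trajectories = traj,
                    centers = centers))
}

#' Simulate an Annexin-V death-assay stack
#'
#' Per-cell death times are drawn from a piecewise-exponential hazard: the
#' baseline hazard `death$baseline_hazard_per_h` applies throughout; once TNFa
#' is added at `death$tnf_add_min` (and `with_tnf = TRUE`) the hazard is
#' multiplied by `death$tnf_multiplier`. Death is irreversible: from its death
#' time onward a cell renders as an Annexin-positive blob that persists to the
#' end of the movie. A transmission channel with intracellular texture is
#' rendered for cell-area estimation.
#'
#' @param cfg a [sim_config()].
#' @param with_tnf logical; apply the TNFa hazard multiplier after
#'   `tnf_add_min`?
#' @param cell_radius_px rendered cell radius.
#' @return List with `stack` (channels `death`, `transmission`, `nuclei`) and
#'   `truth` (`death_time_min` per cell, `NA` for survivors; `centers`;
#'   `cell_area_px`, the summed rendered cell area).
#' @export
simulate_death_series <- function(cfg, with_tnf = FALSE,
                                  cell_radius_px = 2 * cfg$nucleus_radius_px) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  times <- frame_times(cfg)
  nt <- length(times)
  sz <- cfg$image_size
  set.seed(cfg$seed + 30L)
  h1 <- cfg$death$baseline_hazard_per_h / 60   # per minute
  h2 <- h1 * if (with_tnf) cfg$death$tnf_multiplier else 1
  t_add <- cfg$death$tnf_add_min
  # inverse cumulative hazard of E ~ Exp(1)
  e <- stats::rexp(cfg$n_cells)
  death_time <- ifelse(
    h1 > 0 & e <= h1 * t_add,
    e / ifelse(h1 > 0, h1, 1),
    if (h2 > 0) t_add + (e - h1 * t_add) / h2 else Inf
  )
  if (h1 == 0 && h2 == 0) death_time <- rep(Inf, cfg$n_cells)
  death_time[death_time > cfg$duration_min] <- NA
  centers <- place_cells(cfg$n_cells, sz, cell_radius_px)
  cell_idx <- lapply(seq_len(cfg$n_cells), function(i)
    disk_idx(centers$row[i], centers$col[i], cell_radius_px, sz))
  nuc_idx <- lapply(seq_len(cfg$n_cells), function(i)
    disk_idx(centers$row[i], centers$col[i], cfg$nucleus_radius_px, sz))
  death_ch <- array(cfg$background_level, dim = c(sz, sz, nt))
  trans <- array(1000, dim = c(sz, sz, nt))
  nuc <- array(cfg$background_level, dim = c(sz, sz, nt))
  texture <- stats::rnorm(sz * sz, sd = 80)  # static intracellular texture
  for (f in seq_len(nt)) {
    df <- death_ch[, , f]
    tf <- trans[, , f]
    nf <- nuc[, , f]
    for (i in seq_len(cfg$n_cells)) {
      idx <- cell_idx[[i]]
      tf[idx] <- 1000 + texture[idx]
      nf[nuc_idx[[i]]] <- cfg$background_level + 500
      if (!is.na(death_time[i]) && times[f] >= death_time[i])
        df[idx] <- cfg$background_level + 400
    }
    death_ch[, , f] <- df
    trans[, , f] <- tf
    nuc[, , f] <- nf
  }
  stack <- timelapse_stack(list(death = death_ch, transmission = trans,
                                nuclei = nuc),
                           cfg$frame_interval_min, t0_min = 0,
                           meta = list(centers = centers))
  list(stack = stack,
       truth = list(death_time_min = death_time, centers = centers,
                    cell_area_px = sum(lengths(cell_idx))))
}
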