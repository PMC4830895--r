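#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all synthetic
#' generators. Defaults encode the acquisition regime of the live-cell assays:
#' GFP-p65 imaged every 6 min over 6 h, Srxn1-GFP and Annexin-V every 30 min
#' over 24 h, 512 x 512 pixel fields, and TNFa (10 ng/mL) added after an 8-h
#' drug pre-incubation. The control oscillation pattern places NF-kB nuclear
#' translocation maxima at 30 and 150 min after TNFa, with later peaks damped
#' and progressively desynchronised across the population.
#'
#' @param seed integer seed controlling every stochastic draw.
#' @param n_cells number of cells per simulated field/population.
#' @param frame_interval_min minutes between frames.
#' @param duration_min total imaging duration in minutes.
#' @param image_size side length of the square field, pixels.
#' @param nucleus_radius_px nucleus radius, pixels.
#' @param ring_width_px cytoplasmic ring width used when rendering, pixels.
#' @param background_level camera background intensity (arbitrary units).
#' @param noise_sd additive noise s.d.; on ratio traces in ratio units, on
#'   rendered images in intensity units.
#' @param oscillation list of NF-kB oscillation parameters:
#'   \describe{
#'     \item{first_peak_min}{time of the first translocation maximum.}
#'     \item{inter_peak_min}{spacing between successive maxima.}
#'     \item{peak_width_min}{full width at half maximum of each peak.}
#'     \item{amplitude}{height of the first peak in ratio units above baseline.}
#'     \item{damping}{multiplicative amplitude decay per peak index, in (0,1].}
#'     \item{desync_sd_min}{timing jitter s.d. per peak index (peak k jitters
#'       with s.d. k * desync_sd_min), emulating progressive desynchronisation.}
#'     \item{treatment_delay_min}{minutes added to every peak after the first
#'       in treated populations (drug pre-exposure delays the second and later
#'       translocation events, not the first).}
#'   }
#' @param srxn1 list of Srxn1-GFP induction parameters: \code{onset_min}
#'   (sigmoid midpoint), \code{rate} (maximal intensity slope per minute),
#'   \code{plateau} (asymptotic intensity above background), \code{onset_sd_min}
#'   (cell-to-cell onset spread).
#' @param death list of death-kinetics parameters: \code{baseline_hazard_per_h},
#'   \code{tnf_multiplier} (hazard fold change once TNFa is present) and
#'   \code{tnf_add_min} (time TNFa is added; 480 min = 8 h).
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 10, noise_sd = 0)
#' cfg$oscillation$first_peak_min
sim_config <- function(seed = 1L,
                       n_cells = 50L,
                       frame_interval_min = 6,
                       duration_min = 360,
                       image_size = 512L,
                       nucleus_radius_px = 9,
                       ring_width_px = 4,
                       background_level = 100,
                       noise_sd = 0.05,
                       oscillation = list(),
                       srxn1 = list(),
                       death = list()) {
  osc_def <- list(first_peak_min = 30, inter_peak_min = 120,
                  peak_width_min = 30, amplitude = 1.0, damping = 0.5,
                  desync_sd_min = 6, treatment_delay_min = 0)
  srx_def <- list(onset_min = 480, rate = 2.5, plateau = 600,
                  onset_sd_min = 60)
  dth_def <- list(baseline_hazard_per_h = 0.002, tnf_multiplier = 1,
                  tnf_add_min = 480)
  cfg <- list(
    seed = as.integer(seed),
    n_cells = as.integer(n_cells),
    frame_interval_min = frame_interval_min,
    duration_min = duration_min,
    image_size = as.integer(image_size),
    nucleus_radius_px = nucleus_radius_px,
    ring_width_px = ring_width_px,
    background_level = background_level,
    noise_sd = noise_sd,
    oscillation = utils::modifyList(osc_def, oscillation),
    srxn1 = utils::modifyList(srx_def, srxn1),
    death = utils::modifyList(dth_def, death)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[c("frame_interval_min", "duration_min", "nucleus_radius_px",
                      "ring_width_px", "background_level", "noise_sd")],
                use.names = FALSE)
  num <- c(num, unlist(cfg$oscillation), unlist(cfg$srxn1), unlist(cfg$death))
  if (any(!is.finite(num)))
    stop("sim_config: all numeric parameters must be finite")
  if (cfg$frame_interval_min <= 0)
    stop("sim_config: frame_interval_min must be > 0")
  if (cfg$duration_min < cfg$frame_interval_min)
    stop("sim_config: duration_min must be >= frame_interval_min")
  if (cfg$n_cells < 0) stop("sim_config: n_cells must be >= 0")
  osc <- cfg$oscillation
  if (osc$damping <= 0 || osc$damping > 1)
    stop("sim_config: oscillation$damping must be in (0, 1]")
  if (osc$amplitude <= 0) stop("sim_config: oscillation$amplitude must be > 0")
  sds <- c(osc$desync_sd_min, osc$peak_width_min, cfg$srxn1$onset_sd_min,
           cfg$noise_sd)
  if (any(sds < 0)) stop("sim_config: sd/width parameters must be >= 0")
  if (cfg$death$baseline_hazard_per_h < 0 || cfg$death$tnf_multiplier < 0)
    stop("sim_config: hazards must be >= 0")
  cfg
}

#' Frame times of a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @return Numeric vector of frame times in minutes after stimulation,
#'   starting at 0.
#' @export
frame_times <- function(cfg) {
  seq(0, cfg$duration_min, by = cfg$frame_interval_min)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells,",
      x$duration_min, "min at", x$frame_interval_min, "min/frame,",
      x$image_size, "px field, seed", x$seed, "\n")
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}
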