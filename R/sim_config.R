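#' Virtual microscope configuration
#'
#' Bundles the acquisition geometry and noise model of the simulated
#' microscope. Defaults reproduce the real instrument's geometry: 352 px
#' square crops at a back-projected pixel size of 111 nm (about a 39 um
#' field of view) and 8 simultaneous z-planes. The `benchmark` preset keeps
#' that geometry on record but renders 128 px images so that a full
#' train-and-evaluate cycle stays within minutes on one CPU.
#'
#' @param image_size_px image side length in pixels.
#' @param pixel_size_um back-projected pixel size (um).
#' @param n_zplanes number of simultaneously acquired z-planes.
#' @param z_spacing_um spacing between z-planes (um).
#' @param frame_interval_s time-lapse frame interval (s).
#' @param photon_budget expected peak photons per pixel; `Inf` disables shot
#'   noise.
#' @param read_noise_sd camera read noise SD in counts; 0 disables it.
#' @param bleach_rate_per_s first-order photobleaching rate (1/s).
#' @param cue_contrast strength in `[0,1]` of the learnable pre-onset cue
#'   (proto-punctum plus local variance increase). 0 means events and
#'   non-events are indistinguishable before onset.
#' @param cue_lead_time_s how long before onset the cue starts growing (s).
#' @param onset_duration_s duration of the soluble-to-aggregate transition (s).
#' @param session_length_s length of the virtual session over which onset
#'   times are drawn (s).
#' @param fsr_GHz free spectral range of the virtual spectrometer (GHz).
#' @param n_spectral_bins number of bins of the spectral axis over one FSR.
#' @param instr_linewidth_GHz instrumental response FWHM (GHz); Lorentzian,
#'   so it adds linearly to the true linewidth.
#' @param brillouin_dwell_s per-point Brillouin exposure (s).
#' @param rng_seed default seed recorded in the config.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$image_size_px * cfg$pixel_size_um  # ~39 um field of view
sim_config <- function(image_size_px = 352L,
                       pixel_size_um = 0.111,
                       n_zplanes = 8L,
                       z_spacing_um = 0.35,
                       frame_interval_s = 60,
                       photon_budget = 200,
                       read_noise_sd = 2,
                       bleach_rate_per_s = 0,
                       cue_contrast = 0.6,
                       cue_lead_time_s = 600,
                       onset_duration_s = 300,
                       session_length_s = 3600,
                       fsr_GHz = 15,
                       n_spectral_bins = 512L,
                       instr_linewidth_GHz = 0.270,
                       brillouin_dwell_s = 0.100,
                       rng_seed = 0L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_zplanes = as.integer(n_zplanes),
    z_spacing_um = z_spacing_um,
    frame_interval_s = frame_interval_s,
    photon_budget = photon_budget,
    read_noise_sd = read_noise_sd,
    bleach_rate_per_s = bleach_rate_per_s,
    cue_contrast = cue_contrast,
    cue_lead_time_s = cue_lead_time_s,
    onset_duration_s = onset_duration_s,
    session_length_s = session_length_s,
    fsr_GHz = fsr_GHz,
    n_spectral_bins = as.integer(n_spectral_bins),
    instr_linewidth_GHz = instr_linewidth_GHz,
    brillouin_dwell_s = brillouin_dwell_s,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Benchmark preset of the simulator configuration
#'
#' 128 px images (training stays under a CPU-minutes budget) with the cue
#' calibrated so the reference classifiers reach their accuracy bands;
#' geometry fields still record the instrument-faithful pixel size.
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return a `sim_config`.
#' @export
benchmark_config <- function(...) {
  args <- utils::modifyList(list(image_size_px = 128L, photon_budget = 500),
                            list(...))
  do.call(sim_config, args)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$image_size_px > 0,
            cfg$pixel_size_um > 0,
            cfg$n_zplanes >= 1,
            cfg$z_spacing_um > 0,
            cfg$n_spectral_bins >= 32,
            cfg$fsr_GHz > 0,
            cfg$instr_linewidth_GHz > 0,
            cfg$brillouin_dwell_s > 0,
            cfg$bleach_rate_per_s >= 0,
            cfg$read_noise_sd >= 0)
  if (!(cfg$cue_contrast >= 0 && cfg$cue_contrast <= 1))
    stop("cue_contrast must lie in [0, 1]")
  durations <- c(cfg$frame_interval_s, cfg$cue_lead_time_s,
                 cfg$onset_duration_s, cfg$session_length_s)
  if (any(durations < 0)) stop("all durations must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  fov <- x$image_size_px * x$pixel_size_um
  cat(sprintf("sim_config: %d px @ %.3f um (FOV %.1f um), %d z-planes\n",
              x$image_size_px, x$pixel_size_um, fov, x$n_zplanes))
  cat(sprintf("  cue_contrast %.2f, lead %ds, onset %ds\n",
              x$cue_contrast, as.integer(x$cue_lead_time_s),
              as.integer(x$onset_duration_s)))
  cat(sprintf("  FSR %.1f GHz / %d bins, instrumental width %.3f GHz\n",
              x$fsr_GHz, x$n_spectral_bins, x$instr_linewidth_GHz))
  invisible(x)
}
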