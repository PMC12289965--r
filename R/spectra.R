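# Peak-normalized Lorentzian with FWHM `fwhm` centered at `center`.
lorentz <- function(f, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((f - center)^2 + hw2)
}

#' Spectral axis of the virtual spectrometer
#'
#' Bin midpoints spanning one free spectral range.
#' @param config a [sim_config()].
#' @return numeric vector of length `config$n_spectral_bins`, strictly
#'   increasing.
#' @export
spectral_axis <- function(config) {
  n <- config$n_spectral_bins
  (seq_len(n) - 0.5) * config$fsr_GHz / n
}

#' Render a per-pixel Brillouin spectrum
#'
#' The spectrum over one free spectral range contains Rayleigh remnants at
#' the axis ends, and an anti-Stokes/Stokes Brillouin doublet at `nu_B` and
#' `FSR - nu_B`. The rendered Brillouin peaks carry the *measured* width:
#' the pixel's true linewidth broadened by the instrumental Lorentzian
#' response (0.270 GHz by default) — Lorentzian convolution adds FWHMs
#' exactly. Expected counts are proportional to the dwell time; shot noise
#' is Poisson.
#'
#' @param sample a [make_sample()] result.
#' @param position FOV index.
#' @param pixel integer pair `(row, col)` in image pixel coordinates.
#' @param time_s virtual clock time (s).
#' @param config a [sim_config()]; defaults to the sample's own.
#' @param dwell_s per-point exposure (s); default from the config (100 ms).
#' @param noise logical; `FALSE` renders the noiseless expectation.
#' @return a `brillouin_spectrum`: `freq_axis_GHz`, `counts`, `dwell_s`,
#'   `pixel_index`, plus the underlying truth for reference.
#' @export
render_brillouin_spectrum <- function(sample, position, pixel, time_s,
                                      config = sample$config,
                                      dwell_s = config$brillouin_dwell_s,
                                      noise = TRUE) {
  stopifnot(position %in% sample$stage_grid$fov, length(pixel) == 2L)
  n <- config$image_size_px
  if (any(pixel < 1) || any(pixel > n)) stop("pixel outside the field of view")
  tr <- brillouin_truth_fields(sample, position,
                               x_px = pixel[2L], y_px = pixel[1L],
                               time_s = time_s)
  expected <- brillouin_expected_counts(tr$shift, tr$lw, config, dwell_s)
  counts <- expected
  if (noise) {
    seed <- derive_seed(sample$seed, sprintf("brill/%d/%d/%d/%.3f",
                                             position, pixel[1L], pixel[2L],
                                             time_s))
    counts <- with_seed(seed, rpois(length(expected), expected))
  }
  structure(list(freq_axis_GHz = spectral_axis(config),
                 counts = as.numeric(counts), dwell_s = dwell_s,
                 pixel_index = as.integer(pixel),
                 truth = list(shift_GHz = tr$shift, linewidth_GHz = tr$lw)),
            class = "brillouin_spectrum")
}

# Expected counts per bin for a pixel with true shift/linewidth.
brillouin_expected_counts <- function(shift_GHz, lw_true_GHz, config, dwell_s) {
  f <- spectral_axis(config)
  fsr <- config$fsr_GHz
  gamma_meas <- lw_true_GHz + config$instr_linewidth_GHz
  rate <- dwell_s / 0.1  # amplitudes stated at the 100 ms reference dwell
  baseline <- 20
  a_rayleigh <- 5000
  a_brillouin <- 1000
  rate * (baseline +
            a_rayleigh * (lorentz(f, 0, config$instr_linewidth_GHz) +
                            lorentz(f, fsr, config$instr_linewidth_GHz)) +
            a_brillouin * (lorentz(f, shift_GHz, gamma_meas) +
                             lorentz(f, fsr - shift_GHz, gamma_meas)))
}

# Vectorized ground-truth lookup at fractional pixel coordinates.
# Outside the cell: water-like background truth. Inside the aggregate
# footprint the truth ramps linearly from periphery to aggregate values over
# onset_duration_s.
brillouin_truth_fields <- function(sample, position, x_px, y_px, time_s) {
  bt <- sample$brillouin_truth
  cfg <- sample$config
  cell <- cell_for_fov(sample, position)
  n <- length(x_px)
  shift <- rep(bt$background_shift_GHz, n)
  lw <- rep(bt$background_lw_GHz, n)
  in_cell <- rep(FALSE, n)
  in_agg <- rep(FALSE, n)
  if (!is.null(cell)) {
    r <- sqrt((x_px - cell$cx)^2 + (y_px - cell$cy)^2)
    in_cell <- r <= cell$radius_px
    shift[in_cell] <- bt$shift_peri_GHz
    lw[in_cell] <- bt$lw_peri_GHz
    if (is.finite(cell$t0_s) && time_s > cell$t0_s) {
      ra <- sqrt((x_px - cell$agg_x)^2 + (y_px - cell$agg_y)^2)
      in_agg <- in_cell & (ra <= aggregate_radius_px(cfg))
      u <- if (cfg$onset_duration_s > 0)
        min((time_s - cell$t0_s) / cfg$onset_duration_s, 1) else 1
      shift[in_agg] <- bt$shift_peri_GHz +
        u * (bt$shift_agg_GHz - bt$shift_peri_GHz)
      lw[in_agg] <- bt$lw_peri_GHz + u * (bt$lw_agg_GHz - bt$lw_peri_GHz)
    }
  }
  list(shift = shift, lw = lw, in_cell = in_cell, in_agg = in_agg)
}

# Sampling grid for a Brillouin map: a W um window at step s includes both
# endpoints, i.e. floor(W/s) + 1 points per axis. Returns fractional pixel
# coordinates (centered on the aggregate site for zoomed windows on EVENT
# cells, else on the image center).
map_grid_px <- function(sample, position, step_um, fov_um = NULL,
                        config = sample$config) {
  full_fov <- config$image_size_px * config$pixel_size_um
  if (is.null(fov_um)) fov_um <- full_fov
  stopifnot(step_um > 0, fov_um > 0)
  n_pts <- as.integer(floor(fov_um / step_um)) + 1L
  span_um <- (n_pts - 1L) * step_um
  cell <- cell_for_fov(sample, position)
  center <- c(x = (config$image_size_px + 1) / 2,
              y = (config$image_size_px + 1) / 2)
  if (!is.null(cell) && fov_um < 0.5 * full_fov && is.finite(cell$t0_s))
    center <- c(x = cell$agg_x, y = cell$agg_y)
  off_px <- (seq_len(n_pts) - 1L) * step_um / config$pixel_size_um -
    span_um / 2 / config$pixel_size_um
  list(x_px = center[["x"]] + off_px, y_px = center[["y"]] + off_px,
       n_pts = n_pts, step_um = step_um)
}

#' Ground-truth Brillouin maps
#'
#' Samples the true shift and (un-broadened) linewidth fields on a map grid,
#' together with the aggregate and cell masks — the reference against which
#' the fit/deconvolution/segmentation chain is scored. A `W` um window at
#' step `s` includes both endpoints: `floor(W/s) + 1` points per axis, so a
#' 35 um field at 1 um yields a 36 x 36 grid.
#'
#' @inheritParams render_brillouin_spectrum
#' @param step_um grid step (um), `> 0`.
#' @param fov_um map window side (um); default the full field of view.
#' @return a `ground_truth_maps` list: `shift_GHz`, `linewidth_GHz`
#'   (matrices), `aggregate_mask`, `cell_mask`, `step_um`, `time_s`.
#' @export
true_brillouin_maps <- function(sample, position, time_s, step_um,
                                fov_um = NULL, config = sample$config) {
  g <- map_grid_px(sample, position, step_um, fov_um, config)
  xs <- rep(g$x_px, each = g$n_pts)   # row-major: rows vary with y
  ys <- rep(g$y_px, times = g$n_pts)
  tr <- brillouin_truth_fields(sample, position, xs, ys, time_s)
  as_mat <- function(v) matrix(v, nrow = g$n_pts, ncol = g$n_pts)
  structure(list(shift_GHz = as_mat(tr$shift),
                 linewidth_GHz = as_mat(tr$lw),
                 aggregate_mask = as_mat(tr$in_agg),
                 cell_mask = as_mat(tr$in_cell),
                 step_um = step_um, time_s = time_s, grid = g),
            class = "ground_truth_maps")
}

#' Acquire a grid of Brillouin spectra
#'
#' Point-by-point acquisition over a map window; the virtual clock cost is
#' `dwell_s` per point. Grid convention matches [true_brillouin_maps()].
#'
#' @inheritParams true_brillouin_maps
#' @param dwell_s per-point exposure (s).
#' @param noise logical; `FALSE` renders noiseless expectations.
#' @return a `spectra_grid`: list with `spectra` (list-matrix), `freq_axis_GHz`,
#'   `n_pts`, `step_um`, `dwell_s`, `time_s`.
#' @export
acquire_brillouin_grid <- function(sample, position, time_s, step_um,
                                   fov_um = NULL, config = sample$config,
                                   dwell_s = config$brillouin_dwell_s,
                                   noise = TRUE) {
  g <- map_grid_px(sample, position, step_um, fov_um, config)
  xs <- rep(g$x_px, each = g$n_pts)
  ys <- rep(g$y_px, times = g$n_pts)
  tr <- brillouin_truth_fields(sample, position, xs, ys, time_s)
  f <- spectral_axis(config)
  seed <- derive_seed(sample$seed, sprintf("brillgrid/%d/%.3f/%.4f",
                                           position, time_s, step_um))
  spectra <- with_seed(seed, {
    lapply(seq_along(xs), function(i) {
      expected <- brillouin_expected_counts(tr$shift[i], tr$lw[i], config,
                                            dwell_s)
      counts <- if (noise) rpois(length(expected), expected) else expected
      structure(list(freq_axis_GHz = f, counts = as.numeric(counts),
                     dwell_s = dwell_s,
                     pixel_index = c(((i - 1L) %% g$n_pts) + 1L,
                                     ((i - 1L) %/% g$n_pts) + 1L)),
                class = "brillouin_spectrum")
    })
  })
  dim(spectra) <- c(g$n_pts, g$n_pts)
  structure(list(spectra = spectra, freq_axis_GHz = f, n_pts = g$n_pts,
                 step_um = step_um, dwell_s = dwell_s, time_s = time_s),
            class = "spectra_grid")
}
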