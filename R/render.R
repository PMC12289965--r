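#' Render a multi-plane fluorescence acquisition
#'
#' Produces one timepoint of the virtual fluorophore-labelled sample at a
#' stage position: a smooth cell-shaped soluble intensity plus shot and read
#' noise. For EVENT cells a proto-punctum of contrast `cue_contrast` grows at
#' the aggregate site during the cue window `[t0 - cue_lead_time, t0]`
#' (together with a ~10 percent local variance increase); after onset the
#' soluble pool condenses into a tight punctum over `onset_duration_s`.
#' The condensation is a pure redistribution: with noise and bleaching
#' disabled the per-cell pixel sum is time-invariant. All z-planes share the
#' lateral structure, blurred by a defocus that grows with distance from the
#' focal plane.
#'
#' @param sample a [make_sample()] result.
#' @param position FOV index into `sample$stage_grid`.
#' @param time_s virtual clock time (s), `>= 0`.
#' @param config a [sim_config()]; defaults to the sample's own.
#' @param exposure_scale multiplies the expected photon budget (laser power /
#'   exposure product of the current scan settings).
#' @return an [image_stack()] with T = 1 and Z = `config$n_zplanes`.
#' @export
render_fluorescence <- function(sample, position, time_s,
                                config = sample$config, exposure_scale = 1) {
  stopifnot(position %in% sample$stage_grid$fov, time_s >= 0)
  n <- config$image_size_px
  cell <- cell_for_fov(sample, position)
  img <- render_fluor_field(sample, cell, time_s, config)
  zs <- (seq_len(config$n_zplanes) - (config$n_zplanes + 1) / 2) *
    config$z_spacing_um
  planes <- array(0, dim = c(1L, config$n_zplanes, n, n))
  noise_seed <- derive_seed(sample$seed,
                            sprintf("fluor/%d/%.3f", position, time_s))
  with_seed(noise_seed, {
    for (zi in seq_along(zs)) {
      sig <- 1.0 + 2.5 * abs(zs[zi])
      plane <- gauss_blur(img, sig) * exposure_scale
      planes[1L, zi, , ] <- apply_noise(plane,
                                        shot = is.finite(config$photon_budget),
                                        read_noise_sd = config$read_noise_sd)
    }
  })
  image_stack(planes, timestamps_s = time_s, modality = "FLUOR",
              position = position,
              settings = list(exposure_scale = exposure_scale,
                              time_s = time_s))
}

# Noise-free model intensity field (single lateral plane, pre-defocus),
# in expected-photon units at exposure_scale 1.
render_fluor_field <- function(sample, cell, time_s, config) {
  n <- config$image_size_px
  if (is.null(cell)) return(matrix(0, n, n))
  pb <- if (is.finite(config$photon_budget)) config$photon_budget else 200
  base <- base_cell_image(cell, n, amplitude = pb)
  S <- sum(base)
  st <- punctum_state(time_s, cell$t0_s, config, cell$radius_px)
  f <- st[["f"]]; sig <- st[["sigma"]]
  img <- base
  if (f > 0) {
    P <- gauss_bump(n, cell$agg_x, cell$agg_y, sig)
    img <- (1 - f) * base + f * S * P / sum(P)
  }
  # local variance cue: small multiplicative speckle near the site during the
  # cue window, renormalized so the cell total is conserved
  lead <- config$cue_lead_time_s
  if (is.finite(cell$t0_s) && config$cue_contrast > 0 &&
      time_s >= cell$t0_s - lead && time_s < cell$t0_s) {
    u <- if (lead > 0) (time_s - (cell$t0_s - lead)) / lead else 1
    w <- (1 - exp(-4 * u)) / (1 - exp(-4))  # same saturating ramp as punctum
    v <- cue_speckle_field(cell, n)
    img <- img * exp(0.1 * config$cue_contrast * w * v)
    img <- img * (S / sum(img))
  }
  img * exp(-config$bleach_rate_per_s * time_s)
}

# Smooth positive cell body: soft super-Gaussian disk modulated by a frozen
# low-frequency texture drawn from the cell's texture seed.
base_cell_image <- function(cell, n, amplitude = 1) {
  x <- seq_len(n)
  r2 <- outer((x - cell$cy)^2, (x - cell$cx)^2, `+`)
  disk <- exp(-(r2 / cell$radius_px^2)^2)
  tex <- with_seed(cell$tex_seed, {
    g <- matrix(0, n, n)
    for (k in 1:6) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.8) * cell$radius_px
      g <- g + runif(1, -1, 1) *
        gauss_bump(n, cell$cx + rad * cos(ang), cell$cy + rad * sin(ang),
                   cell$radius_px / 3)
    }
    g
  })
  amplitude * disk * exp(0.25 * tex)
}

# Frozen zero-mean speckle localized around the aggregate site (the
# variance component of the pre-onset cue).
cue_speckle_field <- function(cell, n) {
  with_seed(cell$tex_seed + 1L, {
    v <- matrix(0, n, n)
    for (k in 1:8) {
      v <- v + runif(1, -1, 1) *
        gauss_bump(n, cell$agg_x + runif(1, -8, 8),
                   cell$agg_y + runif(1, -8, 8), 2.0)
    }
    v - mean(v)
  })
}

#' Render a brightfield acquisition
#'
#' Cells appear as low-contrast ring/halo objects on a bright background;
#' a mature aggregate (clock past `t0 + onset_duration_s`) adds a localized
#' high-contrast punctum with a faint diffraction ring. Pre-onset EVENT
#' fields are indistinguishable from NON_EVENT fields in expectation:
#' brightfield carries no pre-onset cue.
#'
#' @inheritParams render_fluorescence
#' @return an [image_stack()] with T = 1 and Z = 1.
#' @export
render_brightfield <- function(sample, position, time_s,
                               config = sample$config, exposure_scale = 1) {
  stopifnot(position %in% sample$stage_grid$fov, time_s >= 0)
  n <- config$image_size_px
  cell <- cell_for_fov(sample, position)
  img <- matrix(1, n, n)  # relative transmission; background = 1
  if (!is.null(cell)) {
    x <- seq_len(n)
    r <- sqrt(outer((x - cell$cy)^2, (x - cell$cx)^2, `+`))
    ring <- exp(-((r - cell$radius_px) / (0.10 * cell$radius_px))^2)
    inner <- exp(-(r^2 / cell$radius_px^2)^2)
    img <- img * (1 - 0.08 * ring - 0.02 * inner)
    if (is.finite(cell$t0_s) &&
        time_s > cell$t0_s + config$onset_duration_s) {
      ra <- sqrt(outer((x - cell$agg_y)^2, (x - cell$agg_x)^2, `+`))
      img <- img * (1 - 0.5 * exp(-ra^2 / (2 * 2.5^2)) +
                      0.15 * exp(-((ra - 6) / 1.5)^2))
    }
  }
  img <- gauss_blur(img, 1.0)
  # brightfield is photon-rich: 5x the fluorescence budget at the background
  pb <- if (is.finite(config$photon_budget)) config$photon_budget else 200
  img <- img * 5 * pb * exposure_scale
  noise_seed <- derive_seed(sample$seed,
                            sprintf("bf/%d/%.3f", position, time_s))
  out <- with_seed(noise_seed, {
    apply_noise(img, shot = is.finite(config$photon_budget),
                read_noise_sd = config$read_noise_sd)
  })
  dim(out) <- c(1L, 1L, n, n)
  image_stack(out, timestamps_s = time_s, modality = "BRIGHTFIELD",
              position = position,
              settings = list(exposure_scale = exposure_scale,
                              time_s = time_s))
}
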