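# Synthetic spectrum straight from the generator's model: baseline +
# Rayleigh remnants + mirrored Brillouin doublet, optionally noiseless.
synth_spectrum <- function(nu, gamma_true, cfg = noiseless_config(),
                           dwell = 0.1, noise = FALSE, seed = 1) {
  s <- event_sample(cfg, t0 = 100, seed = seed)
  s$brillouin_truth$background_shift_GHz <- nu
  s$brillouin_truth$background_lw_GHz <- gamma_true
  render_brillouin_spectrum(s, 1, c(2, 2), 0, dwell_s = dwell,
                            noise = noise)
}

test_that("noiseless fits recover shift and instrument-broadened width", {
  cfg <- noiseless_config()
  sp <- synth_spectrum(6.50, 0.60, cfg)
  ft <- fit_spectrum(sp, cfg$fsr_GHz)
  expect_true(ft$valid)
  expect_lt(abs(ft$shift_GHz - 6.500), 1e-3)
  expect_lt(abs(ft$linewidth_meas_GHz - 0.870), 1e-3)  # 0.60 + 0.27
  expect_lt(abs(ft$linewidth_corr_GHz - 0.600), 1e-3)

  # round trip across the deconvolution range
  for (g in c(0.3, 0.6, 1.0)) {
    ft <- fit_spectrum(synth_spectrum(6.2, g, cfg), cfg$fsr_GHz)
    expect_lt(abs(ft$linewidth_corr_GHz - g), 1e-3)
  }

  # flat spectrum -> invalid
  flat <- structure(list(freq_axis_GHz = spectral_axis(cfg),
                         counts = rep(10, cfg$n_spectral_bins)),
                    class = "brillouin_spectrum")
  expect_false(fit_spectrum(flat, cfg$fsr_GHz)$valid)
})

test_that("fitter agrees with the exhaustive grid-search oracle", {
  cfg <- noiseless_config()
  set.seed(20)
  for (k in 1:10) {
    nu <- runif(1, 4.5, 7.2)
    g <- runif(1, 0.3, 1.0)
    sp <- synth_spectrum(nu, g, cfg)
    ft <- fit_spectrum(sp, cfg$fsr_GHz)
    oracle <- grid_fit_oracle(sp, cfg$fsr_GHz)
    expect_lt(abs(ft$shift_GHz - oracle$nu), 1e-3)
    expect_lt(abs(ft$linewidth_meas_GHz - oracle$gamma), 1e-3)
  }
})

test_that("deconvolution subtracts the instrumental width with clamping", {
  expect_equal(deconvolve_linewidth(0.85, 0.27)$linewidth_corr_GHz, 0.58)
  expect_true(deconvolve_linewidth(0.85, 0.27)$valid)
  r <- deconvolve_linewidth(0.27, 0.27)
  expect_identical(r$linewidth_corr_GHz, 0)
  expect_false(r$valid)
  r2 <- deconvolve_linewidth(0.20, 0.27)
  expect_identical(r2$linewidth_corr_GHz, 0)
  expect_false(r2$valid)
  expect_error(deconvolve_linewidth(0), "positive")
})

test_that("shift estimator is unbiased and precise at the 100 ms dwell", {
  cfg <- tiny_config()
  s <- event_sample(cfg, t0 = 1e6, seed = 31)
  px <- c(round(s$cells$cy[1]), round(s$cells$cx[1]))  # periphery: 6.39
  shifts <- vapply(1:100, function(k) {
    sp <- render_brillouin_spectrum(s, 1, px, k, noise = TRUE)
    fit_spectrum(sp, cfg$fsr_GHz)$shift_GHz
  }, numeric(1))
  expect_lt(abs(mean(shifts) - 6.39), 0.005)  # bias < 5 MHz
  expect_lt(sd(shifts), 0.040)         # within the +/-0.04 GHz spread scale
})

test_that("otsu_threshold maximizes between-class variance", {
  thr <- otsu_threshold(c(1, 1, 1, 10, 10))
  expect_true(thr >= 1 && thr < 10)
  expect_identical(c(1, 1, 1, 10, 10) > thr, c(F, F, F, T, T))

  # perfectly bimodal two-delta histogram: foreground is the upper mode
  x <- c(rep(2, 50), rep(8, 30))
  expect_identical(sum(x > otsu_threshold(x)), 30L)

  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant")

  set.seed(33)
  for (k in 1:100) {
    img <- c(rnorm(60, sample(0:3, 1)), rnorm(40, sample(4:8, 1)))
    expect_equal(otsu_threshold(img), otsu_brute(img))
  }
})

truth_at <- function(s, grid) {
  # reference shift truths at the acquisition grid, via the truth accessor
  gm <- true_brillouin_maps(s, 1, grid$time_s, grid$step_um,
                            (grid$n_pts - 1) * grid$step_um)
  gm$shift_GHz
}

test_that("build_map fits whole grids on the endpoint convention", {
  cfg <- noiseless_config(image_size_px = 352L)
  s <- make_sample(cfg, list(n_events = 0, n_nonevents = 1), seed = 40)
  grid <- acquire_brillouin_grid(s, 1, 0, step_um = 1, fov_um = 10,
                                 noise = FALSE)
  expect_identical(grid$n_pts, 11L)
  map <- build_map(grid, cfg$fsr_GHz)
  expect_identical(dim(map$shift_map), c(11L, 11L))
  expect_true(all(map$valid_mask))
  # all-background corner recovers the background truth
  expect_lt(max(abs(map$shift_map - truth_at(s, grid))), 1e-3)
})

test_that("segmentation separates aggregate, signal and periphery", {
  # fixture with a known disk aggregate
  set.seed(50)
  n <- 40
  x <- seq_len(n)
  d2 <- outer((x - 18)^2, (x - 24)^2, `+`)
  truth_mask <- d2 <= 6^2
  fluor <- 10 + 90 * truth_mask + rnorm(n^2, sd = 3)
  cell <- outer((x - 20)^2, (x - 20)^2, `+`) <= 15^2
  shift <- matrix(6.0, n, n); shift[cell] <- 6.39; shift[truth_mask] <- 6.51
  lw <- matrix(0.30, n, n); lw[cell] <- 0.54; lw[truth_mask] <- 0.58
  map <- structure(list(shift_map = shift, linewidth_map = lw,
                        valid_mask = matrix(TRUE, n, n)),
                   class = "brillouin_map")
  mk <- segment_regions(matrix(fluor, n, n), map)
  iou <- sum(mk$aggregate & truth_mask) / sum(mk$aggregate | truth_mask)
  expect_gte(iou, 0.7)
  expect_identical(sum(mk$periphery_shift & mk$aggregate), 0L)
  expect_identical(sum(mk$periphery_lw & mk$aggregate), 0L)
  expect_true(all(mk$periphery_shift == (mk$signal_shift & !mk$aggregate)))

  # uniform cell, no aggregate: foreground stays tiny
  fluor_u <- 10 + 20 * cell + rnorm(n^2, sd = 0.5)
  mk_u <- segment_regions(matrix(fluor_u, n, n), map)
  expect_lt(sum(mk_u$aggregate & !cell), 0.01 * n^2)

  st <- region_stats(list(map), list(mk))
  agg_shift <- st[st$region == "aggregate" & st$quantity == "shift", ]
  peri_shift <- st[st$region == "periphery" & st$quantity == "shift", ]
  expect_lt(abs(agg_shift$mean - 6.51), 0.03)
  expect_lt(abs(peri_shift$mean - 6.39), 0.03)
  expect_gt(agg_shift$mean, peri_shift$mean)

  # single-pixel region: sd is 0, not NA
  tiny_mask <- mk
  tiny_mask$aggregate[] <- FALSE
  tiny_mask$aggregate[18, 24] <- TRUE
  st1 <- region_stats(list(map), list(tiny_mask))
  expect_identical(st1$sd[st1$region == "aggregate" &
                            st1$quantity == "shift"], 0)
})

test_that("recovered aggregate shift rises monotonically through onset", {
  cfg <- noiseless_config(image_size_px = 128L)
  s <- event_sample(cfg, t0 = 1000, seed = 60)
  times <- 1000 + cfg$onset_duration_s * c(0.25, 0.5, 0.75, 1)
  means <- vapply(times, function(t) {
    gm <- true_brillouin_maps(s, 1, t, step_um = 0.5, fov_um = 8)
    grid <- acquire_brillouin_grid(s, 1, t, step_um = 0.5, fov_um = 8,
                                   noise = FALSE)
    map <- build_map(grid, cfg$fsr_GHz)
    mean(map$shift_map[gm$aggregate_mask & map$valid_mask])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[4] - 6.51), 0.005)
})
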