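test_that("make_sample assigns exact fate counts and is deterministic", {
  cfg <- tiny_config()
  s <- make_sample(cfg, list(n_events = 71, n_nonevents = 68), seed = 0)
  expect_identical(sum(s$cells$fate == "EVENT"), 71L)
  expect_identical(sum(s$cells$fate == "NON_EVENT"), 68L)
  expect_true(all(is.finite(s$cells$t0_s[s$cells$fate == "EVENT"])))
  expect_true(all(is.infinite(s$cells$t0_s[s$cells$fate == "NON_EVENT"])))

  # aggregate sites lie inside their cells
  d <- with(s$cells, sqrt((agg_x - cx)^2 + (agg_y - cy)^2))
  expect_true(all(d <= s$cells$radius_px))

  s2 <- make_sample(cfg, list(n_events = 71, n_nonevents = 68), seed = 0)
  expect_identical(s, s2)

  # event fraction 0 -> all NON_EVENT; bad grid rejected
  s0 <- make_sample(cfg, list(rows = 2, cols = 3, event_fraction = 0), 1)
  expect_true(all(s0$cells$fate == "NON_EVENT"))
  expect_error(make_sample(cfg, list(rows = 0, cols = 3,
                                     event_fraction = 0.5), 1),
               "grid dims")
})

test_that("fluorescence conserves per-cell intensity through aggregation", {
  cfg <- noiseless_config()
  s <- event_sample(cfg, t0 = 1000)
  total <- function(t) sum(render_fluorescence(s, 1, t)$data[1, 1, , ])
  ref <- total(999.9)
  # through the cue window, onset and maturity
  for (t in c(500, 950, 1000 + cfg$onset_duration_s, 2000)) {
    expect_lt(abs(total(t) - ref) / ref, 1e-6)
  }

  # NON_EVENT cells are static up to bleaching
  cfgb <- noiseless_config(bleach_rate_per_s = 1e-4)
  sn <- make_sample(cfgb, list(n_events = 0, n_nonevents = 1), seed = 3)
  a <- render_fluorescence(sn, 1, 100)$data
  b <- render_fluorescence(sn, 1, 700)$data
  expect_equal(a * exp(-1e-4 * (700 - 100)), b, tolerance = 1e-12)
})

test_that("zero cue contrast leaves pre-onset events indistinguishable", {
  cfg <- tiny_config(cue_contrast = 0)
  s <- make_sample(cfg, list(n_events = 1, n_nonevents = 1), seed = 7)
  ev <- which(s$cells$fate == "EVENT")
  ne <- which(s$cells$fate == "NON_EVENT")
  s$cells$t0_s[ev] <- 1e6  # deep inside the cue window for every draw below
  # same texture seed isolates the cue pathway from cell-to-cell variation
  s$cells$tex_seed[ne] <- s$cells$tex_seed[ev]
  s$cells[ne, c("cx", "cy", "radius_px", "agg_x", "agg_y")] <-
    s$cells[ev, c("cx", "cy", "radius_px", "agg_x", "agg_y")]
  times <- seq(1e6 - 500, 1e6 - 1, length.out = 50)
  px_ev <- unlist(lapply(times, function(t)
    render_fluorescence(s, s$cells$fov[ev], t)$data[1, 2, , ]))
  px_ne <- unlist(lapply(times, function(t)
    render_fluorescence(s, s$cells$fov[ne], t)$data[1, 2, , ]))
  ks <- suppressWarnings(stats::ks.test(px_ev, px_ne))
  expect_gt(ks$p.value, 0.01)
})

test_that("pre-onset cue contrast statistic grows with cue_contrast", {
  levels <- c(0.05, 0.25, 0.5, 0.75, 1)
  stat <- vapply(levels, function(cc) {
    cfg <- tiny_config(cue_contrast = cc)
    s <- event_sample(cfg, t0 = 2000, seed = 11)
    mean(vapply(seq(1950, 1999, length.out = 50), function(t) {
      img <- render_fluorescence(s, 1, t)$data[1, 2, , ]
      cell <- s$cells[1, ]
      site <- img[round(cell$agg_y) + (-2:2), round(cell$agg_x) + (-2:2)]
      max(site) / mean(img[img > mean(img)])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(stat) > 0))
})

test_that("brightfield renders cells, puncta and flat empty fields", {
  cfg <- tiny_config()
  # no cells -> flat background + noise
  s_empty <- make_sample(cfg, list(n_events = 0, n_nonevents = 1), seed = 1)
  s_empty$cells <- s_empty$cells[0, ]
  img <- render_brightfield(s_empty, 1, 0)$data[1, 1, , ]
  expect_lt(sd(img) / mean(img), 0.05)

  # mature aggregate -> local contrast beyond 3 x background SD
  s <- event_sample(cfg, t0 = 100, seed = 5)
  t_mature <- 100 + cfg$onset_duration_s + 60
  imgm <- render_brightfield(s, 1, t_mature)$data[1, 1, , ]
  bg <- imgm[1:10, 1:10]
  contrast <- max(abs(imgm - mean(bg))) / sd(bg)
  expect_gt(contrast, 3)

  # pre-onset EVENT and NON_EVENT agree in expectation (same geometry)
  imgp <- render_brightfield(s, 1, 10)$data[1, 1, , ]
  s$cells$t0_s[1] <- Inf
  imgn <- render_brightfield(s, 1, 10)$data[1, 1, , ]
  expect_lt(abs(mean(imgp) - mean(imgn)) / mean(imgn), 0.01)
})

test_that("spectra respect truth location, dwell linearity and broadening", {
  cfg <- noiseless_config()
  s <- event_sample(cfg, t0 = 100, seed = 2)
  t_mature <- 100 + cfg$onset_duration_s + 1
  px <- c(round(s$cells$agg_y[1]), round(s$cells$agg_x[1]))
  sp <- render_brillouin_spectrum(s, 1, px, t_mature, noise = FALSE)
  expect_identical(sp$truth$shift_GHz, 6.51)

  # anti-Stokes argmax within one bin of nu_B
  f <- sp$freq_axis_GHz
  lo <- f > 1 & f < cfg$fsr_GHz / 2
  expect_lt(abs(f[lo][which.max(sp$counts[lo])] - 6.51),
            cfg$fsr_GHz / cfg$n_spectral_bins + 1e-9)

  # doubling dwell doubles expected counts
  sp2 <- render_brillouin_spectrum(s, 1, px, t_mature,
                                   dwell_s = 2 * cfg$brillouin_dwell_s,
                                   noise = FALSE)
  expect_equal(sp2$counts, 2 * sp$counts, tolerance = 1e-12)

  # outside the cell: water-like background truth
  spb <- render_brillouin_spectrum(s, 1, c(2, 2), t_mature, noise = FALSE)
  expect_identical(spb$truth$shift_GHz,
                   s$brillouin_truth$background_shift_GHz)

  expect_error(render_brillouin_spectrum(s, 1, c(0, 5), 0), "outside")
})

test_that("ground-truth maps follow the endpoint grid convention and onset ramp", {
  cfg <- sim_config()  # full 352 px geometry holds a 35 um window
  s <- event_sample(cfg, t0 = 500, seed = 9)
  gm <- true_brillouin_maps(s, 1, 400, step_um = 1, fov_um = 35)
  expect_identical(dim(gm$shift_GHz), c(36L, 36L))
  expect_identical(sum(gm$aggregate_mask), 0L)  # pre-onset: no aggregate

  gm2 <- true_brillouin_maps(s, 1, 500 + cfg$onset_duration_s,
                             step_um = 0.2, fov_um = 10)
  expect_identical(dim(gm2$shift_GHz), c(51L, 51L))
  expect_gt(sum(gm2$aggregate_mask), 0)
  expect_true(all(gm2$shift_GHz[gm2$aggregate_mask] == 6.51))
  expect_true(all(gm2$aggregate_mask[gm2$aggregate_mask] ==
                    gm2$cell_mask[gm2$aggregate_mask]))  # agg within cell

  # mid-onset: interpolated strictly between periphery and aggregate truth
  gmm <- true_brillouin_maps(s, 1, 500 + cfg$onset_duration_s / 2,
                             step_um = 0.2, fov_um = 10)
  mid <- gmm$shift_GHz[gmm$aggregate_mask]
  expect_true(all(mid > 6.39 & mid < 6.51))
})

test_that("onset datasets have exact composition, valid labels, determinism", {
  cfg <- tiny_config()
  ds <- simulate_onset_dataset(cfg, n_events = 6, n_nonevents = 5,
                               T = 1, Z = 2, seed = 0)
  labs <- vapply(ds$examples, `[[`, integer(1), "label")
  expect_identical(sum(labs), 6L)
  expect_length(labs, 11L)
  expect_identical(dim(ds$examples[[1]]$tensor), c(1L, 2L, 64L, 64L))

  # EVENT examples are strictly pre-onset, inside the cue window
  offs <- ds$manifest$table$t0_offset_s[labs == 1]
  expect_true(all(offs > 0 & offs <= cfg$cue_lead_time_s))

  # NON_EVENT source cells never aggregate at any rendered time
  ne_cells <- ds$manifest$table$cell_id[labs == 0]
  expect_true(all(is.infinite(ds$sample$cells$t0_s[ne_cells])))

  ds2 <- simulate_onset_dataset(cfg, 6, 5, T = 1, Z = 2, seed = 0)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$examples[[3]]$tensor, ds2$examples[[3]]$tensor)

  # T, Z contracts
  expect_error(simulate_onset_dataset(cfg, 2, 2, T = 1, Z = 99, seed = 0),
               "Z must be")
  ds1 <- simulate_onset_dataset(cfg, 2, 2, T = 2, Z = 1, seed = 1)
  expect_identical(dim(ds1$examples[[1]]$tensor)[1:2], c(2L, 1L))
})

test_that("renderers are pure functions of (config, seed)", {
  cfg <- tiny_config()
  s <- event_sample(cfg, t0 = 800, seed = 4)
  expect_identical(render_fluorescence(s, 1, 300)$data,
                   render_fluorescence(s, 1, 300)$data)
  expect_identical(render_brightfield(s, 1, 300)$data,
                   render_brightfield(s, 1, 300)$data)
  expect_identical(render_brillouin_spectrum(s, 1, c(5, 5), 10)$counts,
                   render_brillouin_spectrum(s, 1, c(5, 5), 10)$counts)
  # different times draw different noise
  expect_false(identical(render_fluorescence(s, 1, 300)$data,
                         render_fluorescence(s, 1, 301)$data))
})
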