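# Shared fixtures: small, fast configurations for property tests.
# Geometry-faithful settings are exercised in test-acceptance.R.

tiny_config <- function(...) {
  benchmark_config(image_size_px = 64L, n_zplanes = 4L, ...)
}

# bleach_rate_per_s already defaults to 0; callers may override it
noiseless_config <- function(...) {
  tiny_config(photon_budget = Inf, read_noise_sd = 0, ...)
}

# A one-EVENT-cell sample with a controllable onset time.
event_sample <- function(config, t0 = 1000, seed = 42) {
  s <- make_sample(config, list(n_events = 1, n_nonevents = 0), seed = seed)
  s$cells$t0_s[1] <- t0
  s
}

# Toy feature-separable examples: class 1 carries a sharp punctum, class 0 a
# diffuse blob of the same total intensity.
toy_examples <- function(n_per_class = 20, size = 64, seed = 1) {
  set.seed(seed)
  mk <- function(label, id) {
    img <- matrix(50, size, size)
    cx <- size / 2 + runif(1, -5, 5); cy <- size / 2 + runif(1, -5, 5)
    sig <- if (label == 1) 2 else 10
    x <- seq_len(size)
    bump <- exp(-outer((x - cy)^2, (x - cx)^2, `+`) / (2 * sig^2))
    img <- img + 2000 * bump / sum(bump)
    img <- img + matrix(rnorm(size^2, sd = 0.5), size, size)
    arr <- array(pmax(img, 0), dim = c(1, 1, size, size))
    structure(list(tensor = arr, label = label,
                   meta = list(cell_id = id, t_obs_s = 0,
                               dt_to_t0_s = NA_real_)),
              class = "labeled_example")
  }
  c(lapply(seq_len(n_per_class), function(i) mk(1L, i)),
    lapply(seq_len(n_per_class), function(i) mk(0L, n_per_class + i)))
}
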