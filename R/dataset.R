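#' Simulate a labeled aggregation-onset dataset
#'
#' Renders time-lapse multi-plane fluorescence examples of events and
#' non-events. EVENT examples (label 1, "will aggregate") are sampled inside
#' the pre-onset cue window of an aggregating cell — the protein is still
#' fully soluble in every frame. NON_EVENT examples (label 0) come from
#' matched observation times in cells that never aggregate. The default
#' composition is 71 events / 68 non-events. The manifest records the seed,
#' per-example offsets to onset, and the configuration hash; two calls with
#' identical arguments produce identical datasets.
#'
#' @param config a [sim_config()].
#' @param n_events,n_nonevents exact class counts.
#' @param T number of timepoints per example (`>= 1`).
#' @param Z number of z-planes per frame (the `Z` planes closest to focus);
#'   must not exceed `config$n_zplanes`.
#' @param seed integer seed.
#' @return an `onset_dataset`: `examples` (list of `labeled_example`: a
#'   `T x Z x H x W` tensor, a binary label and metadata) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' ds <- simulate_onset_dataset(benchmark_config(), 5, 5, T = 1, Z = 2, seed = 0)
#' sum(ds$manifest$table$label)
#' }
simulate_onset_dataset <- function(config, n_events = 71L, n_nonevents = 68L,
                                   T = 1L, Z = config$n_zplanes, seed = 0L) {
  stopifnot(inherits(config, "sim_config"), T >= 1)
  T <- as.integer(T); Z <- as.integer(Z)
  if (Z < 1L || Z > config$n_zplanes)
    stop(sprintf("Z must be in 1..%d (requested %d)", config$n_zplanes, Z))

  sample <- make_sample(config,
                        list(n_events = n_events, n_nonevents = n_nonevents),
                        seed = derive_seed(seed, "dataset-sample"))
  dt <- config$frame_interval_s
  lead <- config$cue_lead_time_s
  t_min <- lead + (T - 1) * dt
  # ensure every event's full sequence fits inside the session, pre-onset
  ev <- sample$cells$fate == "EVENT"
  sample$cells$t0_s[ev] <- with_seed(derive_seed(seed, "dataset-t0"), {
    runif(sum(ev), t_min, max(config$session_length_s, t_min + 1))
  })

  zsel <- focus_planes(config, Z)
  n_all <- nrow(sample$cells)
  obs <- with_seed(derive_seed(seed, "dataset-times"), {
    u <- runif(n_all, 0.05, 0.9)
    t0_like <- ifelse(ev, sample$cells$t0_s,
                      runif(n_all, t_min, max(config$session_length_s,
                                              t_min + 1)))
    t0_like - u * lead
  })

  examples <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    times <- obs[i] - ((T - 1):0) * dt
    tensor <- array(0, dim = c(T, Z, config$image_size_px,
                               config$image_size_px))
    for (ti in seq_len(T)) {
      stk <- render_fluorescence(sample, position = sample$cells$fov[i],
                                 time_s = times[ti], config = config)
      tensor[ti, , , ] <- stk$data[1L, zsel, , , drop = FALSE]
    }
    examples[[i]] <- structure(list(
      tensor = tensor,
      label = if (ev[i]) 1L else 0L,
      meta = list(cell_id = sample$cells$id[i],
                  t_obs_s = obs[i],
                  dt_to_t0_s = if (ev[i]) sample$cells$t0_s[i] - obs[i]
                               else NA_real_)
    ), class = "labeled_example")
  }

  manifest <- list(
    table = data.frame(example = seq_len(n_all),
                       cell_id = sample$cells$id,
                       label = as.integer(ev),
                       t_obs_s = obs,
                       t0_offset_s = ifelse(ev, sample$cells$t0_s - obs,
                                            NA_real_)),
    T = T, Z = Z, seed = as.integer(seed),
    config_hash = sample$config_hash
  )
  structure(list(examples = examples, manifest = manifest, sample = sample),
            class = "onset_dataset")
}

# Indices of the Z planes closest to the focal plane, in axial order.
focus_planes <- function(config, Z) {
  zs <- (seq_len(config$n_zplanes) - (config$n_zplanes + 1) / 2) *
    config$z_spacing_um
  sort(order(abs(zs))[seq_len(Z)])
}

#' Simulate a labeled brightfield aggregate-presence dataset
#'
#' Positives are brightfield images of cells carrying a mature aggregate
#' (rendered after `t0 + onset_duration_s`); negatives are never-aggregating
#' cells at matched times. Label 1 = aggregate present. Single plane, single
#' timepoint.
#'
#' @inheritParams simulate_onset_dataset
#' @param n_pos,n_neg exact class counts.
#' @return an `onset_dataset`-shaped object with 1 x 1 x H x W tensors.
#' @export
simulate_brightfield_dataset <- function(config, n_pos = 100L, n_neg = 100L,
                                         seed = 0L) {
  stopifnot(inherits(config, "sim_config"))
  sample <- make_sample(config, list(n_events = n_pos, n_nonevents = n_neg),
                        seed = derive_seed(seed, "bf-sample"))
  ev <- sample$cells$fate == "EVENT"
  n_all <- nrow(sample$cells)
  obs <- with_seed(derive_seed(seed, "bf-times"), {
    extra <- runif(n_all, 60, 600)
    ifelse(ev, sample$cells$t0_s + config$onset_duration_s + extra,
           runif(n_all, 0, config$session_length_s))
  })
  examples <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    stk <- render_brightfield(sample, position = sample$cells$fov[i],
                              time_s = obs[i], config = config)
    examples[[i]] <- structure(list(
      tensor = stk$data,
      label = if (ev[i]) 1L else 0L,
      meta = list(cell_id = sample$cells$id[i], t_obs_s = obs[i],
                  dt_to_t0_s = NA_real_)
    ), class = "labeled_example")
  }
  manifest <- list(
    table = data.frame(example = seq_len(n_all),
                       cell_id = sample$cells$id,
                       label = as.integer(ev), t_obs_s = obs,
                       t0_offset_s = NA_real_),
    T = 1L, Z = 1L, seed = as.integer(seed),
    config_hash = sample$config_hash
  )
  structure(list(examples = examples, manifest = manifest, sample = sample),
            class = "onset_dataset")
}

#' @export
print.onset_dataset <- function(x, ...) {
  labs <- vapply(x$examples, `[[`, integer(1), "label")
  cat(sprintf("onset_dataset: %d examples (%d positive), T=%d Z=%d\n",
              length(labs), sum(labs), x$manifest$T, x$manifest$Z))
  invisible(x)
}
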