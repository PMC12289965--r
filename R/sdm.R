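#' Plan a stage-scan grid
#'
#' Row-major raster, or serpentine (odd rows reversed), covering each grid
#' cell exactly once.
#'
#' @param n_rows,n_cols grid dimensions (`>= 1`).
#' @param fov_um field-of-view side (um); positions step by `fov_um -
#'   overlap_um`.
#' @param overlap_um overlap between adjacent FOVs (must be `< fov_um`).
#' @param pattern `"RASTER"` or `"SERPENTINE"`.
#' @return data frame of ordered positions: `seq`, `row`, `col`, `x_um`,
#'   `y_um` (0-based rows/cols).
#' @export
#' @examples
#' plan_grid(2, 2, pattern = "SERPENTINE")[, c("row", "col")]
plan_grid <- function(n_rows, n_cols, fov_um = 39.072, overlap_um = 0,
                      pattern = c("RASTER", "SERPENTINE")) {
  pattern <- match.arg(pattern)
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (overlap_um >= fov_um) stop("overlap must be smaller than the FOV")
  step <- fov_um - overlap_um
  rows <- integer(0); cols <- integer(0)
  for (r in seq_len(n_rows) - 1L) {
    cc <- seq_len(n_cols) - 1L
    if (pattern == "SERPENTINE" && r %% 2L == 1L) cc <- rev(cc)
    rows <- c(rows, rep(r, n_cols)); cols <- c(cols, cc)
  }
  data.frame(seq = seq_along(rows), row = rows, col = cols,
             x_um = cols * step, y_um = rows * step)
}

#' Scan settings for one acquisition phase
#'
#' @param modalities ordered character vector from `"FLUOR"`,
#'   `"BRIGHTFIELD"`, `"BRILLOUIN"`.
#' @param exposure_s named (or recycled) exposures per modality (s), `> 0`.
#' @param power_level dimensionless scaling of the photon budget.
#' @param frame_interval_s interval between optimized-scan frames (s).
#' @param n_frames number of optimized-scan frames (`>= 1`).
#' @param brillouin_step_um,brillouin_fov_um Brillouin map geometry (used
#'   when `"BRILLOUIN"` is among the modalities).
#' @return a `scan_settings`.
#' @export
scan_settings <- function(modalities = "FLUOR", exposure_s = 0.1,
                          power_level = 1, frame_interval_s = 60,
                          n_frames = 1L, brillouin_step_um = 1,
                          brillouin_fov_um = 10) {
  modalities <- match.arg(modalities, c("FLUOR", "BRIGHTFIELD", "BRILLOUIN"),
                          several.ok = TRUE)
  exposure_s <- rep_len(exposure_s, length(modalities))
  names(exposure_s) <- modalities
  stopifnot(all(exposure_s > 0), n_frames >= 1, power_level > 0)
  structure(list(modalities = modalities, exposure_s = exposure_s,
                 power_level = power_level,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 brillouin_step_um = brillouin_step_um,
                 brillouin_fov_um = brillouin_fov_um),
            class = "scan_settings")
}

#' Control-model constructors
#'
#' `oracle_model()` reads the ground truth and scores 1 exactly when the
#' visited FOV hosts an EVENT cell whose cue-or-onset window
#' `[t0 - cue_lead_time, t0 + onset_duration)` covers the clock.
#' `constant_model()` always emits the given score; `constant_model(0)` is
#' the always-negative classifier. `random_model()` draws scores uniformly
#' from the session's RNG stream.
#'
#' @param sample the [make_sample()] ground truth the oracle may read.
#' @param score fixed score for `constant_model`.
#' @return a control model usable in [run_session()].
#' @export
oracle_model <- function(sample) {
  structure(list(sample = sample), class = c("oracle_model", "control_model"))
}

#' @rdname oracle_model
#' @export
constant_model <- function(score) {
  structure(list(score = score), class = c("constant_model", "control_model"))
}

#' @rdname oracle_model
#' @export
random_model <- function() {
  structure(list(), class = c("random_model", "control_model"))
}

# Score a visit. Control models never need pixels; sdm_models get the
# rendered tensor.
session_predict <- function(model, sample, position, clock, config, zsel) {
  if (inherits(model, "oracle_model")) {
    cell <- cell_for_fov(model$sample, position)
    pos <- !is.null(cell) && is.finite(cell$t0_s) &&
      clock >= cell$t0_s - config$cue_lead_time_s &&
      clock < cell$t0_s + config$onset_duration_s
    return(c(score = as.numeric(pos), label = as.numeric(pos)))
  }
  if (inherits(model, "constant_model")) {
    return(c(score = model$score,
             label = as.numeric(model$score >= 0.5)))
  }
  if (inherits(model, "random_model")) {
    sc <- runif(1)
    return(c(score = sc, label = as.numeric(sc >= 0.5)))
  }
  stk <- render_fluorescence(sample, position, clock, config)
  predict_example(model, stk$data[, zsel, , , drop = FALSE])
}

#' Run a self-driving acquisition session
#'
#' An initial low-dose scan visits every grid position once on a virtual
#' clock; each visit is scored by the model. In `BATCH` mode all FOVs are
#' acquired and scored first, positives are appended to a list, and the list
#' is then iterated with optimized scans in scan order. In `IMMEDIATE` mode
#' a positive prediction launches the optimized scan at that FOV before the
#' initial scan resumes at the next unvisited FOV. The clock advances by the
#' declared duration of every action (exposures, per-point Brillouin dwells,
#' a per-move overhead), and the sample evolves with the clock, so late
#' triggers can miss events. A FOV triggers at most once per session.
#'
#' @param sample a [make_sample()] virtual sample (the simulator handle).
#' @param model an `sdm_model` or a control model ([oracle_model()] etc.).
#' @param grid a [plan_grid()] data frame; rows/cols index the sample's
#'   stage grid.
#' @param initial [scan_settings()] for the exploration scan (`BRILLOUIN`
#'   is rejected here: exploration must stay fast and low-dose).
#' @param optimized [scan_settings()] for the triggered scan.
#' @param mode `"BATCH"` or `"IMMEDIATE"`.
#' @param clock_start virtual clock at session start (s).
#' @param move_overhead_s stage-move overhead added to each FOV's first
#'   acquisition (s).
#' @param seed session seed (scores of stochastic models, replay identity).
#' @return a `session_log`: `entries` data frame (`clock_s`, `fov`,
#'   `action`, `modality`, `score`, `label`, `duration_s`), mode, seed,
#'   config hash.
#' @export
run_session <- function(sample, model, grid,
                        initial = scan_settings("FLUOR", 0.1),
                        optimized = scan_settings("FLUOR", 0.5, n_frames = 3L),
                        mode = c("IMMEDIATE", "BATCH"),
                        clock_start = 0, move_overhead_s = 0.5, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "virtual_sample"),
            inherits(initial, "scan_settings"),
            inherits(optimized, "scan_settings"))
  if (nrow(grid) == 0) stop("empty grid")
  if ("BRILLOUIN" %in% initial$modalities)
    stop("BRILLOUIN is not allowed in the initial scan")
  config <- sample$config
  zsel <- if (inherits(model, "sdm_model"))
    focus_planes(config, model$arch$input_shape[2]) else seq_len(config$n_zplanes)
  if (inherits(model, "sdm_model")) {
    shape <- model$arch$input_shape
    if (shape[1] != 1L)
      stop("initial scans produce single-timepoint stacks; model wants T > 1")
    if (shape[3] != config$image_size_px || shape[4] != config$image_size_px)
      stop("model input shape does not match the initial-scan output shape")
  }

  # map grid rows/cols to the sample's FOV indices
  key <- paste(grid$row, grid$col)
  skey <- paste(sample$stage_grid$row, sample$stage_grid$col)
  fovs <- match(key, skey)
  if (anyNA(fovs)) stop("grid positions outside the sample's stage grid")

  entries <- list()
  clock <- clock_start
  log_entry <- function(action, fov, duration, modality = NA_character_,
                        score = NA_real_, label = NA_integer_) {
    entries[[length(entries) + 1L]] <<- data.frame(
      clock_s = clock, fov = fov, action = action, modality = modality,
      score = score, label = label, duration_s = duration)
    clock <<- clock + duration
  }

  init_acq_s <- move_overhead_s + sum(initial$exposure_s)
  frame_cost <- function(s) {
    cost <- sum(s$exposure_s[s$modalities != "BRILLOUIN"])
    if ("BRILLOUIN" %in% s$modalities) {
      npts <- (floor(s$brillouin_fov_um / s$brillouin_step_um) + 1L)^2
      cost <- cost + config$brillouin_dwell_s * npts
    }
    cost
  }
  run_optimized <- function(fov, first_move) {
    log_entry("TRIGGER", fov, 0)
    for (k in seq_len(optimized$n_frames)) {
      dur <- frame_cost(optimized) + if (k == 1L) first_move else 0
      if (k < optimized$n_frames)
        dur <- max(dur, optimized$frame_interval_s)
      log_entry("ACQUIRE_OPTIMIZED", fov, dur,
                modality = paste(optimized$modalities, collapse = "+"))
    }
  }

  triggered <- integer(0)
  pending <- integer(0)
  with_seed(derive_seed(seed, "session"), {
    for (i in seq_along(fovs)) {
      fov <- fovs[i]
      log_entry("ACQUIRE_INITIAL", fov, init_acq_s,
                modality = paste(initial$modalities, collapse = "+"))
      pr <- session_predict(model, sample, fov, clock, config, zsel)
      log_entry("PREDICT", fov, 0, score = pr[["score"]],
                label = as.integer(pr[["label"]]))
      if (pr[["label"]] >= 1 && !(fov %in% c(triggered, pending))) {
        if (mode == "IMMEDIATE") {
          run_optimized(fov, move_overhead_s)
          triggered <- c(triggered, fov)
          if (i < length(fovs)) log_entry("RESUME", fov, 0)
        } else {
          pending <- c(pending, fov)
        }
      }
    }
    if (mode == "BATCH") {
      for (fov in pending) {
        run_optimized(fov, move_overhead_s)
        triggered <- c(triggered, fov)
      }
    }
  })

  structure(list(entries = do.call(rbind, entries), mode = mode,
                 seed = as.integer(seed), config_hash = sample$config_hash,
                 initial = initial, optimized = optimized,
                 clock_start = clock_start,
                 move_overhead_s = move_overhead_s),
            class = "session_log")
}

#' Score a session against the ground truth
#'
#' A trigger is a true capture iff its FOV hosts an EVENT cell and the first
#' optimized frame starts before `t0 + onset_duration_s` (the transition has
#' not completed). Detection lead is `t0 - trigger_time`. The capture rate
#' is true captures over EVENT cells among visited FOVs.
#'
#' @param log a [run_session()] result.
#' @param sample the [make_sample()] sample the session ran against.
#' @return a `capture_report`: `n_true_events`, `n_triggered`,
#'   `n_true_captures`, `n_false_triggers`, `capture_rate`,
#'   `mean_detection_lead_s`.
#' @export
score_session <- function(log, sample) {
  stopifnot(inherits(log, "session_log"), inherits(sample, "virtual_sample"))
  if (!identical(log$config_hash, sample$config_hash))
    stop("session log and sample have different config hashes")
  e <- log$entries
  visited <- unique(e$fov[e$action == "ACQUIRE_INITIAL"])
  cells <- sample$cells[sample$cells$fov %in% visited, ]
  n_true_events <- sum(cells$fate == "EVENT")
  trig <- e[e$action == "TRIGGER", , drop = FALSE]
  n_true <- 0L; n_false <- 0L; leads <- numeric(0)
  if (nrow(trig) > 0) {
    for (k in seq_len(nrow(trig))) {
      fov <- trig$fov[k]
      cell <- cell_for_fov(sample, fov)
      opt <- e[e$action == "ACQUIRE_OPTIMIZED" & e$fov == fov &
                 e$clock_s >= trig$clock_s[k], , drop = FALSE]
      first_frame <- if (nrow(opt) > 0) opt$clock_s[1] else Inf
      is_event <- !is.null(cell) && cell$fate == "EVENT"
      if (is_event &&
          first_frame < cell$t0_s + sample$config$onset_duration_s) {
        n_true <- n_true + 1L
        leads <- c(leads, cell$t0_s - trig$clock_s[k])
      } else if (!is_event) {
        n_false <- n_false + 1L
      }
    }
  }
  structure(list(
    n_true_events = n_true_events,
    n_triggered = nrow(trig),
    n_true_captures = n_true,
    n_false_triggers = n_false,
    capture_rate = if (n_true_events > 0) n_true / n_true_events else NA_real_,
    mean_detection_lead_s = if (length(leads)) mean(leads) else NA_real_),
    class = "capture_report")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("session_log [%s]: %d entries, %d triggers, ends at %.1f s\n",
              x$mode, nrow(x$entries),
              sum(x$entries$action == "TRIGGER"),
              x$entries$clock_s[nrow(x$entries)] +
                x$entries$duration_s[nrow(x$entries)]))
  invisible(x)
}
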