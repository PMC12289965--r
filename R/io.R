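#' Save / load a trained model
#'
#' Models serialize to JSON (parameters at full precision) with the
#' architecture spec, feature-normalization contract, decision threshold and
#' training seed — everything needed to reproduce inference exactly.
#'
#' @param model an `sdm_model`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `sdm_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sdm_model"))
  out <- list(par = model$par,
              arch = unclass(model$arch),
              cfg = unclass(model$cfg),
              feat_stats = model$feat_stats,
              decision_threshold = model$decision_threshold,
              best_epoch = model$best_epoch, val_loss = model$val_loss)
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                collapse = "\n"))
  arch <- arch_spec(x$arch$variant, as.integer(x$arch$input_shape),
                    x$arch$width)
  cfg <- do.call(train_config, x$cfg)
  structure(list(par = as.numeric(x$par), arch = arch, cfg = cfg,
                 feat_stats = list(mu = as.numeric(x$feat_stats$mu),
                                   sd = as.numeric(x$feat_stats$sd)),
                 decision_threshold = x$decision_threshold,
                 best_epoch = x$best_epoch, val_loss = x$val_loss,
                 history = NULL),
            class = "sdm_model")
}

#' Save / load a virtual sample
#'
#' Ground-truth samples serialize to JSON so SDM sessions can be replayed
#' and scored from files.
#'
#' @param sample a [make_sample()] result.
#' @param path JSON file path.
#' @return `path` (save) or the restored `virtual_sample` (load).
#' @export
save_sample <- function(sample, path) {
  stopifnot(inherits(sample, "virtual_sample"))
  out <- list(config = unclass(sample$config), seed = sample$seed,
              stage_grid = sample$stage_grid, cells = sample$cells,
              brillouin_truth = sample$brillouin_truth,
              config_hash = sample$config_hash)
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE,
                                           digits = NA, na = "string")),
             path)
  invisible(path)
}

#' @rdname save_sample
#' @export
load_sample <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                collapse = "\n"))
  cfg <- do.call(sim_config, x$config)
  cells <- as.data.frame(x$cells)
  cells$t0_s <- suppressWarnings(as.numeric(cells$t0_s))
  cells$t0_s[is.na(cells$t0_s)] <- Inf
  structure(list(config = cfg, seed = as.integer(x$seed),
                 stage_grid = as.data.frame(x$stage_grid), cells = cells,
                 brillouin_truth = as.list(x$brillouin_truth),
                 config_hash = x$config_hash),
            class = "virtual_sample")
}

#' Write / read a session log as JSON-lines
#'
#' One JSON record per log entry, preceded by a header record carrying the
#' mode, seed and config hash.
#'
#' @param log a [run_session()] result.
#' @param path output path (conventionally `.jsonl`).
#' @return `path` (write) or the restored `session_log` (read).
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  hdr <- jsonlite::toJSON(list(record = "header", mode = log$mode,
                               seed = log$seed,
                               config_hash = log$config_hash),
                          auto_unbox = TRUE)
  lines <- vapply(seq_len(nrow(log$entries)), function(i)
    as.character(jsonlite::toJSON(c(list(record = "entry"),
                                    as.list(log$entries[i, ])),
                                  auto_unbox = TRUE, digits = NA, na = "null")),
    character(1))
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  hdr <- recs[[1]]
  if (!identical(hdr$record, "header"))
    stop("session log must start with a header record")
  entries <- do.call(rbind, lapply(recs[-1], function(r)
    data.frame(clock_s = r$clock_s, fov = r$fov, action = r$action,
               modality = if (is.null(r$modality)) NA_character_
                          else r$modality,
               score = if (is.null(r$score)) NA_real_ else r$score,
               label = if (is.null(r$label)) NA_integer_
                       else as.integer(r$label),
               duration_s = r$duration_s)))
  structure(list(entries = entries, mode = hdr$mode,
                 seed = as.integer(hdr$seed), config_hash = hdr$config_hash),
            class = "session_log")
}

#' Write / read a grid of Brillouin spectra as CSV
#'
#' Long format: `row`, `col`, `freq_GHz`, `counts`, with the dwell recorded
#' in a comment-free side column.
#'
#' @param grid a `spectra_grid` from [acquire_brillouin_grid()].
#' @param path CSV path.
#' @return `path` (write) or a `spectra_grid` (read).
#' @export
write_spectra_csv <- function(grid, path) {
  stopifnot(inherits(grid, "spectra_grid"))
  n <- grid$n_pts; f <- grid$freq_axis_GHz
  rows <- vector("list", n * n)
  k <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sp <- grid$spectra[[i, j]]
    rows[[k]] <- data.frame(row = i, col = j, freq_GHz = f,
                            counts = sp$counts, dwell_s = sp$dwell_s)
    k <- k + 1L
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path)
  need <- c("row", "col", "freq_GHz", "counts")
  if (!all(need %in% names(df)))
    stop("spectra CSV must have columns row, col, freq_GHz, counts")
  n <- max(df$row)
  stopifnot(max(df$col) == n)
  f <- sort(unique(df$freq_GHz))
  spectra <- vector("list", n * n)
  dim(spectra) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sub <- df[df$row == i & df$col == j, ]
    sub <- sub[order(sub$freq_GHz), ]
    spectra[[i, j]] <- structure(
      list(freq_axis_GHz = sub$freq_GHz, counts = sub$counts,
           dwell_s = if ("dwell_s" %in% names(sub)) sub$dwell_s[1] else NA,
           pixel_index = c(i, j)),
      class = "brillouin_spectrum")
  }
  structure(list(spectra = spectra, freq_axis_GHz = f, n_pts = n,
                 step_um = NA_real_, dwell_s = NA_real_, time_s = NA_real_),
            class = "spectra_grid")
}

#' Write a Brillouin map as CSV
#'
#' Long format `row`, `col`, `shift_GHz`, `linewidth_GHz`, `valid`.
#'
#' @param map a [build_map()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  n <- nrow(map$shift_map)
  grid <- expand.grid(row = seq_len(n), col = seq_len(ncol(map$shift_map)))
  df <- data.frame(grid,
                   shift_GHz = map$shift_map[as.matrix(grid)],
                   linewidth_GHz = map$linewidth_map[as.matrix(grid)],
                   valid = map$valid_mask[as.matrix(grid)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Dataset directory layout: example_XXX.tif + manifest.json.
write_dataset_dir <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(ds$examples))
  for (i in seq_along(ds$examples)) {
    ex <- ds$examples[[i]]
    paths[i] <- file.path(dir, sprintf("example_%03d.tif", i))
    stk <- image_stack(ex$tensor,
                       timestamps_s = seq_len(dim(ex$tensor)[1]) - 1)
    write_stack(stk, paths[i])
  }
  man <- ds$manifest
  man$table$file <- basename(paths)
  writeLines(as.character(jsonlite::toJSON(man, auto_unbox = TRUE,
                                           digits = NA, na = "null")),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

read_dataset_dir <- function(dir) {
  man <- jsonlite::fromJSON(paste(readLines(file.path(dir, "manifest.json"),
                                            warn = FALSE), collapse = "\n"))
  tab <- as.data.frame(man$table)
  examples <- lapply(seq_len(nrow(tab)), function(i) {
    stk <- read_stack(file.path(dir, tab$file[i]))
    structure(list(tensor = stk$data, label = as.integer(tab$label[i]),
                   meta = list(cell_id = tab$cell_id[i],
                               t_obs_s = tab$t_obs_s[i],
                               dt_to_t0_s = tab$t0_offset_s[i])),
              class = "labeled_example")
  })
  structure(list(examples = examples,
                 manifest = list(table = tab, T = man$T, Z = man$Z,
                                 seed = man$seed,
                                 config_hash = man$config_hash)),
            class = "onset_dataset")
}
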