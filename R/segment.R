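#' Segment aggregate, signal and periphery regions
#'
#' The fluorescence image localizes the aggregating region (Otsu foreground);
#' the shift and linewidth maps provide the full signal support, without
#' background (Otsu foreground of each map). The aggregate mask is subtracted
#' from each signal mask to obtain the periphery: each quantity's statistic
#' uses its own periphery mask. The fluorescence image must already be
#' resampled to the map grid (nearest neighbor); see [resample_to_map()].
#'
#' @param fluor_image numeric matrix on the map grid.
#' @param map a [build_map()] result.
#' @return a `region_masks` list: `aggregate`, `signal_shift`, `signal_lw`,
#'   `periphery_shift`, `periphery_lw` (logical matrices).
#' @export
segment_regions <- function(fluor_image, map) {
  stopifnot(all(dim(fluor_image) == dim(map$shift_map)))
  otsu_mask <- function(img, valid = NULL) {
    vals <- if (is.null(valid)) img else img[valid]
    vals <- vals[is.finite(vals)]
    if (length(unique(vals)) < 2) return(array(FALSE, dim(img)))
    thr <- otsu_threshold(vals)
    out <- img > thr
    out[!is.finite(img)] <- FALSE
    if (!is.null(valid)) out <- out & valid
    out
  }
  aggregate <- otsu_mask(fluor_image)
  signal_shift <- otsu_mask(map$shift_map, map$valid_mask)
  signal_lw <- otsu_mask(map$linewidth_map, map$valid_mask)
  structure(list(aggregate = aggregate,
                 signal_shift = signal_shift,
                 signal_lw = signal_lw,
                 periphery_shift = signal_shift & !aggregate,
                 periphery_lw = signal_lw & !aggregate),
            class = "region_masks")
}

#' Resample an acquired image onto a Brillouin map grid
#'
#' Nearest-neighbor lookup of the camera image at the map's sample points.
#'
#' @param image H x W numeric matrix in camera pixels.
#' @param grid the `grid` element of a [true_brillouin_maps()] result (or
#'   any list with `x_px`, `y_px`).
#' @return a matrix on the map grid.
#' @export
resample_to_map <- function(image, grid) {
  n <- nrow(image)
  ri <- pmin(pmax(round(grid$y_px), 1L), n)
  ci <- pmin(pmax(round(grid$x_px), 1L), ncol(image))
  out <- image[ri, ci, drop = FALSE]
  matrix(out, length(ri), length(ci))
}

#' Region statistics over time
#'
#' Mean and standard deviation of the Brillouin shift and (deconvolved)
#' linewidth over the aggregate and periphery regions at each timepoint,
#' restricted to valid fit pixels. Empty regions are omitted with a flag
#' (`n = 0`, `NA` statistics) — the valid pre-onset state.
#'
#' @param maps list of [build_map()] results (one per timepoint).
#' @param masks list of [segment_regions()] results, parallel to `maps`.
#' @return a `region_stats` data frame: `timepoint`, `region`, `quantity`,
#'   `mean`, `sd`, `n`.
#' @export
region_stats <- function(maps, masks) {
  stopifnot(length(maps) == length(masks), length(maps) >= 1)
  rows <- list()
  for (ti in seq_along(maps)) {
    map <- maps[[ti]]; mk <- masks[[ti]]
    pull <- function(vals, region) {
      v <- vals[region & map$valid_mask]
      v <- v[is.finite(v)]
      data.frame(mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v)) sd(v) else NA_real_,
                 n = length(v))
    }
    for (spec in list(
      list("aggregate", "shift", map$shift_map, mk$aggregate),
      list("periphery", "shift", map$shift_map, mk$periphery_shift),
      list("aggregate", "linewidth", map$linewidth_map, mk$aggregate),
      list("periphery", "linewidth", map$linewidth_map, mk$periphery_lw))) {
      st <- pull(spec[[3]], spec[[4]])
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = ti, region = spec[[1]], quantity = spec[[2]],
        mean = st$mean, sd = st$sd, n = st$n)
    }
  }
  out <- do.call(rbind, rows)
  # single-pixel regions have sd 0, not NA
  out$sd[out$n == 1] <- 0
  class(out) <- c("region_stats", class(out))
  out
}
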