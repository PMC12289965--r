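#' Min-max normalize an image to [0, 1]
#'
#' Each image is rescaled independently before entering a classifier:
#' `(img - min) / (max - min)`. A constant image maps to all zeros (the
#' declared degenerate case). Idempotent on non-constant input.
#'
#' @param img numeric matrix/array of finite intensities.
#' @return object of the same shape with values in `[0, 1]`.
#' @export
#' @examples
#' normalize_image(matrix(c(0, 5, 10), 1))
normalize_image <- function(img) {
  if (!all(is.finite(img))) stop("normalize_image: non-finite values in input")
  rng <- range(img)
  if (rng[1] == rng[2]) {
    img[] <- 0
    return(img)
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Stratified, cell-disjoint train/validation/test split
#'
#' Splits a labeled dataset into disjoint, exhaustive train/validation/test
#' subsets. The split is stratified by label, and examples originating from
#' the same source cell never straddle subsets (prevents leakage between
#' sequences of one cell). Sizes follow the floor convention with the
#' remainder going to train: `n_test = floor(n * test_fraction)` per the
#' whole set, then `n_val = floor(n_rest * val_fraction)`.
#'
#' @param data an `onset_dataset` or a plain list of `labeled_example`s.
#' @param test_fraction fraction held out for test (default 0.15).
#' @param val_fraction fraction of the *remainder* used for validation
#'   (default 0.20).
#' @param seed integer seed controlling the shuffle.
#' @return list with `train`, `val`, `test` (lists of examples) and `index`
#'   (the assignment table).
#' @export
split_dataset <- function(data, test_fraction = 0.15, val_fraction = 0.20,
                          seed = 0L) {
  examples <- if (inherits(data, "onset_dataset")) data$examples else data
  stopifnot(length(examples) >= 2)
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie in (0, 1)")
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must lie in (0, 1)")
  labels <- vapply(examples, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2)
    stop("both classes must be present to split")
  cells <- vapply(examples, function(e) as.integer(e$meta$cell_id),
                  integer(1))

  n <- length(examples)
  n_test <- floor(n * test_fraction)
  n_val <- floor((n - n_test) * val_fraction)

  # Per-class targets (floor, remainder to the larger class first)
  assign <- rep("train", n)
  # largest-remainder allocation: per-class quotas that sum exactly to the
  # requested split size
  class_quotas <- function(want, class_sizes) {
    frac <- want * class_sizes / sum(class_sizes)
    base <- floor(frac)
    extra <- want - sum(base)
    if (extra > 0) {
      ord <- order(frac - base, decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
    }
    base
  }

  with_seed(derive_seed(seed, "split"), {
    for (split in list(c("test", n_test), c("val", n_val))) {
      want <- as.integer(split[2])
      labs <- sort(unique(labels))
      quotas <- class_quotas(want, vapply(labs, function(l)
        sum(labels == l), numeric(1)))
      # stratified quotas for this split among still-unassigned examples
      for (li in seq_along(labs)) {
        lab <- labs[li]
        pool_ex <- which(assign == "train" & labels == lab)
        quota <- quotas[li]
        # draw whole cells until the quota is met (cell-disjointness)
        pool_cells <- unique(cells[pool_ex])
        pool_cells <- base::sample(pool_cells)
        taken <- 0L
        for (cl in pool_cells) {
          if (taken >= quota) break
          idx <- pool_ex[cells[pool_ex] == cl]
          assign[idx] <- split[1]
          taken <- taken + length(idx)
        }
      }
    }
  })

  index <- data.frame(example = seq_len(n), label = labels, cell = cells,
                      split = assign)
  list(train = examples[assign == "train"],
       val = examples[assign == "val"],
       test = examples[assign == "test"],
       index = index)
}
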