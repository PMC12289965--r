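#' Otsu threshold of an image
#'
#' Classic histogram thresholding: the returned threshold maximizes the
#' between-class variance over a binned histogram. Ties are broken toward
#' the lowest threshold. Foreground convention: `value > threshold`.
#'
#' @param image numeric matrix/vector with at least two distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold (a bin edge), a numeric scalar.
#' @export
#' @examples
#' otsu_threshold(c(1, 1, 1, 10, 10))
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("otsu_threshold: constant image has no threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, all.inside = TRUE),
                               1L), n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  n <- length(x)
  w0 <- cumsum(counts) / n               # weight of class <= edge k+1
  m0 <- cumsum(counts * mids) / n        # unnormalized class mean
  mt <- m0[n_bins]
  w1 <- 1 - w0
  # between-class variance at each candidate split (after bin k)
  num <- (mt * w0 - m0)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, -Inf)
  bcv <- bcv[-n_bins]                    # split after the last bin is void
  k <- which.max(bcv)                    # which.max takes the first maximum
  edges[k + 1L]
}
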