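# Independent oracles used by the equivalence tests. These re-derive the
# quantities by exhaustive search / direct formulas and must stay independent
# of the implementation paths they check.

# Exhaustive (nu, gamma) grid search for the Brillouin fit, sharing the
# fitter's residual definition (profiled linear amplitudes). Coarse global
# pass followed by a 1 MHz local pass. Returns the grid minimum.
grid_fit_oracle <- function(spec, fsr, instr = 0.27, guard = 0.5) {
  f <- spec$freq_axis_GHz
  y <- spec$counts
  win <- f > guard & f < fsr - guard
  fw <- f[win]; yw <- y[win]
  ray <- (instr / 2)^2 / (fw^2 + (instr / 2)^2) +
    (instr / 2)^2 / ((fw - fsr)^2 + (instr / 2)^2)
  rss_for <- function(nus, gam) {
    hw2 <- (gam / 2)^2
    M <- hw2 / (outer(fw, nus, `-`)^2 + hw2) +
      hw2 / (outer(fw, fsr - nus, `-`)^2 + hw2)
    vapply(seq_along(nus), function(k) {
      X <- cbind(M[, k], ray, 1)
      cf <- qr.coef(qr(X), yw)
      sum((yw - X %*% cf)^2)
    }, numeric(1))
  }
  scan <- function(nus, gams) {
    best <- c(Inf, NA, NA)
    for (g in gams) {
      r <- rss_for(nus, g)
      k <- which.min(r)
      if (r[k] < best[1]) best <- c(r[k], nus[k], g)
    }
    best
  }
  coarse <- scan(seq(guard + 0.05, fsr / 2 - 0.05, by = 0.05),
                 seq(0.1, 1.6, by = 0.05))
  fine <- scan(seq(coarse[2] - 0.05, coarse[2] + 0.05, by = 0.001),
               seq(max(coarse[3] - 0.05, 0.01), coarse[3] + 0.05,
                   by = 0.001))
  list(nu = fine[2], gamma = fine[3], rss = fine[1])
}

# Brute-force Otsu: try every histogram split, maximizing the between-class
# variance computed directly from class weights and means.
otsu_brute <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1L), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  counts <- tabulate(bin, nbins = n_bins)
  best <- -Inf; best_k <- NA
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    v <- (w0 / sum(counts)) * (w1 / sum(counts)) * (m0 - m1)^2
    if (v > best + 1e-12) { best <- v; best_k <- k }
  }
  edges[best_k + 1L]
}
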