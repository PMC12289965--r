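# Fixed convolutional feature stem.
#
# With no deep-learning framework in the environment, the desk-scale
# architectures use a frozen filter bank as their convolutional stem,
# followed by trainable heads (see nnet.R) -- the scattering-network idea:
# fixed conv features, learned classifier on top. The bank is matched to the
# punctum physics: a difference-of-Gaussians band-pass at proto-punctum
# scale (sigma ~1-3 px), re-smoothed at punctum scale (matched filter), a
# local-variance map (the cue's speckle component), and, when several
# z-planes are available, a focus-minus-defocus contrast map that cancels
# the smooth cytosolic texture shared by all planes while keeping the
# axially confined punctum.

# Feature maps for one plane (full resolution, normalized to [0,1]).
plane_maps <- function(x) {
  d <- gauss_blur(x, 1.2) - gauss_blur(x, 3.5)  # punctum band-pass
  md <- gauss_blur(d, 1.8)                      # matched smoothing
  lv <- pmax(gauss_blur(x^2, 3) - gauss_blur(x, 3)^2, 0)
  list(x = x, d = d, md = md, lv = lv)
}

# 10 pooled statistics summarizing one plane. Both tails of the band-pass
# response are pooled: fluorescent puncta are bright (max side), brightfield
# aggregates are absorption dips (min side).
plane_features <- function(plane) {
  x <- normalize_image(plane)
  m <- plane_maps(x)
  msd <- sd(as.numeric(m$md)) + 1e-9
  c(md_max = max(m$md),
    md_q999 = as.numeric(quantile(m$md, 0.999)),
    md_q995 = as.numeric(quantile(m$md, 0.995)),
    md_con = (max(m$md) - mean(m$md)) / msd,
    md_min = min(m$md),
    md_negcon = (mean(m$md) - min(m$md)) / msd,
    d_sd = sd(as.numeric(m$d)),
    lv_max = max(m$lv),
    lv_q995 = as.numeric(quantile(m$lv, 0.995)),
    lv_sd = sd(as.numeric(m$lv)))
}

# Focus-minus-defocus contrast features (requires >= 2 planes): smooth
# texture is shared across planes and cancels; the punctum, confined near
# focus, survives.
zcontrast_features <- function(frame_zyx) {
  Zn <- dim(frame_zyx)[1]
  near <- normalize_image(frame_zyx[(Zn + 1) %/% 2, , ])
  far <- normalize_image(frame_zyx[1, , ])
  dz <- gauss_blur(near - far, 1.8)
  c(zc_max = max(dz),
    zc_q999 = as.numeric(quantile(dz, 0.999)),
    zc_con = (max(dz) - mean(dz)) / (sd(as.numeric(dz)) + 1e-9))
}

# Per-frame feature vector. Single-plane frames get the full per-plane
# statistics. Multi-plane frames add cross-plane aggregates rather than
# concatenating every plane's statistics: the punctum is axially confined,
# so its matched-filter response peaks sharply at focus, while out-of-focus
# planes carry mostly diluted copies of the same texture. Aggregating keeps
# the informative z-structure without flooding the head with weak inputs.
frame_features <- function(frame_zyx) {
  Zn <- dim(frame_zyx)[1]
  focus <- plane_features(frame_zyx[(Zn + 1) %/% 2, , ])
  if (Zn == 1) return(focus)
  md_prof <- vapply(seq_len(Zn), function(zi) {
    x <- normalize_image(frame_zyx[zi, , ])
    md <- gauss_blur(gauss_blur(x, 1.2) - gauss_blur(x, 3.5), 1.8)
    max(md)
  }, numeric(1))
  outer_planes <- c(1L, Zn)
  c(focus,
    zprof_max = max(md_prof),
    zprof_mean = mean(md_prof),
    zprof_sharp = md_prof[(Zn + 1) %/% 2] - mean(md_prof[outer_planes]),
    zcontrast_features(frame_zyx))
}

# Patch tokens for the attention heads: the plane is cut into a grid of
# patches; each token is (matched-filter max, band-pass sd, local-variance
# mean, intensity mean, row, col).
plane_tokens <- function(plane, grid = 8L) {
  x <- normalize_image(plane)
  m <- plane_maps(x)
  n <- nrow(x)
  p <- n %/% grid
  toks <- matrix(0, grid * grid, 6L)
  k <- 1L
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      ri <- ((i - 1L) * p + 1L):(i * p)
      cj <- ((j - 1L) * p + 1L):(j * p)
      toks[k, ] <- c(max(m$md[ri, cj]), sd(as.numeric(m$d[ri, cj])),
                     mean(m$lv[ri, cj]), mean(m$x[ri, cj]),
                     (i - (grid + 1) / 2) / grid, (j - (grid + 1) / 2) / grid)
      k <- k + 1L
    }
  }
  toks
}

# Featurize a T x Z x H x W tensor for a given architecture variant.
# Returns a numeric vector (dense variants), a T x d matrix (recurrent), or
# a tokens matrix (attention variants).
featurize_tensor <- function(tensor, variant) {
  d <- dim(tensor)
  Tn <- d[1]; Zn <- d[2]
  frame <- function(ti) {
    f <- tensor[ti, , , , drop = FALSE]
    dim(f) <- d[2:4]
    f
  }
  switch(variant,
    SINGLE_FRAME_CONV = frame_features(frame(1L)),
    CONV_RECURRENT = {
      first <- frame_features(frame(1L))
      t(vapply(seq_len(Tn), function(ti) frame_features(frame(ti)),
               numeric(length(first))))
    },
    SINGLE_FRAME_ATTENTION = {
      do.call(rbind, lapply(seq_len(Zn), function(zi) {
        toks <- plane_tokens(tensor[1L, zi, , ])
        cbind(toks, z = (zi - (Zn + 1) / 2) / max(Zn, 2))
      }))
    },
    VIDEO_ATTENTION = {
      do.call(rbind, lapply(seq_len(Tn), function(ti)
        do.call(rbind, lapply(seq_len(Zn), function(zi) {
          toks <- plane_tokens(tensor[ti, zi, , ])
          cbind(toks, z = (zi - (Zn + 1) / 2) / max(Zn, 2),
                t = (ti - (Tn + 1) / 2) / max(Tn, 2))
        }))))
    },
    stop("unknown variant: ", variant))
}
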