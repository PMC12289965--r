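#' Multi-dimensional image stack
#'
#' Container for acquired images: a T x Z x H x W array of nonnegative
#' intensities with strictly increasing timestamps, a modality tag and a
#' snapshot of the acquisition settings.
#'
#' @param data numeric array with dim (T, Z, H, W); 2D/3D inputs are promoted.
#' @param timestamps_s numeric vector of length T, strictly increasing.
#' @param modality `"FLUOR"` or `"BRIGHTFIELD"`.
#' @param position FOV index (or any position identifier).
#' @param settings optional list snapshot of the acquisition settings.
#' @return an `image_stack`.
#' @export
image_stack <- function(data, timestamps_s = 0, modality = "FLUOR",
                        position = NA_integer_, settings = list()) {
  if (length(dim(data)) == 2L) dim(data) <- c(1L, 1L, dim(data))
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  stopifnot(length(dim(data)) == 4L)
  if (any(data < 0)) stop("intensities must be >= 0")
  stopifnot(length(timestamps_s) == dim(data)[1L])
  if (any(diff(timestamps_s) <= 0)) stop("timestamps must be strictly increasing")
  modality <- match.arg(modality, c("FLUOR", "BRIGHTFIELD"))
  structure(list(data = data, timestamps_s = as.numeric(timestamps_s),
                 modality = modality, position = position,
                 settings = settings),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack [%s] T=%d Z=%d %dx%d, t0=%.1fs\n",
              x$modality, d[1], d[2], d[3], d[4], x$timestamps_s[1]))
  invisible(x)
}

# cache of kernel FFTs keyed by (n, sigma)
.blur_cache <- new.env(parent = emptyenv())

# Circular (FFT) Gaussian blur of an n x n image. Circular convolution with a
# normalized kernel conserves the pixel sum exactly, which the fluorescence
# conservation invariant relies on.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  key <- sprintf("%d_%.4f", n, sigma)
  kf <- .blur_cache[[key]]
  if (is.null(kf)) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # wraparound distances
    k1 <- exp(-d^2 / (2 * sigma^2))
    kern <- outer(k1, k1)
    kern <- kern / sum(kern)
    kf <- fft(kern)
    .blur_cache[[key]] <- kf
  }
  Re(fft(fft(img) * kf, inverse = TRUE)) / n^2
}

# Unnormalized 2D Gaussian bump exp(-r^2 / 2 sigma^2) at (cx, cy) (pixels).
gauss_bump <- function(n, cx, cy, sigma) {
  x <- seq_len(n)
  outer((x - cy)^2, (x - cx)^2, `+`) |> (\(r2) exp(-r2 / (2 * sigma^2)))()
}

# Apply the shot + read noise model to an image in expected-photon units.
# `shot = FALSE` (used when the photon budget is infinite) disables shot
# noise; read_noise_sd = 0 disables read noise. Output is clamped at 0 so
# intensities stay nonnegative.
apply_noise <- function(img, shot = TRUE, read_noise_sd = 0) {
  out <- img
  if (shot) {
    out <- rpois(length(img), pmax(img, 0))
    dim(out) <- dim(img)
  }
  if (read_noise_sd > 0) {
    out <- out + rnorm(length(out), sd = read_noise_sd)
  }
  pmax(out, 0)
}
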