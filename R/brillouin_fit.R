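#' Fit a Brillouin spectrum
#'
#' Nonlinear least squares of `baseline + A * (L(nu) + L(FSR - nu))`, two
#' mirrored Lorentzians with a shared measured width, to the counts over one
#' free spectral range. Rayleigh guard bands (0.5 GHz at both axis ends) are
#' excluded from the fit window, and the residual Rayleigh tails reaching
#' into the window are absorbed by two fixed-width (instrumental) Lorentzian
#' components at 0 and FSR whose common amplitude enters linearly. All
#' linear parameters (Brillouin amplitude, Rayleigh amplitude, baseline)
#' are profiled out, so only `(nu, Gamma_meas)` are optimized;
#' initialization comes from the largest local maximum outside the guard
#' bands. The reported shift is the
#' anti-Stokes center, in `(0, FSR/2)`. The measured width is then
#' deconvolved via [deconvolve_linewidth()].
#'
#' @param spec a `brillouin_spectrum` (or list with `freq_axis_GHz`, `counts`).
#' @param fsr_GHz free spectral range (GHz).
#' @param instr_GHz instrumental FWHM subtracted from the measured width.
#' @param init optional `c(nu, gamma)` starting point.
#' @param guard_GHz half-width of the Rayleigh exclusion bands.
#' @return a `spectral_fit`: `shift_GHz`, `linewidth_meas_GHz`,
#'   `linewidth_corr_GHz`, `amplitude`, `baseline`, `residual_rms`, `valid`.
#' @export
fit_spectrum <- function(spec, fsr_GHz, instr_GHz = 0.270, init = NULL,
                         guard_GHz = 0.5) {
  f <- spec$freq_axis_GHz
  y <- spec$counts
  stopifnot(length(f) >= 32, length(f) == length(y))
  invalid <- function() structure(
    list(shift_GHz = NA_real_, linewidth_meas_GHz = NA_real_,
         linewidth_corr_GHz = NA_real_, amplitude = NA_real_,
         baseline = NA_real_, residual_rms = NA_real_, valid = FALSE),
    class = "spectral_fit")
  if (!any(y > 0)) return(invalid())

  win <- f > guard_GHz & f < fsr_GHz - guard_GHz
  fw <- f[win]; yw <- y[win]
  if (length(fw) < 16) return(invalid())

  # detection gate: a peak must rise above baseline + 3 sigma
  base0 <- stats::median(yw)
  sig0 <- stats::mad(yw)
  if (sig0 <= 0) sig0 <- sqrt(max(base0, 1))
  if (max(yw) < base0 + 3 * sig0) return(invalid())

  if (is.null(init)) {
    pk <- fw[which.max(yw)]
    nu0 <- min(pk, fsr_GHz - pk)
    init <- c(nu0, 0.6)
  }

  # profiled residual: for fixed (nu, gamma), the Brillouin amplitude,
  # Rayleigh-tail amplitude and baseline solve a small linear LSQ problem
  rayleigh <- lorentz(fw, 0, instr_GHz) + lorentz(fw, fsr_GHz, instr_GHz)
  profile_rss <- function(p) {
    nu <- p[1]; gam <- p[2]
    m <- lorentz(fw, nu, gam) + lorentz(fw, fsr_GHz - nu, gam)
    X <- cbind(m, rayleigh, 1)
    cf <- tryCatch(qr.coef(qr(X), yw), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(1e18)
    sum((yw - X %*% cf)^2)
  }
  opt <- tryCatch(
    optim(init, profile_rss, method = "L-BFGS-B",
          lower = c(guard_GHz, 0.05), upper = c(fsr_GHz / 2, fsr_GHz / 2)),
    error = function(e) NULL)
  if (is.null(opt)) return(invalid())
  nu <- opt$par[1]; gam <- opt$par[2]
  m <- lorentz(fw, nu, gam) + lorentz(fw, fsr_GHz - nu, gam)
  X <- cbind(m, rayleigh, 1)
  cf <- qr.coef(qr(X), yw)
  resid <- yw - X %*% cf
  dec <- deconvolve_linewidth(gam, instr_GHz)
  valid <- is.finite(nu) && nu > 0 && nu < fsr_GHz / 2 && gam > 0 &&
    cf[1] > 0 && dec$valid
  structure(list(shift_GHz = nu, linewidth_meas_GHz = gam,
                 linewidth_corr_GHz = dec$linewidth_corr_GHz,
                 amplitude = unname(cf[1]), baseline = unname(cf[3]),
                 residual_rms = sqrt(mean(resid^2)), valid = valid),
            class = "spectral_fit")
}

#' Deconvolve the instrumental linewidth
#'
#' For Lorentzian lineshapes, convolution adds full widths exactly, so the
#' instrumental response of the spectrometer (270 MHz by default) is removed
#' from the measured width by plain subtraction. A result at or below zero
#' is clamped to 0 and flagged invalid (the peak is unresolved).
#'
#' @param linewidth_meas_GHz measured FWHM (GHz), `> 0`.
#' @param instr_GHz instrumental FWHM (GHz).
#' @return list with `linewidth_corr_GHz` and `valid`.
#' @export
#' @examples
#' deconvolve_linewidth(0.85, 0.27)  # 0.58 GHz
deconvolve_linewidth <- function(linewidth_meas_GHz, instr_GHz = 0.270) {
  if (!is.finite(linewidth_meas_GHz) || linewidth_meas_GHz <= 0)
    stop("measured linewidth must be positive")
  corr <- linewidth_meas_GHz - instr_GHz
  if (corr <= 0) list(linewidth_corr_GHz = 0, valid = FALSE)
  else list(linewidth_corr_GHz = corr, valid = TRUE)
}

#' Build Brillouin shift and linewidth maps from a grid of spectra
#'
#' Fits every pixel's spectrum and assembles shift and (deconvolved)
#' linewidth maps with a validity mask.
#'
#' @param grid a `spectra_grid` from [acquire_brillouin_grid()], or a
#'   list-matrix of `brillouin_spectrum` objects.
#' @param fsr_GHz free spectral range (GHz).
#' @param instr_GHz instrumental FWHM (GHz).
#' @return a `brillouin_map`: `shift_map`, `linewidth_map`, `valid_mask`,
#'   `step_um`, `timestamp_s`.
#' @export
build_map <- function(grid, fsr_GHz, instr_GHz = 0.270) {
  spectra <- if (inherits(grid, "spectra_grid")) grid$spectra else grid
  stopifnot(is.matrix(spectra) || is.array(spectra))
  nr <- nrow(spectra); nc <- ncol(spectra)
  shift <- matrix(NA_real_, nr, nc)
  lw <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ft <- fit_spectrum(spectra[[i, j]], fsr_GHz, instr_GHz)
      if (ft$valid) {
        shift[i, j] <- ft$shift_GHz
        lw[i, j] <- ft$linewidth_corr_GHz
        valid[i, j] <- TRUE
      }
    }
  }
  structure(list(shift_map = shift, linewidth_map = lw, valid_mask = valid,
                 step_um = if (inherits(grid, "spectra_grid")) grid$step_um
                           else NA_real_,
                 timestamp_s = if (inherits(grid, "spectra_grid"))
                   grid$time_s else NA_real_),
            class = "brillouin_map")
}
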