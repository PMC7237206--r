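#' Double-gamma hemodynamic response function
#'
#' Canonical difference-of-gammas HRF, parameterized by the delay of the
#' response peak and of the undershoot (both in seconds), their dispersions,
#' and the peak:undershoot amplitude ratio. Each lobe is a gamma density with
#' `shape = delay / dispersion + 1` and `scale = dispersion`, so the positive
#' lobe's mode sits exactly at `peak_delay_s`. The output is normalized to
#' unit peak amplitude.
#'
#' @param t_s times in seconds (>= 0).
#' @param peak_delay_s response peak delay (default 6 s).
#' @param undershoot_delay_s undershoot delay (default 16 s).
#' @param peak_disp_s,undershoot_disp_s dispersions (default 1 s each).
#' @param ratio peak:undershoot amplitude ratio (default 6).
#' @return HRF amplitudes at `t_s`, unit peak.
#' @examples
#' doubleGammaHrf(0)      # 0
#' doubleGammaHrf(6)      # ~1 (peak)
#' @export
doubleGammaHrf <- function(t_s, peak_delay_s = 6, undershoot_delay_s = 16,
                           peak_disp_s = 1, undershoot_disp_s = 1,
                           ratio = 6) {
  if (peak_disp_s <= 0 || undershoot_disp_s <= 0) {
    stopf("dispersions must be positive")
  }
  if (any(t_s < 0)) stopf("t_s must be non-negative")
  raw <- function(t) {
    dgamma(t, shape = peak_delay_s / peak_disp_s + 1, scale = peak_disp_s) -
      dgamma(t, shape = undershoot_delay_s / undershoot_disp_s + 1,
             scale = undershoot_disp_s) / ratio
  }
  # unit-peak normalization via a fine grid over the response's support
  grid <- seq(0, max(32, undershoot_delay_s * 2), by = 0.01)
  peak <- max(raw(grid))
  raw(t_s) / peak
}

# HRF kernel sampled on the dt grid used for convolution, scaled by dt so
# that discrete convolution approximates the continuous-time integral (a
# sustained unit boxcar then plateaus at the HRF's area, independent of dt)
.hrfKernel <- function(dt, length_s = 32, hrf_params = list()) {
  t <- seq(0, length_s, by = dt)
  do.call(doubleGammaHrf, c(list(t_s = t), hrf_params)) * dt
}

# Convolve a fine-grid time course with the HRF kernel (causal, 'open'
# type), via FFT padded to a friendly length; the kernel FFT is cached.
.hrfCache <- new.env(parent = emptyenv())

.kernelFft <- function(kernel, m) {
  hit <- !is.null(.hrfCache$m) && .hrfCache$m == m &&
    identical(.hrfCache$kernel, kernel)
  if (!hit) {
    .hrfCache$kernel <- kernel
    .hrfCache$m <- m
    .hrfCache$K <- stats::fft(c(kernel, numeric(m - length(kernel))))
  }
  .hrfCache$K
}

.convolveHrf <- function(x, kernel) {
  n <- length(x)
  m <- stats::nextn(n + length(kernel) - 1L)
  X <- stats::fft(c(x, numeric(m - n)))
  Re(stats::fft(X * .kernelFft(kernel, m), inverse = TRUE))[seq_len(n)] / m
}

# Convolve two real series at once by packing them into one complex FFT
.convolveHrfPair <- function(x1, x2, kernel) {
  n <- length(x1)
  m <- stats::nextn(n + length(kernel) - 1L)
  Z <- stats::fft(complex(real = c(x1, numeric(m - n)),
                          imaginary = c(x2, numeric(m - n))))
  out <- stats::fft(Z * .kernelFft(kernel, m), inverse = TRUE)[seq_len(n)] / m
  list(Re(out), Im(out))
}
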