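# Internal numeric helpers shared across modules.

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

#' Gaussian smoothing of a binned series with exact mass conservation
#'
#' Symmetric FIR convolution with a Gaussian kernel truncated at +/- 4 SD.
#' Each source bin's kernel is renormalized by the mass retained inside the
#' series, so the total count is conserved exactly even at the edges.
#'
#' @param x numeric vector (e.g. spike counts per bin).
#' @param sd_bins kernel standard deviation in bins.
#' @return smoothed numeric vector of the same length.
#' @keywords internal
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- ceiling(4 * sd_bins)
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  pad_conv <- function(v) {
    vp <- c(rep(0, half), v, rep(0, half))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  retained <- pad_conv(rep(1, n))
  pad_conv(x / retained)
}

# Analytic signal via FFT (positive-frequency doubling). The signal is
# zero-padded to a highly composite length for FFT speed.
analytic_signal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, rep(0, n - n0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

# Zero-phase Butterworth band-pass (forward-backward).
bandpass <- function(x, fs, lo, hi, order = 4) {
  assert_that(lo > 0 && hi < fs / 2 && lo < hi,
              "band edges must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% overlap; the workhorse
#' estimator for stationary epoch spectra.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default: min(length(x), fs/2)).
#' @return tibble with columns `freq_hz` and `power`.
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  nperseg <- nperseg %||% min(n, round(fs / 2))
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  starts <- seq(1, n - nperseg + 1, by = step)
  u <- sum(win^2)
  acc <- numeric(floor(nperseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(fft(seg))^2 / (u * fs)
    half <- P[seq_len(length(acc))]
    # one-sided: double everything except DC (and Nyquist for even n)
    half[-1] <- 2 * half[-1]
    if (nperseg %% 2 == 0) half[length(half)] <- half[length(half)] / 2
    acc <- acc + half
  }
  acc <- acc / length(starts)
  tibble(freq_hz = (seq_along(acc) - 1) * fs / nperseg, power = acc)
}

#' Morlet wavelet power spectrogram
#'
#' Complex Morlet convolution implemented in the frequency domain; returns
#' time-resolved power at each requested center frequency.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param freqs center frequencies in Hz.
#' @param n_cycles wavelet width in cycles (time-frequency trade-off).
#' @return matrix `length(x)` x `length(freqs)` of power values.
#' @export
morlet_power <- function(x, fs, freqs, n_cycles = 7) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, rep(0, n - n0))
  X <- fft(x)
  fgrid <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  out <- matrix(0, n0, length(freqs))
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sigma_f <- f0 / n_cycles
    # Gaussian on positive frequencies only -> analytic wavelet
    H <- exp(-0.5 * ((fgrid - f0) / sigma_f)^2)
    H[fgrid < 0] <- 0
    w <- (fft(X * H, inverse = TRUE) / n)[seq_len(n0)]
    out[, j] <- Mod(w)^2
  }
  colnames(out) <- as.character(freqs)
  out
}

# Deterministic child seed derivation (kept below 2^31).
child_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) + h * 1009) %% 2147483647)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
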