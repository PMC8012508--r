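#' One-sided FFT amplitude spectrum
#'
#' Decomposes the series into its frequency components and returns the
#' one-sided amplitude spectrum (µV per component): `2|X_k|/n` for interior
#' bins, `|X_k|/n` at DC and (even n) Nyquist, so a unit-amplitude sine maps
#' to amplitude 1 at its frequency. With this scaling
#' `sum(amplitude^2 / 2)` over non-DC bins equals the series variance
#' (Parseval), up to the Nyquist-bin convention.
#'
#' @param rec a [recording()] (n >= 16).
#' @param include_dc keep the 0 Hz bin (default `FALSE`; downstream power-law
#'   fits must not see DC).
#' @return List of class `SpectrumEstimate`: `freqs` (Hz, ascending),
#'   `values` (amplitudes), `kind = "fft_amplitude"`, `method_params`.
#' @export
fft_spectrum <- function(rec, include_dc = FALSE) {
  x <- as_samples(rec)
  n <- length(x)
  if (n < 16L) stop("series too short for a spectrum (n >= 16)")
  fs <- if (inherits(rec, "Recording")) rec$fs else 1
  X <- fft(x)
  half <- n %/% 2L
  idx <- 1:(half + 1L)                       # DC .. Nyquist (or near)
  amp <- Mod(X[idx]) / n
  scale2 <- rep(2, length(idx))
  scale2[1] <- 1
  if (n %% 2L == 0L) scale2[length(idx)] <- 1
  amp <- amp * scale2
  freqs <- (idx - 1L) / n * fs
  keep <- if (include_dc) seq_along(freqs) else -1L
  structure(list(freqs = freqs[keep], values = amp[keep],
                 kind = "fft_amplitude",
                 method_params = list(n = n, fs = fs)),
            class = "SpectrumEstimate")
}

# Hann window
hann <- function(m) 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))

# default Welch segment length: min(2^14, n/8) rounded down to a power of two
default_seg_len <- function(n) {
  target <- min(16384, max(16, floor(n / 8)))
  2^floor(log2(target))
}

#' Power spectral density estimate
#'
#' One-sided PSD in µV²/Hz. The default is Welch's method: the series is cut
#' into mean-removed, Hann-windowed segments with 50% overlap; their
#' periodograms are averaged. `method = "periodogram"` uses one full-length
#' rectangular segment. Density scaling: `sum(psd) * df` approximates the
#' series variance.
#'
#' @param rec a [recording()].
#' @param method `"welch"` (default) or `"periodogram"`.
#' @param seg_len segment length in samples (Welch); default
#'   `min(2^14, n/8)` rounded to a power of two.
#' @param window window name; only `"hann"` and `"rectangular"` are provided.
#' @param overlap fraction of segment overlap (default 0.5).
#' @return A `SpectrumEstimate` with `kind = "psd"` (DC bin excluded).
#' @export
psd <- function(rec, method = c("welch", "periodogram"), seg_len = NULL,
                window = "hann", overlap = 0.5) {
  method <- match.arg(method)
  x <- as_samples(rec)
  n <- length(x)
  fs <- if (inherits(rec, "Recording")) rec$fs else 1
  if (method == "periodogram") {
    seg_len <- n
    window <- "rectangular"
    overlap <- 0
  }
  if (is.null(seg_len)) seg_len <- default_seg_len(n)
  seg_len <- as.integer(seg_len)
  if (seg_len > n) stop("seg_len exceeds series length")
  if (seg_len < 16L) stop("seg_len too small")
  w <- switch(window,
              hann = hann(seg_len),
              rectangular = rep(1, seg_len),
              stop("unknown window: ", window))
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  half <- seg_len %/% 2L
  acc <- numeric(half + 1L)
  u <- sum(w^2)                              # window power normalisation
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg)[1:(half + 1L)])^2 / (fs * u)
    dbl <- if (seg_len %% 2L == 0L) 2:half else 2:(half + 1L)
    P[dbl] <- 2 * P[dbl]                     # one-sided (DC, Nyquist once)
    acc <- acc + P
  }
  pxx <- acc / length(starts)
  freqs <- (0:half) / seg_len * fs
  structure(list(freqs = freqs[-1L], values = pxx[-1L], kind = "psd",
                 method_params = list(method = method, seg_len = seg_len,
                                      window = window, overlap = overlap,
                                      n_segments = length(starts), fs = fs)),
            class = "SpectrumEstimate")
}

#' Fit a power-law exponent to a PSD
#'
#' Ordinary least squares of `log10(PSD)` on `log10(f)` over a frequency
#' band, optionally excluding sub-bands (e.g. a narrowband acquisition
#' artifact near 5 Hz). For `PSD ~ 1/f^beta` the scaling exponent is
#' `beta = -slope`.
#'
#' @param spec a `SpectrumEstimate` (PSD or amplitude spectrum).
#' @param band `(lo, hi)` Hz fit band; default `(0.01, 10)`.
#' @param exclude_bands list of `(lo, hi)` pairs to drop; default
#'   `list(c(4.5, 5.5))`.
#' @return List of class `PowerLawFit`: `exponent` (beta), `slope`,
#'   `intercept`, `r2`, `stderr`, `fit_band`, `n_points`, `ok`.
#' @export
fit_psd_exponent <- function(spec, band = c(0.01, 10),
                             exclude_bands = list(c(4.5, 5.5))) {
  stopifnot(inherits(spec, "SpectrumEstimate"))
  f <- spec$freqs
  v <- spec$values
  keep <- f >= band[1] & f <= band[2] & f > 0
  for (ex in exclude_bands)
    keep <- keep & !(f >= ex[1] & f <= ex[2])
  if (any(v[keep] <= 0)) {
    warning("dropping non-positive spectral values inside the fit band")
    keep <- keep & v > 0
  }
  if (sum(keep) < 10L) stop("fewer than 10 frequency points in the fit band")
  lx <- log10(f[keep])
  ly <- log10(v[keep])
  fit <- lm(ly ~ lx)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2L])
  structure(list(exponent = -slope, slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r2 = sm$r.squared, stderr = sm$coefficients[2L, 2L],
                 fit_band = band, exclude_bands = exclude_bands,
                 n_points = sum(keep),
                 ok = sm$r.squared >= 0.5),
            class = "PowerLawFit")
}

#' @export
print.PowerLawFit <- function(x, ...) {
  cat(sprintf(
    "<PowerLawFit> exponent = %.4g (se %.2g) | r2 = %.3f | %d points in [%.3g, %.3g] | ok: %s\n",
    x$exponent, x$stderr, x$r2, x$n_points, x$fit_band[1], x$fit_band[2],
    x$ok))
  invisible(x)
}

#' Classify a PSD exponent as a noise colour
#'
#' Symbolic colour names for `PSD ~ 1/f^beta`: white (beta near 0), pink
#' (near 1), brown (near 2), black (near 3); `0.5 <= beta <= 1.5` outside the
#' pink window is "reddened" (long-range correlated but less complex than
#' pink).
#'
#' @param beta fitted scaling exponent.
#' @param tol half-width of each colour window (default 0.25).
#' @return One of `"white"`, `"pink"`, `"brown"`, `"black"`, `"reddened"`,
#'   `"other"`.
#' @export
classify_noise <- function(beta, tol = 0.25) {
  if (!is.finite(beta)) stop("beta must be finite")
  if (abs(beta) <= tol) return("white")
  if (abs(beta - 1) <= tol) return("pink")
  if (abs(beta - 2) <= tol) return("brown")
  if (abs(beta - 3) <= tol) return("black")
  if (beta >= 0.5 && beta <= 1.5) return("reddened")
  "other"
}

#' Continuous wavelet scalogram (Morlet)
#'
#' Magnitude of the continuous wavelet transform on log-spaced scales mapped
#' to pseudo-frequencies, computed by FFT convolution with an analytic Morlet
#' wavelet (centre frequency parameter `omega0 = 6`, for which the
#' pseudo-frequency of scale `a` is approximately `fs * omega0 / (2*pi*a)`).
#' Wavelets trade frequency resolution for time resolution as frequency
#' rises.
#'
#' @param rec a [recording()].
#' @param n_scales number of scales (default 64), log-spaced.
#' @param freq_range `(lo, hi)` Hz pseudo-frequency range; default
#'   `(4*fs/n, fs/4)` clipped inside `(0, fs/2)`.
#' @param omega0 Morlet centre frequency parameter.
#' @return List of class `Scalogram`: `freqs` (Hz, ascending), `times` (s),
#'   `magnitude` (n_scales x n_times), `wavelet = "morlet"`.
#' @export
cwt_scalogram <- function(rec, n_scales = 64L, freq_range = NULL, omega0 = 6) {
  x <- as_samples(rec)
  n <- length(x)
  fs <- if (inherits(rec, "Recording")) rec$fs else 1
  if (is.null(freq_range)) freq_range <- c(max(4 * fs / n, 1e-6), fs / 4)
  if (freq_range[1] <= 0 || freq_range[2] >= fs / 2 ||
      freq_range[1] >= freq_range[2])
    stop("freq_range must satisfy 0 < lo < hi < fs/2")
  freqs <- 10^seq(log10(freq_range[1]), log10(freq_range[2]),
                  length.out = n_scales)
  scales <- fs * omega0 / (2 * pi * freqs)
  X <- fft(x)
  ang <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n  # rad/sample
  mag <- matrix(0, nrow = n_scales, ncol = n)
  for (k in seq_len(n_scales)) {
    a <- scales[k]
    # analytic Morlet in the frequency domain, L2-normalised
    psi <- sqrt(2 * pi * a) * pi^(-0.25) * exp(-0.5 * (a * ang - omega0)^2)
    psi[ang < 0] <- 0
    mag[k, ] <- Mod(fft(X * psi, inverse = TRUE)) / n
  }
  structure(list(freqs = freqs, times = (seq_len(n) - 1L) / fs,
                 magnitude = mag, wavelet = "morlet",
                 method_params = list(omega0 = omega0, n_scales = n_scales)),
            class = "Scalogram")
}

#' Ridge of a scalogram
#'
#' Frequency of maximum wavelet magnitude at each time point; used to track
#' a dominant frequency through time.
#'
#' @param scal a `Scalogram`.
#' @return Numeric vector (Hz), one value per time point.
#' @export
scalogram_ridge <- function(scal) {
  stopifnot(inherits(scal, "Scalogram"))
  scal$freqs[apply(scal$magnitude, 2L, which.max)]
}
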