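#' Mean voltage variation
#'
#' Arithmetic mean of the recorded micro-voltage series. A shift after a
#' stimulus suggests polarisation of the signal; an increase often reflects
#' more frequent high-amplitude spikes.
#'
#' @param rec a [recording()] or numeric vector.
#' @return Mean in µV.
#' @export
mean_voltage <- function(rec) {
  x <- as_samples(rec)
  if (length(x) < 1L) stop("empty series")
  mean(x)
}

as_samples <- function(rec) {
  if (inherits(rec, "Recording")) rec$samples else as.numeric(rec)
}

#' Dispersion summary: SD, skewness, kurtosis
#'
#' Sample moments of the voltage distribution: `skewness = m3 / m2^1.5` and
#' `kurtosis = m4 / m2^2` (raw convention; a Gaussian has raw kurtosis 3), or
#' excess (`raw - 3`). Moments use the biased (1/n) definitions. Heavy-tailed
#' electromes typically show raw kurtosis far above 3.
#'
#' @param rec a [recording()] or numeric vector.
#' @param kurtosis_convention `"raw"` (default) or `"excess"`.
#' @return List with `mean`, `sd`, `skewness`, `kurtosis`,
#'   `kurtosis_convention`, `n`. For zero-variance input the shape statistics
#'   are `NA` with `degenerate = TRUE`.
#' @export
dispersion <- function(rec, kurtosis_convention = c("raw", "excess")) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  x <- as_samples(rec)
  n <- length(x)
  if (n < 3L) stop("need n >= 3 for shape statistics")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  out <- list(mean = mu, sd = sd(x), n = n,
              kurtosis_convention = kurtosis_convention, degenerate = FALSE)
  if (m2 <= 0) {
    out$skewness <- NA_real_
    out$kurtosis <- NA_real_
    out$degenerate <- TRUE
    return(out)
  }
  out$skewness <- mean(d^3) / m2^1.5
  k <- mean(d^4) / m2^2
  out$kurtosis <- if (kurtosis_convention == "excess") k - 3 else k
  out
}

#' Histogram of voltage variations
#'
#' @param rec a [recording()] or numeric vector.
#' @param bins number of equal-width bins over `[min, max]` (default 101), or
#'   a numeric vector of strictly increasing bin edges.
#' @return List with `edges` (length nbins + 1) and `counts` (summing to n).
#' @export
voltage_histogram <- function(rec, bins = 101L) {
  x <- as_samples(rec)
  if (length(bins) == 1L) {
    if (bins < 1) stop("bins must be >= 1")
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    edges <- as.numeric(bins)
    if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
    if (min(x) < edges[1] || max(x) > edges[length(edges)])
      stop("custom edges do not span the data")
  }
  h <- graphics::hist(x, breaks = edges, plot = FALSE, include.lowest = TRUE)
  list(edges = h$breaks, counts = h$counts)
}

#' Autocorrelation function of a recording
#'
#' Biased-normalisation sample ACF:
#' `acf[k] = sum((x_t - xbar)(x_{t+k} - xbar)) / sum((x_t - xbar)^2)`,
#' computed via `stats::acf` (FFT-backed) but numerically equal to the direct
#' sum. The 1/n normalisation keeps the estimate positive semidefinite.
#'
#' @param rec a [recording()] or numeric vector.
#' @param max_lag largest lag in samples (< n).
#' @return List of class `ACFResult` with `lags` (0..max_lag), `acf`, `fs`.
#' @export
acf_recording <- function(rec, max_lag = 1000L) {
  x <- as_samples(rec)
  fs <- if (inherits(rec, "Recording")) rec$fs else NA_real_
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be < n")
  if (var(x) == 0) stop("zero-variance series has no autocorrelation")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  structure(list(lags = 0:max_lag, acf = as.numeric(a), fs = fs),
            class = "ACFResult")
}

#' Correlation time from an ACF
#'
#' Characteristic persistence of the signal. `"integral"` (default) sums the
#' ACF from lag 0 up to (exclusive) its first non-positive value — for an
#' AR(1) process this approximates `1/(1 - phi)`; for white noise it is about
#' 1. `"one_over_e"` returns the smallest lag where the ACF falls to `1/e`.
#'
#' @param acfres an `ACFResult` from [acf_recording()].
#' @param method `"integral"` or `"one_over_e"`.
#' @return List with `L` (samples), `L_seconds` (if `fs` known), `method`,
#'   and `lower_bound` — `TRUE` when the ACF never crosses the threshold
#'   inside `max_lag`, so `L` is only a lower bound.
#' @export
correlation_time <- function(acfres, method = c("integral", "one_over_e")) {
  method <- match.arg(method)
  stopifnot(inherits(acfres, "ACFResult"))
  a <- acfres$acf
  lower_bound <- FALSE
  if (method == "integral") {
    k0 <- which(a <= 0)[1L]
    if (is.na(k0)) {
      k0 <- length(a) + 1L
      lower_bound <- TRUE
    }
    L <- sum(a[seq_len(k0 - 1L)])
  } else {
    k0 <- which(a <= exp(-1))[1L]
    if (is.na(k0)) {
      L <- acfres$lags[length(a)]
      lower_bound <- TRUE
    } else {
      L <- acfres$lags[k0]
    }
  }
  list(L = L,
       L_seconds = if (is.finite(acfres$fs)) L / acfres$fs else NA_real_,
       method = method, lower_bound = lower_bound)
}

#' All descriptive statistics of one recording
#'
#' Convenience wrapper returning the mean, dispersion summary, and the
#' integral correlation time in one flat list.
#'
#' @param rec a [recording()].
#' @param max_lag ACF lag range for the correlation time.
#' @return Named list: `mean`, `sd`, `skewness`, `kurtosis`, `L`.
#' @export
describe_recording <- function(rec, max_lag = min(rec$n - 1L, 5000L)) {
  d <- dispersion(rec)
  ct <- correlation_time(acf_recording(rec, max_lag = max_lag))
  list(mean = d$mean, sd = d$sd, skewness = d$skewness, kurtosis = d$kurtosis,
       L = ct$L)
}
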