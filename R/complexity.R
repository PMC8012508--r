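#' Approximate entropy (ApEn)
#'
#' Pincus approximate entropy `Phi^m(r) - Phi^(m+1)(r)` with Chebyshev
#' distance and self-matches included, in nats. Higher values indicate more
#' irregular dynamics; a deterministic (constant) series has ApEn exactly 0.
#'
#' For long series the quadratic neighbour count is evaluated on a centred
#' sub-window of at most `max_n` samples (the sub-window policy is recorded
#' in the result's attributes); set `max_n = Inf` for an exact full-series
#' value.
#'
#' @param series numeric vector (or [recording()]).
#' @param m embedding dimension (default 2).
#' @param r tolerance, in the same units as the series (µV); must be > 0.
#' @param max_n sub-window cap for long series (default 20000).
#' @return Entropy in nats (`numeric(1)`), with attribute `"n_used"`.
#' @examples
#' apen(rep(1, 100), m = 2, r = 0.2)  # 0
#' @export
apen <- function(series, m = 2L, r, max_n = 20000L) {
  x <- subwindow(as_samples(series), max_n)
  out <- apen_cpp(x, as.integer(m), r)
  attr(out, "n_used") <- length(x)
  out
}

#' Sample entropy (SampEn)
#'
#' `-log(A/B)` where `B` and `A` count the template pairs matching within
#' tolerance `r` at lengths `m` and `m + 1` (Chebyshev distance, self-matches
#' excluded). Returns `NA` when no matches exist at either length; a constant
#' series gives 0 (`A == B`).
#'
#' @inheritParams apen
#' @return Entropy in nats, with attribute `"n_used"`.
#' @export
sampen <- function(series, m = 2L, r, max_n = 20000L) {
  x <- subwindow(as_samples(series), max_n)
  out <- sampen_cpp(x, as.integer(m), r)
  attr(out, "n_used") <- length(x)
  out
}

subwindow <- function(x, max_n) {
  n <- length(x)
  if (!is.finite(max_n) || n <= max_n) return(x)
  start <- (n - max_n) %/% 2L + 1L
  x[start:(start + max_n - 1L)]
}

#' Coarse-grain a series at scale s
#'
#' Non-overlapping block means of length `s`; output length `floor(n/s)`.
#' This is the coarse-graining step of multiscale entropy.
#'
#' @param series numeric vector (or [recording()]).
#' @param s integer scale >= 1.
#' @return Numeric vector of block means.
#' @examples
#' coarse_grain(c(1, 3, 5, 7), 2)  # c(2, 6)
#' @export
coarse_grain <- function(series, s) {
  x <- as_samples(series)
  s <- as.integer(s)
  if (s < 1L) stop("scale s must be >= 1")
  if (s > length(x)) stop("scale s exceeds series length")
  if (s == 1L) return(x)
  nb <- length(x) %/% s
  colMeans(matrix(x[seq_len(nb * s)], nrow = s))
}

#' Multiscale entropy profile ApEn(s)
#'
#' Entropy of the series coarse-grained at scales `s = 1..S`. The tolerance
#' is fixed from the scale-1 standard deviation as `r_coef * SD1` (the
#' Costa convention) unless `per_scale_r = TRUE`. For white noise the profile
#' decreases with `s` (coarse-graining averages the randomness away); for
#' low-complexity processes such as Brownian noise it rises.
#'
#' @param rec a [recording()] or numeric vector.
#' @param m embedding dimension (default 2).
#' @param r_coef tolerance coefficient (default 0.2).
#' @param S largest scale (default 50); truncated with a warning when the
#'   coarse-grained series would fall below `10 * 2^m` points.
#' @param variant `"apen"` (default) or `"sampen"`.
#' @param per_scale_r recompute `r` from each scale's own SD.
#' @param max_n sub-window cap passed to the entropy kernel.
#' @return List of class `ComplexityProfile`: `scales`, `apen` (one value per
#'   scale, nats), `m`, `r_coef`, `r_abs`, `variant`.
#' @export
multiscale_entropy <- function(rec, m = 2L, r_coef = 0.2, S = 50L,
                               variant = c("apen", "sampen"),
                               per_scale_r = FALSE, max_n = 20000L) {
  variant <- match.arg(variant)
  x <- as_samples(rec)
  min_len <- 10L * 2L^m
  S_max <- length(x) %/% min_len
  if (S_max < 1L) stop("series too short for multiscale entropy")
  S <- as.integer(S)
  if (S > S_max) {
    warning("S truncated from ", S, " to ", S_max, " (series too short)")
    S <- S_max
  }
  r_abs <- r_coef * sd(x)
  fun <- if (variant == "apen") apen else sampen
  vals <- if (r_abs == 0) {
    # constant series: perfectly regular at every scale and any tolerance
    rep(0, S)
  } else {
    vapply(seq_len(S), function(s) {
      xs <- coarse_grain(x, s)
      r_s <- if (per_scale_r) r_coef * sd(xs) else r_abs
      as.numeric(fun(xs, m = m, r = r_s, max_n = max_n))
    }, numeric(1))
  }
  structure(list(scales = seq_len(S), apen = vals, m = as.integer(m),
                 r_coef = r_coef, r_abs = r_abs, variant = variant),
            class = "ComplexityProfile")
}

#' Power-law fit to the tail of the voltage-variation distribution
#'
#' Centres the series, takes absolute values, forms a log-spaced histogram
#' density of `|dV|`, and regresses `log10(density)` on `log10(|dV|)` over
#' the bins above the `tail_quantile` of `|dV|`. For a density
#' `f(|dV|) ~ |dV|^-mu` the tail exponent is `mu = -slope`. The `ok` flag
#' marks whether a power law is a credible description: it requires
#' r2 >= 0.9, at least 5 tail bins, and near-zero log-log curvature
#' (quadratic coefficient > -2). A true power law is exactly linear in
#' log-log coordinates; a Gaussian tail is strongly concave (curvature
#' around -15 at these settings) and fails the flag.
#'
#' @param rec a [recording()] or numeric vector (n >= 1000 recommended).
#' @param tail_quantile start of the fitted tail, in `[0.5, 1)`; default 0.90.
#' @param n_bins number of log-spaced bins (default 60).
#' @param min_count bins with fewer events than this are excluded from the
#'   regression (default 5): their log-density is dominated by discreteness
#'   noise, which flattens the apparent slope.
#' @return A `PowerLawFit` (see [fit_psd_exponent()]) whose `exponent` is mu.
#' @export
pdf_tail_fit <- function(rec, tail_quantile = 0.90, n_bins = 60L,
                         min_count = 5L) {
  if (tail_quantile < 0.5 || tail_quantile >= 1)
    stop("tail_quantile must be in [0.5, 1)")
  x <- abs(as_samples(rec) - mean(as_samples(rec)))
  x <- x[x > 0]
  if (length(x) < 100L) stop("too few non-zero points for a tail fit")
  lo <- quantile(x, 0.01)
  hi <- max(x)
  edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1L)
  cnt <- graphics::hist(x[x >= lo], breaks = edges, plot = FALSE,
                        include.lowest = TRUE)$counts
  width <- diff(edges)
  dens <- cnt / (sum(cnt) * width)
  centers <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
  thr <- quantile(x, tail_quantile)
  keep <- centers >= thr & dens > 0 & cnt >= min_count
  if (sum(keep) < 3L) stop("too few tail bins for a regression")
  lx <- log10(centers[keep])
  ly <- log10(dens[keep])
  fit <- lm(ly ~ lx)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2L])
  curvature <- unname(coef(lm(ly ~ lx + I(lx^2)))[3L])
  structure(list(exponent = -slope, slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r2 = sm$r.squared,
                 stderr = sm$coefficients[2L, 2L],
                 curvature = curvature,
                 fit_band = c(thr, hi), n_points = sum(keep),
                 ok = sm$r.squared >= 0.9 && sum(keep) >= 5L &&
                   curvature > -2),
            class = "PowerLawFit")
}
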