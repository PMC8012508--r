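#' Generate coloured 1/f^beta noise by spectral synthesis
#'
#' Builds a series whose power spectral density follows `PSD ~ 1/f^beta`:
#' Fourier amplitudes proportional to `f^(-beta/2)`, phases i.i.d. uniform on
#' `[0, 2*pi)`, zero DC component, inverse transform, then standardisation to
#' mean 0 and variance 1. `beta = 0` gives white noise, 1 pink, 2 brown,
#' 3 black.
#'
#' @param beta spectral exponent, >= 0.
#' @param n sample count (>= 16). Defaults to a 2 h recording at 62.5 Hz.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return A [recording()] with `treatment = "synthetic"`.
#' @examples
#' rec <- gen_colored_noise(1, n = 4096, seed = 1)
#' @export
gen_colored_noise <- function(beta, n = 450000L, fs = 62.5, seed = 1L) {
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  x <- with_seed(seed, {
    nf <- n %/% 2L                      # positive-frequency bins
    f <- (1:nf) / n * fs
    amp <- f^(-beta / 2)
    ph <- runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = ph)
    # hermitian assembly: DC = 0; Nyquist (even n) forced real
    if (n %% 2L == 0L) {
      full <- c(0 + 0i, spec[-nf], complex(real = amp[nf] * sign(cos(ph[nf]))),
                Conj(rev(spec[-nf])))
    } else {
      full <- c(0 + 0i, spec, Conj(rev(spec)))
    }
    Re(fft(full, inverse = TRUE)) / n
  })
  x <- (x - mean(x)) / sd(x)
  recording(x, fs = fs, plant_id = sprintf("synth-beta%.2g-s%d", beta, seed))
}

#' Generate Brownian noise (cumulative sum of Gaussian increments)
#'
#' Random-walk series whose fitted PSD exponent is close to 2 ("brown
#' noise"). The output is standardised to mean 0, variance 1; differencing it
#' recovers white noise.
#'
#' @inheritParams gen_colored_noise
#' @return A [recording()].
#' @export
gen_brownian <- function(n = 450000L, fs = 62.5, seed = 1L) {
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  x <- with_seed(seed, cumsum(rnorm(n)))
  x <- (x - mean(x)) / sd(x)
  recording(x, fs = fs, plant_id = sprintf("synth-brown-s%d", seed))
}

#' Add a slow undulation (long voltage waves) to a recording
#'
#' Superimposes a sum of low-frequency sinusoids with random frequencies in
#' `band` and random phases, scaled so the added component's RMS equals
#' `amp` times the RMS of the (centred) base signal. This emulates the
#' long-period waves of voltage variation oscillating around the mean that
#' appear in stimulated electromes; it increases the correlation time while
#' leaving the mean unchanged.
#'
#' @param base a [recording()].
#' @param amp relative amplitude (>= 0); 0 returns the base unchanged.
#' @param band `(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param n_components number of sinusoids.
#' @param seed integer seed.
#' @return A [recording()].
#' @export
gen_undulation <- function(base, amp = 1, band = c(0.002, 0.02),
                           n_components = 5L, seed = 1L) {
  stopifnot(inherits(base, "Recording"))
  if (amp < 0) stop("amp must be >= 0")
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= base$fs / 2)
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  if (amp == 0) return(base)
  wave <- with_seed(seed, {
    t <- (seq_len(base$n) - 1L) / base$fs
    fr <- runif(n_components, band[1], band[2])
    ph <- runif(n_components, 0, 2 * pi)
    w <- rowSums(vapply(seq_len(n_components),
                        function(k) sin(2 * pi * fr[k] * t + ph[k]),
                        numeric(base$n)))
    w - mean(w)
  })
  target_rms <- amp * sd(base$samples)
  wave <- wave * target_rms / sqrt(mean(wave^2))
  out <- base
  out$samples <- base$samples + wave
  out$plant_id <- paste0(base$plant_id, "+und")
  out
}

#' Add heavy-tailed voltage spikes to a recording
#'
#' Injects Poisson-timed biexponential transients (default rise 0.2 s, decay
#' 2 s) whose peak amplitudes follow a Pareto law with probability-density
#' tail exponent `tail_mu` (density ~ amplitude^-mu). Random spike signs.
#' Rare large events raise the standard deviation and lengthen the
#' distribution tails, as spikes do in real electromes.
#'
#' @param base a [recording()].
#' @param rate expected events per second (>= 0); 0 returns the base.
#' @param tail_mu density tail exponent (> 1).
#' @param amp_scale Pareto scale (minimum spike amplitude), in units of the
#'   base SD.
#' @param rise_s,decay_s transient kinetics in seconds.
#' @param seed integer seed.
#' @return A [recording()].
#' @export
gen_spikes <- function(base, rate = 0.05, tail_mu = 4.5, amp_scale = 1.5,
                       rise_s = 0.2, decay_s = 2, seed = 1L) {
  stopifnot(inherits(base, "Recording"))
  if (rate < 0) stop("rate must be >= 0")
  if (tail_mu <= 1) stop("tail_mu must be > 1")
  if (rate == 0) return(base)
  out <- base
  spikes <- with_seed(seed, {
    dur_s <- base$n / base$fs
    k <- rpois(1L, rate * dur_s)
    add <- numeric(base$n)
    if (k > 0) {
      t0 <- sort(runif(k, 0, dur_s))
      # Pareto: density ~ x^-(a+1) with a = mu - 1, so pdf exponent = mu
      a <- tail_mu - 1
      pk <- amp_scale * sd(base$samples) * runif(k)^(-1 / a)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      tpl_len <- min(base$n, ceiling((rise_s + 6 * decay_s) * base$fs))
      tt <- (seq_len(tpl_len) - 1L) / base$fs
      tpl <- (1 - exp(-tt / rise_s)) * exp(-tt / decay_s)
      tpl <- tpl / max(tpl)
      for (j in seq_len(k)) {
        i0 <- floor(t0[j] * base$fs) + 1L
        idx <- i0:min(base$n, i0 + tpl_len - 1L)
        add[idx] <- add[idx] + sgn[j] * pk[j] * tpl[seq_along(idx)]
      }
    }
    add
  })
  out$samples <- base$samples + spikes
  out$plant_id <- paste0(base$plant_id, "+spk")
  out
}

#' Default synthesis configuration for one experimental class
#'
#' @param beta spectral exponent of the baseline noise.
#' @param n sample count per recording.
#' @param fs sampling rate (Hz).
#' @param undulation_amp relative amplitude of the slow undulation.
#' @param undulation_band frequency band of the undulation (Hz).
#' @param spike_rate spikes per second.
#' @param spike_tail_mu spike amplitude density tail exponent.
#' @return A named list understood by [gen_experiment()].
#' @export
synthesis_config <- function(beta = 1.2, n = 450000L, fs = 62.5,
                             undulation_amp = 0.3,
                             undulation_band = c(0.002, 0.02),
                             spike_rate = 0.01, spike_tail_mu = 4.5) {
  stopifnot(beta >= 0, undulation_amp >= 0, spike_rate >= 0, spike_tail_mu > 1,
            undulation_band[1] > 0, undulation_band[1] < undulation_band[2],
            undulation_band[2] < fs / 2)
  list(beta = beta, n = as.integer(n), fs = fs,
       undulation_amp = undulation_amp, undulation_band = undulation_band,
       spike_rate = spike_rate, spike_tail_mu = spike_tail_mu)
}

# Synthesise one recording from a config. `seed` drives the baseline noise
# (the plant's intrinsic electrome); `layer_seed` drives the undulation and
# spike layers, so a before/after pair can share a baseline while the
# stimulus-dependent layers differ.
synth_one <- function(cfg, seed, layer_seed = seed, plant_id = "synth",
                      treatment = "synthetic", phase = "none") {
  rec <- gen_colored_noise(cfg$beta, n = cfg$n, fs = cfg$fs, seed = seed)
  if (cfg$undulation_amp > 0)
    rec <- gen_undulation(rec, amp = cfg$undulation_amp,
                          band = cfg$undulation_band,
                          seed = derive_seed(layer_seed, 1L))
  if (cfg$spike_rate > 0)
    rec <- gen_spikes(rec, rate = cfg$spike_rate, tail_mu = cfg$spike_tail_mu,
                      seed = derive_seed(layer_seed, 2L))
  rec$plant_id <- plant_id
  rec$treatment <- treatment
  rec$phase <- phase
  rec
}

#' Default class configurations emulating the before/after host experiment
#'
#' The two "before" classes share one configuration: a pink-like 1/f^1.2
#' baseline with sparse spikes and no slow undulation — the undulating
#' long-wave pattern is a post-stimulus phenomenon. "after-bean" carries a
#' strong undulation — lowering
#' entropy and raising the correlation time — and "after-wheat" an
#' intermediate one, reproducing the direction (not the magnitude) of the
#' reported before/after effects.
#'
#' @param n sample count per recording.
#' @param fs sampling rate (Hz).
#' @return Named list of [synthesis_config()]s for classes `bean-before`,
#'   `bean-after`, `wheat-before`, `wheat-after`.
#' @export
experiment_configs <- function(n = 450000L, fs = 62.5) {
  before <- synthesis_config(n = n, fs = fs, undulation_amp = 0)
  list(
    "bean-before"  = before,
    "bean-after"   = synthesis_config(n = n, fs = fs, undulation_amp = 2.5,
                                      spike_rate = 0.03),
    "wheat-before" = before,
    "wheat-after"  = synthesis_config(n = n, fs = fs, undulation_amp = 1.2,
                                      spike_rate = 0.02)
  )
}

#' Generate a labelled set of synthetic recordings
#'
#' @param configs named list of [synthesis_config()]s, one per class; names
#'   are the class labels. Defaults to [experiment_configs()].
#' @param n_per_class recordings per class.
#' @param seed master seed; per-recording seeds are derived deterministically.
#' @param n optional sample-count override applied to every config.
#' @return A list of [recording()]s; each carries its class label in
#'   `$class` and a unique `$plant_id`.
#' @details Class labels ending in `-before`/`-after` are treated as a paired
#'   design: recording *j* of both phases represents the same plant (same
#'   `plant_id` and the same baseline-noise seed), while the
#'   stimulus-dependent undulation and spike layers get phase-specific seeds.
#' @export
gen_experiment <- function(configs = experiment_configs(), n_per_class = 5L,
                           seed = 1L, n = NULL) {
  if (length(configs) < 2L) stop("need at least 2 classes")
  if (anyDuplicated(names(configs))) stop("duplicate class names")
  out <- list()
  pair_ids <- sub("-(before|after)$", "", names(configs))
  for (ci in seq_along(configs)) {
    cls <- names(configs)[ci]
    cfg <- configs[[ci]]
    if (!is.null(n)) cfg$n <- as.integer(n)
    treatment <- if (grepl("bean", cls)) "bean"
                 else if (grepl("wheat", cls)) "wheat" else "synthetic"
    phase <- if (grepl("after", cls)) "after"
             else if (grepl("before", cls)) "before" else "none"
    pi <- match(pair_ids[ci], unique(pair_ids))
    for (j in seq_len(n_per_class)) {
      # paired design: recording j of a "before" class and of the matching
      # "after" class represent the same plant — shared id and baseline seed
      rec <- synth_one(cfg,
                       seed = derive_seed(seed, pi * 1000L + j),
                       layer_seed = derive_seed(seed, ci * 1000L + j + 500L),
                       plant_id = sprintf("%s-p%02d", pair_ids[ci], j),
                       treatment = treatment, phase = phase)
      rec$class <- cls
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}
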