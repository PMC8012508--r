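test_that("fft_spectrum locates tones and respects linearity", {
  fs <- 62.5
  t <- (0:9999) / fs
  rec <- recording(sin(2 * pi * 0.5 * t), fs = fs)
  sp <- fft_spectrum(rec)
  expect_equal(sp$freqs[which.max(sp$values)], 0.5, tolerance = 1e-3)

  rec2 <- recording(2 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 1.0 * t), fs = fs)
  sp2 <- fft_spectrum(rec2)
  a_lo <- max(sp2$values[abs(sp2$freqs - 0.1) < 0.02])
  a_hi <- max(sp2$values[abs(sp2$freqs - 1.0) < 0.02])
  expect_equal(a_lo / a_hi, 2, tolerance = 0.05)
  expect_error(fft_spectrum(recording(rnorm(8))), "short")
})

test_that("fft_spectrum satisfies Parseval's identity", {
  set.seed(31)
  x <- rnorm(4097)  # odd length: no Nyquist-bin ambiguity
  sp <- fft_spectrum(recording(x, fs = 62.5))
  energy <- sum(sp$values^2) / 2
  varn <- mean((x - mean(x))^2)
  expect_lt(abs(energy - varn) / varn, 1e-6)
})

test_that("white-noise PSD is flat at sigma^2 / (fs/2)", {
  set.seed(41)
  sig <- 3
  rec <- recording(rnorm(2^16, sd = sig), fs = 62.5)
  p <- psd(rec)
  expect_lt(abs(mean(p$values) - sig^2 / (62.5 / 2)) / (sig^2 / (62.5 / 2)), 0.1)
})

test_that("psd finds a tone and periodogram agrees with Welch on total power", {
  fs <- 62.5
  t <- (0:(2^15 - 1)) / fs
  set.seed(43)
  rec <- recording(sin(2 * pi * 0.5 * t) + 0.1 * rnorm(length(t)), fs = fs)
  pw <- psd(rec)
  expect_lt(abs(pw$freqs[which.max(pw$values)] - 0.5), 2 * diff(pw$freqs[1:2]))

  pp <- psd(rec, method = "periodogram")
  tot_w <- sum(pw$values) * diff(pw$freqs[1:2])
  tot_p <- sum(pp$values) * diff(pp$freqs[1:2])
  expect_lt(abs(tot_w - tot_p) / tot_p, 0.05)
  expect_error(psd(rec, seg_len = rec$n + 1), "exceeds")
})

test_that("periodogram matches spec.pgram up to the one-sided factor", {
  set.seed(47)
  x <- rnorm(4096)
  fs <- 62.5
  mine <- psd(recording(x, fs = fs), method = "periodogram")
  ref <- spec.pgram(ts(x, frequency = fs), taper = 0, fast = FALSE,
                    detrend = FALSE, plot = FALSE)
  expected <- 2 * ref$spec
  # the Nyquist bin of an even-length series has no mirror and is not doubled
  expected[length(expected)] <- ref$spec[length(ref$spec)]
  expect_equal(mine$values, expected, tolerance = 1e-9)
  expect_equal(mine$freqs, as.numeric(ref$freq), tolerance = 1e-12)

  # odd length: every non-DC bin is mirrored, so the factor is uniformly 2
  x2 <- x[1:4095]
  mine2 <- psd(recording(x2, fs = fs), method = "periodogram")
  ref2 <- spec.pgram(ts(x2, frequency = fs), taper = 0, fast = FALSE,
                     detrend = FALSE, plot = FALSE)
  expect_equal(mine2$values, 2 * ref2$spec, tolerance = 1e-9)
})

test_that("fit_psd_exponent is exact on noiseless grid power laws", {
  f <- seq(0.02, 9, length.out = 500)
  spec <- structure(list(freqs = f, values = f^(-1.5), kind = "psd",
                         method_params = list()), class = "SpectrumEstimate")
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_psd_exponent(spec))
  expect_equal(fit$exponent, 1.5, tolerance = 1e-9)
  expect_equal(fit$slope, -1.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  short <- structure(list(freqs = f[1:5], values = f[1:5]^-1, kind = "psd",
                          method_params = list()), class = "SpectrumEstimate")
  expect_error(fit_psd_exponent(short), "10")
})

test_that("the exclusion band removes a 5 Hz artifact's bias", {
  fs <- 62.5
  n <- 2^16
  t <- (0:(n - 1)) / fs
  base <- gen_colored_noise(1, n = n, fs = fs, seed = 51)
  beta_clean <- fit_psd_exponent(psd(base))$exponent
  tone <- recording(base$samples + 0.5 * sin(2 * pi * 5 * t), fs = fs)
  beta_excl <- fit_psd_exponent(psd(tone))$exponent  # default excludes 4.5-5.5
  beta_noexcl <- fit_psd_exponent(psd(tone), exclude_bands = list())$exponent
  expect_lt(abs(beta_excl - beta_clean), 0.1)
  expect_gt(abs(beta_noexcl - beta_clean), abs(beta_excl - beta_clean))
})

test_that("noise colours are classified by exponent windows", {
  expect_equal(classify_noise(0), "white")
  expect_equal(classify_noise(1), "pink")
  expect_equal(classify_noise(2), "brown")
  expect_equal(classify_noise(3), "black")
  expect_equal(classify_noise(1.24), "pink")   # inside the pink window
  expect_equal(classify_noise(1.4), "reddened")
  expect_equal(classify_noise(5), "other")
  expect_error(classify_noise(NA))
})

test_that("scalogram tracks stationary and swept tones", {
  fs <- 62.5
  n <- 8192
  t <- (0:(n - 1)) / fs
  rec <- recording(sin(2 * pi * 1 * t), fs = fs)
  scal <- cwt_scalogram(rec, n_scales = 48, freq_range = c(0.1, 4))
  ridge <- scalogram_ridge(scal)
  mid <- ridge[(n %/% 4):(3 * n %/% 4)]
  expect_true(all(abs(log(mid / 1)) < log(1.2)))  # within one log-spaced bin

  # chirp 0.1 -> 1 Hz: ridge frequency increases over time
  f0 <- 0.1; f1 <- 1
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * max(t))))
  scal2 <- cwt_scalogram(recording(chirp, fs = fs), n_scales = 48,
                         freq_range = c(0.05, 4))
  r2 <- scalogram_ridge(scal2)[seq(n %/% 8, 7 * n %/% 8, length.out = 20)]
  expect_gt(cor(seq_along(r2), r2, method = "kendall"), 0.5)

  expect_error(cwt_scalogram(rec, freq_range = c(1, 40)), "freq_range")
})

test_that("scalogram energy scales quadratically with amplitude; zero in, zero out", {
  set.seed(53)
  x <- rnorm(2048)
  s1 <- cwt_scalogram(recording(x, fs = 62.5), n_scales = 16)
  s3 <- cwt_scalogram(recording(3 * x, fs = 62.5), n_scales = 16)
  expect_equal(sum(s3$magnitude^2) / sum(s1$magnitude^2), 9, tolerance = 1e-8)

  z <- cwt_scalogram(recording(rep(0, 2048), fs = 62.5), n_scales = 8)
  expect_true(all(z$magnitude == 0))
  expect_equal(dim(z$magnitude), c(8L, 2048L))
})
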