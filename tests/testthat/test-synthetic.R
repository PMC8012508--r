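test_that("generators are seed-deterministic and length-exact", {
  a <- gen_colored_noise(1.2, n = 2048, seed = 7)
  b <- gen_colored_noise(1.2, n = 2048, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_equal(a$n, 2048L)
  expect_false(identical(a$samples, gen_colored_noise(1.2, n = 2048, seed = 8)$samples))

  expect_identical(gen_brownian(1024, seed = 3)$samples,
                   gen_brownian(1024, seed = 3)$samples)

  base <- gen_colored_noise(1, n = 4096, seed = 1)
  expect_identical(gen_spikes(base, rate = 0.5, seed = 5)$samples,
                   gen_spikes(base, rate = 0.5, seed = 5)$samples)
  expect_identical(gen_undulation(base, amp = 1, seed = 5)$samples,
                   gen_undulation(base, amp = 1, seed = 5)$samples)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(gen_colored_noise(1, n = 1024, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("pure-noise output is standardised to mean 0, variance 1", {
  for (beta in c(0, 1, 2)) {
    rec <- gen_colored_noise(beta, n = 8192, seed = beta + 1)
    expect_lt(abs(mean(rec$samples)), 1e-9)
    expect_lt(abs(var(rec$samples) - 1), 1e-6)
  }
  expect_error(gen_colored_noise(-0.5, n = 1024), "beta")
})

test_that("fitted PSD exponent tracks the synthesis exponent", {
  # deep 20-seed recovery lives in the acceptance suite; spot-check here
  for (beta in c(0, 1)) {
    est <- mean(sapply(1:5, function(s)
      fit_psd_exponent(psd(gen_colored_noise(beta, n = 2^16, seed = s)))$exponent))
    expect_lt(abs(est - beta), 0.15)
  }
})

test_that("brownian series fit near beta 2 and difference back to white", {
  est <- mean(sapply(1:5, function(s)
    fit_psd_exponent(psd(gen_brownian(n = 2^16, seed = s)))$exponent))
  expect_lt(abs(est - 2), 0.15)
  # increments of a random walk are white noise
  rec <- gen_brownian(n = 2^16, seed = 11)
  incr <- recording(diff(rec$samples), fs = rec$fs)
  expect_lt(abs(fit_psd_exponent(psd(incr))$exponent), 0.15)
})

test_that("undulation preserves the mean, lengthens correlation, peaks in band", {
  base <- gen_colored_noise(1.2, n = 16384, seed = 4)
  expect_identical(gen_undulation(base, amp = 0), base)

  und <- gen_undulation(base, amp = 2, band = c(0.002, 0.02), seed = 9)
  expect_lt(abs(mean(und$samples) - mean(base$samples)), 1e-9)
  L0 <- correlation_time(acf_recording(base, 5000))$L
  L1 <- correlation_time(acf_recording(und, 5000))$L
  expect_gt(L1, L0)

  # dominant low-frequency FFT peak falls inside the undulation band
  sp <- fft_spectrum(und)
  low <- sp$freqs < 0.05
  fpeak <- sp$freqs[low][which.max(sp$values[low])]
  expect_gte(fpeak, 0.002)
  expect_lte(fpeak, 0.02)

  expect_error(gen_undulation(base, amp = 1, band = c(0.02, 0.002)), "band")
})

test_that("spikes raise the SD and carry a recoverable power-law tail", {
  base <- gen_colored_noise(1.2, n = 8192, seed = 2)
  expect_identical(gen_spikes(base, rate = 0), base)

  sds <- sapply(1:10, function(s)
    sd(gen_spikes(base, rate = 0.5, tail_mu = 3, seed = s)$samples))
  expect_true(all(sds >= sd(base$samples)))

  # tail-exponent recovery: dense spikes on a quiet baseline, 10 seeds
  mus <- sapply(1:10, function(s) {
    quiet <- recording(rnorm(1e5, sd = 0.05), fs = 62.5)
    spiked <- gen_spikes(quiet, rate = 3, tail_mu = 2.5, seed = s)
    pdf_tail_fit(spiked, tail_quantile = 0.95)$exponent
  })
  expect_lt(abs(mean(mus) - 2.5), 0.3)

  expect_error(gen_spikes(base, rate = 1, tail_mu = 1), "tail_mu")
})

test_that("gen_experiment labels, pairs and counts its recordings", {
  recs <- gen_experiment(experiment_configs(n = 4096), n_per_class = 5, seed = 2)
  expect_length(recs, 20L)
  cls <- vapply(recs, function(r) r$class, character(1))
  expect_equal(sort(unique(cls)),
               c("bean-after", "bean-before", "wheat-after", "wheat-before"))
  # paired design: before/after share plant ids
  pid <- vapply(recs, function(r) r$plant_id, character(1))
  expect_identical(sort(pid[cls == "bean-before"]), sort(pid[cls == "bean-after"]))
  expect_error(gen_experiment(list(a = synthesis_config(), a = synthesis_config())),
               "duplicate")
  cfg2 <- experiment_configs(n = 4096)[c(1, 3)]
  expect_length(gen_experiment(cfg2, n_per_class = 5, seed = 1), 10L)
})

test_that("the two before-classes are statistically indistinguishable in ApEn", {
  recs <- gen_experiment(experiment_configs(n = 4096), n_per_class = 10, seed = 6)
  cls <- vapply(recs, function(r) r$class, character(1))
  ap <- function(r) as.numeric(apen(r, m = 2, r = 0.2 * sd(r$samples)))
  a <- sapply(recs[cls == "bean-before"], ap)
  b <- sapply(recs[cls == "wheat-before"], ap)
  expect_gt(t.test(a, b)$p.value, 0.01)
})

test_that("after-bean shifts ApEn down and L up relative to before", {
  recs <- gen_experiment(experiment_configs(n = 8192), n_per_class = 5, seed = 8)
  cls <- vapply(recs, function(r) r$class, character(1))
  ap <- function(r) as.numeric(apen(r, m = 2, r = 0.2 * sd(r$samples)))
  Lf <- function(r) correlation_time(acf_recording(r, 4000))$L
  expect_lt(mean(sapply(recs[cls == "bean-after"], ap)),
            mean(sapply(recs[cls == "bean-before"], ap)))
  expect_gt(mean(sapply(recs[cls == "bean-after"], Lf)),
            mean(sapply(recs[cls == "bean-before"], Lf)))
})
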