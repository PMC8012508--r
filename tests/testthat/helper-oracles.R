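# Brute-force reference implementations used as independent oracles.
# All are direct transcriptions of the textbook definitions, O(n^2) where
# applicable, and deliberately share no code with the package.

apen_bruteforce <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

acf_bruteforce <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  sapply(0:max_lag, function(k) sum(xc[1:(n - k)] * xc[(1 + k):n]) / denom)
}

moments_bruteforce <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# Mann-Whitney U for group a vs b: pairwise wins + half ties
u_bruteforce <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# fixture: AR(1) series without using the package generators
ar1_series <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}
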