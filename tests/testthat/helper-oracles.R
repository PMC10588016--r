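# Independent oracles, coded without touching the package's FFT path.

# direct discrete-Fourier-sum transform (no FFT)
dft_direct <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  vapply(j, function(jj) {
    sum(x * exp(-2i * pi * jj * j / n))
  }, complex(1))
}

idft_direct <- function(X) {
  n <- length(X)
  j <- 0:(n - 1)
  vapply(j, function(mm) {
    sum(X * exp(2i * pi * j * mm / n)) / n
  }, complex(1))
}

# closed-form Morse filter amplitude, recomputed from scratch
morse_amp_direct <- function(omega, gamma, p2) {
  beta <- p2 / gamma
  alpha <- 2 * (exp(1) * gamma / beta)^(beta / gamma)
  ifelse(omega > 0, alpha * omega^beta * exp(-omega^gamma), 0)
}

# direct-sum CWT oracle: re-codes boundary extension, forward transform,
# filtering and inverse transform without any shared FFT code
cwt_direct <- function(signal, bank, boundary = "reflect") {
  n <- length(signal)
  if (boundary == "reflect") {
    e <- ceiling(n / 2)
    ext <- c(rev(signal[1:e]), signal, rev(signal[(n - e + 1):n]))
    nfft <- 2^ceiling(log2(length(ext)))
    x <- c(ext, numeric(nfft - length(ext)))
    keep <- (e + 1):(e + n)
  } else {
    nfft <- n
    x <- signal
    keep <- 1:n
  }
  X <- dft_direct(x)
  wp <- (bank$params$beta / bank$params$gamma)^(1 / bank$params$gamma)
  omega <- 2 * pi * (0:(nfft - 1)) / nfft
  out <- matrix(0i, nrow = length(bank$centers_rad), ncol = n)
  for (k in seq_along(bank$centers_rad)) {
    f <- numeric(nfft)
    pos <- which(0:(nfft - 1) <= nfft / 2 & omega > 0)
    f[pos] <- morse_amp_direct(omega[pos] * wp / bank$centers_rad[k],
                               bank$params$gamma, bank$params$p2)
    f <- 2 * f / max(f)       # discrete-grid peak-2 normalization
    y <- idft_direct(X * f)
    out[k, ] <- y[keep]
  }
  out
}

# simple peak finder used on noiseless synthetic beat tracks: local maxima
# above a fraction of the global maximum, separated by a refractory gap
find_r_peaks <- function(x, fs, min_height_frac = 0.4, refractory_s = 0.25) {
  thr <- min_height_frac * max(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < length(x)]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0 || (i - peaks[length(peaks)]) / fs >= refractory_s) {
      peaks <- c(peaks, i)
    } else if (x[i] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  peaks
}
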