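#' Generalized Morse wavelet parameters
#'
#' The generalized Morse wavelets are a two-parameter family of exactly
#' analytic wavelets defined in the frequency domain as
#' \deqn{\Psi(\omega) = \alpha\, \omega^{\beta} e^{-\omega^{\gamma}}, \quad \omega > 0,}
#' and identically zero for \eqn{\omega \le 0}.  The symmetry parameter
#' \eqn{\gamma} controls the envelope shape (\eqn{\gamma = 3} gives zero
#' skewness and a near-minimal Heisenberg area), and the time-bandwidth
#' product \eqn{P^2 = \beta\gamma} controls how many oscillations fit under
#' the envelope.
#'
#' @param gamma Symmetry parameter, dimensionless, `> 0`. Default 3.
#' @param p2 Time-bandwidth product \eqn{P^2}, dimensionless, `> 0`.
#'   Default 60.
#'
#' @return An object of class `morse_params`: a list with elements `gamma`,
#'   `p2` and the derived decay parameter `beta = p2 / gamma`.
#'
#' @examples
#' p <- morse_params(gamma = 3, p2 = 60)
#' p$beta  # 20
#' @export
morse_params <- function(gamma = 3, p2 = 60) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single finite number > 0, got ", format(gamma))
  }
  if (!is.numeric(p2) || length(p2) != 1L || !is.finite(p2) || p2 <= 0) {
    stop("`p2` must be a single finite number > 0, got ", format(p2))
  }
  structure(
    list(gamma = as.numeric(gamma), p2 = as.numeric(p2),
         beta = as.numeric(p2) / as.numeric(gamma)),
    class = "morse_params"
  )
}

#' @export
print.morse_params <- function(x, ...) {
  cat(sprintf(
    "Generalized Morse wavelet: gamma = %g, P^2 = %g (beta = %g)\n",
    x$gamma, x$p2, x$beta))
  cat(sprintf("  peak angular frequency: %.6g rad/sample\n",
              morse_peak_frequency(x)))
  invisible(x)
}

#' Frequency-domain amplitude of a generalized Morse wavelet
#'
#' Evaluates \eqn{\alpha\,\omega^{\beta} e^{-\omega^{\gamma}}} on a grid of
#' angular frequencies, with amplitude exactly zero for \eqn{\omega \le 0}
#' (the wavelet is analytic: no support at non-positive frequency).  The
#' normalizing constant is fixed to
#' \eqn{\alpha = 2 (e\gamma/\beta)^{\beta/\gamma}} so that the peak
#' amplitude equals 2, the usual analytic-wavelet convention.
#'
#' @param omega Numeric vector of angular frequencies in radians/sample.
#'   All entries must be finite.
#' @param params A [morse_params()] object.
#'
#' @return Numeric vector of nonnegative amplitudes, same length as `omega`.
#' @examples
#' p <- morse_params(3, 60)
#' morse_wavelet_ft(c(-1, 0, morse_peak_frequency(p)), p)  # 0, 0, 2
#' @export
morse_wavelet_ft <- function(omega, params) {
  stopifnot(inherits(params, "morse_params"))
  if (!is.numeric(omega)) stop("`omega` must be numeric")
  if (anyNA(omega) || any(!is.finite(omega))) {
    stop("`omega` contains non-finite entries; the frequency grid must be finite")
  }
  beta <- params$beta
  gamma <- params$gamma
  amp <- numeric(length(omega))
  pos <- omega > 0
  if (any(pos)) {
    w <- omega[pos]
    # log-space evaluation: 2 * exp(beta/gamma * (1 + log(gamma/beta))
    #                                + beta*log(w) - w^gamma)
    loga <- (beta / gamma) * (1 + log(gamma / beta))
    amp[pos] <- 2 * exp(loga + beta * log(w) - w^gamma)
  }
  amp
}

#' Peak frequency of a generalized Morse wavelet
#'
#' The frequency-domain amplitude of the Morse wavelet attains its maximum
#' at the peak angular frequency \eqn{\omega_p = (\beta/\gamma)^{1/\gamma}}.
#'
#' @param params A [morse_params()] object with `beta > 0`.
#' @param sampling_rate Optional sampling rate in Hz.  When supplied the
#'   peak is returned in Hz (\eqn{f = \omega f_s / 2\pi}) instead of
#'   radians/sample.
#'
#' @return Peak frequency (radians/sample, or Hz when `sampling_rate` is
#'   given).
#' @examples
#' morse_peak_frequency(morse_params(3, 9))             # 1 (beta == gamma)
#' morse_peak_frequency(morse_params(3, 60))            # (20/3)^(1/3)
#' morse_peak_frequency(morse_params(3, 60), 128)       # ~38.34 Hz
#' @export
morse_peak_frequency <- function(params, sampling_rate = NULL) {
  stopifnot(inherits(params, "morse_params"))
  if (params$beta <= 0) {
    stop("peak frequency requires beta > 0; the wavelet has no interior maximum")
  }
  wp <- (params$beta / params$gamma)^(1 / params$gamma)
  if (is.null(sampling_rate)) {
    wp
  } else {
    stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
    wp * sampling_rate / (2 * pi)
  }
}

# Filter matrix on an n-point DFT grid for a set of center frequencies.
# Bin j (0-based) carries angular frequency 2*pi*j/nfft; bins above nfft/2
# are negative frequencies and stay exactly zero (analyticity).  Each row
# is rescaled so its maximum over the discrete grid is exactly 2: narrow
# low-frequency filters are undersampled by the DFT grid and would
# otherwise fall short of the continuous peak value.
morse_filter_matrix <- function(centers_rad, nfft, params) {
  wp <- morse_peak_frequency(params)
  omega <- 2 * pi * (seq_len(nfft) - 1) / nfft
  pos <- seq_len(nfft) - 1 <= nfft / 2          # nonnegative-frequency bins
  filters <- matrix(0, nrow = length(centers_rad), ncol = nfft)
  for (k in seq_along(centers_rad)) {
    # rescale the argument so the peak lands at the center frequency
    row <- morse_wavelet_ft(omega[pos] * wp / centers_rad[k], params)
    filters[k, pos] <- 2 * row / max(row)
  }
  filters
}

# Upper half-amplitude abscissa of the base wavelet: the a > omega_p with
# amplitude(a) == half the peak (i.e. 1 under the peak-2 convention), by
# bisection.
morse_upper_half_point <- function(params, tol = 1e-12) {
  wp <- morse_peak_frequency(params)
  hi <- 2 * wp
  while (morse_wavelet_ft(hi, params) > 1) hi <- hi * 2
  lo <- wp
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (morse_wavelet_ft(mid, params) > 1) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Design an analytic Morse wavelet filterbank
#'
#' Builds a constant-Q bank of generalized Morse wavelet filters on the
#' discrete Fourier grid of the padded transform length.  Center frequencies
#' form a geometric grid \eqn{\omega_k = \omega_{max} 2^{-k/v}} (with
#' \eqn{v} voices per octave) descending from \eqn{\omega_{max}} to the
#' smallest center still \eqn{\ge \omega_{min}}.  Each filter is the base
#' wavelet evaluated at the rescaled argument
#' \eqn{\omega\,\omega_p/\omega_c}, so its peak lands exactly at its
#' center, then rescaled so the maximum over the discrete grid equals 2
#' (narrow low-frequency filters would otherwise undershoot the continuous
#' peak value between grid bins).
#'
#' Default frequency limits (used when `freq_limits` is `NULL`):
#' \eqn{\omega_{max}} is the largest center whose filter amplitude at the
#' Nyquist frequency \eqn{\pi} does not exceed half its peak (found by
#' bisection), and \eqn{\omega_{min} = 2\sqrt{2}\sqrt{P^2}/N} rad/sample
#' (two approximate time-domain standard deviations fit inside the
#' N-sample analysis window).
#'
#' @param signal_length Segment length in samples, `>= 4`.
#' @param sampling_rate Sampling rate in Hz.
#' @param params A [morse_params()] object. Default `morse_params(3, 60)`.
#' @param voices_per_octave Integer `>= 1`; number of filters per frequency
#'   doubling.  Default 12.
#' @param freq_limits Optional `c(low, high)` in Hz with
#'   `0 < low < high <= sampling_rate / 2`; overrides the default limits.
#'
#' @return An object of class `morse_filterbank` with elements
#'   `centers_rad` (descending, radians/sample), `centers_hz`, `filters`
#'   (matrix, n_filters x nfft, nonnegative frequency-domain amplitudes),
#'   `nfft` (padded transform length), `signal_length`, `sampling_rate`,
#'   `voices_per_octave` and `params`.
#'
#' @examples
#' fb <- morse_filterbank(500, 128)
#' nrow(fb$filters)                   # number of voices in the span
#' fb$centers_rad[1] / fb$centers_rad[2]  # 2^(1/12)
#' @export
morse_filterbank <- function(signal_length, sampling_rate,
                             params = morse_params(),
                             voices_per_octave = 12,
                             freq_limits = NULL) {
  stopifnot(inherits(params, "morse_params"))
  if (!is.numeric(signal_length) || length(signal_length) != 1L ||
      signal_length < 4 || signal_length != round(signal_length)) {
    stop("`signal_length` must be an integer >= 4 samples")
  }
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0)
  if (!is.numeric(voices_per_octave) || length(voices_per_octave) != 1L ||
      voices_per_octave < 1 || voices_per_octave != round(voices_per_octave)) {
    stop("`voices_per_octave` must be an integer >= 1")
  }
  signal_length <- as.integer(signal_length)
  vpo <- as.integer(voices_per_octave)

  # padded transform length: reflection extension by ceiling(N/2) on each
  # side, rounded up to the next power of two
  ext_len <- signal_length + 2L * as.integer(ceiling(signal_length / 2))
  nfft <- 2L^as.integer(ceiling(log2(ext_len)))

  if (!is.null(freq_limits)) {
    if (length(freq_limits) != 2L || !is.numeric(freq_limits) ||
        any(!is.finite(freq_limits)) ||
        freq_limits[1] <= 0 || freq_limits[2] <= freq_limits[1] ||
        freq_limits[2] > sampling_rate / 2) {
      stop("`freq_limits` must satisfy 0 < low < high <= sampling_rate/2 (Hz); got [",
           paste(format(freq_limits), collapse = ", "), "]")
    }
    omega_min <- 2 * pi * freq_limits[1] / sampling_rate
    omega_max <- 2 * pi * freq_limits[2] / sampling_rate
  } else {
    omega_min <- 2 * sqrt(2) * sqrt(params$p2) / signal_length
    wp <- morse_peak_frequency(params)
    omega_max <- pi * wp / morse_upper_half_point(params)
  }
  if (omega_max < omega_min) {
    stop("frequency grid is empty: omega_max (", format(omega_max),
         ") < omega_min (", format(omega_min), ") rad/sample")
  }

  n_oct <- log2(omega_max / omega_min)
  k <- 0:floor(n_oct * vpo + 1e-9)
  centers <- omega_max * 2^(-k / vpo)
  centers <- centers[centers >= omega_min * (1 - 1e-12)]
  if (length(centers) == 0L) {
    stop("frequency grid produced zero filters")
  }

  structure(
    list(
      centers_rad = centers,
      centers_hz = centers * sampling_rate / (2 * pi),
      filters = morse_filter_matrix(centers, nfft, params),
      nfft = nfft,
      signal_length = signal_length,
      sampling_rate = sampling_rate,
      voices_per_octave = vpo,
      params = params
    ),
    class = "morse_filterbank"
  )
}

#' @export
print.morse_filterbank <- function(x, ...) {
  cat(sprintf(
    "Morse wavelet filterbank: %d filters, %d voices/octave\n",
    length(x$centers_rad), x$voices_per_octave))
  cat(sprintf("  signal length %d samples at %g Hz (FFT length %d)\n",
              x$signal_length, x$sampling_rate, x$nfft))
  cat(sprintf("  centers %.4g - %.4g Hz (%.4g - %.4g rad/sample)\n",
              min(x$centers_hz), max(x$centers_hz),
              min(x$centers_rad), max(x$centers_rad)))
  cat(sprintf("  gamma = %g, P^2 = %g\n", x$params$gamma, x$params$p2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a Morse filterbank into a tibble of center frequencies
#'
#' @param x A `morse_filterbank`.
#' @param ... Unused.
#' @return A tibble with one row per filter: `filter`, `center_rad`
#'   (radians/sample), `center_hz`, and `peak_amplitude` on the discrete
#'   grid.
#' @method tidy morse_filterbank
#' @export
tidy.morse_filterbank <- function(x, ...) {
  tibble::tibble(
    filter = seq_along(x$centers_rad),
    center_rad = x$centers_rad,
    center_hz = x$centers_hz,
    peak_amplitude = apply(x$filters, 1, max)
  )
}

#' Export a filterbank as plain-text artifacts
#'
#' Writes two files: `<prefix>_centers.csv` (one row per filter with center
#' frequencies in rad/sample and Hz) and `<prefix>_filters.tsv` (the
#' n_filters x nfft amplitude matrix, tab-delimited).
#'
#' @param bank A `morse_filterbank`.
#' @param prefix Path prefix for the two output files.
#' @return Invisibly, the two paths written.
#' @export
write_filterbank <- function(bank, prefix) {
  stopifnot(inherits(bank, "morse_filterbank"))
  centers_path <- paste0(prefix, "_centers.csv")
  filters_path <- paste0(prefix, "_filters.tsv")
  utils::write.csv(as.data.frame(tidy(bank)), centers_path, row.names = FALSE)
  utils::write.table(bank$filters, filters_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(centers = centers_path, filters = filters_path))
}
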