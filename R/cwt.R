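#' Continuous wavelet transform of an ECG segment
#'
#' FFT-based analytic CWT of a real signal against a Morse filterbank.
#' The signal is boundary-extended, transformed, multiplied by each
#' frequency-domain filter, inverse-transformed and trimmed back to the
#' original support.  Filters are real and nonnegative in frequency, so no
#' conjugation ambiguity arises; coefficients are complex because the
#' filters vanish at negative frequencies.
#'
#' Boundary handling: `"reflect"` (default) extends the signal by symmetric
#' reflection of `ceiling(N/2)` samples on each side before transforming,
#' which curbs edge artifacts on short segments; `"periodic"` wraps the
#' signal circularly (no padding), which makes the transform exactly
#' covariant under circular shifts.
#'
#' @param signal Real numeric vector; its length must equal
#'   `bank$signal_length`.
#' @param bank A [morse_filterbank()].
#' @param boundary `"reflect"` or `"periodic"`.
#'
#' @return An object of class `ecg_scalogram`: a list with `coefficients`
#'   (complex matrix, n_filters x n_samples, rows in descending frequency),
#'   `frequencies` (Hz per row), `times` (seconds per column), `params`,
#'   `sampling_rate` and `boundary`.
#'
#' @examples
#' fb <- morse_filterbank(64, 128, voices_per_octave = 8)
#' x <- cos(2 * pi * 10 * (0:63) / 128)
#' sc <- cwt(x, fb)
#' dim(sc$coefficients)
#' @export
cwt <- function(signal, bank, boundary = c("reflect", "periodic")) {
  stopifnot(inherits(bank, "morse_filterbank"))
  boundary <- match.arg(boundary)
  if (!is.numeric(signal)) stop("`signal` must be a numeric vector")
  n <- length(signal)
  if (n != bank$signal_length) {
    stop("signal length (", n, ") does not match the filterbank design length (",
         bank$signal_length, ")")
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("`signal` contains NA or non-finite samples")
  }

  if (boundary == "reflect") {
    e <- as.integer(ceiling(n / 2))
    ext <- c(rev(signal[seq_len(e)]), signal, rev(signal[(n - e + 1):n]))
    nfft <- bank$nfft
    x <- c(ext, numeric(nfft - length(ext)))
    filters <- bank$filters
    keep <- (e + 1):(e + n)
  } else {
    nfft <- n
    x <- signal
    filters <- morse_filter_matrix(bank$centers_rad, nfft, bank$params)
    keep <- seq_len(n)
  }

  X <- stats::fft(x)
  # one column per filter; X recycles down each column
  fm <- t(filters) * X
  co <- stats::mvfft(fm, inverse = TRUE) / nfft
  coefficients <- t(co[keep, , drop = FALSE])

  structure(
    list(
      coefficients = coefficients,
      frequencies = bank$centers_hz,
      times = (seq_len(n) - 1) / bank$sampling_rate,
      params = bank$params,
      sampling_rate = bank$sampling_rate,
      boundary = boundary
    ),
    class = "ecg_scalogram"
  )
}

#' Magnitude of a scalogram
#'
#' Elementwise modulus of the complex CWT coefficients.
#'
#' @param x An `ecg_scalogram` (or a complex matrix).
#' @return Nonnegative numeric matrix of the same shape.
#' @export
scalogram_magnitude <- function(x) {
  if (inherits(x, "ecg_scalogram")) x <- x$coefficients
  if (!is.matrix(x)) stop("`x` must be an `ecg_scalogram` or a matrix")
  Mod(x)
}

#' @export
print.ecg_scalogram <- function(x, ...) {
  cat(sprintf(
    "ECG scalogram: %d frequencies x %d samples (%.4g s at %g Hz), %s boundary\n",
    nrow(x$coefficients), ncol(x$coefficients),
    ncol(x$coefficients) / x$sampling_rate, x$sampling_rate, x$boundary))
  cat(sprintf("  frequency span %.3g - %.3g Hz; gamma = %g, P^2 = %g\n",
              min(x$frequencies), max(x$frequencies),
              x$params$gamma, x$params$p2))
  invisible(x)
}

#' Plot a scalogram as a time-frequency heat map
#'
#' @param object An `ecg_scalogram`.
#' @param ... Unused.
#' @return A ggplot object (magnitude over time, log-scaled frequency axis).
#' @method autoplot ecg_scalogram
#' @export
autoplot.ecg_scalogram <- function(object, ...) {
  mag <- scalogram_magnitude(object)
  df <- tidyr::expand_grid(
    frequency_hz = object$frequencies,
    time_s = object$times
  )
  df$magnitude <- as.vector(t(mag))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$frequency_hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  fill = "|CWT|")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a scalogram as plain-text artifacts
#'
#' Writes `<prefix>_magnitude.tsv` (the magnitude matrix, tab-delimited)
#' and `<prefix>_axes.json` (frequencies in Hz, times in seconds, sampling
#' rate and wavelet parameters).
#'
#' @param x An `ecg_scalogram`.
#' @param prefix Path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_scalogram <- function(x, prefix) {
  stopifnot(inherits(x, "ecg_scalogram"))
  mag_path <- paste0(prefix, "_magnitude.tsv")
  axes_path <- paste0(prefix, "_axes.json")
  utils::write.table(scalogram_magnitude(x), mag_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(frequencies_hz = x$frequencies, times_s = x$times,
         sampling_rate = x$sampling_rate,
         gamma = x$params$gamma, p2 = x$params$p2,
         boundary = x$boundary),
    axes_path, auto_unbox = TRUE, digits = NA)
  invisible(c(magnitude = mag_path, axes = axes_path))
}
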