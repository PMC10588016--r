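#' PQRST beat morphology defaults
#'
#' Each simulated heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T)
#' placed relative to the R peak.  Offsets and widths are in seconds,
#' amplitudes in millivolts; all amplitudes are multiplied by the rhythm's
#' `qrs_amplitude_scale`.  Ectopic beats widen the QRS bumps (Q, R, S) by
#' 2.5x, raise their amplitude by 1.3x, and drop the P wave.
#'
#' @return A data frame with columns `wave`, `offset`, `width`, `amp`.
#' @export
pqrst_morphology <- function() {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    offset = c(-0.200, -0.035, 0.000, 0.035, 0.300),
    width  = c(0.035, 0.012, 0.016, 0.014, 0.060),
    amp    = c(0.15, -0.12, 1.00, -0.25, 0.35)
  )
}

#' Rhythm class generative specification
#'
#' Describes one rhythm class for the synthetic ECG generator: mean and
#' standard deviation of the RR interval, per-beat probability of an
#' ectopic (wide-QRS, absent-P) beat, QRS amplitude scaling, measurement
#' noise and sinusoidal baseline wander.
#'
#' Class presets:
#' \itemize{
#'   \item `NSR` -- regular rhythm: `rr_mean` 0.8 s, `rr_sd` 0.03 s, no
#'     ectopy.
#'   \item `ARR` -- arrhythmic: `rr_mean` 0.8 s, `rr_sd` 0.18 s, ectopic
#'     probability 0.10.
#'   \item `CHF` -- fast, metronomic, low-amplitude rhythm: `rr_mean`
#'     0.6 s, `rr_sd` 0.005 s, `qrs_amplitude_scale` 0.6.
#' }
#'
#' @param class_label `"NSR"`, `"ARR"` or `"CHF"`; selects the preset.
#' @param rr_mean,rr_sd,ectopic_rate,qrs_amplitude_scale,noise_sd,baseline_wander_amp,baseline_wander_freq
#'   Optional overrides of the preset values (seconds, probability,
#'   dimensionless, millivolts, millivolts, Hz respectively).
#'
#' @return An object of class `rhythm_spec`.
#' @examples
#' rhythm_spec("ARR")
#' rhythm_spec("NSR", noise_sd = 0)
#' @export
rhythm_spec <- function(class_label = c("NSR", "ARR", "CHF"),
                        rr_mean = NULL, rr_sd = NULL, ectopic_rate = NULL,
                        qrs_amplitude_scale = NULL, noise_sd = NULL,
                        baseline_wander_amp = NULL,
                        baseline_wander_freq = NULL) {
  class_label <- match.arg(class_label)
  preset <- switch(class_label,
    NSR = list(rr_mean = 0.8, rr_sd = 0.03, ectopic_rate = 0,
               qrs_amplitude_scale = 1),
    ARR = list(rr_mean = 0.8, rr_sd = 0.18, ectopic_rate = 0.10,
               qrs_amplitude_scale = 1),
    CHF = list(rr_mean = 0.6, rr_sd = 0.005, ectopic_rate = 0,
               qrs_amplitude_scale = 0.6)
  )
  spec <- list(
    class_label = class_label,
    rr_mean = rr_mean %||% preset$rr_mean,
    rr_sd = rr_sd %||% preset$rr_sd,
    ectopic_rate = ectopic_rate %||% preset$ectopic_rate,
    qrs_amplitude_scale = qrs_amplitude_scale %||% preset$qrs_amplitude_scale,
    noise_sd = noise_sd %||% 0.03,
    baseline_wander_amp = baseline_wander_amp %||% 0.05,
    baseline_wander_freq = baseline_wander_freq %||% 0.25
  )
  if (spec$rr_mean <= 0) stop("`rr_mean` must be > 0 seconds")
  if (spec$rr_sd < 0) stop("`rr_sd` must be >= 0")
  if (spec$ectopic_rate < 0 || spec$ectopic_rate > 1) {
    stop("`ectopic_rate` must lie in [0, 1]")
  }
  if (spec$qrs_amplitude_scale <= 0) stop("`qrs_amplitude_scale` must be > 0")
  if (spec$noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(spec, class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf(
    "Rhythm spec [%s]: RR %.3g +/- %.3g s, ectopic rate %.2g, QRS scale %.2g\n",
    x$class_label, x$rr_mean, x$rr_sd, x$ectopic_rate,
    x$qrs_amplitude_scale))
  cat(sprintf("  noise sd %.3g mV; baseline wander %.3g mV at %.3g Hz\n",
              x$noise_sd, x$baseline_wander_amp, x$baseline_wander_freq))
  invisible(x)
}

#' Generate one synthetic ECG record
#'
#' Beats are placed at cumulative RR intervals drawn from
#' `Normal(rr_mean, rr_sd)` truncated below at 0.2 s.  Each beat is the sum
#' of five Gaussian bumps (see [pqrst_morphology()]) scaled by
#' `qrs_amplitude_scale`; with probability `ectopic_rate` a beat is
#' replaced by a wide-QRS, absent-P ectopic template.  White measurement
#' noise and sinusoidal baseline wander are added last, so regenerating
#' with `noise_sd = 0` and `baseline_wander_amp = 0` under the same seed
#' reproduces the noiseless beat track exactly.  Output is deterministic
#' given `(spec, n_samples, sampling_rate, seed)`.
#'
#' @param spec A [rhythm_spec()].
#' @param n_samples Number of samples to generate; must cover at least one
#'   mean RR interval.
#' @param sampling_rate Sampling rate in Hz. Default 128.
#' @param seed Integer seed (required).
#'
#' @return An `ecg_record` labeled with the spec's class.
#' @examples
#' rec <- synth_ecg_record(rhythm_spec("NSR"), 128 * 10, 128, seed = 7)
#' @export
synth_ecg_record <- function(spec, n_samples, sampling_rate = 128, seed) {
  stopifnot(inherits(spec, "rhythm_spec"),
            is.numeric(n_samples), length(n_samples) == 1L,
            is.numeric(sampling_rate), sampling_rate > 0)
  if (missing(seed)) stop("`seed` is required for reproducible generation")
  n_samples <- as.integer(n_samples)
  duration <- n_samples / sampling_rate
  if (duration < spec$rr_mean) {
    stop("n_samples = ", n_samples, " covers only ", signif(duration, 4),
         " s; at least one mean RR interval (", spec$rr_mean,
         " s) is required")
  }

  morph <- pqrst_morphology()
  t_grid <- (seq_len(n_samples) - 1) / sampling_rate

  with_private_seed(seed, {
    # beat times: cumulative truncated-normal RR intervals
    n_guess <- ceiling(duration / max(spec$rr_mean - 3 * spec$rr_sd, 0.2)) + 8L
    rr <- pmax(rnorm(n_guess, spec$rr_mean, spec$rr_sd), 0.2)
    while (sum(rr) < duration + 1) {
      rr <- c(rr, pmax(rnorm(8L, spec$rr_mean, spec$rr_sd), 0.2))
    }
    beat_t <- cumsum(rr) - rr[1] / 2
    beat_t <- beat_t[beat_t < duration + 0.5]
    ectopic <- runif(length(beat_t)) < spec$ectopic_rate
    wander_phase <- runif(1, 0, 2 * pi)

    clean <- numeric(n_samples)
    half_win <- 0.6  # seconds of support around each R peak
    for (b in seq_along(beat_t)) {
      i0 <- max(1L, floor((beat_t[b] - half_win) * sampling_rate) + 1L)
      i1 <- min(n_samples, ceiling((beat_t[b] + half_win) * sampling_rate) + 1L)
      if (i0 > i1) next
      tt <- t_grid[i0:i1] - beat_t[b]
      contrib <- numeric(length(tt))
      for (w in seq_len(nrow(morph))) {
        wave <- morph$wave[w]
        if (ectopic[b] && wave == "P") next
        width <- morph$width[w]
        amp <- morph$amp[w]
        if (ectopic[b] && wave %in% c("Q", "R", "S")) {
          width <- width * 2.5
          amp <- amp * 1.3
        }
        contrib <- contrib +
          amp * exp(-((tt - morph$offset[w])^2) / (2 * width^2))
      }
      clean[i0:i1] <- clean[i0:i1] + contrib * spec$qrs_amplitude_scale
    }

    signal <- clean +
      spec$baseline_wander_amp *
        sin(2 * pi * spec$baseline_wander_freq * t_grid + wander_phase) +
      rnorm(n_samples, 0, spec$noise_sd)

    new_ecg_record(signal, sampling_rate,
                   sprintf("%s_seed%d", spec$class_label, as.integer(seed)),
                   spec$class_label)
  })
}

#' Generate a balanced labeled synthetic ECG dataset
#'
#' Generates `n_records_per_class` records for each class, with per-record
#' seeds derived reproducibly from the master seed, so two calls with the
#' same arguments produce identical datasets.
#'
#' @param n_records_per_class Records per class, `>= 1`. Default 30.
#' @param n_samples Samples per record. Default 10000 (twenty 500-sample
#'   segments at 128 Hz).
#' @param sampling_rate Sampling rate in Hz. Default 128.
#' @param seed Master integer seed.
#' @param classes Character vector of class labels to generate.
#'
#' @return A tibble with columns `record_id`, `label` and `record` (list
#'   column of `ecg_record` objects), balanced across classes.
#' @examples
#' ds <- synth_ecg_dataset(2, n_samples = 2000, seed = 1)
#' table(ds$label)
#' @export
synth_ecg_dataset <- function(n_records_per_class = 30, n_samples = 10000,
                              sampling_rate = 128, seed = 1,
                              classes = c("ARR", "CHF", "NSR")) {
  stopifnot(is.numeric(n_records_per_class), n_records_per_class >= 1,
            n_records_per_class == round(n_records_per_class))
  n_per <- as.integer(n_records_per_class)
  grid <- expand.grid(class_label = classes, i = seq_len(n_per),
                      stringsAsFactors = FALSE)
  rec_seeds <- with_private_seed(seed, {
    sample.int(.Machine$integer.max - 1L, nrow(grid))
  })
  records <- purrr::map(seq_len(nrow(grid)), function(r) {
    rec <- synth_ecg_record(rhythm_spec(grid$class_label[r]), n_samples,
                            sampling_rate, seed = rec_seeds[r])
    rec$record_id <- sprintf("%s_%02d", grid$class_label[r], grid$i[r])
    rec
  })
  tibble::tibble(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    label = grid$class_label,
    record = records
  )
}

#' Write a synthetic dataset as CSV records plus a labels manifest
#'
#' One single-column CSV per record (sample values in millivolts) and a
#' `labels.csv` manifest (`record_id`, `label`, `file`, `sampling_rate`).
#'
#' @param dataset A tibble from [synth_ecg_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_ecg_dataset <- function(dataset, dir) {
  stopifnot(is.data.frame(dataset), "record" %in% names(dataset))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(dataset$record, function(rec) {
    f <- file.path(dir, paste0(rec$record_id, ".csv"))
    writeLines(format(rec$samples, digits = 10, trim = TRUE, scientific = FALSE), f)
    f
  }, character(1))
  manifest <- data.frame(
    record_id = dataset$record_id,
    label = dataset$label,
    file = basename(files),
    sampling_rate = vapply(dataset$record, function(r) r$sampling_rate,
                           numeric(1))
  )
  mf <- file.path(dir, "labels.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
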