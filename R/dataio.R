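#' ECG rhythm class labels
#'
#' The three target rhythm classes plus `UNKNOWN`: cardiac arrhythmia
#' (ARR), congestive heart failure (CHF) and normal sinus rhythm (NSR).
#'
#' @export
ecg_classes <- c("ARR", "CHF", "NSR", "UNKNOWN")

new_ecg_record <- function(samples, sampling_rate, record_id, label) {
  label <- match.arg(label, ecg_classes)
  stopifnot(is.numeric(samples), length(samples) >= 1,
            is.numeric(sampling_rate), sampling_rate > 0)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("record `", record_id, "` contains non-finite samples")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         record_id = as.character(record_id), label = label),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf(
    "ECG record `%s` [%s]: %d samples at %g Hz (%.5g s, sample interval %.7g s)\n",
    x$record_id, x$label, n, x$sampling_rate, n / x$sampling_rate,
    1 / x$sampling_rate))
  invisible(x)
}

# Minimal WFDB header parser: returns record name, n_sig, fs, n_samples and
# per-signal (file_name, format, gain, adc_zero, baseline).
parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("WFDB header `", hea_path, "` is incomplete")
  head_f <- strsplit(lines[1], "\\s+")[[1]]
  record_name <- head_f[1]
  n_sig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3) as.numeric(sub("/.*$", "", head_f[3])) else 250
  n_samples <- if (length(head_f) >= 4) as.integer(head_f[4]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L || length(lines) < 1L + n_sig) {
    stop("WFDB header `", hea_path, "` signal specification is inconsistent")
  }
  signals <- lapply(lines[1 + seq_len(n_sig)], function(ln) {
    f <- strsplit(ln, "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    # gain field may look like "200", "200(0)", "200(0)/mV"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else NA_real_
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(gain) || gain == 0) gain <- 200
    list(file_name = f[1], format = sub("x.*$", "", f[2]),
         gain = gain,
         baseline = if (is.na(baseline)) adc_zero else baseline)
  })
  list(record_name = record_name, n_sig = n_sig, fs = fs,
       n_samples = n_samples, signals = signals)
}

# Read WFDB sample data for all signals; supports formats 16 (16-bit
# little-endian two's complement) and 212 (paired 12-bit).
read_wfdb_samples <- function(dat_path, fmt, n_sig, n_samples) {
  if (!file.exists(dat_path)) stop("WFDB signal file does not exist: ", dat_path)
  if (fmt == "16") {
    raw_n <- n_sig * n_samples
    v <- readBin(dat_path, "integer", n = raw_n, size = 2L,
                 endian = "little", signed = TRUE)
    if (length(v) < raw_n) {
      stop("WFDB signal file `", dat_path, "` holds ", length(v),
           " samples but the header declares ", raw_n)
    }
    matrix(v, nrow = n_sig)          # interleaved by sample
  } else if (fmt == "212") {
    total <- n_sig * n_samples
    nbytes <- ceiling(total / 2) * 3
    b <- readBin(dat_path, "integer", n = nbytes, size = 1L, signed = FALSE)
    if (length(b) < 3 * floor(total / 2)) {
      stop("WFDB signal file `", dat_path,
           "` is shorter than the header declares")
    }
    b1 <- b[seq(1, length(b), by = 3)]
    b2 <- b[seq(2, length(b), by = 3)]
    b3 <- b[seq(3, length(b), by = 3)]
    s1 <- b1 + 256 * (b2 %% 16)       # low 12 bits
    s2 <- b3 + 256 * (b2 %/% 16)      # high 12 bits
    s1 <- ifelse(s1 >= 2048, s1 - 4096, s1)
    s2 <- ifelse(s2 >= 2048, s2 - 4096, s2)
    v <- as.vector(rbind(s1, s2))[seq_len(total)]
    matrix(v, nrow = n_sig)
  } else {
    stop("unsupported WFDB signal format `", fmt,
         "` (formats 16 and 212 are supported)")
  }
}

#' Read a single-channel ECG record
#'
#' Reads either a WFDB header+signal pair (formats 16 and 212; the first
#' signal is taken and converted to millivolts via the header's gain and
#' baseline) or a single-column delimited text file of raw sample values in
#' millivolts.
#'
#' @param path For WFDB, the `.hea` header path (or the record path without
#'   extension); for CSV, the text file path.
#' @param format `"auto"` (by extension), `"wfdb"` or `"csv"`.
#' @param sampling_rate Sampling rate in Hz.  Required meaning differs by
#'   format: for CSV it declares the rate (default 128 Hz); for WFDB it is
#'   an optional cross-check -- a value conflicting with the header is an
#'   error.
#' @param label Class label to attach (`"ARR"`, `"CHF"`, `"NSR"` or
#'   `"UNKNOWN"`).
#' @param record_id Identifier; defaults to the file base name.
#'
#' @return An `ecg_record`.
#' @export
read_ecg_record <- function(path, format = c("auto", "wfdb", "csv"),
                            sampling_rate = NULL, label = "UNKNOWN",
                            record_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path) ||
                  file.exists(paste0(path, ".hea"))) "wfdb" else "csv"
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("file does not exist: ", path)
    txt <- readLines(path, warn = FALSE)
    txt <- trimws(txt)
    txt <- txt[nzchar(txt)]
    if (length(txt) == 0L) stop("file `", path, "` is empty")
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("file `", path, "` has a non-numeric row (line ", bad, "): `",
           txt[bad], "`")
    }
    fs <- sampling_rate %||% 128
    new_ecg_record(v, fs, record_id %||% sub("\\.[^.]*$", "", basename(path)),
                   label)
  } else {
    hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
    if (!file.exists(hea_path)) stop("WFDB header does not exist: ", hea_path)
    hd <- parse_wfdb_header(hea_path)
    if (!is.null(sampling_rate) && !isTRUE(all.equal(sampling_rate, hd$fs))) {
      stop("requested sampling rate (", sampling_rate,
           " Hz) conflicts with the WFDB header rate (", hd$fs, " Hz)")
    }
    sig <- hd$signals[[1]]
    dat_path <- file.path(dirname(hea_path), sig$file_name)
    m <- read_wfdb_samples(dat_path, sig$format, hd$n_sig, hd$n_samples)
    mv <- (m[1, ] - sig$baseline) / sig$gain
    new_ecg_record(mv, hd$fs, record_id %||% hd$record_name, label)
  }
}

#' Cut a record into fixed-length labeled segments
#'
#' Produces contiguous, non-overlapping windows starting at sample 1 (no
#' offset, no overlap); each segment inherits the parent record's label.
#'
#' @param record An `ecg_record`.
#' @param seg_len Segment length in samples. Default 500.
#' @param n_segments Optional number of segments; when omitted, all
#'   `floor(N / seg_len)` complete windows are returned.
#'
#' @return A tibble with one row per segment: `segment_id`, `record_id`,
#'   `index` (ordinal within the record), `label`, and `samples` (a list
#'   column of numeric vectors of length `seg_len`).
#' @examples
#' rec <- synth_ecg_record(rhythm_spec("NSR"), 2000, 128, seed = 1)
#' segment_record(rec, seg_len = 500)
#' @export
segment_record <- function(record, seg_len = 500, n_segments = NULL) {
  stopifnot(inherits(record, "ecg_record"),
            is.numeric(seg_len), seg_len >= 1, seg_len == round(seg_len))
  seg_len <- as.integer(seg_len)
  n <- length(record$samples)
  if (is.null(n_segments)) {
    n_segments <- n %/% seg_len
    if (n_segments == 0L) {
      stop("record `", record$record_id, "` is too short: ", n,
           " samples available, ", seg_len, " required per segment")
    }
  } else {
    stopifnot(n_segments >= 1, n_segments == round(n_segments))
    n_segments <- as.integer(n_segments)
    if (n < seg_len * n_segments) {
      stop("record `", record$record_id, "` is too short: ",
           seg_len * n_segments, " samples required for ", n_segments,
           " segments of ", seg_len, ", only ", n, " available")
    }
  }
  idx <- seq_len(n_segments)
  tibble::tibble(
    segment_id = sprintf("%s_%03d", record$record_id, idx),
    record_id = record$record_id,
    index = idx,
    label = record$label,
    samples = lapply(idx, function(i) {
      record$samples[((i - 1L) * seg_len + 1L):(i * seg_len)]
    })
  )
}

#' Segment every record of a dataset
#'
#' @param records A list of `ecg_record` objects, or a dataset tibble from
#'   [synth_ecg_dataset()] (with a `record` list column).
#' @inheritParams segment_record
#' @return A tibble of segments (see [segment_record()]).
#' @export
segment_records <- function(records, seg_len = 500, n_segments = NULL) {
  if (is.data.frame(records) && "record" %in% names(records)) {
    records <- records$record
  }
  purrr::map_dfr(records, segment_record, seg_len = seg_len,
                 n_segments = n_segments)
}

# Run `expr` under a private Mersenne-Twister stream, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Plan a stratified train/validation/test split of segments
#'
#' Per class, `test_per_class` segments are reserved for the test partition
#' first; the remainder is split `train_frac / (1 - train_frac)` between
#' training and validation.  All selections are drawn from a named, seeded
#' pseudorandom stream, so the plan is a pure function of (input, seed).
#'
#' With `group_by_record = TRUE` whole records are assigned to partitions,
#' so no record contributes segments to more than one partition.  The
#' default (`FALSE`) splits at segment level, which mirrors the common
#' practice of per-segment pooling but lets one recording appear on both
#' sides of the split -- a leakage risk worth knowing about when reading
#' accuracy numbers.
#'
#' @param segments A segments tibble (from [segment_record()] or
#'   [segment_records()]).
#' @param train_frac Fraction of the non-test segments assigned to
#'   training, in (0, 1). Default 0.8.
#' @param test_per_class Number of test segments reserved per class.
#' @param seed Integer seed recorded in the plan.
#' @param group_by_record Assign whole records to partitions.
#'
#' @return The input tibble with a `partition` factor column
#'   (`train`/`validation`/`test`), carrying attributes `seed` and
#'   `split_counts` (per class x partition table).
#' @examples
#' recs <- synth_ecg_dataset(2, n_samples = 3000, seed = 1)
#' segs <- segment_records(recs)
#' plan <- make_split(segs, train_frac = 0.8, test_per_class = 2, seed = 9)
#' table(plan$label, plan$partition)
#' @export
make_split <- function(segments, train_frac = 0.8, test_per_class, seed,
                       group_by_record = FALSE) {
  stopifnot(is.data.frame(segments),
            all(c("segment_id", "record_id", "label") %in% names(segments)))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly between 0 and 1")
  }
  stopifnot(is.numeric(test_per_class), test_per_class >= 0,
            test_per_class == round(test_per_class),
            is.numeric(seed), length(seed) == 1L)

  partition <- character(nrow(segments))
  with_private_seed(seed, {
    for (cl in unique(segments$label)) {
      rows <- which(segments$label == cl)
      if (length(rows) <= test_per_class) {
        stop("class `", cl, "` has only ", length(rows),
             " segments; more than test_per_class = ", test_per_class,
             " are required")
      }
      if (group_by_record) {
        recs <- sample(unique(segments$record_id[rows]))
        seg_count <- cumsum(vapply(
          recs, function(r) sum(segments$record_id[rows] == r), integer(1)))
        n_test_rec <- which(seg_count >= test_per_class)[1]
        if (is.na(n_test_rec) || n_test_rec >= length(recs)) {
          stop("class `", cl, "` has too few records to reserve ",
               test_per_class, " grouped test segments")
        }
        test_recs <- recs[seq_len(n_test_rec)]
        rest_recs <- recs[-seq_len(n_test_rec)]
        n_train_rec <- max(1L, round(train_frac * length(rest_recs)))
        train_recs <- rest_recs[seq_len(n_train_rec)]
        partition[rows] <- ifelse(
          segments$record_id[rows] %in% test_recs, "test",
          ifelse(segments$record_id[rows] %in% train_recs, "train",
                 "validation"))
        if (!any(partition[rows] == "validation")) {
          stop("class `", cl,
               "` has too few records for a grouped three-way split")
        }
      } else {
        shuffled <- sample(rows)
        test_rows <- shuffled[seq_len(test_per_class)]
        rest <- shuffled[-seq_len(test_per_class)]
        n_train <- round(train_frac * length(rest))
        partition[test_rows] <- "test"
        partition[rest[seq_len(n_train)]] <- "train"
        partition[rest[-seq_len(n_train)]] <- "validation"
      }
    }
  })

  out <- segments
  out$partition <- factor(partition, levels = c("train", "validation", "test"))
  attr(out, "seed") <- seed
  attr(out, "split_counts") <- table(out$label, out$partition)
  out
}

#' Export a split plan as a JSON manifest
#'
#' @param plan A split tibble from [make_split()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_manifest <- function(plan, path) {
  stopifnot(is.data.frame(plan), "partition" %in% names(plan))
  jsonlite::write_json(
    list(seed = attr(plan, "seed"),
         assignment = as.list(stats::setNames(as.character(plan$partition),
                                              plan$segment_id))),
    path, auto_unbox = TRUE)
  invisible(path)
}
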