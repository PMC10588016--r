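# fixture writers: encode WFDB signal files at test time (binary fixtures
# are never shipped)
write_wfdb16 <- function(dir, name, adc, fs, gain = 200, baseline = 0) {
  writeLines(c(
    sprintf("%s 1 %g %d", name, fs, length(adc)),
    sprintf("%s.dat 16 %g(%d)/mV 16 0 %d 0 0 ECG", name, gain, baseline,
            adc[1])
  ), file.path(dir, paste0(name, ".hea")))
  writeBin(as.integer(adc), file.path(dir, paste0(name, ".dat")),
           size = 2L, endian = "little")
  file.path(dir, name)
}

write_wfdb212 <- function(dir, name, adc, fs, gain = 200, baseline = 0) {
  # single-signal format 212: successive samples packed in 3-byte pairs
  writeLines(c(
    sprintf("%s 1 %g %d", name, fs, length(adc)),
    sprintf("%s.dat 212 %g(%d)/mV 12 0 %d 0 0 ECG", name, gain, baseline,
            adc[1])
  ), file.path(dir, paste0(name, ".hea")))
  v <- as.integer(adc)
  if (length(v) %% 2 == 1) v <- c(v, 0L)
  u <- ifelse(v < 0, v + 4096L, v)           # 12-bit two's complement
  s1 <- u[seq(1, length(u), 2)]
  s2 <- u[seq(2, length(u), 2)]
  bytes <- as.vector(rbind(s1 %% 256,
                           (s1 %/% 256) + 16 * (s2 %/% 256),
                           s2 %% 256))
  writeBin(as.raw(bytes), file.path(dir, paste0(name, ".dat")))
  file.path(dir, name)
}

test_that("single-column text records load with the declared sampling rate", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.csv")
  set.seed(4)
  v <- round(rnorm(500), 6)
  writeLines(format(v, trim = TRUE), path)
  rec <- read_ecg_record(path, format = "csv", sampling_rate = 128)
  expect_s3_class(rec, "ecg_record")
  expect_length(rec$samples, 500)
  expect_equal(rec$samples, v, tolerance = 1e-9)
  expect_equal(length(rec$samples) / rec$sampling_rate, 3.90625)
  expect_equal(1 / rec$sampling_rate, 0.0078125)  # 0.00781 s per sample
  expect_identical(rec$label, "UNKNOWN")
})

test_that("malformed text records produce explicit errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("1.0", "2.0", "oops", "3.0"), bad)
  expect_error(read_ecg_record(bad, format = "csv"), "non-numeric")
  empty <- file.path(dir, "empty.csv")
  writeLines(character(0), empty)
  expect_error(read_ecg_record(empty, format = "csv"), "empty")
  expect_error(read_ecg_record(file.path(dir, "missing.csv"), format = "csv"),
               "exist")
})

test_that("WFDB format 16 and 212 records decode to millivolts", {
  dir <- withr::local_tempdir()
  adc <- c(-2048L, -100L, 0L, 55L, 200L, 2047L, 13L, -7L)
  for (writer in list(write_wfdb16, write_wfdb212)) {
    base <- writer(dir, paste0("r", sample.int(1e6, 1)), adc, 128,
                   gain = 200, baseline = 10)
    rec <- read_ecg_record(base, format = "wfdb", label = "NSR")
    expect_equal(rec$samples, (adc - 10) / 200, tolerance = 1e-12)
    expect_equal(rec$sampling_rate, 128)
    expect_identical(rec$label, "NSR")
  }
})

test_that("a conflicting sampling-rate override is an error naming both values", {
  dir <- withr::local_tempdir()
  base <- write_wfdb16(dir, "conf", c(1L, 2L, 3L, 4L), fs = 128)
  expect_error(read_ecg_record(base, format = "wfdb", sampling_rate = 250),
               "250.*128|128.*250")
  expect_silent(read_ecg_record(base, format = "wfdb", sampling_rate = 128))
})

test_that("truncated or inconsistent WFDB pairs are rejected", {
  dir <- withr::local_tempdir()
  base <- write_wfdb16(dir, "trunc", 1:100, fs = 128)
  # truncate the signal file below what the header declares
  writeBin(as.integer(1:10), paste0(base, ".dat"), size = 2L,
           endian = "little")
  expect_error(read_ecg_record(base, format = "wfdb"), "header declares")
  expect_error(read_ecg_record(file.path(dir, "ghost"), format = "wfdb"),
               "exist")
})

test_that("segmentation cuts contiguous non-overlapping windows from sample one", {
  rec <- synth_ecg_record(rhythm_spec("NSR"), 65536, 128, seed = 31)
  segs <- segment_record(rec, seg_len = 500, n_segments = 20)
  expect_equal(nrow(segs), 20L)
  expect_true(all(lengths(segs$samples) == 500))
  expect_identical(unique(segs$label), "NSR")
  expect_equal(segs$index, 1:20)
  # concatenating the segments reproduces the first 10,000 samples exactly
  expect_identical(unlist(segs$samples), rec$samples[1:10000])
  # without n_segments every complete window is returned
  all_segs <- segment_record(rec, seg_len = 500)
  expect_equal(nrow(all_segs), 65536L %/% 500L)
})

test_that("segmentation refuses records shorter than one window", {
  rec <- synth_ecg_record(rhythm_spec("NSR"), 499, 128, seed = 3)
  expect_error(segment_record(rec, seg_len = 500), "499")
  expect_error(segment_record(rec, seg_len = 400, n_segments = 2), "too short")
})

fake_segments <- function(n_per_class, classes = c("ARR", "CHF", "NSR"),
                          segs_per_record = 20) {
  do.call(rbind, lapply(classes, function(cl) {
    n_rec <- ceiling(n_per_class / segs_per_record)
    rec <- rep(sprintf("%s_%03d", cl, seq_len(n_rec)),
               each = segs_per_record)[seq_len(n_per_class)]
    tibble::tibble(
      segment_id = sprintf("%s_%04d", cl, seq_len(n_per_class)),
      record_id = rec, index = seq_len(n_per_class), label = cl)
  }))
}

test_that("split reserves the test set then divides the rest 80/20 per class", {
  segs <- fake_segments(1200)
  plan <- make_split(segs, train_frac = 0.8, test_per_class = 120, seed = 77)
  counts <- table(plan$label, plan$partition)
  for (cl in c("ARR", "CHF", "NSR")) {
    expect_equal(unname(counts[cl, "train"]), 864)
    expect_equal(unname(counts[cl, "validation"]), 216)
    expect_equal(unname(counts[cl, "test"]), 120)
  }
  # partitions are disjoint and exhaustive by construction of the column
  expect_false(anyNA(plan$partition))
  expect_equal(nrow(plan), nrow(segs))
  # train:validation ratio 4:1 within one segment per class
  expect_true(all(abs(counts[, "train"] - 4 * counts[, "validation"]) <= 4))
})

test_that("splitting is deterministic in the seed and sensitive to it", {
  segs <- fake_segments(50)
  a <- make_split(segs, test_per_class = 5, seed = 123)
  b <- make_split(segs, test_per_class = 5, seed = 123)
  expect_identical(a$partition, b$partition)
  c <- make_split(segs, test_per_class = 5, seed = 124)
  expect_false(identical(a$partition, c$partition))
  expect_equal(attr(a, "seed"), 123)
})

test_that("split fails loudly when a class is too small", {
  segs <- fake_segments(10)
  expect_error(make_split(segs, test_per_class = 10, seed = 1),
               "ARR.*10|10.*ARR")
  expect_error(make_split(segs, test_per_class = 3, seed = 1,
                          train_frac = 1.2), "train_frac")
})

test_that("stratification keeps per-class fractions within one segment", {
  segs <- fake_segments(100)
  plan <- make_split(segs, train_frac = 0.8, test_per_class = 10, seed = 5)
  counts <- table(plan$label, plan$partition)
  for (p in colnames(counts)) {
    expect_lte(diff(range(counts[, p])), 1)
  }
})

test_that("grouped splitting never places one record in two partitions", {
  segs <- fake_segments(200, segs_per_record = 20)
  plan <- make_split(segs, test_per_class = 25, seed = 42,
                     group_by_record = TRUE)
  crossing <- table(plan$record_id, plan$partition) > 0
  expect_true(all(rowSums(crossing) == 1))
  # every partition is populated for every class
  expect_true(all(table(plan$label, plan$partition) > 0))
})

test_that("split manifests serialize the assignment", {
  segs <- fake_segments(30)
  plan <- make_split(segs, test_per_class = 3, seed = 8)
  p <- file.path(withr::local_tempdir(), "split.json")
  write_split_manifest(plan, p)
  m <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(m$seed, 8)
  expect_equal(unname(unlist(m$assignment[plan$segment_id])),
               as.character(plan$partition))
})
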