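mont <- standard_1020_montage()

make_rec <- function(duration = 4, fs = 256, fn = function(n) rnorm(n),
                     seed = 1) {
  set.seed(seed)
  n <- duration * fs
  data <- t(replicate(19, fn(n)))
  eeg_recording(data, "S1", "MDD", "EC", sampling_rate = fs)
}

test_that("delimited recordings round-trip with shuffled channel columns", {
  rec <- make_rec(2)
  f <- tempfile(fileext = ".tsv")
  tab <- as.data.frame(t(rec$data))
  set.seed(3)
  shuffled <- tab[, sample(ncol(tab))]
  utils::write.table(shuffled, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_recording(f, "delimited", subject_id = "S1")
  expect_equal(rownames(back$data), mont$channel_names)
  expect_equal(unname(back$data), unname(rec$data), tolerance = 1e-8)
})

test_that("a recording missing a montage channel errors naming it", {
  rec <- make_rec(1)
  f <- tempfile(fileext = ".tsv")
  tab <- as.data.frame(t(rec$data))
  tab$O2 <- NULL
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_recording(f, "delimited"), "O2")
})

test_that("EDF files round-trip within 16-bit quantization precision", {
  rec <- make_rec(3, fn = function(n) 50 * sin(seq_len(n) / 10) + rnorm(n))
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_recording(f, "edf", subject_id = "S1")
  expect_equal(back$sampling_rate, 256)
  # quantization step = range / 65535
  tol <- max(apply(rec$data, 1, function(r) diff(range(r)))) / 65535
  expect_lt(max(abs(back$data - rec$data)), 1.01 * tol)
})

test_that("band-pass plus notch attenuates line noise and keeps the passband", {
  fs <- 256
  tt <- seq_len(6 * fs) / fs
  mk <- function(freq) make_rec(6, fn = function(n) sin(2 * pi * freq * tt))
  rms <- function(x) sqrt(mean(x^2))
  mid <- (2 * fs):(4 * fs)    # avoid filter edge transients

  out50 <- bandpass_notch(mk(50))
  expect_lt(rms(out50$data[1, mid]) / rms(mk(50)$data[1, mid]), 0.05)

  out10 <- bandpass_notch(mk(10))
  expect_lt(abs(rms(out10$data[1, mid]) / rms(mk(10)$data[1, mid]) - 1), 0.1)

  dc <- make_rec(12, fn = function(n) rep(7.5, n))
  dc_mid <- (5 * fs):(7 * fs)
  expect_lt(mean(abs(bandpass_notch(dc)$data[, dc_mid])), 0.15)

  expect_error(bandpass_notch(mk(10), low = 10, high = 200), "band")
})

test_that("filtering is linear and length-preserving", {
  rec <- make_rec(3, seed = 9)
  f1 <- bandpass_notch(rec)
  expect_equal(dim(f1$data), dim(rec$data))
  rec3 <- rec
  rec3$data <- 3 * rec$data
  f3 <- bandpass_notch(rec3)
  expect_equal(f3$data, 3 * f1$data, tolerance = 1e-8)
})

test_that("average re-referencing zeroes the instantaneous channel mean", {
  rec <- average_reference(make_rec(1, seed = 2))
  expect_lt(max(abs(colMeans(rec$data))), 1e-10)
})

test_that("middle-segment extraction is centered and validates length", {
  fs <- 256
  ramp <- make_rec(300, fn = function(n) seq_len(n))
  seg <- extract_middle_segment(ramp, 180)
  expect_equal(ncol(seg$data), 180 * fs)
  # 300 s -> starts at exactly 60 s
  expect_equal(unname(seg$data[1, 1]), 60 * fs + 1)
  expect_equal(unname(seg$data[1, ncol(seg$data)]), 240 * fs)

  exact <- make_rec(180)
  expect_equal(extract_middle_segment(exact, 180)$data, exact$data)

  expect_error(extract_middle_segment(make_rec(100), 180), "shorter")
})

test_that("windowing is exact bookkeeping and reassembles the signal", {
  rec <- make_rec(5, seed = 4)
  w <- make_windows(rec, 2)
  expect_equal(dim(w$x), c(19, 512, 2))      # 1 s remainder dropped
  expect_equal(w$info$window_index, 0:1)
  # concatenating windows reproduces the covered prefix exactly
  expect_equal(cbind(w$x[, , 1], w$x[, , 2]), unname(rec$data[, 1:1024]))

  expect_error(make_windows(rec, 0.3), "integer")

  w2 <- make_windows(rec, 2, overlap = 1)
  expect_equal(dim(w2$x)[3], 4)              # 1 s hop on 5 s
})

test_that("manifests round-trip and load whole cohorts", {
  dir <- tempfile()
  coh <- generate_cohort(synth_spec(n_pairs = 1, duration = 3, seed = 2),
                         dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  recs <- load_cohort(man)
  expect_length(recs, 4)
  expect_equal(recs[[1]]$data, coh$recordings[[1]]$data, tolerance = 1e-4)
  expect_equal(vapply(recs, function(r) r$group, ""),
               man$group)
})
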