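test_that("synthesizer is periodic without jitter and wander, and deterministic", {
  p <- ppg_synth_params(heart_rate_bpm = 60, hr_jitter = 0, wander_amp = 0, seed = 3)
  x <- synthesize_ppg(p, n_seconds = 30, fs = 50)
  # period 60/60 = 1 s = 50 samples, exactly
  n <- length(x$samples)
  expect_equal(x$samples[51:n], x$samples[1:(n - 50)], tolerance = 1e-12)

  # dominant autocorrelation lag at 60 bpm is ~50 samples (brute-force acf)
  pj <- ppg_synth_params(heart_rate_bpm = 60, hr_jitter = 0.02, seed = 3)
  y <- synthesize_ppg(pj, n_seconds = 30, fs = 50)$samples
  yc <- y - mean(y)
  lags <- 25:75
  ac <- vapply(lags, function(k) sum(yc[1:(n - k)] * yc[(k + 1):n]), numeric(1))
  expect_lt(abs(lags[which.max(ac)] - 50), 3)

  # pure function of (params, n_seconds, fs)
  a <- synthesize_ppg(pj, 10, 50)
  b <- synthesize_ppg(pj, 10, 50)
  expect_identical(a$samples, b$samples)

  expect_error(ppg_synth_params(heart_rate_bpm = 20), "heart_rate_bpm")
  expect_error(ppg_synth_params(hr_jitter = -1), "hr_jitter")
})

test_that("resampling preserves length arithmetic and band-limited content", {
  x <- synthesize_ppg(ppg_synth_params(seed = 1), 10, 125)
  expect_identical(resample_signal(x, 125)$samples, x$samples)

  # 8 minutes at 125 Hz down to 50 Hz -> 24000 samples
  long <- ppg_signal(sin(2 * pi * 1.2 * (0:(8 * 60 * 125 - 1)) / 125), 125)
  down <- resample_signal(long, 50)
  expect_identical(length(down$samples), 24000L)
  expect_identical(down$fs, 50)

  # 2 Hz sine at 256 Hz -> 50 Hz keeps its spectral peak at 2 Hz
  t <- (0:2559) / 256  # 10 s, integer number of periods
  s <- ppg_signal(sin(2 * pi * 2 * t), 256)
  r <- resample_signal(s, 50)
  spec <- Mod(stats::fft(r$samples))[2:(length(r$samples) %/% 2)]
  freqs <- (seq_along(spec)) * 50 / length(r$samples)
  expect_equal(freqs[which.max(spec)], 2, tolerance = 1e-9)

  # round trip on a band-limited sine: relative RMS error < 1e-2
  back <- resample_signal(r, 256)
  rel_rms <- sqrt(mean((back$samples - s$samples)^2)) / sqrt(mean(s$samples^2))
  expect_lt(rel_rms, 1e-2)

  expect_error(resample_signal(s, 0), "target_fs")
})

test_that("segmentation drops the remainder and covers a prefix partition", {
  x <- ppg_signal(seq_len(24000), 50)
  segs <- segment_signal(x, 6)
  expect_length(segs, 80L)
  expect_true(all(vapply(segs, function(s) length(s$samples), numeric(1)) == 300))
  # windows tile the first 80*300 samples exactly once each
  starts <- vapply(segs, function(s) s$origin$start_index, numeric(1))
  expect_identical(starts, as.numeric(seq(1, 23701, by = 300)))
  expect_identical(unlist(lapply(segs, `[[`, "samples")), as.double(1:24000))

  expect_length(segment_signal(ppg_signal(rnorm(299), 50), 6), 0L)
  expect_length(segment_signal(ppg_signal(rnorm(300), 50), 6), 1L)
  expect_error(segment_signal(x, 0.001), "duration")
})

test_that("normalization maps endpoints, is idempotent, rejects constants", {
  w <- list(samples = c(0, 0.5, 1), fs = 3, duration = 1,
            origin = list(source_id = "t", start_index = 1L))
  n1 <- normalize_segment(w, "signed_unit")
  expect_equal(n1$samples, c(-1, 0, 1))
  expect_equal(normalize_segment(n1, "signed_unit")$samples, n1$samples)
  expect_equal(normalize_segment(w, "unit")$samples, c(0, 0.5, 1))

  # output always attains both endpoints and stays inside the range
  for (seed in 1:20) {
    s <- local({set.seed(seed); rnorm(50)})
    w2 <- list(samples = s, fs = 50, duration = 1,
               origin = list(source_id = "t", start_index = 1L))
    n2 <- normalize_segment(w2, "signed_unit")
    expect_equal(range(n2$samples), c(-1, 1))
  }

  wc <- list(samples = rep(2, 10), fs = 10, duration = 1,
             origin = list(source_id = "t", start_index = 1L))
  expect_error(normalize_segment(wc), "constant")
})

test_that("CSV and WFDB files round-trip", {
  seg <- make_clean_seg(5)
  csv <- tempfile(fileext = ".csv")
  write_signal(seg, csv, "csv")
  rd <- read_signal(csv, "csv")
  expect_equal(rd$samples, seg$samples, tolerance = 1e-15)
  expect_identical(rd$fs, seg$fs)

  # malformed inputs
  bad <- tempfile(fileext = ".csv")
  writeLines(c("0.1", "0.2"), bad)
  expect_error(read_signal(bad, "csv"), "fs")
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_signal(empty, "csv"), "empty")
  nonnum <- tempfile(fileext = ".csv")
  writeLines(c("# fs=50", "0.1", "abc"), nonnum)
  expect_error(read_signal(nonnum, "csv"), "non-numeric")

  base <- file.path(tempdir(), "rec01")
  write_signal(seg, base, "wfdb", gain = 8192)
  wf <- read_signal(paste0(base, ".hea"), "wfdb")
  expect_identical(wf$fs, 50)
  expect_lt(max(abs(wf$samples - seg$samples)), 1 / 8192)
})
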