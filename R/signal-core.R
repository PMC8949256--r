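# Signal containers, synthetic PPG generation, preprocessing chain and file I/O.

#' Construct a raw PPG signal
#'
#' A `ppg_signal` is the container for a continuous single-channel recording:
#' a numeric sample vector, its sampling rate in Hz, and a free-text
#' provenance label.
#'
#' @param samples Numeric vector of sample values (finite, non-empty).
#' @param fs Sampling rate in Hz (> 0).
#' @param source_id Free-text provenance label.
#' @return An object of class `ppg_signal`.
#' @export
ppg_signal <- function(samples, fs, source_id = "unknown") {
  samples <- as.double(samples)
  if (length(samples) < 1L) stop_param("samples must be non-empty")
  if (!all(is.finite(samples))) stop_param("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_param("fs must be a single positive number")
  }
  structure(
    list(samples = samples, fs = as.double(fs), source_id = as.character(source_id)),
    class = "ppg_signal"
  )
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal> %d samples @ %g Hz (%.2f s), source: %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$source_id))
  invisible(x)
}

#' Construct a fixed-length PPG segment
#'
#' A `ppg_segment` is the unit of corruption, denoising and scoring: a
#' window of `round(duration * fs)` samples carrying a declared value range
#' (`"signed_unit"` for \eqn{[-1, 1]}, `"unit"` for \eqn{[0, 1]}) and its
#' origin within the source signal.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param duration Window duration in seconds; defaults to `length(samples)/fs`.
#' @param range_tag `"signed_unit"` or `"unit"`.
#' @param origin List with `source_id` and 1-based `start_index`.
#' @return An object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, fs, duration = length(samples) / fs,
                        range_tag = c("signed_unit", "unit"),
                        origin = list(source_id = "unknown", start_index = 1L)) {
  range_tag <- match.arg(range_tag)
  samples <- as.double(samples)
  if (!all(is.finite(samples))) stop_param("segment samples must be finite")
  if (length(samples) != round(duration * fs)) {
    stop_param("segment length must equal round(duration * fs)")
  }
  lim <- if (range_tag == "signed_unit") c(-1, 1) else c(0, 1)
  if (any(samples < lim[1] - 1e-12) || any(samples > lim[2] + 1e-12)) {
    stop_param("segment values outside declared range ", range_tag)
  }
  structure(
    list(samples = pmin(pmax(samples, lim[1]), lim[2]), fs = as.double(fs),
         duration = as.double(duration), range_tag = range_tag, origin = origin),
    class = "ppg_segment"
  )
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("<ppg_segment> %d samples @ %g Hz, range %s, from %s[%d]\n",
              length(x$samples), x$fs, x$range_tag,
              x$origin$source_id, x$origin$start_index))
  invisible(x)
}

#' Parameters for the synthetic PPG generator
#'
#' Describes a quasi-periodic pulse waveform: per beat, a systolic bump and
#' a delayed dicrotic bump placed on the beat phase, with beat-to-beat
#' period jitter and sinusoidal baseline wander. Defaults are typical
#' resting adult values: 70 bpm, 4\% beat-period jitter, dicrotic wave at
#' 45\% of systolic amplitude arriving mid-beat, and respiratory baseline
#' wander at 0.25 Hz.
#'
#' @param heart_rate_bpm Mean heart rate in beats/min (30--220).
#' @param hr_jitter Relative standard deviation of the beat period (>= 0).
#' @param sys_amp,dic_amp Amplitudes of the systolic and dicrotic bumps (>= 0).
#' @param sys_center,dic_center Bump centers in beat-phase units (0--1).
#' @param sys_width,dic_width Bump widths (Gaussian sigma) in beat-phase units.
#' @param wander_amp Baseline wander amplitude (>= 0).
#' @param wander_freq Baseline wander frequency in Hz.
#' @param seed RNG seed.
#' @return An object of class `ppg_synth_params`.
#' @export
ppg_synth_params <- function(heart_rate_bpm = 70, hr_jitter = 0.04,
                             sys_amp = 1, dic_amp = 0.45,
                             sys_center = 0.3, dic_center = 0.62,
                             sys_width = 0.1, dic_width = 0.12,
                             wander_amp = 0.15, wander_freq = 0.25,
                             seed = 1L) {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220) {
    stop_param("heart_rate_bpm must be in [30, 220]")
  }
  if (hr_jitter < 0) stop_param("hr_jitter must be >= 0")
  if (sys_amp < 0 || dic_amp < 0 || wander_amp < 0) {
    stop_param("amplitudes must be >= 0")
  }
  structure(
    list(heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
         sys_amp = sys_amp, dic_amp = dic_amp,
         sys_center = sys_center, dic_center = dic_center,
         sys_width = sys_width, dic_width = dic_width,
         wander_amp = wander_amp, wander_freq = wander_freq,
         seed = as.integer(seed)),
    class = "ppg_synth_params"
  )
}

#' Synthesize a quasi-periodic PPG signal
#'
#' Beat onsets are laid down sequentially with periods drawn from a normal
#' distribution around `60/heart_rate_bpm` seconds (relative sd
#' `hr_jitter`, truncated to stay positive). Within each beat, the waveform
#' is the sum of two Gaussian bumps on the beat phase (systolic peak and
#' dicrotic wave); sinusoidal baseline wander is added on top. The output
#' is a pure function of `(params, n_seconds, fs)`.
#'
#' @param params A [ppg_synth_params()] object.
#' @param n_seconds Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return A [ppg_signal()].
#' @examples
#' x <- synthesize_ppg(ppg_synth_params(heart_rate_bpm = 60), n_seconds = 10, fs = 50)
#' @export
synthesize_ppg <- function(params, n_seconds, fs) {
  if (!inherits(params, "ppg_synth_params")) stop_param("params must be ppg_synth_params")
  n <- round(n_seconds * fs)
  if (n < 1) stop_param("n_seconds * fs must be >= 1")
  period0 <- 60 / params$heart_rate_bpm
  local_seed(params$seed, {
    # enough beats to cover the signal even under negative jitter draws
    n_beats <- ceiling(n_seconds / period0 * 1.5) + 4L
    periods <- stats::rnorm(n_beats, mean = period0, sd = params$hr_jitter * period0)
    periods <- pmax(periods, 0.25 * period0)
    onsets <- c(0, cumsum(periods))
    t <- (seq_len(n) - 1) / fs
    beat <- findInterval(t, onsets)        # >= 1 because onsets[1] = 0
    phase <- (t - onsets[beat]) / periods[beat]
    bump <- function(amp, center, width) {
      amp * exp(-0.5 * ((phase - center) / width)^2)
    }
    y <- bump(params$sys_amp, params$sys_center, params$sys_width) +
      bump(params$dic_amp, params$dic_center, params$dic_width) +
      params$wander_amp * sin(2 * pi * params$wander_freq * t)
    ppg_signal(y, fs, source_id = sprintf("synth(hr=%g,seed=%d)",
                                          params$heart_rate_bpm, params$seed))
  })
}

#' Band-limited resampling
#'
#' FFT-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) so that content below the smaller Nyquist
#' frequency is preserved exactly for periodic band-limited inputs. Output
#' length is `round(length(x) * target_fs / fs)`.
#'
#' @param x A [ppg_signal()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return A [ppg_signal()] at `target_fs`.
#' @export
resample_signal <- function(x, target_fs) {
  if (!inherits(x, "ppg_signal")) stop_param("x must be a ppg_signal")
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop_param("target_fs must be a single positive number")
  }
  n <- length(x$samples)
  m <- round(n * target_fs / x$fs)
  if (m == n && isTRUE(all.equal(target_fs, x$fs))) {
    return(ppg_signal(x$samples, target_fs, x$source_id))
  }
  if (m < 1) stop_param("resampled length would be < 1")
  X <- stats::fft(x$samples)
  Y <- complex(m)
  nk <- min(n, m)
  half <- nk %/% 2
  Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
  if (half > 0) {
    Y[m - seq_len(half) + 1] <- X[n - seq_len(half) + 1]
  }
  if (nk %% 2 == 0 && half > 0) {
    # shared Nyquist bin: split symmetrically to keep the result real
    if (m > n) {
      Y[half + 1] <- X[half + 1] / 2
      Y[m - half + 1] <- Conj(X[half + 1]) / 2
    } else {
      Y[half + 1] <- X[half + 1] + X[n - half + 1]
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  ppg_signal(y, target_fs, x$source_id)
}

#' Split a signal into fixed-duration segments
#'
#' Non-overlapping consecutive windows of `round(duration_s * fs)` samples;
#' a trailing remainder shorter than one window is dropped. Segments carry
#' their origin (source id and 1-based start index) and inherit the
#' `"signed_unit"` range tag only after [normalize_segment()]; here samples
#' are returned as-is with no range declared, so windows are plain lists
#' until normalized.
#'
#' @param x A [ppg_signal()].
#' @param duration_s Window duration in seconds (default 6).
#' @return A list of un-normalized windows, each a list with `samples`,
#'   `fs`, `duration`, `origin`. Pass each to [normalize_segment()] to get a
#'   [ppg_segment()].
#' @export
segment_signal <- function(x, duration_s = 6) {
  if (!inherits(x, "ppg_signal")) stop_param("x must be a ppg_signal")
  L <- round(duration_s * x$fs)
  if (L < 1) stop_param("duration_s * fs must be >= 1")
  n_win <- length(x$samples) %/% L
  lapply(seq_len(n_win), function(i) {
    start <- (i - 1L) * L + 1L
    list(samples = x$samples[start:(start + L - 1L)], fs = x$fs,
         duration = duration_s,
         origin = list(source_id = x$source_id, start_index = start))
  })
}

#' Min-max normalize a segment to a declared range
#'
#' Affine per-segment map sending the window minimum and maximum exactly to
#' the bounds of the target range (`[-1, 1]` for `"signed_unit"`, `[0, 1]`
#' for `"unit"`). Idempotent when the input already spans the target range.
#' A constant window has no well-defined map and raises an error.
#'
#' @param x A [ppg_segment()] or a raw window from [segment_signal()].
#' @param target `"signed_unit"` (default) or `"unit"`.
#' @return A [ppg_segment()] tagged with `target`.
#' @export
normalize_segment <- function(x, target = c("signed_unit", "unit")) {
  target <- match.arg(target)
  s <- x$samples
  lo <- min(s); hi <- max(s)
  if (!(lo < hi)) stop_param("degenerate input: constant segment cannot be normalized")
  lim <- if (target == "signed_unit") c(-1, 1) else c(0, 1)
  y <- (s - lo) / (hi - lo) * (lim[2] - lim[1]) + lim[1]
  origin <- if (!is.null(x$origin)) x$origin else list(source_id = "unknown", start_index = 1L)
  ppg_segment(y, x$fs, duration = x$duration, range_tag = target, origin = origin)
}

#' Read a PPG signal from disk
#'
#' CSV dialect: first line `# fs=<Hz>`, then one sample per line. WFDB
#' subset: `<record>.hea` header plus format-16 (little-endian 16-bit)
#' single-channel `.dat`; pass the path to the `.hea` file or the record
#' base name.
#'
#' @param path File path (CSV file, or WFDB `.hea`/record base name).
#' @param format `"csv"` or `"wfdb"`.
#' @return A [ppg_signal()].
#' @export
read_signal <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    if (length(lines) == 0L) stop_param("parse error: empty file ", path)
    m <- regmatches(lines[1], regexec("^#\\s*fs=([0-9.eE+-]+)\\s*$", lines[1]))[[1]]
    if (length(m) != 2L) stop_param("format error: missing '# fs=<Hz>' header in ", path)
    fs <- as.double(m[2])
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L) stop_param("parse error: no samples in ", path)
    vals <- suppressWarnings(as.double(body))
    if (any(is.na(vals))) stop_param("parse error: non-numeric rows in ", path)
    ppg_signal(vals, fs, source_id = basename(path))
  } else {
    base <- sub("\\.hea$", "", path)
    hea <- paste0(base, ".hea")
    if (!file.exists(hea)) stop_param("format error: header not found: ", hea)
    lines <- readLines(hea)
    rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(rec) < 4L) stop_param("format error: malformed WFDB record line")
    fs <- as.double(rec[3]); nsamp <- as.integer(rec[4])
    sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    datfile <- file.path(dirname(hea), sig[1])
    gain <- as.double(strsplit(sig[3], "[(/]")[[1]][1])
    if (!is.finite(gain) || gain == 0) gain <- 200
    raw <- readBin(datfile, what = "integer", n = nsamp, size = 2L,
                   signed = TRUE, endian = "little")
    if (length(raw) < nsamp) stop_param("parse error: truncated .dat file")
    ppg_signal(raw / gain, fs, source_id = basename(base))
  }
}

#' Write a PPG signal to disk
#'
#' Inverse of [read_signal()]. CSV writes full double precision and
#' round-trips exactly; the WFDB subset quantizes to 16-bit integers at
#' `gain` counts per unit (round-trip exact to `1/(2*gain)`).
#'
#' @param x A [ppg_signal()] or [ppg_segment()].
#' @param path Output path (for WFDB, the record base name or `.hea` path).
#' @param format `"csv"` or `"wfdb"`.
#' @param gain WFDB integer counts per physical unit (default 8192).
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("csv", "wfdb"), gain = 8192) {
  format <- match.arg(format)
  if (inherits(x, "ppg_segment")) {
    x <- ppg_signal(x$samples, x$fs, source_id = x$origin$source_id)
  }
  if (!inherits(x, "ppg_signal")) stop_param("x must be a ppg_signal or ppg_segment")
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.17g", x$fs), con)
    writeLines(sprintf("%.17g", x$samples), con)
  } else {
    base <- sub("\\.hea$", "", path)
    rec <- basename(base)
    q <- as.integer(round(pmin(pmax(x$samples * gain, -32768), 32767)))
    writeLines(c(
      sprintf("%s 1 %.17g %d", rec, x$fs, length(q)),
      sprintf("%s.dat 16 %g 16 0 0 0 0 ppg", rec, gain)
    ), paste0(base, ".hea"))
    writeBin(q, paste0(base, ".dat"), size = 2L, endian = "little")
  }
  invisible(path)
}
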