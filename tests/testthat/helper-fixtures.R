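# Shared fixture builders: everything is generated in code, no files.

# One normalized clean synthetic segment (300 samples at 50 Hz).
make_clean_seg <- function(seed = 1L, hr = 70, fs = 50, duration = 6) {
  sig <- synthesize_ppg(ppg_synth_params(heart_rate_bpm = hr, seed = seed),
                        n_seconds = duration, fs = fs)
  normalize_segment(segment_signal(sig, duration)[[1]], "signed_unit")
}

# Heart rate varied deterministically with the index, like the runner does.
hr_for <- function(i) 55 + (i %% 46)

# A constant unit-range segment of length n (for moment checks).
const_unit_seg <- function(value, n) {
  ppg_segment(rep(value, n), fs = n, duration = 1, range_tag = "unit")
}

# Brute-force sliding median with edge replication (independent oracle).
brute_median <- function(v, w) {
  h <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    idx <- pmin(pmax((i - h):(i + h), 1L), n)
    sort(v[idx])[h + 1L]
  }, numeric(1))
}

# Brute-force relevance matrix: normalized inner products via double loop.
brute_relevance <- function(Q, K, p) {
  if (is.vector(Q)) Q <- matrix(Q, ncol = 1L)
  if (is.vector(K)) K <- matrix(K, ncol = 1L)
  nq <- nrow(Q) - p + 1L
  nk <- nrow(K) - p + 1L
  rel <- matrix(0, nq, nk)
  for (i in seq_len(nq)) {
    qi <- as.vector(t(Q[i:(i + p - 1L), , drop = FALSE]))
    qi <- qi / max(sqrt(sum(qi^2)), .Machine$double.eps)
    for (j in seq_len(nk)) {
      kj <- as.vector(t(K[j:(j + p - 1L), , drop = FALSE]))
      kj <- kj / max(sqrt(sum(kj^2)), .Machine$double.eps)
      rel[i, j] <- sum(qi * kj)
    }
  }
  rel
}

# Brute-force gather + overlap-average oracle for texture transfer.
brute_transfer <- function(V, H, p) {
  if (is.vector(V)) V <- matrix(V, ncol = 1L)
  C <- ncol(V)
  L <- length(H) + p - 1L
  acc <- matrix(0, L, C)
  cnt <- numeric(L)
  for (i in seq_along(H)) {
    patch <- V[H[i]:(H[i] + p - 1L), , drop = FALSE]
    rows <- i:(i + p - 1L)
    acc[rows, ] <- acc[rows, ] + patch
    cnt[rows] <- cnt[rows] + 1
  }
  acc / cnt
}
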