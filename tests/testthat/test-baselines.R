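test_that("wavelet decomposition reconstructs exactly for orthogonal families", {
  set.seed(10)
  x <- rnorm(300)
  for (w in c("db18", "db19", "db20", "sym15")) {
    for (lev in c(3L, 6L, 9L)) {
      expect_lt(max(abs(waverec(wavedec(x, w, lev)) - x)), 1e-8,
                label = sprintf("%s level %d round-trip", w, lev))
    }
  }
  # the 62-tap discrete Meyer FIR approximation is only near-orthogonal
  expect_lt(max(abs(waverec(wavedec(x, "dmey", 3)) - x)), 0.05)
  expect_error(wavedec(x, "haar", 3), "unsupported")
})

test_that("wavelet shrinkage maps zero to zero and reduces gaussian noise", {
  cfg <- wavelet_config("dmey", 3)
  expect_equal(wavelet_denoise(rep(0, 300), cfg), rep(0, 300), tolerance = 1e-12)

  # Monte-Carlo improvement with the per-kind configuration (20 seeds)
  clean <- make_clean_seg(1)
  deltas <- vapply(1:20, function(s) {
    pair <- corrupt(clean, noise_chain(noise_spec("gaussian", sigma = 0.1),
                                       master_seed = s))
    mse(wavelet_denoise(pair$noisy, wavelet_for("gaussian")), clean) -
      mse(pair$noisy, clean)
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("median filter matches the brute-force sliding median", {
  expect_equal(median_filter(c(0, 0, 1, 0, 0), 3), c(0, 0, 0, 0, 0))
  expect_identical(median_filter(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_identical(median_filter(rep(2, 10), 5), rep(2, 10))
  expect_error(median_filter(rnorm(10), 4), "odd")

  for (s in 1:50) {
    set.seed(s)
    v <- rnorm(60)
    w <- sample(c(3, 5, 7), 1)
    expect_equal(median_filter(v, w), brute_median(v, w), tolerance = 1e-14)
  }
})

test_that("wiener filter has its degenerate identities and denoises steps", {
  # constant input: local variance is zero, so the gain vanishes and the
  # local mean (equal to the constant, up to rounding) passes through
  expect_equal(wiener_filter(rep(1.5, 20), 5), rep(1.5, 20), tolerance = 1e-12)
  v <- rnorm(20)
  expect_identical(wiener_filter(v, 1), v)
  expect_error(wiener_filter(v, 2), "odd")

  step <- rep(c(0, 1), each = 150)
  deltas <- vapply(1:200, function(s) {
    set.seed(s)
    noisy <- step + rnorm(300, 0, 0.1)
    mean((wiener_filter(noisy, 5) - step)^2) - mean((noisy - step)^2)
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("gaussian smoothing kernel is normalized and shrinks white noise", {
  expect_equal(sum(gaussian_kernel(1)), 1, tolerance = 1e-12)
  expect_equal(sum(gaussian_kernel(0.3)), 1, tolerance = 1e-12)
  expect_identical(gaussian_smooth(rep(0.7, 30), 1), rep(0.7, 30))
  expect_error(gaussian_smooth(rnorm(10), 0), "sigma")

  # output variance on white noise ~ sum(k^2) x input variance
  k2 <- sum(gaussian_kernel(1)^2)
  set.seed(99)
  ratios <- vapply(1:30, function(s) {
    x <- rnorm(2000)
    stats::var(gaussian_smooth(x, 1)) / stats::var(x)
  }, numeric(1))
  expect_lt(abs(mean(ratios) / k2 - 1), 0.1)
})

test_that("per-noise configuration tables match the reference settings", {
  expect_identical(best_respective("salt_pepper")$filter_kind, "median")
  expect_identical(best_respective("salt_pepper")$window, 5L)
  expect_identical(best_respective("uniform")$filter_kind, "gaussian")
  expect_identical(best_respective("uniform")$sigma, 1)
  expect_identical(best_respective("gaussian")$filter_kind, "wiener")
  expect_identical(best_respective("gaussian")$window, 5L)
  expect_identical(best_respective("poisson")$window, 3L)
  expect_identical(best_respective("speckle")$window, 3L)

  wf <- wavelet_for("salt_pepper")
  expect_identical(wf$wavelet_name, "db18")
  expect_identical(wf$level, 6L)
  expect_identical(wavelet_for("gaussian")$wavelet_name, "dmey")
  expect_identical(wavelet_for("uniform")$level, 9L)
  expect_identical(wavelet_for("poisson")$wavelet_name, "db19")
  expect_identical(wavelet_for("speckle")$wavelet_name, "db20")
  expect_error(best_respective("motion"), "no reference filter")
  expect_error(wavelet_for("motion"), "no reference wavelet")
})

test_that("all baseline denoisers preserve length and produce finite values", {
  seg <- corrupt(make_clean_seg(3),
                 noise_chain(noise_spec("salt_pepper"), master_seed = 2))$noisy
  outs <- list(
    median_filter(seg, 5), wiener_filter(seg, 5), gaussian_smooth(seg, 1),
    wavelet_denoise(seg, wavelet_config("sym15", 9))
  )
  for (o in outs) {
    expect_length(o$samples, 300L)
    expect_true(all(is.finite(o$samples)))
    expect_true(all(abs(o$samples) <= 1))
  }
})
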