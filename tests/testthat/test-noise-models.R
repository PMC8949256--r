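test_that("unit range maps are fixed affine inverses", {
  seg <- ppg_segment(c(-1, 0, 1), fs = 3, duration = 1, range_tag = "signed_unit")
  u <- to_unit(seg)
  expect_equal(u$samples, c(0, 0.5, 1))
  expect_equal(from_unit(u)$samples, seg$samples)
  expect_error(to_unit(u), "signed_unit")
  expect_error(from_unit(seg), "unit")

  # monotone: ordering of samples preserved
  s <- make_clean_seg(2)
  expect_identical(order(to_unit(s)$samples), order(s$samples))
})

test_that("null parameters make every generator the identity", {
  x <- const_unit_seg(0.37, 500)
  expect_identical(add_gaussian(x, 0, seed = 1)$samples, x$samples)
  expect_identical(add_speckle(x, 0, seed = 1)$samples, x$samples)
  expect_identical(add_salt_pepper(x, 0, seed = 1)$samples, x$samples)
  expect_identical(add_uniform(x, 0, 0, seed = 1)$samples, x$samples)
})

test_that("generators respect clipping bounds and structural contracts", {
  ones <- const_unit_seg(1, 1000)
  expect_true(all(add_gaussian(ones, 0.5, seed = 2)$samples <= 1))
  zeros <- const_unit_seg(0, 1000)
  expect_identical(add_poisson(zeros, 255, seed = 3)$samples, zeros$samples)
  expect_identical(add_speckle(zeros, 0.5, seed = 3)$samples, zeros$samples)

  # salt-and-pepper: exact count, extreme values only, others untouched
  x <- const_unit_seg(0.5, 300)
  sp <- add_salt_pepper(x, 0.05, seed = 4)
  hit <- sp$samples != 0.5
  expect_identical(sum(hit), 15L)
  expect_true(all(sp$samples[hit] %in% c(0, 1)))
  all_hit <- add_salt_pepper(x, 1, seed = 4)
  expect_true(all(all_hit$samples %in% c(0, 1)))

  # uniform offsets stay within the support when no clipping is active
  u <- add_uniform(const_unit_seg(0.4, 1000), 0, 0.1, seed = 5)
  d <- u$samples - 0.4
  expect_true(all(d >= 0 & d <= 0.1))

  # poisson MSE shrinks monotonically with scale
  x2 <- const_unit_seg(0.5, 20000)
  mses <- vapply(c(1e2, 1e4, 1e6), function(sc) {
    mean((add_poisson(x2, sc, seed = 6)$samples - 0.5)^2)
  }, numeric(1))
  expect_true(all(diff(mses) < 0))
})

test_that("corrupt pipeline is deterministic and composes with single ops", {
  clean <- make_clean_seg(7)
  ch <- noise_chain(noise_spec("gaussian", sigma = 0.05),
                    noise_spec("uniform"), master_seed = 11)
  p1 <- corrupt(clean, ch)
  p2 <- corrupt(clean, ch)
  expect_identical(p1$noisy$samples, p2$noisy$samples)
  expect_identical(p1$noisy$range_tag, "signed_unit")
  expect_true(all(abs(p1$noisy$samples) <= 1))

  # zero-noise chain is the identity
  pid <- corrupt(clean, noise_chain(noise_spec("gaussian", sigma = 0), master_seed = 1))
  expect_equal(pid$noisy$samples, clean$samples, tolerance = 1e-12)

  # a single-spec chain equals the direct op with the derived stage seed
  ch1 <- noise_chain(noise_spec("gaussian", sigma = 0.05), master_seed = 9)
  via_chain <- corrupt(clean, ch1)$noisy
  direct <- from_unit(add_gaussian(to_unit(clean), 0.05, seed = derive_seed(9, 1L)))
  expect_identical(via_chain$samples, direct$samples)

  # serialization round-trips to the identical noisy segment
  js <- chain_to_json(ch)
  p3 <- corrupt(clean, chain_from_json(js))
  expect_identical(p3$noisy$samples, p1$noisy$samples)

  expect_error(noise_chain(noise_spec("gaussian"), noise_spec("gaussian")), "distinct")
})

test_that("random mixed chains sample kinds uniformly without replacement", {
  ch5 <- random_mixed_chain(5, master_seed = 1)
  expect_setequal(vapply(ch5$specs, `[[`, character(1), "kind"),
                  c("gaussian", "poisson", "salt_pepper", "speckle", "uniform"))

  a <- random_mixed_chain(2, master_seed = 123)
  b <- random_mixed_chain(2, master_seed = 123)
  expect_identical(vapply(a$specs, `[[`, character(1), "kind"),
                   vapply(b$specs, `[[`, character(1), "kind"))
  expect_error(random_mixed_chain(1, 1), "k must be")
  expect_error(random_mixed_chain(6, 1), "k must be")

  # each unordered pair appears with frequency within 3 sigma of 1/10
  pairs <- vapply(1:1000, function(s) {
    k <- sort(vapply(random_mixed_chain(2, master_seed = s)$specs,
                     `[[`, character(1), "kind"))
    paste(k, collapse = "+")
  }, character(1))
  counts <- table(pairs)
  expect_identical(length(counts), 10L)
  sigma <- sqrt(1000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 100) <= 3 * sigma))
})

test_that("motion artifacts are band-limited, bounded and localized", {
  a <- synthesize_motion_artifact(3000, 50, seed = 5)
  b <- synthesize_motion_artifact(3000, 50, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_true(all(abs(a$samples) <= 1))

  # > 90% of spectral power within 0.25-6 Hz on a 60 s draw
  pg <- stats::spec.pgram(stats::ts(a$samples, frequency = 50), plot = FALSE, taper = 0)
  inband <- sum(pg$spec[pg$freq >= 0.25 & pg$freq <= 6]) / sum(pg$spec)
  expect_gt(inband, 0.9)

  clean <- make_clean_seg(8)
  art <- synthesize_motion_artifact(300, 50, seed = 6)
  pair <- inject_motion_artifact(clean, art, ratio = 0.3, start_index = 101L)
  # exactly round(0.3 * 300) = 90 samples may differ; the rest are untouched
  w <- 90L
  inside <- 101:190
  expect_equal(pair$noisy$samples[-inside], clean$samples[-inside], tolerance = 1e-14)
  zero_art <- ppg_signal(rep(0, 300), 50)
  expect_equal(inject_motion_artifact(clean, zero_art, 0.3, 1L)$noisy$samples,
               clean$samples, tolerance = 1e-12)
  expect_error(inject_motion_artifact(clean, art, 0.5, 200L), "bounds")
})

test_that("expected corruption grows with nested chain length", {
  seg <- make_clean_seg(1)
  mses <- vapply(1:200, function(s) {
    ch5 <- random_mixed_chain(5, master_seed = s)
    vapply(1:5, function(k) {
      mse(corrupt(seg, noise_chain(ch5$specs[1:k], master_seed = s))$noisy, seg)
    }, numeric(1))
  }, numeric(5))
  expect_true(all(diff(rowMeans(mses)) > 0))
})
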