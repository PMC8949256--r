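test_that("input preparation aligns all four signals", {
  noisy <- make_clean_seg(1)
  ref <- make_clean_seg(2)
  inp <- prepare_inputs(noisy, ref, scale_factor = 4)
  expect_true(all(lengths(inp) == 300L))
  # the degraded-domain reference really goes through 75 samples
  expect_length(ppgdenoise:::lin_down(ref$samples, 4), 75L)
  # scale_factor 1 is the identity round trip
  inp1 <- prepare_inputs(noisy, ref, scale_factor = 1)
  expect_identical(inp1$ref_down_up, ref$samples)
  expect_identical(inp1$noisy_up, noisy$samples)
  expect_error(prepare_inputs(noisy$samples, ref$samples[-1]), "equal length")
})

test_that("shared encoder gives identical features for identical inputs", {
  cfg <- npd_config(feature_channels = 8, levels = 2, seed = 4)
  w <- npd_init(cfg)
  inp <- prepare_inputs(make_clean_seg(1), make_clean_seg(1), 4)
  tx <- extract_textures(w, cfg, inp)
  expect_identical(tx$Q, tx$K)  # same input, same weights
  expect_identical(dim(tx$Q), c(300L, 8L))
  # features respond to weight changes
  w2 <- w
  w2$enc1$W <- w2$enc1$W * 2
  expect_gt(max(abs(extract_textures(w2, cfg, inp)$Q - tx$Q)), 0)
})

test_that("relevance embedding matches the brute-force oracle", {
  # self-similarity: normalized diagonal is exactly 1
  set.seed(5)
  Q <- matrix(rnorm(32 * 4), 32, 4)
  rel_self <- relevance_embedding(Q, Q, patch_size = 3)
  expect_equal(diag(rel_self), rep(1, nrow(rel_self)), tolerance = 1e-12)
  expect_true(all(rel_self >= -1 - 1e-12 & rel_self <= 1 + 1e-12))

  # orthogonal patches give zero relevance
  q <- c(1, 0, 0, 0)
  k <- c(0, 0, 0, 1)
  expect_equal(relevance_embedding(q, k, patch_size = 3)[1, 2], 0, tolerance = 1e-12)

  for (s in 1:40) {
    set.seed(s)
    C <- sample(1:4, 1)
    Q <- matrix(rnorm(32 * C), 32, C)
    K <- matrix(rnorm(24 * C), 24, C)
    expect_equal(relevance_embedding(Q, K, 3), brute_relevance(Q, K, 3),
                 tolerance = 1e-6)
  }
  expect_error(relevance_embedding(rnorm(2), rnorm(2), 3), "patch longer")
})

test_that("hard and soft attention match an exhaustive scan", {
  relI <- diag(10) + matrix(0.1, 10, 10)
  att <- hard_soft_attention(relI)
  expect_identical(att$H, 1:10)
  expect_equal(att$S, rep(1.1, 10))

  # ties break toward the lowest index
  flat <- matrix(0.5, 4, 7)
  expect_identical(hard_soft_attention(flat)$H, rep(1L, 4))

  for (s in 1:40) {
    set.seed(s)
    rel <- matrix(rnorm(20 * 30), 20, 30)
    att <- hard_soft_attention(rel)
    bh <- apply(rel, 1, which.max)
    expect_identical(att$H, as.integer(bh))
    expect_equal(att$S, rel[cbind(1:20, bh)])
  }
  expect_error(hard_soft_attention(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(hard_soft_attention(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("texture transfer equals the gather-and-average oracle", {
  set.seed(6)
  V <- matrix(rnorm(12 * 3), 12, 3)
  # identity gather reconstructs V exactly
  H_id <- seq_len(10)
  expect_equal(transfer_textures(V, H_id, 3), V, tolerance = 1e-12)
  # constant V stays constant
  Vc <- matrix(2, 12, 3)
  expect_true(all(transfer_textures(Vc, c(3, 1, 7, 2, 5, 10, 4, 8, 6, 9), 3) == 2))

  for (s in 1:40) {
    set.seed(s)
    V <- matrix(rnorm(8 * 2), 8, 2)
    H <- sample(6, 6, replace = TRUE)
    expect_equal(transfer_textures(V, H, 3), brute_transfer(V, H, 3),
                 tolerance = 1e-12)
  }
  expect_error(transfer_textures(V, c(1, 99), 3), "out of range")
})

test_that("fusion gates the transfer branch with the soft scores", {
  cfg <- npd_config(feature_channels = 8, levels = 2, seed = 7)
  w <- npd_init(cfg)
  noisy <- make_clean_seg(3)$samples
  set.seed(8)
  F <- matrix(rnorm(300 * 8, sd = 0.1), 300, 8)
  T1 <- matrix(rnorm(300 * 8), 300, 8)
  T2 <- matrix(rnorm(300 * 8), 300, 8)
  # S = 0: transferred textures cannot influence the output
  o1 <- fuse_features(w, cfg, F, T1, rep(0, 300), noisy)
  o2 <- fuse_features(w, cfg, F, T2, rep(0, 300), noisy)
  expect_identical(o1, o2)
  expect_length(o1, 300L)
  expect_true(all(o1 >= -1 & o1 <= 1))
  # with nonzero S the textures matter
  o3 <- fuse_features(w, cfg, F, T1, rep(0.5, 300), noisy)
  o4 <- fuse_features(w, cfg, F, T2, rep(0.5, 300), noisy)
  expect_gt(max(abs(o3 - o4)), 0)
})

test_that("forward pass is pure and respects the output contract", {
  cfg <- npd_config(seed = 9)
  w <- npd_init(cfg)
  expect_lte(npd_n_params(w), 100000)
  noisy <- corrupt(make_clean_seg(4), noise_chain(noise_spec("gaussian", sigma = 0.1),
                                                  master_seed = 3))$noisy
  ref <- make_clean_seg(5)
  y1 <- npd_forward(w, cfg, noisy, ref)$out
  y2 <- npd_forward(w, cfg, noisy, ref)$out
  expect_identical(y1, y2)
  expect_length(y1, 300L)
  expect_true(all(y1 >= -1 & y1 <= 1))
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- npd_config(feature_channels = 6, levels = 2, seed = 5)
  w <- npd_init(cfg)
  pair <- corrupt(make_clean_seg(3), noise_chain(noise_spec("salt_pepper"),
                                                 master_seed = 7))
  ref <- make_clean_seg(11)
  lg <- ppgdenoise:::npd_loss_grad(w, cfg, pair$noisy$samples, ref$samples,
                                   pair$clean$samples)
  set.seed(12)
  for (nm in names(w)) {
    for (rep in 1:3) {
      i <- sample(length(w[[nm]]$W), 1)
      eps <- 1e-6
      wp <- w; wp[[nm]]$W[i] <- wp[[nm]]$W[i] + eps
      wm <- w; wm[[nm]]$W[i] <- wm[[nm]]$W[i] - eps
      lp <- ppgdenoise:::npd_loss_grad(wp, cfg, pair$noisy$samples, ref$samples,
                                       pair$clean$samples)$loss
      lm <- ppgdenoise:::npd_loss_grad(wm, cfg, pair$noisy$samples, ref$samples,
                                       pair$clean$samples)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- lg$grads[[nm]]$W[i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-3,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})
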