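# The neural PPG denoiser: a 1D reference-based texture transformer.
#
# Architecture (single attention scale):
#   Q = E(up(down(noisy)))   K = E(up(down(reference)))   V = E(reference)
# with a shared learnable conv encoder E. Patch-wise cosine relevance
# between Q and K yields hard indices H and soft scores S; V-patches
# gathered by H are folded into transferred textures T. A separate conv
# backbone B maps the noisy signal to features F, which are fused as
#   F' = F + conv([F, T]) * S
# and decoded to a residual added onto the noisy input, clamped to [-1, 1].
#
# Gradients are computed analytically. The hard indices H are treated as
# piecewise constant (the almost-everywhere-correct gradient); gradient
# flows through S, T, V, the shared encoder, the backbone, the fusion conv
# and the decoder.

#' Configuration of the neural PPG denoiser
#'
#' @param feature_channels Channel width of every feature map (default 16).
#' @param patch_size Texture patch length in samples (odd, default 3).
#' @param patch_stride Stride between texture patches (default 1).
#' @param scale_factor Down/up ratio used to build the degraded-domain
#'   inputs (default 4).
#' @param levels Encoder/backbone depth in conv stages (default 3).
#' @param kernel_size Convolution kernel length (odd, default 3).
#' @param seed Weight initialization seed.
#' @return An object of class `npd_config`.
#' @export
npd_config <- function(feature_channels = 16L, patch_size = 3L, patch_stride = 1L,
                       scale_factor = 4L, levels = 3L, kernel_size = 3L, seed = 1L) {
  if (scale_factor < 1) stop_param("scale_factor must be >= 1")
  if (patch_size %% 2 != 1) stop_param("patch_size must be odd")
  if (levels < 1) stop_param("levels must be >= 1")
  if (kernel_size %% 2 != 1) stop_param("kernel_size must be odd")
  structure(list(feature_channels = as.integer(feature_channels),
                 patch_size = as.integer(patch_size),
                 patch_stride = as.integer(patch_stride),
                 scale_factor = as.integer(scale_factor),
                 levels = as.integer(levels),
                 kernel_size = as.integer(kernel_size),
                 seed = as.integer(seed)),
            class = "npd_config")
}

# Channel widths of the encoder/backbone stages: 1 -> C -> ... -> C.
stage_channels <- function(cfg) c(1L, rep(cfg$feature_channels, cfg$levels))

#' Initialize model weights
#'
#' He-style normal initialization, fully determined by `cfg$seed`. Weights
#' are a flat named list of matrices/vectors (`enc*/bb*` conv stages,
#' `fuse`, `dec1`, `dec2`).
#'
#' @param cfg An [npd_config()].
#' @return Named list of weight arrays (class `npd_weights`).
#' @export
npd_init <- function(cfg) {
  k <- cfg$kernel_size
  C <- cfg$feature_channels
  ch <- stage_channels(cfg)
  local_seed(cfg$seed, {
    mk <- function(cin, cout) {
      list(W = matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                      k * cin, cout),
           b = numeric(cout))
    }
    w <- list()
    for (i in seq_len(cfg$levels)) {
      w[[paste0("enc", i)]] <- mk(ch[i], ch[i + 1])
      w[[paste0("bb", i)]] <- mk(ch[i], ch[i + 1])
    }
    w$fuse <- mk(2L * C, C)
    w$dec1 <- mk(C, C)
    w$dec2 <- mk(C, 1L)
    structure(w, class = "npd_weights")
  })
}

#' Number of trainable parameters
#'
#' @param weights An `npd_weights` list (or an `npd_checkpoint`).
#' @return Integer parameter count.
#' @export
npd_n_params <- function(weights) {
  if (inherits(weights, "npd_checkpoint")) weights <- weights$weights
  sum(vapply(weights, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Linear down/up sampling (cheap and alignment-exact; band-limited
# resampling is reserved for preprocessing).
lin_down <- function(x, s) {
  if (s == 1L) return(x)
  L <- length(x)
  m <- max(1L, round(L / s))
  stats::approx(seq_len(L), x, xout = seq(1, L, length.out = m))$y
}

lin_up <- function(x, L) {
  m <- length(x)
  if (m == L) return(x)
  stats::approx(seq(1, L, length.out = m), x, xout = seq_len(L))$y
}

#' Prepare the four model inputs
#'
#' Builds the four aligned inputs of the denoiser from a noisy segment and
#' a clean reference of the same length: the noisy signal, the reference,
#' the reference passed through a down/up round trip at `scale_factor`
#' (degraded domain of the keys), and the noisy signal passed through the
#' same round trip (degraded domain of the queries). All outputs have the
#' input length.
#'
#' @param noisy,reference Segments or numeric vectors of equal length.
#' @param scale_factor Down/up ratio (>= 1).
#' @return List with numeric vectors `noisy`, `reference`, `ref_down_up`,
#'   `noisy_up`.
#' @export
prepare_inputs <- function(noisy, reference, scale_factor = 4L) {
  x <- as_samples(noisy)
  r <- as_samples(reference)
  if (length(x) != length(r)) stop_param("noisy and reference must have equal length")
  L <- length(x)
  list(noisy = x,
       reference = r,
       ref_down_up = lin_up(lin_down(r, scale_factor), L),
       noisy_up = lin_up(lin_down(x, scale_factor), L))
}

# Shared encoder / backbone forward with cache (prefix "enc" or "bb").
stack_forward <- function(weights, cfg, x, prefix) {
  k <- cfg$kernel_size
  cur <- matrix(x, ncol = 1L)
  cache <- list()
  for (i in seq_len(cfg$levels)) {
    wl <- weights[[paste0(prefix, i)]]
    cv <- conv1d_forward(cur, wl$W, wl$b, k)
    z <- cv$y
    a <- if (i < cfg$levels) relu_forward(z) else z
    cache[[i]] <- list(Xu = cv$Xu, z = z, cin = ncol(cur))
    cur <- a
  }
  list(out = cur, cache = cache)
}

stack_backward <- function(dout, weights, cfg, cache, prefix, grads) {
  k <- cfg$kernel_size
  L <- nrow(dout)
  d <- dout
  for (i in rev(seq_len(cfg$levels))) {
    cc <- cache[[i]]
    if (i < cfg$levels) d <- relu_backward(d, cc$z)
    wl <- weights[[paste0(prefix, i)]]
    bw <- conv1d_backward(d, cc$Xu, wl$W, k, L, cc$cin)
    nm <- paste0(prefix, i)
    grads[[nm]]$W <- grads[[nm]]$W + bw$dW
    grads[[nm]]$b <- grads[[nm]]$b + bw$db
    d <- bw$dx
  }
  list(dx = d, grads = grads)
}

#' Extract texture features from the prepared inputs
#'
#' Applies the shared learnable encoder to the degraded-domain noisy input
#' (queries `Q`), the degraded-domain reference (keys `K`) and the original
#' reference (values `V`). The same weights produce all three, so identical
#' inputs give identical features.
#'
#' @param weights `npd_weights` (or an `npd_checkpoint`).
#' @param cfg The matching [npd_config()] (ignored if `weights` is a
#'   checkpoint).
#' @param inputs List from [prepare_inputs()].
#' @return List of feature matrices `Q`, `K`, `V`.
#' @export
extract_textures <- function(weights, cfg, inputs) {
  if (inherits(weights, "npd_checkpoint")) {
    cfg <- weights$model_cfg
    weights <- weights$weights
  }
  list(Q = stack_forward(weights, cfg, inputs$noisy_up, "enc")$out,
       K = stack_forward(weights, cfg, inputs$ref_down_up, "enc")$out,
       V = stack_forward(weights, cfg, inputs$reference, "enc")$out)
}

#' Fuse backbone features with transferred textures
#'
#' Residual gated fusion: `F' = F + conv([F, T]) * S`, followed by the
#' decoder and a residual connection from the noisy input, clamped to
#' \eqn{[-1, 1]}. With `S = 0` the transfer branch is gated off and the
#' output is the backbone-only reconstruction.
#'
#' @param weights `npd_weights`.
#' @param cfg The matching [npd_config()].
#' @param F Backbone feature matrix of the noisy input.
#' @param T_feat Transferred texture features aligned to `F`.
#' @param S_pos Per-position soft attention scores (numeric vector).
#' @param noisy Numeric vector, the noisy input (residual source).
#' @return Numeric vector: the restored signal.
#' @export
fuse_features <- function(weights, cfg, F, T_feat, S_pos, noisy) {
  npd_head_forward(weights, cfg, F, T_feat, S_pos, noisy)$out
}

npd_head_forward <- function(weights, cfg, F, T_feat, S_pos, noisy) {
  k <- cfg$kernel_size
  Gin <- cbind(F, T_feat)
  gv <- conv1d_forward(Gin, weights$fuse$W, weights$fuse$b, k)
  G <- gv$y
  F2 <- F + G * S_pos
  d1 <- conv1d_forward(F2, weights$dec1$W, weights$dec1$b, k)
  a1 <- relu_forward(d1$y)
  d2 <- conv1d_forward(a1, weights$dec2$W, weights$dec2$b, k)
  pre <- noisy + as.vector(d2$y)
  out <- pmin(pmax(pre, -1), 1)
  list(out = out, pre = pre, Gin_Xu = gv$Xu, G = G, F2 = F2,
       d1_Xu = d1$Xu, z1 = d1$y, a1 = a1, d2_Xu = d2$Xu)
}

#' Full forward pass of the denoiser
#'
#' Pure function of `(weights, noisy, reference)`: prepares the four
#' inputs, extracts textures, computes relevance/attention, transfers
#' reference textures and fuses them with the backbone features.
#'
#' @param weights `npd_weights` or an `npd_checkpoint`.
#' @param cfg The matching [npd_config()] (taken from the checkpoint when
#'   one is given).
#' @param noisy,reference Segments or numeric vectors of equal length.
#' @param want_cache Keep intermediate values for backprop (internal use).
#' @return List with `out` (numeric restored signal) and, if requested,
#'   `cache`.
#' @export
npd_forward <- function(weights, cfg, noisy, reference, want_cache = FALSE) {
  if (inherits(weights, "npd_checkpoint")) {
    cfg <- weights$model_cfg
    weights <- weights$weights
  }
  inputs <- prepare_inputs(noisy, reference, cfg$scale_factor)
  L <- length(inputs$noisy)
  p <- cfg$patch_size; st <- cfg$patch_stride
  fq <- stack_forward(weights, cfg, inputs$noisy_up, "enc")
  fk <- stack_forward(weights, cfg, inputs$ref_down_up, "enc")
  fv <- stack_forward(weights, cfg, inputs$reference, "enc")
  C <- ncol(fq$out)

  Qp <- unfold_patches(fq$out, p, st)
  Kp <- unfold_patches(fk$out, p, st)
  Vp <- unfold_patches(fv$out, p, st)
  qn <- row_normalize(Qp); kn <- row_normalize(Kp)
  rel <- qn$N %*% t(kn$N)
  att <- hard_soft_attention(rel)
  Tf <- fold_patches(Vp[att$H, , drop = FALSE], p, st, C)
  # per-patch scalar scores are replicated across the patch offsets before
  # overlap-averaging down to per-position scores
  S_pos <- as.vector(fold_patches(matrix(att$S, length(att$S), p), p, st, 1L))

  fb <- stack_forward(weights, cfg, inputs$noisy, "bb")
  head <- npd_head_forward(weights, cfg, fb$out, Tf, S_pos, inputs$noisy)

  res <- list(out = head$out)
  if (want_cache) {
    res$cache <- list(inputs = inputs, L = L, C = C,
                      fq = fq, fk = fk, fv = fv,
                      Qp = Qp, Kp = Kp, Vp = Vp, qn = qn, kn = kn,
                      H = att$H, S = att$S, S_pos = S_pos, Tf = Tf,
                      fb = fb, head = head)
  }
  res
}

zero_grads <- function(weights) {
  g <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  g
}

# L1 reconstruction loss and full analytic gradient for one (noisy, ref,
# clean) triple. Returns list(loss, grads).
npd_loss_grad <- function(weights, cfg, noisy, reference, clean) {
  fwd <- npd_forward(weights, cfg, noisy, reference, want_cache = TRUE)
  cc <- fwd$cache
  target <- as_samples(clean)
  L <- cc$L
  diff <- fwd$out - target
  loss <- mean(abs(diff))
  dout <- sign(diff) / L
  grads <- npd_backward(dout, weights, cfg, cc)
  list(loss = loss, grads = grads, out = fwd$out)
}

npd_backward <- function(dout, weights, cfg, cc) {
  k <- cfg$kernel_size
  p <- cfg$patch_size; st <- cfg$patch_stride
  L <- cc$L; C <- cc$C
  grads <- zero_grads(weights)
  head <- cc$head

  # clamp + residual head
  dpre <- dout * (head$pre > -1 & head$pre < 1)
  dd2 <- matrix(dpre, ncol = 1L)
  bw2 <- conv1d_backward(dd2, head$d2_Xu, weights$dec2$W, k, L, C)
  grads$dec2$W <- grads$dec2$W + bw2$dW; grads$dec2$b <- grads$dec2$b + bw2$db
  da1 <- bw2$dx
  dz1 <- relu_backward(da1, head$z1)
  bw1 <- conv1d_backward(dz1, head$d1_Xu, weights$dec1$W, k, L, C)
  grads$dec1$W <- grads$dec1$W + bw1$dW; grads$dec1$b <- grads$dec1$b + bw1$db
  dF2 <- bw1$dx

  # F' = F + G * S
  dF <- dF2
  dG <- dF2 * cc$S_pos
  dS_pos <- rowSums(dF2 * head$G)
  bwf <- conv1d_backward(dG, head$Gin_Xu, weights$fuse$W, k, L, 2L * C)
  grads$fuse$W <- grads$fuse$W + bwf$dW; grads$fuse$b <- grads$fuse$b + bwf$db
  dF <- dF + bwf$dx[, seq_len(C), drop = FALSE]
  dT <- bwf$dx[, C + seq_len(C), drop = FALSE]

  # backbone
  sb <- stack_backward(dF, weights, cfg, cc$fb$cache, "bb", grads)
  grads <- sb$grads

  # texture transfer path: T = fold(Vp[H, ])
  n_pat <- length(cc$H)
  dTp_g <- fold_patches_backward(dT, p, st, n_pat)
  dVp <- zeros(nrow(cc$Vp), ncol(cc$Vp))
  agg <- rowsum(dTp_g, group = cc$H)
  dVp[as.integer(rownames(agg)), ] <- agg
  dV <- unfold_patches_adjoint(dVp, p, st, L, C)

  # soft attention path: S[i] = <Qn_i, Kn_H[i]>
  dS <- rowSums(fold_patches_backward(matrix(dS_pos, ncol = 1L), p, st, n_pat))
  dQn <- cc$kn$N[cc$H, , drop = FALSE] * dS
  dKn <- zeros(nrow(cc$Kp), ncol(cc$Kp))
  aggk <- rowsum(cc$qn$N * dS, group = cc$H)
  dKn[as.integer(rownames(aggk)), ] <- aggk
  dQp <- row_normalize_backward(dQn, cc$qn$N, cc$qn$nrm)
  dKp <- row_normalize_backward(dKn, cc$kn$N, cc$kn$nrm)
  dQ <- unfold_patches_adjoint(dQp, p, st, L, C)
  dK <- unfold_patches_adjoint(dKp, p, st, L, C)

  # shared encoder: accumulate over the three applications
  grads <- stack_backward(dQ, weights, cfg, cc$fq$cache, "enc", grads)$grads
  grads <- stack_backward(dK, weights, cfg, cc$fk$cache, "enc", grads)$grads
  grads <- stack_backward(dV, weights, cfg, cc$fv$cache, "enc", grads)$grads
  grads
}

#' Denoise a segment with a trained model
#'
#' Deterministic forward pass. The reference must be a clean segment of the
#' training geometry (same length), drawn from the reference pool -- never
#' the ground truth of the corrupted segment.
#'
#' @param checkpoint An `npd_checkpoint` from [npd_train()] (or a bare
#'   `npd_weights` list plus `cfg`).
#' @param noisy A signed-unit [ppg_segment()] or numeric vector.
#' @param reference A signed-unit [ppg_segment()] or numeric vector of the
#'   same length.
#' @param cfg Required only when `checkpoint` is a bare weight list.
#' @return Same type as `noisy`.
#' @export
npd_denoise <- function(checkpoint, noisy, reference, cfg = NULL) {
  if (inherits(checkpoint, "npd_checkpoint")) {
    cfg <- checkpoint$model_cfg
    weights <- checkpoint$weights
  } else {
    if (is.null(cfg)) stop_param("cfg required with bare weights")
    weights <- checkpoint
  }
  x <- as_samples(noisy); r <- as_samples(reference)
  if (length(x) != length(r)) stop_param("geometry mismatch: noisy and reference lengths differ")
  y <- npd_forward(weights, cfg, x, r)$out
  if (inherits(noisy, "ppg_segment")) {
    ppg_segment(y, noisy$fs, noisy$duration, "signed_unit", noisy$origin)
  } else {
    y
  }
}
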