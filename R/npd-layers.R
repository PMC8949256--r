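# Differentiable building blocks for the 1D texture-transformer denoiser.
# Feature maps are L x C matrices (positions x channels). Every forward
# primitive has a matching analytic adjoint used by the training loop; no
# autodiff framework is involved.

zeros <- function(r, c) matrix(0, r, c)

# --- 1D convolution (zero padding, odd kernel, stride 1) -------------------

# Unfold x (L x Cin) into the L x (k*Cin) patch matrix of a same-padded
# convolution; block j holds the channels of tap j.
unfold_conv <- function(x, k) {
  L <- nrow(x); C <- ncol(x); h <- (k - 1L) %/% 2L
  xp <- rbind(zeros(h, C), x, zeros(h, C))
  do.call(cbind, lapply(seq_len(k), function(j) xp[j:(j + L - 1L), , drop = FALSE]))
}

# Adjoint of unfold_conv: scatter-add tap blocks back to positions.
unfold_conv_adjoint <- function(dXu, k, L, C) {
  h <- (k - 1L) %/% 2L
  dxp <- zeros(L + 2L * h, C)
  for (j in seq_len(k)) {
    block <- dXu[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    rows <- j:(j + L - 1L)
    dxp[rows, ] <- dxp[rows, ] + block
  }
  dxp[(h + 1L):(h + L), , drop = FALSE]
}

conv1d_forward <- function(x, W, b, k) {
  Xu <- unfold_conv(x, k)
  y <- Xu %*% W
  y <- sweep(y, 2L, b, `+`)
  list(y = y, Xu = Xu)
}

conv1d_backward <- function(dy, cache_Xu, W, k, L, Cin) {
  dW <- crossprod(cache_Xu, dy)
  db <- colSums(dy)
  dXu <- dy %*% t(W)
  dx <- unfold_conv_adjoint(dXu, k, L, Cin)
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dy, x) dy * (x > 0)

# --- patch unfold / overlap fold for attention ------------------------------

patch_positions <- function(L, p, stride) {
  if (p > L) stop_param("patch longer than the feature length")
  seq.int(1L, L - p + 1L, by = stride)
}

#' Unfold a feature map into overlapping patches
#'
#' Rows of the result are flattened windows of `patch_size` consecutive
#' positions (all channels); block `j` of the columns holds the channels of
#' in-patch offset `j`.
#'
#' @param X Feature matrix (positions x channels); a plain numeric vector
#'   is treated as a single channel.
#' @param patch_size Patch length in positions.
#' @param patch_stride Stride between patch starts (default 1).
#' @return Matrix of `n_patches x (patch_size * channels)`.
#' @export
unfold_patches <- function(X, patch_size, patch_stride = 1L) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  pos <- patch_positions(nrow(X), patch_size, patch_stride)
  do.call(cbind, lapply(seq_len(patch_size) - 1L, function(j) {
    X[pos + j, , drop = FALSE]
  }))
}

#' Fold patch rows back to a per-position feature map
#'
#' Adjoint-with-averaging of [unfold_patches()]: each output position is
#' the average of the contributions of every patch covering it.
#'
#' @param P Patch matrix (`n_patches x (patch_size * channels)`).
#' @param patch_size Patch length in positions.
#' @param patch_stride Stride between patch starts (default 1).
#' @param channels Number of feature channels encoded in `P`.
#' @return Matrix of `(n_patches - 1) * patch_stride + patch_size` rows by
#'   `channels` columns.
#' @export
fold_patches <- function(P, patch_size, patch_stride = 1L, channels = ncol(P) %/% patch_size) {
  n <- nrow(P)
  L <- (n - 1L) * patch_stride + patch_size
  pos <- seq.int(1L, by = patch_stride, length.out = n)
  acc <- zeros(L, channels)
  count <- numeric(L)
  for (j in seq_len(patch_size) - 1L) {
    block <- P[, (j * channels + 1L):((j + 1L) * channels), drop = FALSE]
    rows <- pos + j
    acc[rows, ] <- acc[rows, ] + block
    count[rows] <- count[rows] + 1
  }
  acc / count
}

# Backward of fold_patches: route per-position gradients back to patches,
# dividing by the overlap count.
fold_patches_backward <- function(dY, patch_size, patch_stride, n_patches) {
  channels <- ncol(dY)
  pos <- seq.int(1L, by = patch_stride, length.out = n_patches)
  L <- nrow(dY)
  count <- numeric(L)
  for (j in seq_len(patch_size) - 1L) count[pos + j] <- count[pos + j] + 1
  dYn <- dY / count
  do.call(cbind, lapply(seq_len(patch_size) - 1L, function(j) {
    dYn[pos + j, , drop = FALSE]
  }))
}

# Adjoint of unfold_patches (scatter-add, no averaging) -- used to push
# patch gradients back into the feature map.
unfold_patches_adjoint <- function(dP, patch_size, patch_stride, L, channels) {
  pos <- seq.int(1L, by = patch_stride, length.out = nrow(dP))
  dX <- zeros(L, channels)
  for (j in seq_len(patch_size) - 1L) {
    block <- dP[, (j * channels + 1L):((j + 1L) * channels), drop = FALSE]
    dX[pos + j, ] <- dX[pos + j, ] + block
  }
  dX
}

# --- row normalization ------------------------------------------------------

row_normalize <- function(P) {
  nrm <- sqrt(rowSums(P^2))
  safe <- pmax(nrm, .Machine$double.eps)
  list(N = P / safe, nrm = safe)
}

row_normalize_backward <- function(dN, N, nrm) {
  (dN - N * rowSums(N * dN)) / nrm
}

# --- relevance embedding and attention --------------------------------------

#' Relevance embedding between query and key features
#'
#' Unfolds `Q` and `K` into overlapping patches, L2-normalizes each patch,
#' and returns the matrix of inner products: entry `(i, j)` is the cosine
#' similarity between query patch `i` and key patch `j`, in \eqn{[-1, 1]}.
#'
#' @param Q,K Feature matrices (positions x channels) from the same encoder.
#' @param patch_size Patch length in positions.
#' @param patch_stride Stride between patch starts (default 1).
#' @return `n_q_patches x n_k_patches` relevance matrix.
#' @export
relevance_embedding <- function(Q, K, patch_size, patch_stride = 1L) {
  Qn <- row_normalize(unfold_patches(Q, patch_size, patch_stride))$N
  Kn <- row_normalize(unfold_patches(K, patch_size, patch_stride))$N
  Qn %*% t(Kn)
}

#' Hard and soft attention maps from a relevance matrix
#'
#' Per query row `i`, the hard map `H[i]` is the index of the most relevant
#' key patch (ties broken toward the lowest index) and the soft map `S[i]`
#' is its relevance score.
#'
#' @param rel Relevance matrix (finite, non-empty).
#' @return List with integer vector `H` and numeric vector `S`.
#' @export
hard_soft_attention <- function(rel) {
  if (!is.matrix(rel) || nrow(rel) == 0L || ncol(rel) == 0L) {
    stop_param("rel must be a non-empty matrix")
  }
  if (!all(is.finite(rel))) stop_param("rel must be finite")
  H <- max.col(rel, ties.method = "first")
  S <- rel[cbind(seq_len(nrow(rel)), H)]
  list(H = H, S = S)
}

#' Transfer reference texture patches selected by hard attention
#'
#' Gathers, for each query patch position, the `V` patch indexed by `H`,
#' and folds the gathered patches back to a per-position feature map by
#' overlap averaging.
#'
#' @param V Reference (value) feature matrix (positions x channels).
#' @param H Integer vector of hard-attention indices into the patches of `V`.
#' @param patch_size Patch length in positions.
#' @param patch_stride Stride between patch starts (default 1).
#' @return Feature matrix aligned to the query geometry
#'   (`(length(H) - 1) * patch_stride + patch_size` positions).
#' @export
transfer_textures <- function(V, H, patch_size, patch_stride = 1L) {
  if (is.vector(V)) V <- matrix(V, ncol = 1L)
  Vp <- unfold_patches(V, patch_size, patch_stride)
  if (any(H < 1L) || any(H > nrow(Vp))) stop_param("H index out of range")
  fold_patches(Vp[H, , drop = FALSE], patch_size, patch_stride, ncol(V))
}
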