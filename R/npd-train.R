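# Training loop (Adam on the L1 reconstruction objective) and checkpoints.

#' Training configuration
#'
#' @param epochs Number of passes over the dataset (>= 1).
#' @param batch_size Pairs per gradient step (>= 1).
#' @param learning_rate Adam step size (> 0), default 2e-3.
#' @param loss Only `"l1"` (mean absolute reconstruction error) is provided.
#' @param seed RNG seed for shuffling (weight init is seeded by the model
#'   config).
#' @param device Only `"cpu"`.
#' @return An object of class `npd_train_config`.
#' @export
npd_train_config <- function(epochs = 30L, batch_size = 8L, learning_rate = 2e-3,
                             loss = "l1", seed = 1L, device = "cpu") {
  loss <- match.arg(loss, "l1")
  device <- match.arg(device, "cpu")
  if (epochs < 1) stop_param("epochs must be >= 1")
  if (batch_size < 1) stop_param("batch_size must be >= 1")
  if (learning_rate <= 0) stop_param("learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed), device = device),
            class = "npd_train_config")
}

adam_state <- function(weights) {
  list(m = zero_grads(weights), v = zero_grads(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      state$m[[nm]][[part]] <- beta1 * state$m[[nm]][[part]] + (1 - beta1) * g
      state$v[[nm]][[part]] <- beta2 * state$v[[nm]][[part]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[part]] / bc1
      vhat <- state$v[[nm]][[part]] / bc2
      weights[[nm]][[part]] <- weights[[nm]][[part]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, state = state)
}

#' Train the neural denoiser
#'
#' Minimizes the mean absolute error between the restored and clean
#' segments by Adam, with analytic gradients. Each training pair is a
#' `corrupted_pair` plus a clean reference segment drawn from a separate
#' reference pool (`references[[((i - 1) %% n_ref) + 1]]` for pair `i`);
#' the reference is never the pair's own ground truth. Fully deterministic
#' given the model and training seeds.
#'
#' @param pairs List of `corrupted_pair` objects (non-empty, equal lengths).
#' @param references List of clean signed-unit segments of the same length.
#' @param model_cfg An [npd_config()].
#' @param train_cfg An [npd_train_config()].
#' @param verbose Print per-epoch loss.
#' @return An `npd_checkpoint`: list with `weights`, `model_cfg`,
#'   `train_cfg`, `loss_history` (mean per-epoch training loss) and
#'   `n_params`.
#' @export
npd_train <- function(pairs, references, model_cfg = npd_config(),
                      train_cfg = npd_train_config(), verbose = FALSE) {
  if (length(pairs) == 0) stop_param("empty training dataset")
  if (length(references) == 0) stop_param("empty reference pool")
  lens <- vapply(pairs, function(p) length(p$noisy$samples), numeric(1))
  if (length(unique(lens)) != 1L) stop_param("all segments must have the same length")
  weights <- npd_init(model_cfg)
  state <- adam_state(weights)
  n <- length(pairs)
  nr <- length(references)
  ref_for <- function(i) as_samples(references[[((i - 1L) %% nr) + 1L]])
  loss_history <- numeric(train_cfg$epochs)
  for (epoch in seq_len(train_cfg$epochs)) {
    order <- local_seed(derive_seed(train_cfg$seed, epoch), sample.int(n))
    batches <- split(order, ceiling(seq_along(order) / train_cfg$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      acc <- NULL
      bl <- 0
      for (i in batch) {
        lg <- npd_loss_grad(weights, model_cfg,
                            pairs[[i]]$noisy$samples, ref_for(i),
                            pairs[[i]]$clean$samples)
        bl <- bl + lg$loss
        acc <- if (is.null(acc)) lg$grads else {
          for (nm in names(acc)) {
            acc[[nm]]$W <- acc[[nm]]$W + lg$grads[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + lg$grads[[nm]]$b
          }
          acc
        }
      }
      nb <- length(batch)
      for (nm in names(acc)) {
        acc[[nm]]$W <- acc[[nm]]$W / nb
        acc[[nm]]$b <- acc[[nm]]$b / nb
      }
      st <- adam_step(weights, acc, state, train_cfg$learning_rate)
      weights <- st$weights
      state <- st$state
      epoch_loss <- epoch_loss + bl
    }
    loss_history[epoch] <- epoch_loss / n
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.6f", epoch, train_cfg$epochs,
                      loss_history[epoch]))
    }
  }
  structure(list(weights = weights, model_cfg = model_cfg,
                 train_cfg = train_cfg, loss_history = loss_history,
                 n_params = npd_n_params(weights)),
            class = "npd_checkpoint")
}

#' @export
print.npd_checkpoint <- function(x, ...) {
  cat(sprintf("<npd_checkpoint> %d params, %d epochs, final loss %.6f\n",
              x$n_params, length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Single-file serialized archive embedding the weights, both configs and
#' the loss history; reloading reproduces identical forward outputs.
#'
#' @param checkpoint An `npd_checkpoint`.
#' @param path File path.
#' @return `npd_save`: `path`, invisibly. `npd_load`: the checkpoint.
#' @export
npd_save <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname npd_save
#' @export
npd_load <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "npd_checkpoint")) stop_param("not an npd_checkpoint: ", path)
  ck
}
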