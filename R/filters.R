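# Classical comparison denoisers: sliding median, local-statistics Wiener,
# Gaussian smoothing, and the per-noise-kind configuration tables.

seg_in <- function(x) if (inherits(x, "ppg_segment")) x$samples else as.double(x)

seg_out <- function(y, x) {
  if (inherits(x, "ppg_segment")) {
    lim <- if (x$range_tag == "signed_unit") c(-1, 1) else c(0, 1)
    ppg_segment(pmin(pmax(y, lim[1]), lim[2]), x$fs, x$duration, x$range_tag, x$origin)
  } else {
    y
  }
}

pad_edge <- function(v, h) c(rep(v[1], h), v, rep(v[length(v)], h))

#' Sliding-window median filter
#'
#' Window of odd width with edge replication; length preserved.
#'
#' @param x A [ppg_segment()] or numeric vector.
#' @param window Odd window width (>= 1).
#' @return Same type as `x`.
#' @export
median_filter <- function(x, window) {
  if (window %% 2 != 1 || window < 1) stop_param("window must be an odd integer >= 1")
  v <- seg_in(x)
  if (window == 1) return(seg_out(v, x))
  h <- (window - 1L) %/% 2L
  p <- pad_edge(v, h)
  y <- vapply(seq_along(v), function(i) stats::median(p[i:(i + window - 1L)]), numeric(1))
  seg_out(y, x)
}

#' Local-statistics Wiener filter
#'
#' At each position, the local mean `m` and variance `v` are computed over
#' an odd window (edge replication); the noise power `nu` is the mean of
#' the local variances, and the output is
#' `m + max(v - nu, 0) / max(v, nu) * (x - m)` (pass-through where the
#' local variance exceeds the noise floor, flat where it does not).
#'
#' @inheritParams median_filter
#' @return Same type as `x`.
#' @export
wiener_filter <- function(x, window) {
  if (window %% 2 != 1 || window < 1) stop_param("window must be an odd integer >= 1")
  v <- seg_in(x)
  if (window == 1) return(seg_out(v, x))
  h <- (window - 1L) %/% 2L
  p <- pad_edge(v, h)
  k <- rep(1 / window, window)
  m <- stats::filter(p, k, sides = 2)[(h + 1L):(h + length(v))]
  m2 <- stats::filter(p^2, k, sides = 2)[(h + 1L):(h + length(v))]
  lv <- pmax(m2 - m^2, 0)
  nu <- mean(lv)
  gain <- ifelse(pmax(lv, nu) > 0, pmax(lv - nu, 0) / pmax(lv, nu), 0)
  y <- m + gain * (v - m)
  seg_out(as.double(y), x)
}

#' Gaussian smoothing filter
#'
#' Convolution with a normalized discrete Gaussian kernel truncated at
#' `4 * sigma` taps on each side, with edge replication.
#'
#' @param x A [ppg_segment()] or numeric vector.
#' @param sigma Kernel standard deviation in samples (> 0).
#' @return Same type as `x`.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop_param("sigma must be > 0")
  v <- seg_in(x)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k <- k / sum(k)
  p <- pad_edge(v, h)
  y <- stats::filter(p, k, sides = 2)[(h + 1L):(h + length(v))]
  seg_out(as.double(y), x)
}

#' Gaussian smoothing kernel
#'
#' The normalized kernel used by [gaussian_smooth()]; exposed for variance
#' calculations (`sum(k) == 1`, output variance on white noise is
#' `sum(k^2)` times the input variance).
#'
#' @param sigma Kernel standard deviation in samples (> 0).
#' @return Numeric kernel of length `2 * ceiling(4 * sigma) + 1`.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop_param("sigma must be > 0")
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k / sum(k)
}

.best_filters <- list(
  gaussian    = list(filter_kind = "wiener", window = 5L),
  poisson     = list(filter_kind = "median", window = 3L),
  salt_pepper = list(filter_kind = "median", window = 5L),
  speckle     = list(filter_kind = "wiener", window = 3L),
  uniform     = list(filter_kind = "gaussian", sigma = 1)
)

.best_wavelets <- list(
  gaussian    = list(wavelet_name = "dmey", level = 3L),
  poisson     = list(wavelet_name = "db19", level = 3L),
  salt_pepper = list(wavelet_name = "db18", level = 6L),
  speckle     = list(wavelet_name = "db20", level = 3L),
  uniform     = list(wavelet_name = "sym15", level = 9L)
)

#' Reference denoiser configurations per noise kind
#'
#' `best_respective(kind)` returns the conventional best filter for each
#' single-noise kind (Wiener window 5 for Gaussian, median window 3 for
#' Poisson, median window 5 for salt-and-pepper, Wiener window 3 for
#' speckle, Gaussian sigma 1 for uniform). `wavelet_for(kind)` returns the
#' matching wavelet shrinkage configuration (dmey level 3, db19 level 3,
#' db18 level 6, db20 level 3, sym15 level 9 respectively).
#'
#' @param kind One of the five single-noise kinds.
#' @return `best_respective`: a `filter_config` list (`filter_kind` plus
#'   `window` or `sigma`); `wavelet_for`: a [wavelet_config()].
#' @export
best_respective <- function(kind) {
  cfg <- .best_filters[[kind]]
  if (is.null(cfg)) {
    stop_param("no reference filter defined for kind: ", kind)
  }
  structure(cfg, class = "filter_config")
}

#' @rdname best_respective
#' @export
wavelet_for <- function(kind) {
  cfg <- .best_wavelets[[kind]]
  if (is.null(cfg)) {
    stop_param("no reference wavelet defined for kind: ", kind)
  }
  wavelet_config(cfg$wavelet_name, cfg$level)
}

#' Apply a filter configuration
#'
#' Dispatches a `filter_config` from [best_respective()] (or built by hand)
#' to [median_filter()], [wiener_filter()] or [gaussian_smooth()].
#'
#' @param x A [ppg_segment()] or numeric vector.
#' @param cfg A `filter_config`.
#' @return Same type as `x`.
#' @export
apply_filter <- function(x, cfg) {
  switch(cfg$filter_kind,
         median = median_filter(x, cfg$window),
         wiener = wiener_filter(x, cfg$window),
         gaussian = gaussian_smooth(x, cfg$sigma),
         stop_param("unknown filter kind: ", cfg$filter_kind))
}
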