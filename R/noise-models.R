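# Noise models: range maps, the five single-noise generators, noise chains,
# random mixed-noise composition, and motion-artifact synthesis/injection.
#
# All generators operate in unit space [0, 1]: a signed-unit segment is
# mapped by the fixed affine x -> (x + 1)/2, corrupted, clipped to [0, 1],
# and mapped back by x -> 2x - 1. Clean and noisy segments therefore stay
# comparable sample by sample.

.noise_kinds <- c("gaussian", "poisson", "salt_pepper", "speckle", "uniform")

.default_noise_params <- list(
  gaussian    = list(sigma = 0.01),
  speckle     = list(sigma = 0.01),
  salt_pepper = list(rate = 0.05),
  uniform     = list(lo = 0, hi = 0.1),
  poisson     = list(scale = 255),
  motion      = list(ratio = 0.3, start_index = 1L)
)

#' Map a signed-unit segment to unit range and back
#'
#' Fixed affine maps (not per-segment min-max): `to_unit` applies
#' \eqn{x \mapsto (x+1)/2}, `from_unit` applies \eqn{x \mapsto 2x-1}. They
#' are mutually inverse and order preserving.
#'
#' @param x A [ppg_segment()] with the matching `range_tag`.
#' @return A [ppg_segment()] in the other range.
#' @export
to_unit <- function(x) {
  if (!inherits(x, "ppg_segment") || x$range_tag != "signed_unit") {
    stop_param("to_unit expects a signed_unit ppg_segment")
  }
  ppg_segment((x$samples + 1) / 2, x$fs, x$duration, "unit", x$origin)
}

#' @rdname to_unit
#' @export
from_unit <- function(x) {
  if (!inherits(x, "ppg_segment") || x$range_tag != "unit") {
    stop_param("from_unit expects a unit ppg_segment")
  }
  ppg_segment(2 * x$samples - 1, x$fs, x$duration, "signed_unit", x$origin)
}

# Internal: run one noise generator on a bare numeric vector in [0,1].
apply_noise_vec <- function(x, kind, params, seed, fs = 50) {
  n <- length(x)
  local_seed(seed, switch(
    kind,
    gaussian = {
      sigma <- params$sigma
      if (sigma < 0) stop_param("gaussian sigma must be >= 0")
      if (sigma == 0) x else clip01(x + stats::rnorm(n, 0, sigma))
    },
    speckle = {
      sigma <- params$sigma
      if (sigma < 0) stop_param("speckle sigma must be >= 0")
      if (sigma == 0) x else clip01(x * (1 + stats::rnorm(n, 0, sigma)))
    },
    poisson = {
      scale <- params$scale
      if (scale <= 0) stop_param("poisson scale must be > 0")
      clip01(stats::rpois(n, x * scale) / scale)
    },
    salt_pepper = {
      rate <- params$rate
      if (rate < 0 || rate > 1) stop_param("salt_pepper rate must be in [0, 1]")
      m <- round(rate * n)
      if (m > 0) {
        pos <- sample.int(n, m)
        x[pos] <- sample(c(0, 1), m, replace = TRUE)
      }
      x
    },
    uniform = {
      lo <- params$lo; hi <- params$hi
      if (lo > hi) stop_param("uniform requires lo <= hi")
      if (lo == hi && lo == 0) x else clip01(x + stats::runif(n, lo, hi))
    },
    motion = {
      ratio <- params$ratio
      start <- if (is.null(params$start_index)) 1L else as.integer(params$start_index)
      if (ratio <= 0 || ratio > 1) stop_param("motion ratio must be in (0, 1]")
      w <- round(ratio * n)
      if (start < 1L || start + w - 1L > n) stop_param("motion window out of bounds")
      art <- synthesize_motion_artifact(w, fs, seed = derive_seed(seed, 1L))
      idx <- start:(start + w - 1L)
      # signed-unit artifact amplitude halves under the unit-space affine map
      x[idx] <- clip01(x[idx] + art$samples / 2)
      x
    },
    stop_param("unknown noise kind: ", kind)
  ))
}

#' Describe one noise process
#'
#' @param kind One of `"gaussian"`, `"poisson"`, `"salt_pepper"`,
#'   `"speckle"`, `"uniform"`, `"motion"`.
#' @param ... Kind-specific parameters overriding the defaults
#'   (`gaussian$sigma = 0.01`, `speckle$sigma = 0.01`,
#'   `salt_pepper$rate = 0.05`, `uniform$lo = 0, hi = 0.1`,
#'   `poisson$scale = 255`, `motion$ratio = 0.3, start_index = 1`).
#' @param seed RNG seed for this stage (`NA` to derive from the chain's
#'   master seed).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind, ..., seed = NA_integer_) {
  kind <- match.arg(kind, names(.default_noise_params))
  params <- utils::modifyList(.default_noise_params[[kind]], list(...))
  if (!is.null(params$rate) && (params$rate < 0 || params$rate > 1)) {
    stop_param("rate must be in [0, 1]")
  }
  if (!is.null(params$sigma) && params$sigma < 0) stop_param("sigma must be >= 0")
  if (!is.null(params$scale) && params$scale <= 0) stop_param("scale must be > 0")
  if (!is.null(params$lo) && params$lo > params$hi) stop_param("lo must be <= hi")
  if (kind == "motion" && (params$ratio <= 0 || params$ratio > 1)) {
    stop_param("ratio must be in (0, 1]")
  }
  structure(list(kind = kind, params = params, seed = seed), class = "noise_spec")
}

#' Compose noise processes into an ordered chain
#'
#' @param ... `noise_spec` objects, applied in order (1 to 6 stages; kinds
#'   within a chain must be distinct).
#' @param master_seed Master RNG seed; stage `i` without an explicit seed
#'   uses `derive_seed(master_seed, i)`.
#' @return An object of class `noise_chain`.
#' @export
noise_chain <- function(..., master_seed = 1L) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !inherits(specs[[1]], "noise_spec")) {
    specs <- specs[[1]]
  }
  if (length(specs) < 1L || length(specs) > 6L) {
    stop_param("a noise_chain must have 1 to 6 stages")
  }
  if (!all(vapply(specs, inherits, logical(1), "noise_spec"))) {
    stop_param("all stages must be noise_spec objects")
  }
  kinds <- vapply(specs, `[[`, character(1), "kind")
  if (anyDuplicated(kinds)) stop_param("kinds within a chain must be distinct")
  structure(list(specs = specs, master_seed = as.integer(master_seed)),
            class = "noise_chain")
}

#' @export
print.noise_chain <- function(x, ...) {
  cat(sprintf("<noise_chain> %d stage(s), master_seed=%d\n",
              length(x$specs), x$master_seed))
  for (i in seq_along(x$specs)) {
    sp <- x$specs[[i]]
    cat(sprintf("  %d. %s(%s)%s\n", i, sp$kind,
                paste(names(sp$params), unlist(sp$params), sep = "=", collapse = ", "),
                if (is.na(sp$seed)) "" else sprintf(" seed=%d", sp$seed)))
  }
  invisible(x)
}

# Effective seed of stage i in a chain.
stage_seed <- function(chain, i) {
  s <- chain$specs[[i]]$seed
  if (is.na(s)) derive_seed(chain$master_seed, i) else as.integer(s)
}

#' Corrupt a clean segment with a noise chain
#'
#' Pipeline: [to_unit()] -> apply each stage in order (each clipped to
#' \eqn{[0,1]}) -> [from_unit()]. Fully deterministic given the chain's
#' seeds; the returned pair carries the chain so the noisy segment can be
#' reproduced from the clean one at any time.
#'
#' @param clean A signed-unit [ppg_segment()].
#' @param chain A [noise_chain()].
#' @return A `corrupted_pair`: list with `clean`, `noisy` (both signed-unit
#'   segments) and `chain`.
#' @export
corrupt <- function(clean, chain) {
  if (!inherits(chain, "noise_chain")) stop_param("chain must be a noise_chain")
  u <- to_unit(clean)
  x <- u$samples
  for (i in seq_along(chain$specs)) {
    sp <- chain$specs[[i]]
    x <- apply_noise_vec(x, sp$kind, sp$params, stage_seed(chain, i), fs = clean$fs)
  }
  # a chain that changed nothing returns the clean samples bit for bit,
  # so the zero-noise condition reports an exactly zero error
  noisy <- if (identical(x, u$samples)) {
    clean
  } else {
    from_unit(ppg_segment(clip01(x), u$fs, u$duration, "unit", u$origin))
  }
  structure(list(clean = clean, noisy = noisy, chain = chain),
            class = "corrupted_pair")
}

#' Draw a random mixed-noise chain
#'
#' `k` distinct kinds are drawn uniformly without replacement from the five
#' single-noise kinds, in random order, each with its default parameters
#' and a per-stage sub-seed derived from `master_seed`.
#'
#' @param k Number of mixed noises (2--5).
#' @param master_seed Master RNG seed.
#' @return A [noise_chain()].
#' @export
random_mixed_chain <- function(k, master_seed = 1L) {
  if (k < 2 || k > 5) stop_param("k must be in 2..5")
  kinds <- local_seed(derive_seed(master_seed, 0L),
                      sample(.noise_kinds, k, replace = FALSE))
  specs <- lapply(kinds, function(kind) noise_spec(kind))
  noise_chain(specs, master_seed = master_seed)
}

#' Synthesize a band-limited motion artifact
#'
#' Stand-in for wrist-worn accelerometer-era motion noise: a Gaussian
#' random walk band-pass filtered to the 0.5--5 Hz band typical of walking,
#' running and cycling, then scaled to peak amplitude 1 so the artifact is
#' comparable to a normalized clean segment.
#'
#' @param n_samples Number of samples (>= 1).
#' @param fs Sampling rate in Hz.
#' @param seed RNG seed.
#' @return A [ppg_signal()] with values in \eqn{[-1, 1]}.
#' @export
synthesize_motion_artifact <- function(n_samples, fs, seed = 1L) {
  if (n_samples < 1) stop_param("n_samples must be >= 1")
  nyq <- fs / 2
  hi <- min(5, 0.9 * nyq)
  lo <- min(0.5, hi / 4)
  local_seed(seed, {
    # pad so filtfilt transients do not dominate short windows
    pad <- max(64L, ceiling(2 * fs))
    w <- cumsum(stats::rnorm(n_samples + 2L * pad))
    bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
    y <- signal::filtfilt(bf, w)
    y <- y[(pad + 1L):(pad + n_samples)]
    peak <- max(abs(y))
    if (peak > 0) y <- y / peak
    ppg_signal(y, fs, source_id = sprintf("motion(seed=%d)", seed))
  })
}

#' Inject a motion artifact into part of a clean segment
#'
#' Inside the window `[start_index, start_index + round(ratio * L) - 1]`
#' the artifact is added to the clean signal in unit space and clipped,
#' following the same range round-trip as [corrupt()]; samples outside the
#' window are untouched.
#'
#' @param clean A signed-unit [ppg_segment()].
#' @param artifact A signed-unit [ppg_segment()] or [ppg_signal()] at least
#'   as long as the window.
#' @param ratio Fraction of the segment length covered by the artifact
#'   (0 < ratio <= 1).
#' @param start_index 1-based window start.
#' @return A `corrupted_pair`.
#' @export
inject_motion_artifact <- function(clean, artifact, ratio, start_index = 1L) {
  L <- length(clean$samples)
  if (ratio <= 0 || ratio > 1) stop_param("ratio must be in (0, 1]")
  w <- round(ratio * L)
  start_index <- as.integer(start_index)
  if (start_index < 1L || start_index + w - 1L > L) {
    stop_param("motion window out of bounds")
  }
  a <- artifact$samples
  if (length(a) < w) stop_param("artifact shorter than the window")
  u <- to_unit(clean)
  x <- u$samples
  idx <- start_index:(start_index + w - 1L)
  x[idx] <- clip01(x[idx] + a[seq_len(w)] / 2)
  noisy <- if (identical(x, u$samples)) {
    clean
  } else {
    from_unit(ppg_segment(x, u$fs, u$duration, "unit", u$origin))
  }
  chain <- noise_chain(noise_spec("motion", ratio = ratio, start_index = start_index),
                       master_seed = 0L)
  structure(list(clean = clean, noisy = noisy, chain = chain),
            class = "corrupted_pair")
}

#' Serialize and restore a noise chain
#'
#' JSON with one record per stage (kind, parameters, explicit or derived
#' seed); reloading reproduces the identical noisy segment.
#'
#' @param chain A [noise_chain()].
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `chain_to_json`: JSON string or `path`; `chain_from_json`: a
#'   [noise_chain()].
#' @export
chain_to_json <- function(chain, path = NULL) {
  obj <- list(
    master_seed = chain$master_seed,
    specs = lapply(chain$specs, function(sp) {
      list(kind = sp$kind, params = sp$params,
           seed = if (is.na(sp$seed)) NULL else sp$seed)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname chain_to_json
#' @param json JSON string or file path produced by [chain_to_json()].
#' @export
chain_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "")
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  specs <- lapply(obj$specs, function(sp) {
    do.call(noise_spec, c(list(kind = sp$kind),
                          sp$params,
                          list(seed = if (is.null(sp$seed)) NA_integer_ else as.integer(sp$seed))))
  })
  noise_chain(specs, master_seed = as.integer(obj$master_seed))
}

#' Single-noise generators on unit-range segments
#'
#' Each takes a unit-range [ppg_segment()], applies one noise process and
#' clips the result to \eqn{[0, 1]}:
#' \describe{
#'   \item{`add_gaussian`}{additive i.i.d. \eqn{N(0, \sigma^2)}.}
#'   \item{`add_poisson`}{`y = Poisson(x * scale) / scale`, the shot-noise
#'     model at `scale` counts per unit intensity.}
#'   \item{`add_salt_pepper`}{exactly `round(rate * L)` positions, chosen
#'     without replacement, are set to 0 or 1 with equal probability.}
#'   \item{`add_speckle`}{multiplicative `y = x * (1 + n)`,
#'     \eqn{n \sim N(0, \sigma^2)}.}
#'   \item{`add_uniform`}{additive i.i.d. `Uniform(lo, hi)`.}
#' }
#'
#' @param x A unit-range [ppg_segment()].
#' @param sigma,scale,rate,lo,hi Noise parameters (see above).
#' @param seed RNG seed.
#' @return A unit-range [ppg_segment()].
#' @name single_noise
NULL

add_noise_segment <- function(x, kind, params, seed) {
  if (!inherits(x, "ppg_segment") || x$range_tag != "unit") {
    stop_param(kind, " noise expects a unit-range ppg_segment")
  }
  y <- apply_noise_vec(x$samples, kind, params, seed, fs = x$fs)
  ppg_segment(y, x$fs, x$duration, "unit", x$origin)
}

#' @rdname single_noise
#' @export
add_gaussian <- function(x, sigma = 0.01, seed = 1L) {
  add_noise_segment(x, "gaussian", list(sigma = sigma), seed)
}

#' @rdname single_noise
#' @export
add_poisson <- function(x, scale = 255, seed = 1L) {
  add_noise_segment(x, "poisson", list(scale = scale), seed)
}

#' @rdname single_noise
#' @export
add_salt_pepper <- function(x, rate = 0.05, seed = 1L) {
  add_noise_segment(x, "salt_pepper", list(rate = rate), seed)
}

#' @rdname single_noise
#' @export
add_speckle <- function(x, sigma = 0.01, seed = 1L) {
  add_noise_segment(x, "speckle", list(sigma = sigma), seed)
}

#' @rdname single_noise
#' @export
add_uniform <- function(x, lo = 0, hi = 0.1, seed = 1L) {
  add_noise_segment(x, "uniform", list(lo = lo, hi = hi), seed)
}
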