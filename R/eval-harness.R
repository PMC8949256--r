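# Evaluation: MSE / PSNR, paired comparison, and the experiment runner that
# produces per-segment records and condition x method summary tables.

as_samples <- function(x) if (inherits(x, "ppg_segment")) x$samples else as.double(x)

#' Mean squared error between two segments
#'
#' @param a,b Segments or numeric vectors of equal length.
#' @return Mean of squared sample differences.
#' @export
mse <- function(a, b) {
  a <- as_samples(a); b <- as_samples(b)
  if (length(a) != length(b)) stop_param("mse: length mismatch")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `psnr = -10 * log10(mse)` for signals normalized so the peak value is 1.
#' A zero MSE (identical inputs) returns `Inf`; aggregate statistics
#' exclude infinite values (with a warning at aggregation time).
#'
#' @param a,b Segments or numeric vectors of equal length.
#' @param mse_value Alternatively, a precomputed MSE (then `a`/`b` are ignored).
#' @return PSNR in dB.
#' @export
psnr <- function(a = NULL, b = NULL, mse_value = NULL) {
  m <- if (!is.null(mse_value)) mse_value else mse(a, b)
  if (m < 0) stop_param("mse must be >= 0")
  if (m == 0) return(Inf)
  -10 * log10(m)
}

#' Paired t-test on per-segment scores
#'
#' Two-sided paired t-test on the per-segment differences, via
#' [stats::t.test()]. Degenerate zero-variance differences are handled
#' explicitly: all-zero differences give `t = 0, p = 1`; constant non-zero
#' differences give `t = +/-Inf, p = 0`.
#'
#' @param score_a,score_b Equal-length numeric vectors (n >= 2), paired by
#'   segment.
#' @param labels Character vector of two comparison labels.
#' @return List with `t`, `p`, `df`, `n`, `mean_diff`, `labels`.
#' @export
paired_ttest <- function(score_a, score_b, labels = c("a", "b")) {
  if (length(score_a) != length(score_b)) stop_param("paired_ttest: length mismatch")
  n <- length(score_a)
  if (n < 2) stop_param("paired_ttest requires n >= 2")
  d <- score_a - score_b
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = n - 1L, n = n, mean_diff = md, labels = labels))
  }
  tt <- stats::t.test(score_a, score_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       n = n, mean_diff = unname(tt$estimate), labels = labels)
}

# Built-in method dispatch. A method is either one of the built-in names or
# a function(noisy_segment, kind) -> denoised segment.
apply_method <- function(method, noisy, kind) {
  if (is.function(method)) return(method(noisy, kind))
  switch(method,
         none = noisy,
         wavelet = wavelet_denoise(noisy, wavelet_for(kind)),
         best_respective = apply_filter(noisy, best_respective(kind)),
         stop_param("unknown method: ", method))
}

#' Experiment configuration for the evaluation runner
#'
#' @param conditions Named list; each element is either a [noise_chain()]
#'   factory `function(seed)` or a list with `kind` (single-noise name) to
#'   corrupt with that kind's defaults.
#' @param methods Character vector of built-in method names (`"none"`,
#'   `"wavelet"`, `"best_respective"`) and/or named list entries that are
#'   `function(noisy_segment, kind)` closures (e.g. a trained denoiser).
#' @param n_segments Number of synthetic segments per condition.
#' @param fs Sampling rate in Hz (default 50).
#' @param duration_s Segment duration in seconds (default 6).
#' @param synth_params A [ppg_synth_params()] prototype; per-segment seeds
#'   are derived from `master_seed`.
#' @param master_seed Master RNG seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(conditions, methods = c("none"),
                              n_segments = 50, fs = 50, duration_s = 6,
                              synth_params = ppg_synth_params(),
                              master_seed = 1L) {
  if (length(conditions) == 0 || is.null(names(conditions)) ||
      any(!nzchar(names(conditions)))) {
    stop_param("conditions must be a non-empty named list")
  }
  if (is.character(methods)) methods <- stats::setNames(as.list(methods), methods)
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    stop_param("methods must be named")
  }
  structure(list(conditions = conditions, methods = methods,
                 n_segments = as.integer(n_segments), fs = fs,
                 duration_s = duration_s, synth_params = synth_params,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

# One clean synthetic segment per (master_seed, index).
make_clean_segment <- function(cfg, i) {
  sp <- cfg$synth_params
  sp$seed <- derive_seed(cfg$master_seed, i)
  hr <- 55 + (derive_seed(cfg$master_seed, 100000L + i) %% 46L)  # 55..100 bpm
  sp$heart_rate_bpm <- hr
  sig <- synthesize_ppg(sp, n_seconds = cfg$duration_s, fs = cfg$fs)
  win <- segment_signal(sig, cfg$duration_s)[[1]]
  normalize_segment(win, "signed_unit")
}

condition_chain <- function(cond, cond_name, seed) {
  if (is.function(cond)) return(cond(seed))
  if (!is.null(cond$kind)) {
    return(noise_chain(noise_spec(cond$kind), master_seed = seed))
  }
  stop_param("condition '", cond_name, "' must be a chain factory or list(kind=)")
}

condition_kind <- function(cond) {
  if (is.function(cond)) attr(cond, "kind") else cond$kind
}

#' Run a denoising evaluation experiment
#'
#' For each condition: generates `n_segments` clean synthetic segments,
#' corrupts each with the condition's noise chain, applies every method,
#' and records per-segment MSE and PSNR against the clean reference. The
#' `"none"` method scores the noisy signal itself. Fully deterministic
#' given `master_seed`.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory; per-segment records and the summary
#'   are written there as `records.csv` / `summary.csv`.
#' @return List with `records` (data.frame: segment_id, condition, method,
#'   mse, psnr) and `summary` (data.frame: condition, method, n, mean_psnr,
#'   sd_psnr, sem_psnr, mean_mse).
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "experiment_config")) stop_param("cfg must be an experiment_config")
  rows <- list()
  for (cond_name in names(cfg$conditions)) {
    cond <- cfg$conditions[[cond_name]]
    kind <- condition_kind(cond)
    for (i in seq_len(cfg$n_segments)) {
      clean <- make_clean_segment(cfg, i)
      chain <- condition_chain(cond, cond_name,
                               derive_seed(cfg$master_seed, 200000L + i))
      pair <- corrupt(clean, chain)
      for (mname in names(cfg$methods)) {
        den <- apply_method(cfg$methods[[mname]], pair$noisy, kind)
        m <- mse(den, clean)
        rows[[length(rows) + 1L]] <- data.frame(
          segment_id = i, condition = cond_name, method = mname,
          mse = m, psnr = psnr(mse_value = m), stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  summary <- aggregate_records(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  list(records = records, summary = summary)
}

#' Aggregate per-segment records into a summary table
#'
#' Mean/sd/SEM of per-segment PSNRs and mean MSE per (condition, method).
#' Aggregate PSNR is the arithmetic mean of per-segment PSNRs (not the
#' PSNR of the mean MSE); infinite per-segment PSNRs (zero error) are
#' excluded from PSNR aggregates with a warning.
#'
#' @param records Data frame as produced by [run_experiment()].
#' @return Summary data frame.
#' @export
aggregate_records <- function(records) {
  if (any(!is.finite(records$psnr))) {
    warning("excluding ", sum(!is.finite(records$psnr)),
            " infinite PSNR value(s) from PSNR aggregates")
  }
  groups <- split(records, list(records$condition, records$method), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    p <- g$psnr[is.finite(g$psnr)]
    data.frame(condition = g$condition[1], method = g$method[1],
               n = nrow(g),
               mean_psnr = mean(p), sd_psnr = stats::sd(p),
               sem_psnr = stats::sd(p) / sqrt(length(p)),
               mean_mse = mean(g$mse), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$method), ]
}
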