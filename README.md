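# ppgdenoise

Tools for studying the denoising of photoplethysmography (PPG) signals.
PPG — the optical pulse waveform measured by wearables and pulse oximeters —
is corrupted in practice by several statistical noise families at once and,
dominantly, by motion artifacts whose spectrum overlaps the pulse band. This
package is a self-contained bench for that problem, aimed at researchers
comparing restoration methods: it generates realistic synthetic pulse
segments, corrupts them with composable parametric noise, restores them with
classical baselines and with a small reference-guided neural denoiser, and
scores everything with a reproducible evaluation harness.

## The core methods

All processing operates on 6-second segments at 50 Hz (L = 300 samples),
min–max normalized to [-1, 1]. Noise is defined in unit space [0, 1] via the
fixed affine maps x ↦ (x+1)/2 and back.

**Noise model.** Five generators — additive Gaussian N(0, σ²), multiplicative
speckle x(1+n), salt-and-pepper (exactly round(rate·L) samples forced to the
range extremes), additive uniform U(lo, hi), and Poisson x ↦ Pois(x·s)/s —
plus band-limited (0.5–5 Hz) motion artifacts blended into a window covering
a chosen fraction of the segment. Chains compose noise kinds; mixed chains
draw k distinct kinds in random order. Every stage is seeded through a
splitmix-style stream splitter, `derive_seed(master, index)`, so all results
are bitwise reproducible.

**Classical baselines.** Sliding median, local Wiener gain
max(v−ν, 0)/v, normalized Gaussian smoothing, and wavelet soft thresholding
at the universal threshold σ̂·√(2 ln N), σ̂ = MAD(finest detail)/0.6745, with
symmetric-extension DWT over the dmey/db18/db19/db20/sym15 families. Lookup
tables pair each noise family with its best classical responder.

**Reference-guided denoiser (NPD).** A ~5.6k-parameter 1-D texture
transformer: a shared convolutional encoder embeds the noisy input and a
clean reference from a *different* recording; cosine relevance between
unfolded patches drives hard (arg-max) attention that gathers reference
texture patches, a soft score gates their fusion with a convolutional
backbone, and a decoder predicts a residual, trained with Adam on an L1 loss.
Forward and backward passes are analytic, vectorized base R.

**Evaluation.** MSE, PSNR = −10·log₁₀(MSE) (peak 1 after normalization),
paired t-tests with explicit zero-variance policies, and an experiment runner
that crosses noise conditions with methods over synthetic segment grids.

See `vignettes/ppgdenoise-methods.Rmd` for the full model description,
parameter defaults and rationale, and known limitations.

## Worked example

Corrupt one segment with 5 % salt-and-pepper noise, compare the classical
baselines with the neural denoiser trained on 256 synthetic pairs (about
20 s on one CPU):

```r
library(ppgdenoise)

# 1. synthesize a clean 6-s segment at 72 bpm, 50 Hz, normalized to [-1, 1]
sig <- synthesize_ppg(ppg_synth_params(heart_rate_bpm = 72, seed = 11),
                      n_seconds = 6, fs = 50)
clean <- normalize_segment(segment_signal(sig, 6)[[1]], "signed_unit")

# 2. corrupt it with salt-and-pepper noise (5% of samples)
pair <- corrupt(clean, noise_chain(noise_spec("salt_pepper", rate = 0.05),
                                   master_seed = 3))
cat(sprintf("noisy PSNR:   %.2f dB\n", psnr(pair$noisy, pair$clean)))

# 3. classical baselines
med <- apply_filter(pair$noisy, best_respective("salt_pepper"))
wav <- wavelet_denoise(pair$noisy, wavelet_for("salt_pepper"))
cat(sprintf("median w=5:   %.2f dB\n", psnr(med, pair$clean)))
cat(sprintf("wavelet db18: %.2f dB\n", psnr(wav, pair$clean)))

# 4. train the reference-guided denoiser on 256 corrupted pairs
train_pairs <- lapply(1:256, function(i) {
  seg <- normalize_segment(segment_signal(synthesize_ppg(
    ppg_synth_params(heart_rate_bpm = 55 + (i %% 46), seed = derive_seed(20, i)),
    n_seconds = 6, fs = 50), 6)[[1]], "signed_unit")
  corrupt(seg, noise_chain(noise_spec("salt_pepper"),
                           master_seed = derive_seed(21, i)))
})
refs <- lapply(1:16, function(i) {
  normalize_segment(segment_signal(synthesize_ppg(
    ppg_synth_params(heart_rate_bpm = 60 + i, seed = derive_seed(22, i)),
    n_seconds = 6, fs = 50), 6)[[1]], "signed_unit")
})
ck <- npd_train(train_pairs, refs, npd_config(seed = 1),
                npd_train_config(epochs = 8, batch_size = 8,
                                 learning_rate = 3e-3, seed = 2))
den <- npd_denoise(ck, pair$noisy, refs[[1]])
cat(sprintf("NPD (%d params): %.2f dB\n", ck$n_params, psnr(den, pair$clean)))

# 5. paired comparison of the two best methods over 50 fresh segments
scores <- vapply(1:50, function(i) {
  seg <- normalize_segment(segment_signal(synthesize_ppg(
    ppg_synth_params(heart_rate_bpm = 55 + (i %% 46), seed = derive_seed(30, i)),
    n_seconds = 6, fs = 50), 6)[[1]], "signed_unit")
  p <- corrupt(seg, noise_chain(noise_spec("salt_pepper"),
                                master_seed = derive_seed(31, i)))
  c(npd = psnr(npd_denoise(ck, p$noisy, refs[[1 + (i %% 16)]]), p$clean),
    median = psnr(apply_filter(p$noisy, best_respective("salt_pepper")), p$clean))
}, numeric(2))
tt <- paired_ttest(scores["npd", ], scores["median", ])
cat(sprintf("mean over 50 segments: NPD %.2f dB, median %.2f dB (paired t = %.2f, p = %.3g)\n",
            mean(scores["npd", ]), mean(scores["median", ]), tt$t, tt$p))
```

Output:

```
noisy PSNR:   12.03 dB
median w=5:   26.69 dB
wavelet db18: 14.05 dB
NPD (5649 params): 29.19 dB
mean over 50 segments: NPD 31.37 dB, median 26.64 dB (paired t = 7.66, p = 6.26e-10)
```

Reading the numbers: impulse noise costs ~12 dB of fidelity; wavelet
shrinkage barely helps because soft thresholding spreads impulse energy
across scales; the median filter — the right classical tool — recovers
~27 dB; and the small reference-guided model, after 8 epochs on 256 pairs,
surpasses it, with a paired t-test over 50 held-out segments confirming the
improvement is systematic rather than per-segment luck.

## Command-line interface

A thin CLI over the same functions is installed at `inst/cli/ppg.R`
(after installation: `system.file("cli", "ppg.R", package = "ppgdenoise")`):

```sh
Rscript inst/cli/ppg.R generate   --hr 72 --duration 30 --seed 5 --out sig.csv
Rscript inst/cli/ppg.R preprocess --in sig.csv --out-dir segs
Rscript inst/cli/ppg.R corrupt    --in segs/seg_001.csv --kind salt_pepper --seed 3 --out noisy.csv
Rscript inst/cli/ppg.R denoise    --in noisy.csv --method filter --kind salt_pepper --out den.csv
Rscript inst/cli/ppg.R evaluate   --a den.csv --b segs/seg_001.csv
```

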