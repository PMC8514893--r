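# rrednet

Recursive residual encoder-decoder denoising for low-dose CT images, with a
synthetic phantom simulator, PSNR/SSIM quality metrics, a single-CPU
trainer, and summary-statistic group comparisons for clinical report
tables.

## The problem

Reducing tube current or projection count in computed tomography lowers the
radiation dose but corrupts the reconstructed image with pixelwise noise
and structured streak ("striped") artifacts. Radiologists reading
follow-up liver scans need those artifacts removed without losing lesion
detail. This package is for researchers who want a small, fully
inspectable implementation of residual encoder-decoder denoising — every
convolution, gradient and recursion is in plain code with tests — plus the
simulation and evaluation harness around it.

## The model

A noisy acquisition is treated as strictly additive degradation:

    I = A + N

where `A` is the clean image and `N` the noise field (i.i.d. Gaussian noise
plus streak artifacts in the simulator). The denoiser is a shallow
encoder-decoder built from residual units — two stacked convolutions whose
output is added to the block input, `O' = O + F(O, Q)`, with a 1×1
dimension-mapping convolution `H_s` on the skip when channel counts differ.
The network output is residual:

    g(M) = G(M) + M

so the model learns only the correction `G(M)`, and a zero-initialized
final layer makes the untrained model exactly the identity. Training
minimizes `argmin ‖g(M) − N‖²` against clean targets. At inference the same
network is applied recursively, re-injecting the original input at each
pass so detail cannot be washed out:

    J₁ = (M, M),   Oₙ = RED-Net(Jₙ),   Jₙ₊₁ = (M, Oₙ)

Output quality is scored with `PSNR = 10·log₁₀(D²/MSE)` and the structural
similarity index SSIM.

The clinical module recomputes group comparisons from published summary
statistics alone: pooled/Welch two-sample t-tests from (mean, SD, n),
2×2 chi-square tests, and rounded event rates.

## Worked example

```r
library(rrednet)

# paired synthetic data: 64x64 liver-like phantoms, Gaussian sigma 0.08,
# six streak artifacts per image
ds <- make_dataset(32, seed = 42)
round(psnr(ds[[1]]$clean, ds[[1]]$degraded), 2)
#> [1] 21.79

model <- build_codec(codec_config(), seed = 42)
res <- train(model, ds[1:24], train_config(seed = 42))
res$trace
#> <loss_trace> 30 epochs; train MSE 0.00861 -> 0.00175

ev <- evaluate(res$model, ds[25:32], n_recursions = 3)
ev
#> <denoise_eval> 8 pairs, 3 recursion(s)
#>   mean PSNR: 21.72 dB in -> 27.17 dB out (gain +5.45 dB)
#>   mean SSIM: 0.9025 in -> 0.9693 out
```

The held-out pairs gain about 5 dB of PSNR: the trained codec removes most
of the injected noise and streaks while the residual skip preserves the
phantom structure.

Clinical comparisons run from summary statistics:

```r
tt <- t_test_from_summary(group_summary("humanized", 19.55, 1.72, 30),
                          group_summary("routine",   28.82, 2.16, 30))
sprintf("t(%d) = %.2f, p = %.2g", tt$df, tt$t, tt$p_two_sided)
#> [1] "t(58) = -18.39, p = 7.1e-26"

rate_percent(count_pair(6, 98))
#> [1] 6

head(reproduce_report()[, c("comparison", "statistic", "p", "claim", "flag")], 5)
#>         comparison    statistic            p  claim       flag
#> 1        age_years  -0.72041557 4.741627e-01 P>0.05 consistent
#> 2    tumor_size_cm  -1.00970482 3.168306e-01 P>0.05 consistent
#> 3 operation_time_h   0.09862473 9.217763e-01 P>0.05 consistent
#> 4          acth_t3  -4.93725870 7.047909e-06 P<0.05 consistent
#> 5          acth_t4 -18.38861066 7.132878e-26 P<0.05 consistent
```

Each row recomputes one published comparison and flags whether the
recomputed p-value is consistent with the significance bound the source
table claimed; the flag reports rather than asserts, because a few
published count comparisons are not supported by any standard test on the
printed numbers.

A shell entry point wraps the same functions:

```sh
inst/scripts/rrednet simulate --pairs 8 --seed 1 --out data/
inst/scripts/rrednet train --data data/manifest.json --out model.ckpt
inst/scripts/rrednet eval --manifest data/manifest.json --model model.ckpt
inst/scripts/rrednet stats --out report.csv
```

## Vignette

`vignettes/rrednet-methods.Rmd` documents the degradation model, the
architecture and training choices, the metric definitions, the numerical
conventions, and what the synthetic phantoms do and do not say about real
CT data.
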