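# dermseg

Lightweight hybrid CNN–transformer segmentation of dermoscopic skin lesions,
implemented natively in R.

## What this is for

Automated lesion delineation in dermoscopy images supports melanoma
screening, but the two standard ingredients pull in opposite directions:
convolutions are cheap and local, self-attention is global and quadratically
expensive. `dermseg` implements a U-shaped encoder–decoder that keeps both in
*every* stage by compressing the attention's keys and values at multiple
scales, plus a wavelet-domain refinement of the highest-resolution skip
connection that sharpens lesion boundaries while suppressing hair and texture
artifacts. The package is a complete, self-contained pipeline — synthetic
dermoscopy generator, network, training loop, metrics, profiler and CLI — for
desk-scale experimentation on one CPU, with no deep-learning framework and no
external data.

## The model in brief

Every stage pairs a residual depthwise-separable CNN block

    Z = X + ReLU(BN(Conv1x1(ReLU(BN(DWConv7x7(X))))))

with a **multi-scale query attention block**: full-resolution query tokens
(N = HW) attend to key/value tokens convolutionally compressed at strides
s ∈ {2, 4, 8} (M_i = HW/s² tokens per path, h/2 heads of dimension d = C/h
each),

    SA_i = softmax(Q_i K_iᵀ / √d),   Z_i = SA_i (V_i + DWConv3x3(V_i)),

with the three path outputs concatenated (width 3C/2) and projected back to C
in a residual wrapper. Score memory is N·(M₁+M₂+M₃) ≪ N², which is what
makes attention affordable at all stages. The first skip connection is
refined by **wavelet-attention gating**: an orthonormal Haar DWT splits the
encoder feature into four half-resolution sub-bands, each gated by
`x ⊙ σ(Wψ ReLU(Wx x + Wg g))` with the pooled decoder feature g as guidance,
then recombined exactly by the inverse transform.

Training uses cross-entropy + Dice loss, AdamW and a 300-period cosine
schedule (1e-3 → 1e-5); evaluation reports mIoU, DSC, accuracy, sensitivity,
specificity and HD95. All forward *and backward* passes are hand-implemented
on base-R BLAS and verified against finite differences and dense naive
oracles; see `vignettes/dermseg-methods.Rmd` for the full account.

## Worked example

Profile the calibrated default architecture (256×256 input):

```r
library(dermseg)
print(profile_network(model_config()))
#> Component profile at input 256x256 (1 multiply-accumulate = 1 FLOP)
#> Stage            Params(M)  Param(%)  MACs(G)    MAC(%)
#> Encoder              4.64     81.02     3.68     49.55
#>   CNN                0.08      1.35     0.10      1.34
#>   MSQFormer          4.49     78.49     3.51     47.24
#>   other              0.07      1.18     0.07      0.97
#> Decoder              1.05     18.28     3.59     48.27
#>   CNN                0.02      0.35     0.08      1.04
#>   MSQFormer          0.96     16.70     3.38     45.52
#>   other              0.07      1.23     0.13      1.71
#> WARM                 0.04      0.70     0.16      2.18
#> Complete model       5.72    100.00     7.43    100.00
```

The totals are the model's complexity budget: 5.72 M parameters and 7.43 G
MACs, ~80% of the parameters in the encoder and most of those in the
attention blocks, while the wavelet refinement adds under 1%.

Generate synthetic dermoscopy images and overfit a tiny model (a few minutes
on one CPU):

```r
dir <- file.path(tempdir(), "demo")
dermseg_cli(c("generate", "--n", "8", "--seed", "1", "--out", dir,
              "--size", "64", "--log-level", "quiet"))
ds <- load_dataset(dir, c(64, 64))

set.seed(7)
net <- build_model(model_config(input_size = 64, stage_channels = c(8, 16, 32),
                                enc_blocks = c(1, 1, 1), dec_blocks = c(1, 1),
                                heads = c(2, 2, 4), gate_width = 4))
res <- train(net, ds, train_config(epochs = 60, seed = 42))
tail(res$history[, c("epoch", "lr", "loss", "train_dsc")], 3)
#>    epoch           lr      loss train_dsc
#> 58    58 0.0009144049 0.3285744 0.9509055
#> 59    59 0.0009114689 0.3244637 0.9521136
#> 60    60 0.0009084883 0.3231804 0.9506499

print(evaluate(net, ds))
#> mIoU 94.19%  DSC 95.62%  Acc 97.62%  Sen 94.13%  Spe 98.95%  HD95 1.89
```

After 60 epochs the 164 k-parameter model reconstructs its 8 training masks
with Dice 95.6% and a mean boundary error (HD95) below 2 pixels — the
expected overfitting behaviour that validates gradients, optimiser and data
plumbing end to end.

The same pipeline is available from a shell via the installed script:

```sh
Rscript inst/scripts/dermseg generate --n 8 --seed 1 --out data/
Rscript inst/scripts/dermseg train --data data/ --out run/ --size 64
Rscript inst/scripts/dermseg predict --data data/ --checkpoint run/checkpoint.rds --out preds/
Rscript inst/scripts/dermseg evaluate --data data/ --checkpoint run/checkpoint.rds --out eval/
Rscript inst/scripts/dermseg stats
```

Real dermoscopy datasets in the usual layout (`images/`, `masks/` with 0/255
PNG masks) drop in unchanged.

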