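# gsaunet

Retinal vessel segmentation with a gated skip-connection, adaptive-upsampling
encoder–decoder network (GSAU-Net), implemented natively in R/C++.

Segmenting the vasculature in fundus photographs is a pixelwise binary
classification problem and a standard preprocessing step for diagnosing
diabetic retinopathy, glaucoma and related disease. U-Net-style networks
dominate the task, but the plain skip-connection copies encoder noise into
the decoder, and the usual bilinear upsampling is data-independent. This
package implements the two mechanisms addressing that:

* **Gated skip-connection (GS)** — an attention map computed from the
  concatenated encoder/decoder features,
  `alpha = sigmoid(conv1x1(E ⊕ D))`, gates the encoder feature before it
  crosses the skip: `Y = (E ⊙ alpha + E) ⊕ D`.
* **Adaptive upsampling (AU)** — a learned channel expansion to `r²·C`
  channels followed by a parameter-free periodic rearrangement
  (depth-to-space) into an `r`-times-larger grid; exactly invertible, with
  all learning in the preceding convolution.

Around the architecture sits the full experimental apparatus: the random
48×48 patch-sampling training protocol (10,480 patches/image at full
scale; Adam, lr 0.001, step decay 0.01, weight decay 0.0005), ablation
variants (plain vs. gated skips; adaptive vs. bilinear vs.
transposed-convolution decoders), tiled full-image inference,
FOV-restricted evaluation (accuracy, sensitivity, specificity, precision,
F-measure, ROC/PR areas), DRIVE-style dataset I/O with fixed and
leave-one-out splits, and a procedural generator of fundus-like vessel
phantoms for fully reproducible desk-scale experiments. The tensor engine
(convolution, transposed convolution, batch norm, pixel shuffle, backprop,
Adam) is written against RcppArmadillo — no external deep-learning runtime.

## Worked example

```r
library(gsaunet)

# a reproducible synthetic cohort: image + vessel truth + FOV mask
spec     <- phantom_spec(height = 128, width = 128)
train_ph <- generate_dataset(spec, 10, seed = 100)
test_ph  <- generate_dataset(spec, 3,  seed = 900)
train_ph[[1]]
#> <phantom> 128x128, vessel fraction in FOV: 0.108, seed 209019

# gated/AU network, desk-scale training (single CPU, a few minutes)
net <- build_network(gsau_config(base_width = 16), seed = 1)
net
#> <gsau_net> base_width=16, upsample=adaptive, gating=TRUE, multiscale=TRUE, 4,195,553 params
res <- train_network(net, train_ph,
                     train_config(epochs = 2, batch_size = 32, seed = 1),
                     patch_spec(size = 48, per_image = 200, seed = 1),
                     verbose = TRUE)
#> epoch   1  loss 0.57311  val 0.44536  lr 1.00e-03
#> epoch   2  loss 0.36541  val 0.32953  lr 9.90e-04

# tiled full-image prediction and FOV-restricted metrics
ev <- evaluate_model(res$net, test_ph, tile_spec(size = 48, stride = 24))
round(ev$mean, 4)
#>    accuracy sensitivity specificity   precision   f_measure     auc_roc      auc_pr
#>      0.9684      0.9640      0.9690      0.8425      0.8991      0.9946      0.9696
```

The F-measure (harmonic mean of precision and sensitivity over FOV pixels)
and the area under the ROC curve are the headline numbers: here the
desk-scale network separates vessel from background on held-out phantoms
almost perfectly — synthetic phantoms are much easier than real fundus
images, so these values demonstrate a working pipeline, not benchmark
performance (see the methods vignette).

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/gsaunet.R synth --n 10 --seed 1 --out data/
Rscript inst/cli/gsaunet.R validate data/
Rscript inst/cli/gsaunet.R train --data data/ --out run/ --config inst/configs/desk.yaml
Rscript inst/cli/gsaunet.R predict --checkpoint run/model.rds --image data/images/sample_001.png --out prob.png
Rscript inst/cli/gsaunet.R evaluate --checkpoint run/model.rds --data data/ --out run/eval/
```

## Package layout

| Module | Contents |
|---|---|
| `R/blocks.R` | gated skip, adaptive upsampling, pixel shuffle, bilinear resize, deconvolution size arithmetic, conv block (double-precision reference) |
| `R/network.R` | configuration, builder, forward/backward, parameter counts, prediction, checkpoints |
| `src/` | im2col/GEMM convolution kernels and the single-precision training engine |
| `R/synthvessel.R` | fundus-like phantom generator |
| `R/dataio.R` | DRIVE/CHASE/STARE-style layouts, splits, FOV estimation |
| `R/patching.R` | random patch sampler, tiled inference |
| `R/training.R` | loss, Adam + step decay training loop |
| `R/evaluation.R` | confusion metrics, ROC/PR, multi-image reports |
| `R/cli.R`, `inst/cli/` | `synth` / `validate` / `train` / `predict` / `evaluate` |
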