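# axunet

Binary segmentation of 2-D biomedical images — cell nuclei in microscopy,
vessels in retinal fundus — with a U-shaped encoder–decoder network extended
by two blocks:

* **MDMSC**, a multi-head multi-scale cross-axis attention block applied to
  every pooled encoder map: channels are split across 8 heads; each head runs
  depthwise strip convolutions of sizes 7/11/21 along x and along y on the
  layer-normalized input (giving branches $F_x$, $F_y$), exchanges them by
  scaled dot-product attention along each spatial axis
  ($F_t=\mathrm{Attn}_x(F_y,F_x,F_x)$, $F_b=\mathrm{Attn}_y(F_x,F_y,F_y)$),
  and returns $\mathrm{Conv}_{1\times1}(F_t)+\mathrm{Conv}_{1\times1}(F_b)$;
  a residual connection adds the block input.
* **EF**, a gated efficient-fusion block replacing plain skip concatenation:
  a spatial gate $x\odot(1+\sigma(\mathrm{Conv}_{1\times1}\mathrm{ReLU}(W_g+W_x)))$
  built from 32-group convolutions of the upsampled decoder map $g$ and the
  encoder skip $x$, then channel attention with residual
  ($u\odot\sigma(\mathrm{Conv}_{1\times1}\mathrm{GAP}(u))+u$) on
  $\mathrm{concat}(\mathrm{EA}(g,x),\,g)$.

The whole stack — convolutions, pooling, bilinear upsampling, axial
attention, layer/batch normalization, backpropagation, Adam — is implemented
in R with C++ (RcppArmadillo) kernels; no deep-learning framework is
required. Evaluation uses confusion-matrix metrics
(mIoU, accuracy, recall), and seeded generators produce nucleus-like and
vessel-like image/mask pairs so everything runs end-to-end with no dataset
download. The package is aimed at researchers who want a transparent,
dependency-light reference implementation of cross-axis attention
segmentation that is testable on a plain CPU.

## Worked example

```r
library(axunet)

# architecture: default = 4 stages from 64 channels, 8 heads, MDMSC + EF
model <- build_model(network_config())
count_parameters(model)
#> Trainable parameters: 17,174,149 (17.17 M)
#>   att1            7,936
#>   att2           19,968
#>   att3           56,320
#>   att4          178,176
#>   dec1        8,278,529
#>   dec2        3,006,977
#>   dec3          752,385
#>   dec4          188,417
#>   enc1           38,720
#>   enc2          221,440
#>   enc3          885,248
#>   enc4        3,539,968
#>   head               65

# train a reduced model on eight seeded synthetic nuclei images
spec  <- sample_spec(64, 64, "nuclei")
train <- generate_dataset(spec, 8, seed_start = 100)
set.seed(65)
small <- build_model(network_config(base_width = 16L))
small <- train_model(small, train,
                     training_config(learning_rate = 1e-3, batch_size = 4L,
                                     epochs = 100L, seed = 1L))
tail(attr(small, "log"), 3)
#>     epoch  mean_loss
#> 98     98 0.01421262
#> 99     99 0.01464202
#> 100   100 0.01437876

m <- evaluate_model(small, train)
unlist(m$pooled)
#>      miou       acc    recall
#> 0.9707201 0.9931030 0.9557861
```

The parameter summary is the exact count of trainable scalars per top-level
submodule (encoder stages `enc*`, attention blocks `att*`, decoder stages
`dec*`). The training log shows the per-epoch mean binary cross-entropy
falling by an order of magnitude as the reduced model overfits its eight
training images; the pooled metrics (confusions summed over all images
before the ratios) confirm near-perfect recovery of the ground-truth masks
(mIoU > 0.9).

A thin CLI over the same functions lives in `inst/exec/axunet`
(`generate`, `train`, `evaluate`, `predict`, `ablate`, `params`), driven by
a YAML config with `network:` and `training:` sections.

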