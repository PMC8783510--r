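# chalkcam

Weakly supervised detection and quantification of chalkiness in rice grain
images.

Chalkiness — the opaque region of a grain caused by loosely packed starch
granules — is a major rice quality defect that intensifies under high night
temperature during grain filling. Scoring it across the thousands of grains
a breeding or mapping population produces requires a phenotyping tool, but
pixel-level annotation of chalky regions is prohibitively expensive.
`chalkcam` needs only image-level labels (*chalky* / *non-chalky*): it
trains a small CNN classifier and uses gradient-weighted class activation
mapping to localize and quantify the chalky area from those labels alone.

It is aimed at plant phenomics researchers who scan grains on flatbed
scanners and want per-grain chalkiness phenotypes (for QTL mapping, stress
experiments, or quality control) without building a deep-learning stack.

## What it computes

For a chosen convolutional layer with feature maps $f^k$ ($k=1,\dots,K$,
$N$ positions each) and the chalky-class logit $y^c$, Grad-CAM weights

$$w^c_k = \frac{1}{N}\sum_{i,j}\frac{\partial y^c}{\partial f^k_{i,j}},
\qquad H^c = \mathrm{ReLU}\Big(\sum_k w^c_k f^k\Big),$$

upsampled bilinearly to the input size. With $Z$ the grain-foreground pixel
count, the per-grain phenotypes are

* **ChalkyScore** $=\frac{1}{Z}\sum_{\text{GrainArea}} H^c_{final}/\max
  H^c_{final} \in [0,1]$ (0 = no chalk, 1 = severe chalk everywhere), and
* **chalk-area %** $= 100\,|M \cap \text{GrainArea}|/Z$, where $M$ is the
  heatmap binarized at a threshold $T$ (% of the per-image maximum).

Localization quality against polygon ground truth is scored by IoU,
average IoU, GT-known localization accuracy (IoU ≥ 0.5) and localization
accuracy (label correct *and* IoU ≥ 0.5), with the layer and $T$ selected
by grid search on a development set. Grad-CAM++ and Score-CAM variants are
included for comparison. A synthetic grain/plate generator with exact
ground truth makes the whole pipeline testable offline; see the vignette
(`vignettes/chalkiness-phenotyping.Rmd`) for the methods in full.

## Worked example

```r
library(chalkcam)

# 1. simulate a small labelled dataset (4 plates x 25 grains)
ds <- generate_dataset(4, layout = plate_layout(n_grains = 25),
                       out_dir = tempfile("chalk"), seed = 1)
table(ds$manifest$label, ds$manifest$split)
#>              dev test train
#>   chalky      11   17    19
#>   non-chalky  14    8    31

# 2. train the tiny backbone on the crops
model <- build_backbone("tiny", seed = 1)
model <- train_classifier(model, ds$manifest,
                          train_config(max_epochs = 15, rng_seed = 1),
                          base_dir = dirname(ds$manifest_path))

# 3. classify the held-out test grains
test <- ds$manifest$split == "test"
grains <- lapply(file.path(dirname(ds$manifest_path),
                           ds$manifest$path[test]), read_image)
pred <- predict_batch(model, grains)
classification_metrics(pred$label, ds$manifest$label[test])
#> Accuracy: 100.00% (n = 25)
#>   non-chalky  Pre 100.00  Rec 100.00  F1 100.00
#>   chalky      Pre 100.00  Rec 100.00  F1 100.00

# 4. localize and quantify chalkiness per grain
recs <- quantify_batch(model, grains, layer = "block1", T = 60)
head(recs[, c("grain_id", "label", "chalky_score", "chalk_area_percent")], 4)
#>    grain_id  label chalky_score chalk_area_percent
#> 1 grain0001 chalky    0.4998241           44.14618
#> 2 grain0002 chalky    0.5704363           47.55332
#> 3 grain0003 chalky    0.3405561           28.93401
#> 4 grain0004 chalky    0.3438357           21.03125
```

The ChalkyScore column is the intensity-weighted fraction of the grain
surface that the model attributes to chalk; the chalk-area column is the
percentage of grain pixels inside the binarized chalk mask. Scoring the
binarized masks of the chalky test grains against the generator's polygon
ground truth in the same session gave an average IoU of 94.72% and a
GT-known localization accuracy of 100.00%.

A command-line interface wrapping the same functions
(`simulate`, `crop`, `train`, `explain`, `quantify`, `grid-search`,
`evaluate`) ships in `inst/cli/chalkcam.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "chalkcam.R", package = "chalkcam"))')" \
    simulate --out ds/ --n-plates 4 --seed 1
```

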