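# hippoboost

Fully automated hippocampus segmentation from co-registered structural
MRI by boosted voxel classification, for neuroimaging researchers who
need reproducible hippocampal masks and volumes (e.g. as an atrophy
biomarker in Alzheimer's disease studies).

## The method

Segmentation is cast as voxelwise binary classification inside a fixed
peri-hippocampal volume of interest (VOI, 50 x 60 x 60 voxels). Each
voxel carries a 315-dimensional descriptor: 248 3D Haar-like filter
responses (62 templates at window sizes 3-9), 48 Haralick texture
statistics (energy, contrast, correlation, inverse difference moment on
GLCMs of mean-projection subimages), 16 directional gradients and its 3
grid coordinates.

Hippocampal voxels are a small minority, so the classifier is RUSBoost:
confidence-rated boosting with per-round **r**andom **u**nder**s**ampling
of the majority class. With weights $D_1(i) = 1/m$, each round
undersamples to minority fraction $N$, fits a depth-limited decision
tree $h_t : X \times Y \to [0,1]$, computes the pseudo-loss

$$\epsilon_t = \tfrac12 \sum_{(i,y):\, y \ne y_i} D_t(i)\,
  \bigl(1 - h_t(x_i, y_i) + h_t(x_i, y)\bigr),$$

sets $\alpha_t = \epsilon_t / (1 - \epsilon_t)$ and updates
$D_{t+1}(i) \propto D_t(i)\,\alpha_t^{\eta\,h_t(x_i,y_i)}$. The final
label is $H(x) = \arg\max_y \sum_t h_t(x, y) \log(1/\alpha_t)$. Defaults:
$T = 150$ rounds, learning rate $\eta = 0.1$, $N = 50\%$, depth-3 trees;
`rus = FALSE` gives the plain Adaboost baseline ($T = 400$
conventionally). Classification is restricted to a *reduced VOI* — the
union of the training masks dilated by a 2 x 2 x 2 kernel — inside which
hippocampal voxels make up roughly 27-38% of the candidates.

Evaluation uses Dice, precision, recall and relative overlap (Jaccard),
Pearson volume agreement, and a paired two-sided exact sign test on
volume differences. A synthetic phantom generator produces 50 x 60 x 60
cohorts (textured two-tissue contrast, polynomial bias field, Gaussian
noise, across-subject shape/volume variability) with ground truth, so
the whole pipeline is testable without any scan download.

## Worked example

```r
library(hippoboost)

cohort <- generate_cohort(15, phantom_spec(), seed = 11)
model  <- train_segmenter(cohort, m = 10, subjects = 1:10,
                          boost_params = list(n_rounds = 150))
print(model$rvoi)
#> rVOI: 28282 voxels on a 50 x 60 x 60 grid ( 15.7% )

pred <- segment_image(model, cohort$subjects[[11]]$volume)
overlap_metrics(pred, cohort$subjects[[11]]$mask)
#> Dice 0.9810 | Precision 0.9803 | Recall 0.9816 | R.O. 0.9626
#> counts: TP 8755  FP 176  FN 164  TN 170905
```

The rVOI line says classification was restricted to 28282 candidate
voxels (16% of the crop); the metrics line compares the predicted mask
with the ground truth of a held-out phantom — Dice near 1 means the
predicted and true masks almost coincide, and precision/recall split the
disagreement into false positives vs missed voxels.

## Acceptance run

`scripts/acceptance.R` re-runs the full pipeline from scratch: it
generates a 15-subject phantom cohort at the given seed, trains the
segmenter on 10 subjects at the default operating point (T = 150,
eta = 0.1, N = 50%), segments the 5 held-out subjects, and prints the
overlap metrics and the predicted-vs-true volume agreement before
writing its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
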