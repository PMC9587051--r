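# estrocycle

Automated staging of the rodent estrous cycle from brightfield vaginal
cytology images, for labs that track endocrine state in mice and rats.

The estrous cycle runs through four canonical stages — diestrus (D),
proestrus (P), estrus (E), metestrus (M) — over roughly 4–5 days, and each
stage has a characteristic mix of exfoliated cell types (leukocytes,
cornified epithelial, nucleated epithelial cells). Manual smear reading is
slow and inconsistent between examiners. `estrocycle` provides:

- **Dataset plumbing**: CSV manifests with per-image metadata, the curation
  exclusion rules (images under 300 px or with fewer than 10 counted cells
  are dropped), stage balancing, and a stratified 80/10/10
  train/validation/test split that is proportionally representative of
  stain, species, lab and magnification.
- **Preprocessing**: luminance peak alignment (histogram mode shifted to a
  reference level), 3-channel grayscale conversion, exact quadrisection,
  seeded affine augmentation (reflect/rotate/scale/translate with edge
  replication), bilinear resize to 224×224×3.
- **A pluggable softmax classifier** with the transfer-learning training
  schedule: minibatch RMSprop (squared-gradient decay 0.99), 3 epochs with
  per-epoch shuffling, and the piecewise step-decay learning rate

  $$lr(e) = \max\big(lr_{\text{floor}},\ lr_0 \cdot \text{drop}^{\lfloor e/\text{epochs\_drop}\rfloor}\big).$$

  Deep backbones (ResNet-50, VGG-19, Inception v3, MobileNet v2) plug in via
  `register_backbone()`; a self-contained desk-scale convolutional backbone
  (`smallcnn`) trains in minutes on one CPU.
- **Cycle-aware post-processing**: the softmax margin Confidence Index
  $CI = (P_{\max} - P_{\max-1})/(P_{\max} + P_{\max-1})$; an archetypal
  4.8-day cycle waveform over the stage encoding D=0.5, P=1.5, E=2.5, M=3.5
  (0.0≡4.0 = metestrus/diestrus boundary); phase fitting of sequential
  classifications by Pearson-correlation grid search in 0.1-cycle steps;
  outlier flags, transition-stage suggestions when the network and cycle
  disagree at CI < 0.30, pseudopregnancy warnings when a diestrus run
  exceeds 1.5× the prior baseline, and anestrus detection from >2
  consecutive days above 90% leukocytes.
- **Evaluation machinery**: confusion matrices, one-vs-rest ROC/auROC,
  sensitivity–specificity cutoffs, bootstrap accuracy distributions (5000
  iterations), Fisher's exact comparisons, and grouped k-fold / leave-one-
  category-out out-of-sample testing.
- **A seeded synthetic cytology generator** that renders stage-labelled
  images (and multi-day cycle sequences, optionally with pseudopregnancy
  episodes) with exactly countable cell content, so the entire pipeline is
  testable end to end with no downloads.

See the methods vignette (`vignettes/estrocycle-methods.Rmd`) for the models,
assumptions, parameter defaults and design decisions.

## Worked example

```r
library(estrocycle)

# generate a small synthetic bank and train the desk-scale classifier
bank  <- generate_dataset(n_per_stage = 25, dir = "bank", seed = 1)
split <- split_dataset(bank, seed = 1)
cfg   <- training_config(backbone = "smallcnn", seed = 1)
model <- train(build_model(cfg), split, cfg)
model$history
#>   epoch      loss learning_rate val_accuracy
#> 1     1 6.1074114         0.100          0.8
#> 2     2 1.6403401         0.010          0.9
#> 3     3 0.7129079         0.001          0.9

# classify the held-out images
results <- classify_manifest(model, split$test)
results[[1]]
#> <estrous_result> diestrus (CI 1.00)
acc <- mean(vapply(results, function(r) r$stage, "") == split$test$stage)
#> held-out accuracy: 0.90 (n = 10)

# fit a 12-day daily sampling series to the archetypal cycle
series <- generate_cycle_sequence(
  sequence_spec(n_days = 12, true_phase = 0.3, label_noise = 0.1, seed = 2))
fit <- fit_cycle_phase(series$collected_at_days, series$stage)
fit
#> <cycle_fit> best phase 0.3 cycles, Pearson r = 0.907, 1 outlier(s)
```

The training history shows the step-decay schedule (learning rate dropping
×0.1 each epoch) and validation accuracy per epoch. Each classification
carries the per-stage probabilities and the Confidence Index; the cycle fit
recovers the ground-truth phase (0.3 cycles) of the simulated series and
flags the noise-corrupted sample as an outlier. At this deliberately tiny
scale (25 images/stage) held-out accuracy is already 0.90 on the synthetic
benchmark; the bundled acceptance checks train at 200 images/stage.

A thin CLI over the same functions ships in `inst/cli/estrocycle.R`
(`generate`, `generate-sequence`, `split`, `train`, `classify`, `cyclefit`,
`evaluate`).

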