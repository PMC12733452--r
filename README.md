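# sonoseg

Multisensory brain-MRI tumor segmentation: deep-learning segmentation of
low-grade glioma on 2-D FLAIR slices, plus perceptual rendering of the
predictions as color maps, stereo audio sonifications and MIDI scores.

## The problem

Segmentation masks are easy to produce and hard to *apprehend*: a
radiologist scanning dozens of slices gets little help from a binary
overlay, and subtle anomalies are easy to miss. `sonoseg` renders each
predicted lesion through three coordinated channels so that its size,
intensity, shape complexity and statistical severity become simultaneously
visible and audible:

* **Color**: probability maps and overlays through an ordered colormap.
* **Audio**: each region plays a melody drawn from a musical scale chosen
  by its features — high-intensity regions sound major, low-intensity
  minor, large regions pentatonic, small irregular regions blues — panned
  to the region's position with a constant-power stereo law. Anomaly
  severity is encoded as harmonic dissonance: a **tritone** (6 semitones)
  for high-severity regions, a **minor seventh** (10 semitones) for
  moderate ones.
* **MIDI**: the same mapping as a symbolic score (pitch, duration ∝ area,
  velocity ∝ intensity).

Segmentation itself is done by one of four architectures built on a
compact CPU autodiff engine included in the package:

* **U-Net** — encoder/decoder with skip connections; two 3×3 conv
  (BatchNorm+ReLU) per stage, base width 64 doubling to a 1024-channel
  bottleneck. The reference configuration has **31.04 M** trainable
  parameters (exactly 31,043,521).
* **DeepLab variant** — residual encoder, global channel attention, and
  atrous spatial pyramid pooling at dilation rates {6, 12, 18}.
* **GAT** — the slice is downsampled to a node grid; edges are cosine
  similarities between node features; multi-head attention
  `α_ij = softmax_j(LeakyReLU(aᵀ[Wh_i ‖ Wh_j]))` with 8 heads,
  concatenated.
* **SGNN** — the same attention restricted to each node's top-k most
  similar neighbors (with `k = N−1` it reproduces the dense GAT exactly).

Training follows a fixed protocol: Adam (lr 1e-4), batch 32, soft Dice
loss with the smoothed Jaccard distance (smooth = 100) as auxiliary,
`ReduceLROnPlateau` (factor 0.2, patience 5), early stopping (patience
20), periodic + best-validation-Dice checkpoints. Evaluation uses Dice
`2|A∩B|/(|A|+|B|)` and IoU `|A∩B|/|A∪B|`.

A built-in phantom generator emits synthetic brain slices with
ground-truth masks in the same patient-wise `image` / `image_mask` folder
layout as the curated TCGA-LGG collection, so the entire pipeline runs and
is tested without any external download.

## Worked example

```r
library(sonoseg)

# a synthetic patient cohort on disk, indexed and split by patient
dir <- tempfile()
generate_phantom_dataset(n_patients = 12, slices_per_patient = 6,
                         out_dir = dir, seed = 1, image_size = 64)
idx <- index_dataset(dir)
sp  <- split_patients(idx, c(0.5, 0.25, 0.25), seed = 1)
sp
#> <sonoseg_split> 6 train / 3 val / 3 test patients (seed 1)

# train a small U-Net
tr <- load_split(idx, sp, "train", size = 64)
va <- load_split(idx, sp, "val", size = 64)
fit <- train(build_model(model_spec("unet", input_size = c(64, 64, 3),
                                    base_width = 16, seed = 1)),
             tr, va,
             train_config(batch_size = 16, learning_rate = 1e-3,
                          max_epochs = 8, seed = 1))
fit
#> <sonoseg_fit> unet, 8 epochs, best val Dice 0.8636 (epoch 8)

te <- load_split(idx, sp, "test", size = 64)
glance(evaluate(fit$model, te))
#> # A tibble: 1 × 4
#>   mean_dice mean_iou mean_accuracy n_slices
#>       <dbl>    <dbl>         <dbl>    <int>
#> 1     0.861    0.773         0.987       18

# anomaly analysis and perceptual rendering of one test slice
img  <- te$images[, , 1, 1]
mask <- predict_masks(fit$model, te$images[, , , 1])
rep  <- anomaly_report(img, mask)
rep$regions[, c("area", "complexity", "mean_zscore", "severity")]
#> # A tibble: 1 × 4
#>    area complexity mean_zscore severity
#>   <int>      <dbl>       <dbl> <chr>
#> 1   360       2.04        11.5 high

au  <- create_advanced_brain_sonification(img, mask, rep)
write_wav(au, "slice.wav")          # stereo 44.1 kHz, tritone = high severity
mid <- create_advanced_midi_from_brain(rep)
write_midi(mid, "slice.mid")
write_rgb_png(render_overlay(img, predict_probs(fit$model,
                                                te$images[, , , 1])),
              "slice_overlay.png")
```

The test Dice of 0.86 means the predicted and true tumor masks overlap
well on held-out patients even at this miniature training scale; the single detected region is flagged
`high` (peak z-score far above 3 SD of normal-appearing brain), so both
the WAV and the MIDI phrase carry a tritone dyad on top of the region's
melody.

The same flow is available from the shell via the thin CLI in
`inst/scripts/sonoseg` (subcommands `generate-phantoms`, `train`,
`predict`, `sonify`, `evaluate`, `run`, with `--config`, `--seed`,
`--out`, `--arch`), and end-to-end via `run_pipeline()`, which writes
masks, maps, audio, MIDI, metric reports and a checksummed
`manifest.json`.

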