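# refocus

Selective post-acquisition focus restoration for label-free time-lapse
microscopy of nanowell arrays.

## The problem

Time-lapse imaging of motile cells confined in 50 µm nanowells trades
focusing time for throughput, so intermittent out-of-focus (OOF) frames are
unavoidable.  OOF blur destroys the boundary features that cell
segmentation and cell–cell contact detection depend on, and a video with
more than 5% OOF frames is conventionally discarded — a few bad frames can
cost an entire well's time series.

`refocus` implements the two-step rescue workflow for this setting, for
image-analysis pipelines that want to recover those videos after
acquisition:

1. **Detect**: a small convolutional classifier scores every frame
   (`assess_video()`); a video is flagged when its OOF fraction is
   *strictly* greater than 5%.
2. **Restore selectively**: a conditional denoising diffusion probabilistic
   model (DDPM) regenerates only the flagged frames (`restore_video()`).
   For each frame, K samples (default 5) are drawn by ancestral sampling
   conditioned on the OOF image and averaged pixelwise
   (`restore_averaged()`) — averaging cancels sampling noise and
   hallucinated detail.
3. **Quantify**: Tenenbaum gradient, PSNR, Pearson correlation (whole image
   and Canny-edge-restricted), MSE (`evaluate_pairs()`); downstream
   segmentation, contact-mask fidelity and cell-count error
   (`segment_cells()`, `detect_contacts()`, `count_error()`); usable-video
   yield before and after restoration (`yield_report()`).

The diffusion machinery is the standard DDPM: a 1000-step (desk profile:
200-step) linear noise schedule with β from 1e-4 to 0.05,

    x_t = sqrt(ᾱ_t) x_0 + sqrt(1 − ᾱ_t) ε,   ᾱ_t = Π_{s≤t} (1 − β_s),

a noise-predicting denoiser trained with MSE, and ancestral sampling with
σ_t² = β_t.  The conv-net engine (classifier, denoiser, and a
Charbonnier-loss regression baseline) is implemented from scratch in
RcppArmadillo — no deep-learning runtime is required.

Because the original assay's videos are not distributable, the package
ships a synthetic nanowell simulator (wells, round/elongated cells, beads,
parametric defocus with |Δz|-linear blur plus contrast decay, OOF event
bursts, ground-truth masks), so the complete workflow is generated,
trained and verified from code alone.

## Worked example

About ten minutes on one CPU (the conv nets are hand-rolled BLAS):

```r
library(refocus)

scene <- scene_spec(image_size_px = 64, pixel_pitch_um = 1, n_cells = 2)
optics <- defocus_model()            # sigma = 0.4 px/um, 5%/um contrast decay

# paired in-focus/OOF dataset (25% identity pairs, +/-10 um planes)
ds <- make_pair_dataset(scene, optics, n_pairs = 1400,
                        identity_fraction = 0.25, offsets_um = 10, seed = 1)
held_out <- tail(which(ds$manifest$focus_label == "oof"), 10)
train <- setdiff(which(!ds$manifest$is_identity), held_out)

# train the desk-profile conditional DDPM (T = 200)
ddpm <- train_ddpm(ds$pairs[train],
                   denoiser_spec(base_channels = 12, n_layers = 4),
                   make_schedule(200),
                   diffusion_config(steps = 1500, batch_size = 8,
                                    learning_rate = 1e-3), seed = 1)

# restore the held-out OOF frames by 5-sample averaging and score them
truth <- lapply(ds$pairs[held_out], `[[`, "in_focus")
oof <- lapply(ds$pairs[held_out], `[[`, "oof")
restored <- lapply(seq_along(held_out), function(i) {
  restore_averaged(ddpm, oof[[i]], K = 5, seed = i)$mean_image
})
cat(sprintf("median PSNR  oof -> restored: %.2f -> %.2f dB\n",
            median(mapply(psnr, truth, oof)),
            median(mapply(psnr, truth, restored))))
cat(sprintf("median Tenengrad  oof / restored / truth: %.4f / %.4f / %.4f\n",
            median(sapply(oof, tenengrad)),
            median(sapply(restored, tenengrad)),
            median(sapply(truth, tenengrad))))
```

Output of this exact script (seeds included) on the reference container:

```
median PSNR  oof -> restored: 20.55 -> 22.01 dB
median Tenengrad  oof / restored / truth: 0.0034 / 0.0468 / 0.2953
```

Read: the defocused inputs at Δz = 10 µm sit at 20.6 dB against ground
truth with essentially no gradient energy left (0.0034 vs 0.2953); the
5-sample DDPM means are both closer to the truth (+1.5 dB) and an order of
magnitude sharper (0.047).  The full yield workflow is
`yield_report(videos, classifier, ddpm)`; see the vignette
(`vignettes/focus-restoration.Rmd`) for the models, assumptions, and the
simulator's stated world.

## Command line

```sh
Rscript -e 'refocus::refocus_cli()' run --config config.yaml --out runs/demo
```

Subcommands: `simulate`, `train-classifier`, `train-ddpm`, `assess`,
`restore`, `evaluate`, `yield`, `run` (all stages).  The YAML config mirrors
`scene_spec()` / `video_spec()` / `defocus_model()` plus per-stage
settings; reruns of a completed run are no-ops (stages log `up-to-date`).

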