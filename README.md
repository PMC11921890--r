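# dbytk — hyperspectral detection of non-tobacco related materials

Contaminants mixed into harvested tobacco leaves — weeds, rubber rings,
feathers, collectively *non-tobacco related materials* (NTRMs) — degrade
product quality and are still mostly removed by hand. `dbytk` implements a
complete hyperspectral detection workflow for this problem in R: from
hyperspectral cubes of a conveyor-belt scene to trained-detector metrics.
It is aimed at researchers in agricultural imaging who want a tested,
self-contained reference implementation of the full chain:

1. **Hyperspectral I/O** — ENVI-style cubes (BSQ/BIL/BIP interleaves,
   wavelength metadata) and normalized center-format detection labels.
2. **Synthetic belt scenes** — a generator that composites tobacco leaves,
   belt background and the three NTRM classes with material-specific
   reflectance templates on the 400–900 nm / 5 nm / 101-band grid, so the
   entire pipeline is testable without any proprietary data.
3. **Characteristic-wavelength selection** — region-restricted PCA of ROI
   spectra; bands are ranked by the *weight coefficient*
   γ<sub>ij</sub> = α<sub>i</sub>·β<sub>ij</sub> (eigenvalue × loading of
   principal component *i* at wavelength *j*) and *k* = 3 widely separated
   extrema of the γ curve are selected.
4. **Image enhancement** — pseudo-color composition (PCC: three selected
   bands mapped to R/G/B by descending wavelength) and decorrelation
   contrast stretch (DCS: symmetric whitening of the channel covariance,
   rescaled to a target SD).
5. **Augmentation** — clockwise rotations (90°/180°/270°), background
   patches overlaid onto annotated objects, and per-scene assembly of the
   original with two rotated variants (applied after the 6:2:2 split), the
   protocol that turns 1,000 scenes / 4,203 boxes into 3,000 / 12,609.
6. **A trainable dual-branch detector** — two small-scale anchor-free
   backbones over paired RGB and DCS images, per-scale fusion, and a
   BELFPN neck (BiFPN-style normalized weighted fusion with C2f_EL blocks
   whose inner operator is a three-branch multi-kernel depthwise module
   with channel shuffle), with a decoupled head and the combined
   BCE + CIoU + distribution-focal loss. The convolution engine is
   written in Rcpp/Armadillo with full backward passes, so the model
   actually trains on CPU at desk scale.
7. **Evaluation** — greedy IoU matching, all-points interpolated AP,
   mAP@50 / mAP@50-95, F1 at the best operating point, and an FPS harness.

The single-branch baseline instantiated from the same machinery counts
exactly **3,011,433 parameters / 8.1 GFLOPs** at 640×640, and the default
dual-branch model exactly **3,733,674 parameters / 10.7 GFLOPs** — the
published architecture budgets this package reproduces.

## Worked example

A desk-scale end-to-end run — synthesize 30 annotated 64×64 scenes, select
bands, build DCS images, train the dual-branch detector for 300 iterations
and evaluate on the held-out test split (about two minutes on one CPU):

```r
library(dbytk)
res <- run_pipeline(list(n_scenes = 30, seed = 1, n_iter = 300,
                         batch_size = 8))
res$metrics
#>       Method Input Parameters GFLOPs Precision Recall mAP50 mAP50_95   F1
#>  dual-branch multi    1115778   0.03      70.6    100  95.2     26.4 82.8
res$bands
#> [1] 555 670 850
```

The metrics row is shaped like an ablation-table entry: parameter count
and GFLOPs of the configured model, then percentage-scale precision,
recall, mAP@50, mAP@50-95 and F1 on the test split. The selected triple
(555/670/850 nm here) sits at the green reflectance peak, the chlorophyll
absorption trough and the NIR plateau — the regions where tobacco and
NTRM spectra differ most. At this problem size the detector finds
essentially all objects at IoU 0.5 (mAP@50 ≈ 95%); the stricter
mAP@50-95 stays low because a few-pixel error is a large IoU penalty on
10-pixel objects.

The same stages are scriptable from a shell via the installed CLI:

```sh
dbytk synth --n-scenes 10 --seed 3 --size 64 --out scenes
dbytk select-bands --data scenes --pc 1 --out bands
dbytk enhance --data scenes --bands 550,670,850 --kind dcs
dbytk augment --data scenes --pick 2 --seed 4 --out aug
dbytk pipeline --n-scenes 25 --iters 200 --out run1
dbytk bench --input rgb --size 64
```

## Package layout

| Area | Files |
| --- | --- |
| Cubes, labels, scenes | `R/hsi_core.R` |
| Scene generator | `R/synthetic_scenes.R` |
| PCA band selection | `R/band_selection.R` |
| PCC / DCS enhancement | `R/enhancement.R` |
| Rotation / overlay augmentation | `R/augmentation.R` |
| CNN engine (Rcpp kernels) | `R/nn_engine.R`, `src/nn_ops.cpp` |
| Architectures, counting | `R/model.R` |
| Losses, assignment, training | `R/detect_train.R` |
| Metrics, pipeline | `R/evaluation.R` |
| CLI | `R/cli.R`, `exec/dbytk` |

The methods vignette (`vignettes/ntrm-detection.Rmd`) documents the
modelling choices, parameter conventions and limitations in detail.
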