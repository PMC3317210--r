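# cryocount

Detection and model-based counting of fluorescently labeled cells in
cryo-imaging volumes.

Cryo-imaging alternately sections a frozen specimen and photographs the
block face, yielding aligned 3D two-channel (red/green) fluorescence
volumes covering an entire mouse at 8.8–15.6 µm pixels and 40 µm
sections. Labeled cells (quantum-dot-tagged stem cells, cancer cells) are
about one pixel wide at that resolution, so touching cells merge into
connected fluorescent clusters whose boundaries cannot be resolved. The
question a delivery or homing study needs answered — *how many cells are
in each cluster?* — is solved here by model-based counting: a cluster is
fit with superpositions of `n` fixed-shape, fixed-intensity
pixel-integrated Gaussian cell models, and the `n` minimizing

```
F_obj = sum_m ( I_Gray - sum_n I_gauss )^2
```

is the count. The template (width σ, total intensity I_t) is calibrated
from singleton clusters in the data; the initial guess per cluster is
`N_i = round(∫C_i / I_t)` and integers within `max(2, 30%)` of it are
tested. Fitted centers are sub-pixel in-plane and continuous axially (a
sectioned cell splits its intensity between adjacent sections); centers
may not approach closer than `D_min`, approximately one cell diameter.

Around that core the package provides the full pipeline:

- **preprocessing**: next-image subtraction of subsurface fluorescence,
  background removal by grayscale morphological reconstruction (Rcpp
  kernel, oracle-tested), and red/green ratio thresholding
  (`I_R/I_G ≈ 8` for labeled cells vs `≈ 0.4` for autofluorescence);
- **detection**: hysteresis thresholding (`T_H` from an image of cells in
  culture, `T_L = μ + 1.4 σ` of the working volume) with 3D
  connected-component labeling and knowledge-based false-positive
  rejection (maximum volume, intensity/volume band);
- **phantom simulation**: synthetic microsphere- and cell-grade volumes
  with ground truth (intensity CV 5% / 15%, bleed-through, sectioning,
  autofluorescent background, sensor noise);
- **evaluation**: contingency tables, Fleiss' and Cohen's kappa,
  per-class sensitivity/specificity, total-count error.

## Worked example

Simulate a 60-cluster labeled-cell phantom, run the pipeline, and score
it against ground truth:

```r
library(cryocount)
cfg   <- phantom_config(image_shape = c(6, 256, 256), n_clusters = 60, seed = 7)
study <- run_phantom_study(cfg, seed = 7, culture_n = 100)
print(study$run$model)
print(study$metrics)
print(study$metrics$contingency)
```

```
<cell_model> sigma = 0.989 px (sd 0.026), I_t = 980.5 (sd 169.7), D_min = 1.50 px; 20 singleton fits
<cryo_eval> 60/60 true clusters matched (0 missed, 0 spurious)
  total count 138 est vs 134 true (error 2.99%); within +/-1: 100.0%
  Fleiss kappa 0.858 +/- 0.071; Cohen kappa 0.858
  mean sensitivity 0.851; min specificity 0.961
    est
true  1 2 3 4 5
   1 28 0 0 0 0
   2  1 7 2 0 0
   3  0 0 8 1 0
   4  0 0 0 4 2
   5  0 0 0 0 7
```

The calibrated template recovers the generator's parameters (σ = 1 px,
mean intensity 1000 with 15% CV); every cluster is detected, every count
is within ±1 of truth, and errors concentrate — as expected for a
fixed-intensity model — in clusters whose cells are collectively brighter
or dimmer than average.

The same stages are available as file-based commands
(`cmd_simulate()` / `cmd_run()` / `cmd_evaluate()`, TIFF + CSV/YAML/JSON
interchange) and as a thin CLI in `inst/cli/cryocount.R`:

```sh
Rscript inst/cli/cryocount.R simulate --out study --seed 7
Rscript inst/cli/cryocount.R run --stack study/phantom --culture study/culture --out study
Rscript inst/cli/cryocount.R evaluate --counts study/counts.csv --truth study/truth.csv --out study/metrics.json
```

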