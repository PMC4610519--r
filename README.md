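# waveseg

Illumination-invariant foreground detection in grayscale image sequences,
built on wavelet estimates of the illumination and reflectance components of
each frame. The target application is monitoring animals (a sow and her
piglets in a farrowing pen) on fixed cameras where background subtraction
normally fails: lamps switched on/off mid-sequence, animals that lie
motionless for long stretches, and bedding that gets pushed around.

## Method

Each frame is modelled as `f(x,y) = i(x,y) · r(x,y)` — a smooth, temporally
volatile illumination field times a textured, temporally stable reflectance
field. Two estimators separate the factors:

* **Homomorphic wavelet filter (HWF).** In log space the model is additive.
  An undecimated dyadic spline wavelet transform (J = 3 levels) isolates the
  coarse plane `S_J log f`; a Butterworth high-pass gain
  `H = 1/(1 + (D0/D)^(2n))` (D0 = 0.95, n = 2) strips the residual smooth
  content from the detail planes, and the inverse transform yields the
  log-domain illumination estimate `Ĩ`.
* **Wavelet-quotient image (WQI).** `WQI = Diffuse(f) / max(S_J f, ε)`, a
  Perona–Malik-diffused copy of the frame divided by its own wavelet coarse
  plane: the smooth illumination cancels, leaving a reflectance estimate.

Detection against a fixed reference frame then proceeds per frame: a
texture-difference rate (TDR, in [0, 2]) computed from level-J wavelet
gradient vectors flags where the local texture truly changed (TDR is blind
to pure illumination gain); a virtual image
`exp(α · (Ĩ_c − Ĩ_r) + log(WQI + 1)) − 1` with `α = 2` on texture-changed
pixels brightens foreground relative to background; exact 1-D k-means
(k = 3) on that image gives a foreground mask, an Otsu-thresholded modulus
difference (MMD) gives a boundary mask, and morphological combination
(close, subtract, unite, remove small components, keep the largest, fill
holes) extracts the animal with area, centroid and orientation.

The package also ships a Butterworth homomorphic baseline (BHPF), an
adaptive Gaussian-mixture background-subtraction comparator, pixel-level
metrics (MSE/PSNR, confusion counts, precision, ROC, IoU), and a seeded
synthetic farrowing-pen scene generator with full ground truth, so every
claim is testable offline.

## Worked example

```r
library(waveseg)

scene <- generate_scene(scene_spec(seed = 1))   # 64 empty + 60 sow frames, 256x256
cfg   <- pipeline_config()
run   <- run_pipeline(lapply(scene$frames[1:5], `[[`, "image"),
                      scene$reference$image, cfg,
                      truth = lapply(scene$frames[1:5], `[[`, "animal_mask"))
run$metrics[, c("frame", "psnr", "iou", "area", "centroid_r", "centroid_c",
                "orientation_deg")]
#>        frame psnr   iou area centroid_r centroid_c orientation_deg
#> 1 frame_0001 27.1 0.883 6068        139       80.9            23.4
#> 2 frame_0002 27.1 0.873 5994        138       82.6            23.5
#> 3 frame_0003 27.1 0.877 6034        138       84.0            23.4
#> 4 frame_0004 27.1 0.873 6015        137       86.3            22.6
#> 5 frame_0005 27.1 0.884 6067        137       87.8            23.0
```

Each row is one processed frame: the PSNR of the HWF-filtered image against
the frame, the IoU of the extracted mask against the ground-truth sow mask
(~0.88 here), and the shape features — the generator places a sow of true
orientation 25° whose centroid drifts rightward, which the `centroid_c` and
`orientation_deg` columns track.

The two estimators can be checked against the generator's ground truth
directly (a background-only scene under a spotlight field):

```r
sc <- generate_scene(scene_spec(size = c(128, 128), n_warmup = 0, n_frames = 1,
      lamp_events = NULL, animal = NULL, piglets = NULL, seed = 1,
      illumination_field = list(type = "spot", amplitude = 0.3)))
fr <- sc$frames[[1]]
mean((fr$image - fr$true_illum)^2)                          # 59.9
mean((hwf_filtered_image(fr$image) - fr$true_illum)^2)      #  8.0
cor(as.vector(fr$image), as.vector(fr$true_refl))           # 0.547
cor(as.vector(wavelet_quotient(fr$image)),
    as.vector(fr$true_refl))                                # 0.921
```

The HWF estimate is ~7× closer to the true lighting field than the raw
frame, and the WQI correlates far more strongly with the true reflectance.

A thin command-line front end is installed as `exec/waveseg`
(`waveseg run|synthgen|eval|compare`), with flags mirroring
`pipeline_config()` and YAML config support.

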