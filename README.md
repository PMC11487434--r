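# vertrot

Automated measurement of the vertebral axial rotation angle from 3D surface
point clouds of single vertebrae.

Axial vertebral rotation is a key severity parameter in idiopathic scoliosis.
Measuring it from 2D radiographs or CT slices is projection-biased and
observer-dependent; working directly on a reconstructed 3D vertebral model
avoids both. `vertrot` implements the full 3D pipeline:

1. **Sampling** — vertebral surface clouds arrive with very uneven density
   (posterior elements reconstruct much denser than the body). Plain
   farthest-point sampling (FPS) is augmented with a *distance-distribution
   entropy* term: the candidate score is

   `score(c) = d_min(c, selected) * (1 + λ·Ĥ(c))`

   where `Ĥ(c)` is the Shannon entropy `H = −Σᵢ Pᵢ log(Pᵢ + ε)` of the
   histogram of `c`'s k-nearest-neighbour distances, rescaled to [0, 1] over
   the cloud. With `λ = 0` this reduces exactly to FPS.

2. **Segmentation** — a pure-R encoder–decoder point-cloud network predicts
   the endplate and pedicle structures. Its building block is *relation
   attention*: within kNN patches, features are positionally encoded
   (`F_in = ψ(concat(f, φ(xyz)))`), self-attention
   `F_SA = softmax(QKᵀ/d_a)·V` is computed, and the residual update is
   `F_out = LBR(F_in − F_SA) + F_in` (Linear–BatchNorm–ReLU). The network has
   four FPS+max-pool downsampling stages and four mirrored interpolation
   upsampling stages with skip connections. Training uses Adam
   (lr 0.003, decay 0.5, batch 4) with softmax cross-entropy; quality is
   scored as mIoU = mean over classes of TP/(TP+FP+FN).

3. **Anatomy** — the predicted endplate cloud is split into upper/lower
   plates (K-means, k = 2) and the pedicle cloud into left/right pedicles;
   the vertebral centroid is the midpoint of the endplate centres, the
   transverse plane is normal to the endplate axis, the local frame takes
   z along that axis and y from the pedicle midpoint toward the centroid
   (anterior), and the rotation angle is the in-plane angle between the
   projections of the local and global y-axes onto the transverse plane.

4. **Agreement** — Bland–Altman limits of agreement (mean ± 1.96 SD of
   paired differences) and the two-way absolute-agreement intraclass
   correlation coefficient, single- and average-measures forms, with
   F-based confidence intervals, for validating automatic against manual
   measurements.

A synthetic vertebra **phantom** (elliptical-cylinder body, two endplate
caps, two posterior pedicles, configurable density skew, noise, and applied
axial rotation with exact ground truth) makes every stage testable without
clinical data.

## Worked example

```r
library(vertrot)

# a phantom vertebra rotated 12 degrees, measured from ground-truth labels
ph <- generate_vertebra(phantom_config(theta = 12, seed = 3))
mv <- measure_vertebra(ph$endplate_task$cloud,
                       ph$endplate_task$labels, ph$pedicle_task$labels)
mv
#> <vertebra_measurement: 12.00 deg (signed 12.00)>
#>   points: 1800 total, 700 endplate, 500 pedicle

# agreement between the automatic method and a human observer on the
# packaged 10-vertebra comparison study
tab <- rotation_study_table()
icc_absolute(tab[, c("Automatic", "Observe1")], form = "single")
#> [1] 0.9869341
mean_difference(tab[, "Automatic"], tab[, "Observe1"])$mean
#> [1] -0.472
```

The measured angle equals the applied rotation to machine precision on
noiseless phantoms; the ICC of 0.987 and the mean difference of −0.47°
say the automatic measurements agree with the first observer's to well
within inter-observer variability.

A command-line front end is included (`exec/vertrot`) with `phantom`,
`sample`, `train`, `segment`, `measure` and `agree` subcommands, each
writing machine-readable JSON reports.

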