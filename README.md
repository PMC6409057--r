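# drls — dynamically regulated localized level-set segmentation

`drls` segments a single blob-like, low-contrast object (the motivating case
is a liver tumor in a CT volume of interest) with a 3D localized
region-based level set whose behavior is *regulated while it runs*: a
three-class classifier estimates whether the current contour lies inside
the tumor (probability `p1`), near its boundary (`p2`) or outside (`p3`),
and those probabilities drive

- the energy-functional weights
  `λ1 = exp((1 + p1 + p2) / (1 + p2 + p3))`,
  `λ2 = exp((1 + p2 + p3) / (1 + p1 + p2))` — both in `[e^0.5, e^2]`,
  equal (`= e`) near the boundary;
- the per-point local-window radius — 8 voxels in the near-boundary band
  `0.4 < p2 < 0.6`, growing with `|p1 − p3|` otherwise;
- the automatic choice of the initial contour: signed-distance balls at
  candidate radii (6, 10, 20, 30, 40 voxels) scored by `p2`, best one wins.

The evolving surface is the zero level set of a field `φ` (negative
inside), updated explicitly on the Dirac band with the localized
mean-separation (MS) or uniform-modeling (UM, Chan–Vese-type) force

```
F(x) = δ(φ(x)) Σ_{y∈B(x)} δ(φ(y)) [ λin (I(y)−u_x)²/A_in − λout (I(y)−v_x)²/A_out ]
```

plus curvature regularization `μ δ(φ) div(∇φ/|∇φ|)` (`μ = 0.1`), and kept
numerically stable by a reaction–diffusion scheme (no signed-distance
reinitialization). The classifier can be a small 3D CNN — four `3×3×3`
convolution blocks (batch norm, PReLU, `2×2×2` max pooling) and three fully
connected layers ending in a 3-node softmax, trained with SGD-with-momentum
(`v ← ζv − α∇ω − ηω`) — or a deterministic geometric oracle that computes
the same probabilities from a ground-truth mask, which makes the whole
pipeline testable without any training.

The package also provides a synthetic tumor-phantom generator at VOI scale
(controllable size, contrast, edge blur, texture heterogeneity, noise), the
standard evaluation metrics (DICE, VOE, RVD, ASD, RMSD in mm), NIfTI I/O,
and a command-line interface. Who it is for: researchers studying
parameter regulation in active-contour segmentation, and anyone needing a
dependency-light, fully scriptable 3D level-set baseline with a
reproducible synthetic benchmark.

## Worked example

Segment a synthetic low-contrast tumor (radius 12 voxels, contrast 40,
noise sd 10) with the geometric oracle as classifier:

```r
library(drls)

ph <- generate_phantom(phantom_spec(
  shape = c(80, 80, 60), equiv_radius = 12,
  intensity_bg = 100, intensity_fg = 60,
  edge_blur_sigma = 1, noise_sigma = 10, seed = 7))

cls <- oracle_classifier(ph$gt_mask)

sel <- select_initialization(ph$volume, candidate_radii = c(6, 10, 20, 30, 40),
                             classifier = cls)
sel$candidates
#>   radius        p1           p2        p3
#> 1      6 0.9909347 9.065302e-03 0.0000000
#> 2     10 0.5331111 4.668889e-01 0.0000000
#> 3     20 0.0000000 1.075861e-03 0.9989241
#> 4     30 0.0000000 5.025295e-16 1.0000000
#> 5     40 0.0000000 4.654818e-38 1.0000000
sel$radius
#> [1] 10

res <- evolve(ph$volume, sel$phi, energy_config(max_iter = 200),
              classifier = cls, gt_mask = ph$gt_mask)
res
#> <segmentation_result> 200 iterations, interior 6719 voxels

metric_report(res$mask, ph$gt_mask, spacing = c(1, 1, 1))
#>        dice      voe       rvd       asd      rmsd n_seg_voxels n_gt_voxels
#> 1 0.9564156 8.352828 -6.784129 0.4064475 0.6410374         6719        7208
```

The candidate table shows the initialization logic at work: the radius-10
ball sits nearest the true boundary (`p2 = 0.47`, the maximum) and is
selected. The final segmentation overlaps the ground truth with DICE 0.956;
VOE and RVD are in percent (the negative RVD means slight
undersegmentation), ASD/RMSD are mean and RMS surface distances in mm. The
per-iteration trace in `res$trace` records the regulated `λ1`, `λ2`, window
radius, probabilities, localized energy and DICE.

The same pipeline is available from the shell (see `?cli_main`):

```sh
drls phantom --n 5 --radius-range 8,14 --noise 10 --seed 1 --out-dir phantoms
drls segment --input phantoms/phantom_001.nii.gz --gt phantoms/phantom_001_mask.nii.gz \
             --voi 0,0,0,80,80,60 --classifier oracle --out seg
drls eval --seg seg/mask.nii.gz --gt phantoms/phantom_001_mask.nii.gz
```

and `train` / `predict` subcommands cover the CNN classifier. See the
methods vignette (`vignettes/drls-methods.Rmd`) for the models, the
parameter defaults and the design decisions.

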