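# lbseg — shape-prior lattice-Boltzmann segmentation

`lbseg` segments small, low-contrast objects in 2D grayscale images — the
motivating case is the hippocampus on sagittal MR slices, whose boundaries
are partly invisible — by combining two models:

1. **A deep belief network (DBN) shape prior.** A stacked pair of
   restricted Boltzmann machines is trained by contrastive divergence on
   (image, mask) pairs: the first RBM maps the image `v` to features
   `h1`; the top RBM models the joint distribution of `(h1, L)` under a
   hidden layer `h2`, where `L` is the full pixel-wise label map. Given a
   new image, blocked Gibbs sampling on the top RBM (with the image
   evidence held in `h1`) infers a patient-specific binary shape mask.
2. **A D2Q5 lattice-Boltzmann (LB) active contour.** The inferred mask
   initializes a level-set field `phi` (negative inside) and defines a
   two-valued prior field `psi`. The contour then evolves to minimize

   `E(phi) = lambda * Lg(phi) + alpha * Ag(phi) + mu * S(phi, psi)`

   — an edge-weighted length term, an edge-weighted region (balloon)
   term, and the shape distance `S = sum (H(-phi) - H(-psi))^2` — via BGK
   collision and streaming on a five-direction lattice. The curvature
   diffusion is carried by the relaxation time
   `tau = 5 * lambda * g * delta_eps(phi) + 1/2` and the balloon + shape
   forces are injected during collision; the macroscopic limit is
   `dphi/dt = div((2/5)(tau - 1/2) grad phi) + F`. Defaults follow the
   classic weights `lambda = 10`, `alpha = 0.5`, `mu = 50`.

Because the prior is inferred per image, no label alignment or
shape-to-target registration is needed, occlusions and missing parts are
bridged by the prior, and the contour starts so close to the target that
the evolution converges in a handful of iterations.

The package also ships the synthetic fixture generators used by its
reference studies (ellipses with occlusion/missing parts, fish
silhouettes, banana-shaped blobs with weak boundary segments, all with
rotation augmentation), and agreement metrics (Dice, ICC(2,1),
Bland-Altman).

## Worked example

Train a shape model on the seven rotations of one ellipse, then segment a
partially occluded version of it — the prior bridges the occlusion, while
without the shape term the contour stops at the occluding bar:

```r
library(lbseg)

base  <- make_ellipse(axes = c(20, 12), seed = 1)      # truth: 749 px
model <- train_on_rotations(list(base), study_dbn_config("light"),
                            seed = 42)

occ <- make_ellipse(axes = c(20, 12), mode = "occluded", seed = 9)
cfg <- run_config(dbn = study_dbn_config("light"), seed = 7)
ab  <- ablate_shape_term(occ$image, model, occ$truth, cfg)

ab$with_prior
#> <lbseg_segmentation> mask area 749 px, 6 LB iterations, 200 Gibbs sweeps
round(c(with = ab$dice_with, without = ab$dice_without), 3)
#>    with without
#>   1.000   0.907
```

Dice 1.000 against the *full* ellipse truth: the inferred prior restores
the occluded part exactly, and the evolution settles in 6 iterations
because the initial contour already sits on the object edge. With the
shape term ablated (`mu = 0`) the contour leaks around the occluding bar
and Dice drops to 0.907.

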