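---
title: "Prototype-part attention: model, training, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-part attention: model, training, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protopart)
```

This vignette documents the science inside `protopart`: the model and its
assumptions, the three-stage training procedure, the synthetic phantom study
used to exercise it, the numerical choices, and the places where the design
was genuinely open and a decision had to be made.

## The model

An image is mapped by a convolutional feature extractor to a latent grid of
depth $D$: one code vector per spatial cell, each describing one local image
part. The model also owns $m$ *feature patterns* (prototypes) per class —
latent vectors of the same depth, each ultimately anchored to a real patch
of a reference *push* image. For prototype $p$ and latent patch $z$ the
similarity is

$$\mathrm{sim}(z, p) = \log\frac{\lVert z - p\rVert^2 + 1}
                                {\lVert z - p\rVert^2 + \varepsilon},$$

strictly decreasing in the squared distance, equal to
$\log(1/\varepsilon)$ at distance zero. Evaluated over all cells it yields
the prototype's *activation map*; the spatial maximum is its pooled score.
Class logits are formed from each class's ten highest-scoring prototypes,
weighted by non-negative class-connection weights; the prediction is the
argmax. Because a logit is literally a sum of (similarity × weight) terms
over visualizable parts, the same arithmetic that classifies the image is
shown to the user as the local explanation.

Key assumptions: (i) class identity is expressed in *local* textures that a
depth-$D$ code at one grid cell can capture; (ii) background and healthy
tissue carry no class information; (iii) a bounded latent space (the final
add-on layer is a sigmoid) in which prototypes and patches live in the same
unit box.

## Three-stage training

1. **Warm-up** — only the two add-on 1×1 layers and the prototype vectors
   train; the base stack and the class connections are frozen.
2. **Joint stage** — all convolutional layers train, the base at a small
   rate (it is treated as pretrained), under
   $\mathrm{CE} + r_1\,\mathrm{Clst} + r_2\,\mathrm{Sep}$.
   The cluster term is the batch mean of each image's smallest squared
   patch–prototype distance over *same-class* prototypes; the separation
   term is minus the same quantity over *other-class* prototypes.
3. **Projection + convex stage** — at scheduled epochs each prototype is
   replaced by its nearest same-class latent patch of the push set
   (recording source image and location), then the class connections are
   re-fit by full-batch gradient descent on cross-entropy with an L1
   penalty on cross-class weights, after which cross-class weights are
   clamped to exactly zero and same-class weights to be non-negative.

The optimizer is plain momentum SGD (momentum 0.9), with per-group
gradient-norm clipping (base / add-on / prototypes separately): near a
projected prototype the similarity gradient enters a $1/\varepsilon$ regime
and would otherwise drown the convolutional layers' signal under a global
clip.

### Backbone pretraining

The schedule above presumes the base stack starts from informative
features, protected by its small learning rate. When no pretrained
checkpoint is available, `pretrain_backbone()` plays that role: it trains
the backbone with a temporary global-average-pooling linear head whose
weights are re-fit to ridge-penalized optimality (via `glmnet`) at every
epoch, so the residual classification signal flows into the features rather
than into an overfit head. Without this stage, the similarity transform's
gradient — about $-0.009$ at squared distance 10 — is too weak to organize
random features through the prototype bottleneck at realistic epoch counts.

### Prototype initialization from the push set

Feature patterns are produced by the model from the push dataset; the
initializer `init_prototypes_from_push()` realizes that directly. Every
brain-area latent patch of every push image receives a *class-uniqueness*
score: its smallest squared distance to any patch of the other class's push
images (the quantity the separation loss maximizes). Each class's
prototypes start at *typical exemplars* — medoids among the top decile of
uniqueness, at most one per push image. Two measured failure modes motivate
the two halves of this rule. Random initialization lets the min-of-min
cluster dynamics collapse all prototypes onto class-shared codes (healthy
tissue, background), which are the densest clusters in code space; and
picking maximally unique patches alone selects extreme part variants that
other images of the class fail to match closely, which leaves explanation
rankings fragile. Medoids of the unique pool are both class-pure and
representative.

### Brain-area patch restriction

The cluster/separation minima and the projection search run over patches
whose receptive-field center lies on brain tissue and whose receptive field
does not cross the image frame. Skull-stripped images have exactly-zero
backgrounds, so cells that see only background produce image-independent
codes — exact absorbing states for the cluster minimum (a prototype parked
there has zero gradient forever); cells that see the zero-padding boundary
carry frame artifacts with the same property. Restricting the *training*
patch set to brain-area, frame-interior cells removes these attractors;
inference (similarity maps, pooled scores, explanations) always uses all
patches.

## The phantom generator

`generate_dataset()` draws two-class 2-D "lesion phantoms" with
ground-truth lesion and brain masks. Class A mimics an aggressive,
ring-enhancing lesion: a bright enhancing annulus (+0.45 relative to
tissue), a dark heterogeneous core (−0.22 with pixel noise), and a wide dim
halo (−0.12). Class B mimics an indolent lesion: a homogeneous mid-bright
disk (+0.16) with a smooth dark cystic center (−0.40). Lesions are large
(radius 0.13–0.22 of the image side), as in diagnostic glioma slices, and
placed with an intraparenchymal margin inside a randomized brain ellipse.

Class-independent nuisance gives the generator its teeth: per-image tissue
level and contrast gain, a smooth bias field, coarse parenchymal texture,
dark ventricle-like blobs, and pixel noise. These are calibrated so the two
classes' global intensity statistics (mean, SD after z-scoring) overlap
strongly — a global-statistics shortcut then cannot reach low training
loss, and the only reliable class signal is local part texture, which is
the regime this architecture targets. A deliberately trivial check remains:
the fraction of lesion pixels brighter than 0.8 separates the classes
perfectly (the enhancing ring guarantees it), so the classification task is
learnable by construction.

What the phantoms do *not* emulate: 3-D anatomy, MR physics, partial-volume
and motion artifacts, multi-sequence contrast, and inter-rater ambiguity of
real lesion boundaries. Passing the phantom study therefore shows that the
implementation recovers part-level structure under controlled conditions;
it does not certify performance on clinical data.

## The desk-scale study

`run_phantom_experiment()` runs the whole chain at a size chosen to train
in minutes on one CPU: 100 training and 30 test images per class at 64×64,
30 push images per class, 10 prototypes per class, 6 pretraining epochs,
and a 16-epoch three-stage schedule with pushes after epochs 10 and 16. The
`tiny` backbone (two conv blocks, 16×16 latent grid, 10-pixel receptive
field) keeps individual lesion parts resolvable: with receptive fields much
larger than a part, no cell sees a pure part texture and part-level
attention is geometrically impossible. Learning rates follow the reference
schedule (3e-3 for add-on layers and prototypes, 1e-4 for the pretrained
base, 1e-4 for the convex stage).

Evaluation mirrors the published protocol at phantom scale: held-out
accuracy; *prototype validity* (the self-activation peak of each projected
prototype lies inside its source image's lesion mask — background-invalid
prototypes are sub-classified as brain- vs image-background and can be
excluded before local analysis); and *reliability screening* of individual
predictions (correct, all top-10 patterns from the image's class, all
top-10 activation peaks inside the lesion mask). Across seeds 1–3 the study
reaches held-out accuracy 1.00, validity 1.00, and reliable-correct
fractions of 0.68–0.93 — and re-pointing half of one class's prototypes at
brain-background patches collapses the reliability rate to zero while
accuracy barely moves, which is precisely the screening property the
architecture claims: reliability flags models (or predictions) that are
right for the wrong reasons.

Note a structural property of the scaled-down setting: with 10 prototypes
per class, the "all top-10 same-class" criterion requires *every*
same-class prototype to outrank *every* other-class one, which is harsher
than the same criterion over the ~44 per class that survive QC at full
scale. The reliability fractions here are therefore conservative.

## Numerical choices and edge cases

* $\varepsilon = 10^{-4}$ in the similarity transform (configurable); the
  transform is evaluated before the spatial max (equivalent under
  monotonicity, asserted by the oracle tests).
* Argmax tie-breaks are row-major first-occurrence everywhere; exact logit
  ties return the first configured class and emit a message.
* Cluster/separation use population minima of squared distances; loss
  weights default to $r_1 = 0.8$, $r_2 = 0.08$.
* Class connections initialize at +1 (same class) and −0.5 (cross class);
  the convex stage zeroes the negatives, so every explained model uses
  positive evidence only.
* Z-scoring uses the population SD over brain pixels; background stays
  exactly 0. Constant-brain images raise an error.
* Masks are resized/warped with nearest-neighbour, images bilinearly, with
  one shared geometric map per augmentation.
* PNG export quantizes to 8 bits by per-image min–max; round trips agree to
  1/254.
* Sample (n−1) SDs in the reliability summary tables; zero-difference
  pairs are dropped in the signed-rank test, which is reported as undefined
  when all pairs tie.

## Known limitations

* Two classes only in v1; prototypes are 1×1 in latent space.
* The reliability criteria are all-or-nothing over ten rows; a single
  borderline row flips the verdict.
* Bit-exact reproducibility holds with single-threaded BLAS; multithreaded
  BLAS introduces reduction-order noise of about 1e-6 per pass, which the
  tests accommodate with tolerances.
* The 6228-image ambiguity of the reference pipeline (whether originals
  accompany the six augmented copies) is configurable
  (`preprocess.include_originals`, default true).
* VGG16-scale backbones are implemented (`vgg16_random`) but training them
  from scratch at 224×224 is out of desk-scale scope; `vgg16_pretrained`
  requires a checkpoint and refuses politely offline.
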