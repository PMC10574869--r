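---
title: "Radiographic flat-foot grading: models, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiographic flat-foot grading: models, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatfootr)
```

## The clinical problem

Pes planus (flat foot) is graded on a lateral weight-bearing radiograph by
measuring angles between lines drawn through anatomical landmarks.  Three
angles carry the diagnosis here:

* **Calcaneal inclination angle (CIA)** — the pitch of the calcaneal
  inferior border against a base line from the posterior calcaneus to the
  sesamoid.  Normal 20–30°; flattening lowers it (mild 10–20°, moderate
  below 10°).
* **Meary's angle (MA)** — the angle between the talar axis and the first
  metatarsal axis; near 0° when the medial column is straight (normal
  0–4°, mild 4–15°, moderate 15° and above).
* **Arch angle (AA)** — the angle between the calcaneal inferior line and
  the fifth-metatarsal inferior line at the arch apex.  Normal 150–165°;
  a collapsing arch opens it toward and past 180° (mild up to 180°,
  moderate at 180° and beyond — a *reflex* configuration).

Manual measurement is slow and inter-rater variable, so the package
automates the chain: landmark localization → angle measurement → interval
classification → majority vote.

## The pipeline model

Nine points of interest (PoIs) are found per image: two on the first
metatarsal, two on the fifth metatarsal, two on the calcaneal inferior
border, two on the talar axis, one on the sesamoid.  Localization has two
stages:

1. **Template matching.**  Each PoI has a set of 100×100 templates with
   the landmark at the exact patch center.  Every template is slid over
   the image, scoring each start position with the normalized squared
   difference
   $$R = \frac{\sum (T - W)^2}{\sqrt{\sum T^2\,\sum W^2}},$$
   computed exactly via an FFT cross-correlation for the cross term and
   integral images for the window energies.  Lower is better; similarity
   is defined as $1-R$ so the default acceptance threshold of 0.90 reads
   directly as "90 % match".  All starts with similarity ≥ threshold
   become candidate patches (a configurable per-PoI cap, default 50,
   keeps the best by similarity for tractability).
2. **Classifier re-ranking.**  A 9-class Random Forest (100 trees, seed
   42) is trained on feature vectors of ground-truth-centered patches
   plus jittered copies (default ±8 px).  Each candidate receives the
   forest's predicted probability of belonging to its own PoI class; the
   candidate with the highest likelihood wins, exact ties going to the
   first candidate in row-major scan order.  The landmark is the patch
   start plus (50, 50).

Angles follow from the landmarks.  CIA and MA use the two-slope formula
$\tan\theta = |m_2 - m_1|\,/\,|1 + m_1 m_2|$, which yields the acute
angle between two lines.  That formula is mathematically confined to
(0°, 90°], yet the moderate arch-angle class *requires* values of 180°
and above, so AA is measured as $180^\circ-\delta$ with $\delta$ the
signed directed angle (two-argument arctangent of cross and dot) from the
calcaneal inferior direction to the fifth-metatarsal inferior direction.
The sign convention is frozen in one place: a raised arch yields AA
below 180°, a collapsed arch at or above it, and the phantom generator
realizes ground truth with the same constant.

Each angle votes a severity class via the interval table
(`foot_intervals()`); the final diagnosis is the class with the most
votes.  The printed table leaves two gaps, which the package closes in
the direction of the accompanying prose: AA mild spans the full open
interval (165, 180), and MA mild extends to (but excludes) 15 where
moderate begins; at the shared CIA boundary of exactly 20° the inclusive
normal row wins.  The only possible tie with three votes over three
classes is a 1-1-1 split, broken by the angle-reliability priority
CIA > MA > AA (the calcaneal inclination is the steadiest of the three
measurements, the arch angle the most error-prone) — the final class is
then the CIA's vote.  Values outside every stated interval (cavus-range
CIA above 30°, AA below 150°, negative MA) are assigned the nearest
boundary's class and *flagged*, never silently classified.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `size` | 1024 px | canonical square geometry; inputs are center-padded (intensity 0) or center-cropped, never resampled |
| `threshold` | 0.90 | minimum similarity $1-R$ for a candidate |
| `top_k` | 50 | per-PoI candidate cap, by similarity, scan-order ties |
| `templates_per_poi` | all | diverse (farthest-point) thinning of the library per PoI |
| `n_trees`, `seed` | 100, 42 | Random Forest configuration |
| `jitter`, `n_jitter` | 8 px, 4 | training-crop displacement radius and copies |
| `background` | off | adds a 10th background class (see below) |

Coordinates are 0-based throughout: x = column growing rightward,
y = row growing downward, origin at the top-left pixel — the raster
convention.  Right-foot images are mirrored about the vertical axis into
a canonical left-foot orientation before any measurement.  Brightness /
contrast adjustment is an explicit, default-off step because clinical
practice applies it only when bones are not clearly visible.

## The phantom generator

Real annotated radiographs of this kind are not publicly available, so
the package ships a synthetic phantom generator that renders five
stylized bright "bones" on a 1024×1024 black background: a calcaneus
wedge whose inferior edge realizes the CIA against a horizontal base
line to the sesamoid blob, a fifth-metatarsal shaft realizing the AA
(including reflex values), and talus plus first-metatarsal shafts
realizing the MA, split symmetrically about an 18° midfoot axis so each
bone's orientation spread stays small.  Every bone is a capsule with a
distinct mean intensity, a sinusoidal texture whose phase is anchored at
the nearer endpoint (so landmark-centered patches look alike across
phantoms despite length jitter), a linear intensity ramp that tells a
bone's two ends apart, and rounded "heads" centered on the anterior
metatarsal landmarks — rotation-invariant bulges that keep those patches
matchable across shaft orientations.  Gaussian blur (σ = 1 px) and
additive Gaussian noise (σ = 5 intensity units) emulate detector blur
and quantum mottle at a level where matching is challenged but not
dominated; both are explicit spec fields.

Ground-truth angles are *exact by construction*: the landmark
coordinates are the geometric endpoints used for rendering, so measuring
the angles from the ground truth recovers the requested values to
numerical precision, and class-targeted sampling draws all three angles
inside the target class's interval with a 0.5° margin from every
boundary (annotation-grade separation), bounding the open tails at
clinically plausible extremes: CIA moderate in [3, 9.5], AA moderate in
[180.5, 195], MA moderate in [15.5, 25].  Consequently every phantom is
class-consistent — all three angles vote its label — and a perfect
landmark oracle always reaches 100 % accuracy, which pins the
measurement half of the pipeline independently of localization.

Augmentation follows the rotation (±15°) and scaling (up to ×1.5)
scheme, applied as one similarity transform about the image center to
both pixels (bilinear, background 0) and landmark coordinates, with the
ground-truth angles carried over unchanged — similarity transforms
preserve angles between lines, and a test asserts drift below $10^{-6}$
degrees.  Draws that push a landmark out of frame are rejected and
redrawn.

**What the phantoms do not emulate:** soft tissue, trabecular texture,
exposure variation, anatomy outside the five bones of interest, overlap
of superimposed structures, pediatric or rigid feet.  Passing tests
therefore demonstrate geometric and algorithmic correctness of the
pipeline — not radiological performance on patients.

## Numerical choices

* Score maps are clamped to [0, 1]; the normalized ratio can exceed 1
  for windows much more energetic than the template, and any such value
  is a non-match.  Zero-energy windows (black background) score the
  worst value 1 silently; an all-zero template warns.
* The FFT path is exact to ~1e-14 against a brute-force double loop;
  the suite enforces 1e-9.
* Vertical lines carry an infinite-slope marker; the two-slope formula
  handles them through the perpendicular complement, and exactly
  perpendicular lines return 90°.
* Likelihood ties compare exactly (no epsilon): the tie rule is
  positional, so introducing a tolerance would change which candidate
  counts as "first".
* Landmark coordinates stay real-valued in memory; rounding happens
  only when cropping integer-pixel patches or writing integer manifests.
* Metrics with zero denominators return `NA` (an explicit undefined
  marker) rather than 0, so averages cannot be silently inflated.

## Design decisions that were genuinely open

* **PoI-to-line pairing.**  The landmark pairs forming each clinical
  line are frozen in one internal configuration table (`angle_lines`):
  CIA = calcaneal pair 5→6 against base 5→9, MA = talar pair 7→8 against
  first-metatarsal pair 1→2, AA = 5→6 against fifth-metatarsal pair
  3→4.  Alternative pairings are a configuration change, not a code
  change.
* **CIA base line.**  The base is the line from the posterior calcaneal
  landmark to the sesamoid (5→9), not an image horizontal; the phantom
  renders that base horizontal, which makes the two readings coincide
  there.
* **9-class formulation.**  The qualified/disqualified wording of the
  patch-selection stage is realized as the per-class probability of a
  single 9-way classifier rather than nine binary models, matching a
  nine-way prediction layer.  The optional background class exists
  because negative sampling is otherwise unspecified; it samples half
  uniform far-field patches and half near-miss ring offsets just outside
  the jitter radius, which gives the forest a probability gradient that
  discounts off-landmark candidates.  It is off by default and exercised
  by the localization property test.
* **Problem sizes.**  The shipped end-to-end study uses 20
  template-source phantoms and 60 disjoint evaluation phantoms
  (20/20/20 across classes), with the library thinned to 8 templates
  per PoI by greedy farthest-point selection in patch-appearance space
  (normalized squared-difference distance), which keeps the retained
  templates spread over the geometric range of each landmark.  These
  sizes
  were chosen once as a desk-scale stand-in for the original cohort
  study; the full library is available by leaving `templates_per_poi`
  at its default.
* **Per-template score maps are cached as spectra.**  `prepare_matcher()`
  precomputes the padded, index-reversed template FFTs so that matching
  a batch of images against one library costs one forward FFT per image
  plus one inverse FFT per template *pair* (two real templates ride one
  complex transform).

## Known limitations

* The acceptance surface is synthetic; no claim is made about accuracy
  on clinical radiographs, and the headline numbers of the original
  cohort study are not reproducible without its private data.
* Laterality must be supplied (flag or manifest); the package does not
  detect it from image content.
* Only PNG/TIFF input is supported — no DICOM.
* Severe (rigid) flat foot is not a class; the method's scope is the
  flexible adult deformity.
* The classifier's localization precision is bounded by the training
  jitter radius: within ±8 px of a landmark, candidate likelihoods
  saturate and the positional tie rule decides.

## A minimal worked run

```{r, eval = FALSE}
library(flatfootr)

tds <- sample_phantom_dataset(c(normal = 2, mild = 2, moderate = 2),
                              seed = 501)
lib <- build_templates(tds$phantoms)
clf <- train_poi_classifier(dataset_landmarks(tds),
                            lapply(tds$phantoms, `[[`, "image"))

eds <- sample_phantom_dataset(c(normal = 1, moderate = 1), seed = 880)
report <- run_diagnosis(eds$phantoms[[1]]$image, lib, clf,
                        pipeline_config(templates_per_poi = 5))
report
tidy(report)
```
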