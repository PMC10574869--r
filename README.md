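# flatfootr

Automated grading of pes planus (flat foot) severity from lateral
weight-bearing foot radiographs, for researchers and tool-builders in
musculoskeletal image analysis.

A lateral foot X-ray carries three angles that clinicians read off by
hand: the **calcaneal inclination angle** (CIA, the pitch of the
calcaneal inferior border against the base line to the sesamoid; normal
20–30°), **Meary's angle** (MA, between the talar and first-metatarsal
axes; normal 0–4°), and the **arch angle** (AA, between the calcaneal and
fifth-metatarsal inferior lines; normal 150–165°, opening past 180° as
the arch collapses). `flatfootr` finds the nine landmarks (PoIs) that
define those lines by normalized squared-difference template matching,

```
R(Sx, Sy) = Σ(T − W)² / sqrt(ΣT² · ΣW²),   similarity = 1 − R,
```

keeps every patch with similarity ≥ 0.90 as a candidate, re-ranks the
candidates with a 9-class Random Forest (100 trees, seed 42) and takes
the maximum-likelihood patch per landmark (ties: first in scan order).
Each measured angle votes a severity class against published degree
intervals, and the majority vote — CIA > MA > AA on a three-way split —
is the final diagnosis: *normal*, *mild*, or *moderate* flat foot.

Because annotated clinical radiographs of this kind are private, the
package also ships a **synthetic phantom generator**: stylized
five-bone lateral-foot images with exact, class-consistent ground-truth
landmarks and angles, plus the rotation/scaling augmentation scheme.
Everything downstream — template libraries, classifier training,
end-to-end evaluation, the threshold sweep — runs on phantoms out of the
box.

## A worked example

```r
library(flatfootr)

# six template-source phantoms, two per class
tds <- sample_phantom_dataset(c(normal = 2, mild = 2, moderate = 2),
                              seed = 501)
lib <- build_templates(tds$phantoms)          # 54 templates, 9 PoIs
clf <- train_poi_classifier(dataset_landmarks(tds),
                            lapply(tds$phantoms, `[[`, "image"))

eds <- sample_phantom_dataset(c(normal = 1, moderate = 1), seed = 880)
report <- run_diagnosis(eds$phantoms[[1]]$image, lib, clf,
                        pipeline_config(templates_per_poi = 5))
report
#> <foot_report> ph001_normal
#>   CIA 29.66  AA 160.77  MA 2.04
#> <foot_diagnosis> final: normal
#>   votes:  cia=normal  ma=normal  aa=normal
```

The three angles land inside the normal intervals (CIA 29.7° in
[20, 30], AA 160.8° in [150, 165], MA 2.0° in [0, 4)), every angle votes
*normal*, and the unanimous vote is the final class — matching the
phantom's generator label. `tidy(report)` returns the same content as a
one-row tibble; `plot_radiograph(img, report$landmarks)` overlays the
selected landmarks.

Evaluating a whole dataset reproduces the familiar report layout —
per-class precision/recall/specificity/accuracy/F-score, per-angle
error rates, overall accuracy, mean localization score `1/(1+d)`:

```r
ev <- evaluate_dataset(eds, lib, clf, pipeline_config(templates_per_poi = 5))
glance(ev)
autoplot(ev)
```

A thin CLI over the same functions lives at
`inst/scripts/flatfoot-cli.R` (subcommands `simulate`, `templates`,
`train`, `diagnose`, `evaluate`, `sweep`).

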