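# iclcentr

Centration analysis of the EVO-ICL central hole in anterior-segment images.

The EVO Implantable Collamer Lens (EVO-ICL) is a posterior-chamber phakic
lens for moderate-to-high myopia whose optic carries a 360-µm central
perforation (CentraFLOW). Because the perforation is visible through the
pupil in an ordinary slit-lamp photograph, it is the only directly
observable proxy for where the lens optic actually sits. `iclcentr`
implements the full measurement chain that turns such a photograph into
calibrated centration statistics:

1. **Segmentation** — direct least-squares (Halir–Flusser) ellipse fits of
   the limbus, the pupil and the central-hole ring, with illumination
   flattening, sub-pixel boundary refinement, and a consensus (RANSAC) fit
   for the limbus.
2. **Calibration** — absolute scale from the preoperatively measured
   white-to-white (WTW): magnification = WTW (mm) / horizontal limbus
   diameter (px). At the hole-fixed normalisation (hole = 7.5 px) one pixel
   is 48 µm.
3. **Centration records** — each centre *C* is the intersection of the
   longest horizontal and vertical diameters of its ellipse (equivalently,
   the fitted ellipse centre). With the corneal centre C_C as origin,
   +x nasal and +y superior (left-eye x negated so both eyes pool), every
   offset vector (X, Y) yields the distance

   D = (X² + Y²)^½,  Ð = D · WTW / horizontal limbus diameter

   for hole-to-cornea Ð(H-C), pupil-to-cornea Ð(P-C) and hole-to-pupil
   Ð(H-P), together with component magnitudes (ÐHx, ÐHy, ÐPx, ÐPy), signed
   hole-minus-pupil components (ÐHPx, ÐHPy) and quadrant labels
   (superior/inferior × nasal/temporal).
4. **Cohort statistics** — means ± SD, quadrant count/percentage tables,
   paired Wilcoxon signed-rank tests (exact, tie-aware null for ≤ 25
   nonzero pairs), Spearman rank correlations, and correlations of the
   kappa-angle (pupil-offset) components with lens position.

Because clinical photographs cannot be redistributed, the package ships a
first-class synthetic-data module: a seeded generator that samples per-eye
geometry from published cohort distributions (truncated-normal component
magnitudes coupled by a Gaussian copula to published rank correlations) and
a renderer that rasterises each eye as a slit-lamp-like grayscale image
with a ground-truth sidecar, so the whole pipeline is testable end-to-end
against known truth.

## Worked example

```r
library(iclcentr)

eyes <- sample_cohort(cohort_params(n_eyes = 89), seed = 2026)
rec  <- compute_distances(eyes)        # ground-truth centration records
s    <- summarize_cohort(rec)
s
```

```
Centration summary of 89 eyes

  d_hc_mm  0.41 +/- 0.14 mm (range 0.18 ~ 0.78)
  d_pc_mm  0.45 +/- 0.14 mm (range 0.06 ~ 0.92)
  d_hp_mm  0.36 +/- 0.23 mm (range 0.04 ~ 1.01)
  dhx_mm   0.17 +/- 0.10 mm (range 0.00 ~ 0.42)
  ...
  hole vs cornea:
    superior-nasal      44 (49.44%)
    superior-temporal   41 (46.07%)
    inferior-nasal       2 (2.25%)
    inferior-temporal    2 (2.25%)
  ...
  Wilcoxon signed-rank:
    D(H-C) vs D(P-C)   V = 1426, p = 0.018
    DHx vs DPx         V = 278, p < 0.001
    DHy vs DPy         V = 2719, p = 0.003
```

`d_hc_mm` is the calibrated distance from the central hole to the corneal
centre: on this simulated cohort the hole sits on average 0.41 mm from the
corneal centre and 0.45 mm would be obtained for the pupil centre — the
hole tracks the corneal centre more closely than the pupil does, and the
x-axis components differ strongly (`DHx vs DPx`, p < 0.001), the same
qualitative picture reported for real cohorts. `tidy(s)` and `glance(s)`
return the table and headline row as tibbles; `autoplot(s)` draws the
quadrant chart and `plot_centration(rec)` the scatter of hole positions.

The image path works the same way, one eye at a time:

```r
eye <- sample_cohort(cohort_params(n_eyes = 1), seed = 7)
r   <- render_eye(eye, render_config(), seed = 7)   # matrix + ground truth
m   <- measure_eye(r$image, wtw_mm = eye$wtw_mm, laterality = eye$laterality)
m[, c("cx_hole_mm", "cy_hole_mm", "d_hc_mm", "quad_hc")]
```

or in bulk through the YAML-configured pipeline (also available as a shell
script in `inst/cli/iclcentr.R`):

```r
cfg <- run_config(overrides = list(seed = 1, out_dir = "run",
                                   cohort = list(n_eyes = 20)))
run_simulate(cfg)   # images/, cohort.csv, ground_truth_px.csv, manifest
run_measure(cfg)    # records.csv
run_report(cfg)     # summary.json, summary.md
```

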