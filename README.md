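# mandicort

Computer-aided assessment of mandibular cortical bone on dental panoramic
radiograph ROIs, for osteoporosis and osteopenia screening research.

Low bone mineral density shows up on a panoramic radiograph as a thinner,
more porous cortical band along the inferior mandibular border. Given a
pair of 128×128 grayscale ROIs cropped below the left and right mental
foramen, `mandicort`:

1. enhances the band with a **multiscale line operator**
   (`S(x) = max_θ [mean along an oriented segment] − [neighbourhood mean]`,
   computed over a Gaussian pyramid and fused by pixelwise maximum), then
   multiplies the ROI by the normalized response to keep gray information;
2. segments the cortical band by **seeded statistical region merging**: a
   gradient-watershed over-segmentation, automatic selection of a bright
   central object seed and a dark peripheral background seed, then
   iterative merging of regions into the two classes by the absolute
   difference from the class's area-weighted mean gray;
3. measures the **mandibular cortical width (MCW)**: the mask's upper
   border is fitted with the polynomial (degrees 1–5, chosen by
   cross-validated least squares) and width is the distance marched from
   each border point along the inward normal of the border tangent —
   perpendicular thickness, not column height;
4. extracts a **porosity texture feature**: mean of the
   percentile-normalized image over the cortical mask;
5. classifies subjects into normal / osteopenia / osteoporosis with a
   one-vs-one **RBF-SVM** on the 8-feature vector (min/max/avg width ×2
   sides, texture ×2 sides) under stratified k-fold cross-validation with
   an inner hyperparameter grid;
6. evaluates with **ME** (misclassification error) and **RAE** (relative
   foreground area error), 3-class confusion matrices, and binary
   low-bone-density diagnostics (sensitivity, specificity, likelihood
   ratios with exact CIs).

Because no patient images ship with the package, a **phantom generator**
renders class-conditional ROI pairs (bright curved band of known constant
perpendicular thickness, trabecular texture, punched porosity holes,
illumination gradient, noise) with ground-truth masks and widths, so the
whole pipeline can be exercised and audited end to end.

## Worked example

```r
library(mandicort)

# one synthetic subject with ground truth
rec <- generate_phantom_pair("osteoporosis", seed = 5)
rec$right_roi
#> <roi_image 128x128 side=right id=phantom_osteoporosis_5_R gray=[24, 183]>

mask <- segment_cortical(rec$right_roi)
misclassification_error(rec$right_mask, mask)
#> [1] 0.00958252

m <- measure_side(rec$right_roi, mask)
c(true = rec$true_widths$right[["avg"]], measured = m$avg)
#>     true measured
#> 28.57587 28.85119

tex <- mean_cortical_intensity(normalize_intensity(rec$right_roi), mask)
round(tex, 1)
#> [1] 222.7
```

The segmentation disagrees with ground truth on 1.0% of pixels, and the
measured average cortical width (28.9 px) recovers the generated
perpendicular thickness (28.6 px) within ~1% — the width is measured
perpendicular to the fitted border tangent, so it stays accurate even
where the band is tilted or curved.

A whole study, from a manifest of ROI files to the cross-validated
accuracy table:

```r
man   <- generate_dataset(68, 38, 17, seed = 7, out_dir = "phantoms")
feats <- pipeline_features(man, use_gt_masks = FALSE)  # segments on the fly
res   <- pipeline_classify(feats, seed = 7)
res$summary          # rows k = 2,3,5,10 + Average; accuracy % per feature set
res$confusion        # 3-class confusion matrix of held-out predictions
res$diagnostics      # low-bone-density sensitivity/specificity/LRs
```

A thin command-line wrapper with `generate`, `segment`, `features` and
`classify` subcommands is installed at `inst/cli/mandicort.R`.

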