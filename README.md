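# SlideSurv

Digital-pathology survival analysis for perihilar cholangiocarcinoma
(Klatskin tumor), as a tested R package. The pipeline mirrors the current
AI-based workflow for this tumor: whole-slide images (WSI) are tiled into
dual-resolution patch pairs, a dual-pathway convolutional network segments
tumor tissue, the network's concatenation-layer features become one
bag-of-visual-words vector per slide, and a gradient-boosted Cox model with
bootstrap-averaged risk scores relates slide-level and clinical features to
overall survival. It is written for computational pathology and clinical
biostatistics groups who want the method's machinery — patching rules,
leakage-safe feature aggregation, bootstrap evaluation — as reusable,
verifiable code rather than a one-off analysis script.

Clinical WSIs and patient tables of this kind are not publicly deposited,
so the package ships first-class synthetic generators (textured slides
with ground-truth tumor masks, patch embeddings with latent cluster
structure, proportional-hazards cohorts with known coefficients) that make
every stage testable end to end.

## The method

1. **Patching.** Slides are tiled on a non-overlapping grid at the focus
   magnification (20×, 256 px default). An Otsu threshold on the grayscale
   histogram flags background; a tile is kept iff its focus patch has
   < 50 % background. Each kept focus patch is paired with a co-centered
   5× context patch covering a 4× wider field.
2. **Segmentation.** Two encoder pathways (focus, context) produce pooled
   embeddings whose concatenation (2 × 1280 = 2560 canonical) feeds a
   per-pixel decoder. Training uses inverse-frequency class weights, Adam
   (lr 1e-4, decaying), a transfer (frozen encoders, 11 epochs) +
   fine-tune (120 epochs) schedule with early stopping, and 5-fold
   cross-validation split by slide. Pixels with probability ≥ 0.5 are
   called tumor.
3. **Slide features.** Per CV model, tumor-patch embeddings are quantized
   against a k-means codebook (k = 500); slide histograms are TF-IDF
   weighted (smooth IDF `ln((1+N)/(1+df)) + 1`, L2 per model block) and
   concatenated into a 2500-d vector, then reduced to 5 features by NMF.
   Codebooks, IDF and NMF components are fitted on training slides only.
4. **Survival.** MELD scoring
   (`9.57 ln(crea) + 3.78 ln(bili) + 11.2 ln(INR) + 6.43`, creatinine →
   4.0 under dialysis), published imputation rules, univariable Cox screen
   (P < .05) with conditional backward selection, and a gradient-boosted
   Cox model (trees with Cox partial-likelihood loss) evaluated over 1000
   patient-level bootstrap rounds: out-of-bag and held-out test patients
   are scored per round, risks averaged per patient, concordance recorded
   per round, risks split at the median for Kaplan–Meier / log-rank
   comparison, and per-round impurity importances returned as a
   distribution.
5. **Evaluation.** Per-slide accuracy / specificity / sensitivity /
   precision / F1 with exact Clopper–Pearson intervals, pooled ROC-AUC,
   and white-to-red probability heatmaps with ground truth in green.

## Worked example

Generate a slide cohort stand-in, fit the boosted-Cox stage and evaluate:

```r
library(SlideSurv)

slide <- generateSlide(slideGenParams(widthPx = 96, heightPx = 96, seed = 7))
slide
#> SyntheticSlide 96x96 px, tumor fraction 0.350 (target 0.350)

pairs <- extractPatchPairs(slide, patchGridConfig(patchPx = 16L))
pairs
#> PatchPairSet: 32 kept / 36 grid tiles, patch 16 px (20x focus, 5x context)

computeMELD(bilirubin = 1.2, creatinine = 1.01, inr = 1.0)
#> [1] 7.2144

## a 150-patient cohort whose hazard loads on the first of five features
set.seed(1)
X <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, paste0("f", 1:5)))
cohort <- generateCohort(cohortSpec(150, beta = c(1.5, 0, 0, 0, 0),
                                    baselineHazard = 0.1, censorRate = 0.02,
                                    seed = 4), X)
fit <- fitRiskModel(X, cohort, nBoot = 50L, seed = 9)
fit
#> RiskScoreSet: 150 patients, 50 bootstrap rounds; mean concordance val 0.766, test 0.828

test <- riskScores(fit)[riskScores(fit)$split == "test", ]
res <- kmLogrankSplit(test$risk,
                      cohort[match(test$patient_id, cohort$patient_id), ])
round(c(concordance = res$concordance, logrank_p = res$logrank$p), 4)
#> concordance   logrank_p
#>      0.8576      0.0000

featureImportanceDistribution(fit)$summary
#>   feature     median        q25        q75
#> 1      f1 0.59962148 0.56092659 0.63183532
#> 2      f2 0.09312193 0.07183228 0.11364467
#> 3      f3 0.11773887 0.10004352 0.14322494
#> 4      f4 0.07660539 0.05942235 0.09751573
#> 5      f5 0.10023348 0.08544632 0.12817783
```

The planted signal `f1` dominates: the held-out test concordance of the
averaged risks is 0.86, the median split separates survival sharply
(log-rank P ≈ 5e-06, printed as 0.0000 above), and `f1` carries ~60 % of
the impurity importance in every bootstrap round. On cohorts generated
with `beta = 0` the same pipeline stays at chance concordance — see the
test suite.

The segmentation stage runs the same way at desk scale
(`trainSegCV()` on 20 synthetic slides with the `tiny_cnn` backbone
reaches held-out pixel F1 > 0.9 within 20 epochs; see
`tests/testthat/test-acceptance.R`), and `vignettes/` documents every
modelling choice.

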