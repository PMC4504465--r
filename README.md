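# musclefat

Automated muscle MRI fat quantification and imaging-pattern clustering.

In slowly progressive muscular dystrophies such as facioscapulohumeral
muscular dystrophy (FSHD), skeletal muscle is gradually replaced by fat.
On axial T1-weighted MR images of the thigh this infiltration is visible
as bright speckle inside the fascia-enclosed muscle compartment, but
radiological grading of it is ordinal, coarse, and saturates in severe
disease. `musclefat` implements a fully automated quantitative
alternative for researchers working with limb muscle MRI: it segments
each axial slice into subcutaneous adipose tissue (SAT), intramuscular
adipose tissue (IMAT), muscle and bone, and reports the **intramuscular
fat fraction**

```
FF = |IMAT| / (|IMAT| + |muscle|)
```

per slice and averaged over the 20 middle slices of a volume.

The segmentation pipeline is, per slice:

1. **Tissue clustering** — 3-class k-means on pixel intensities
   (Lloyd's iteration, k-means++ seeding, best of 8 restarts): dark
   background/bone/vessels, mid-grey muscle, bright fat.
2. **Morphological cleanup** — vessel lumina are closed out of the fat
   class and the thin skin rim is removed from the muscle class (disc
   structuring element, radius 3 px).
3. **Active contours** — a greedy polygonal snake (N = 50 control
   points) minimizes `ε = Σ α·E_cont + β·E_curv + γ·E_image` with
   (α, β, γ) = (0.1, 0.6, 0.3) to delineate the outer limb boundary and
   the deep fascia on binary target images derived from the tissue map.
4. **Compartments** — SAT is the fat class between the two boundaries;
   inside the fascia the IMAT/muscle separation follows the initial
   clustering; the femur (cortical shell + marrow) is detected and
   excluded. Heuristics flag slices whose SAT/IMAT delimitation is
   unreliable (severe, confluent infiltration) for manual correction,
   and manually drawn contours can be substituted per slice.

Because no real patient data ship with the package, a **synthetic thigh
phantom** generator renders T1-like slices with known ground truth:
concentric skin/SAT/muscle/bone geometry, "moth-eaten" IMAT speckle at a
controllable fraction, a proximal-to-distal infiltration gradient,
multiplicative bias field and Rician noise. Every stage of the pipeline
is validated against these phantoms.

Cohort-level tools mirror the standard analyses of visual-score studies:
k-means clustering of per-muscle visual grades into imaging patterns,
bilateral asymmetry and STIR hyperintensity summaries, ICC(2,1)
reproducibility with per-subject coefficients of variation, Spearman
correlation with exact permutation p-values and Bonferroni correction,
pooled t-tests, and a linear-vs-log R² comparison of the score/fraction
relation.

## Worked example

```r
library(musclefat)

# a 3-slice thigh phantom with 30 % infiltration
ph <- make_thigh_phantom(phantom_spec(imat_fraction_target = 0.3,
                                      n_slices = 3, seed = 7))
ph$truth$true_fat_fraction
#> [1] 0.300063 0.300063 0.300063

res <- run_pipeline(ph$volume, pipeline_config(seed = 1))
res
#> fat_fraction_result (automatic): 3 slice(s)
#>   aggregate fraction 0.3036 over slices 1-3
#>   warnings: only 3 valid slice(s) available for a 20-slice window
round(res$per_slice, 4)
#> [1] 0.3040 0.3065 0.3002
```

The estimated per-slice fractions recover the planted 0.30 ground truth
to within the pipeline's 0.02 tolerance; the warning notes that a
3-slice volume cannot fill the default 20-slice aggregation window.

Cohort side:

```r
tab <- make_cohort_scores(c(16, 10, 9), seed = 1)   # 35 patients, 1120 entries
cl  <- cluster_patients(tab, k = 3, region = "thigh", seed = 1)
table(cl$assignments, tab$true_cluster)
#>     1  2  3
#>  1 16  0  0
#>  2  0 10  0
#>  3  0  0  9
```

A command-line wrapper is installed with the package
(`system.file("cli", "musclefat", package = "musclefat")`) with verbs
`phantom`, `segment`, `manual` and `cohort`.

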