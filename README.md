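# fibroscope

Quantitative fibrosis phenotyping for Masson's trichrome stained cardiac
histology.

Regional myocardial fibrosis — such as the scarring found near the
papillary muscles of patients with mitral valve prolapse — differs between
sites not only in collagen quantity but in collagen *maturity*: established
scar is built from thick, bundled, highly branched ("assembled") fiber
networks, while early or reactive remodeling shows sparse fine fibrils.
`fibroscope` measures both from standard trichrome slides and is aimed at
cardiovascular researchers doing digital pathology on biopsy material.

The pipeline:

1. **Stain deconvolution** — per-pixel optical density
   `OD = -log10(I/255)` is unmixed by the inverse of a trichrome stain
   matrix (aniline blue collagen vs Biebrich scarlet–acid fuchsin
   cytoplasm vectors) into concentration maps.
2. **Collagen segmentation** — Otsu threshold on tissue pixels, closing,
   small-object removal; every mask carries its provenance.
3. **Fiber morphometry** — Guo–Hall thinning to a 1-px skeleton; a
   junction/endpoint/path graph per connected component gives each fiber
   its length, widths (2 × distance transform), junction count,
   continuity, straightness and orientation. Fibers with **> 30
   junctions** are classified *assembled*, the rest *fine*.
4. **GLCM entropy mapping** — windowed co-occurrence entropy (bits,
   max log₂ 64 = 6 at 8 gray levels) quantifies fibrillar disorder.
5. **Compartments** — GeoJSON endocardium/myocardium polygons restrict all
   measurements per tissue layer (plus the whole-biopsy view).
6. **Composite scoring** — per compartment, traits with group mean change
   > 20% and Mann–Whitney p < 0.05 between the peri-papillary and remote
   regions are min–max normalized and averaged equi-weighted into four
   composite fibrosis scores: **Ph-FCS** (all selected traits), **CCS**
   (content), **MCS** (morphometry), **ACS** (architecture), each compared
   between regions with an exact Mann–Whitney U test.

A synthetic trichrome study generator with exact per-fiber ground truth
(length, thickness, branch events, footprints) makes the whole pipeline
testable without patient data.

## Worked example

```r
library(fibroscope)

design <- study_design(n_patients = 6, canvas = c(256, 256), seed = 11)
bundle <- make_study(design)           # 12 samples: 6 patients x 2 regions
result <- run_study(bundle, compartments = "whole")
subset(result$results$whole$group_stats,
       score %in% c("phfcs", "ccs", "mcs", "acs"))
#>   score n_traits mean_peri mean_remote       p stars
#>   phfcs       28      6.60        1.87 0.00216    **
#>     ccs        3      5.86        1.05 0.00216    **
#>     mcs       21      6.53        2.01 0.00216    **
#>     acs        4      7.77        1.66 0.00216    **
```

Each row is one composite score on the 0–10 scale: `n_traits` selected
traits feed it, the group means show the peri-papillary group scoring
higher than the remote group (the programmed effect: thicker, denser, more
branched collagen), and `p` is the exact two-sided Mann–Whitney p-value
for 6 vs 6 samples (minimum attainable 2/924 ≈ 0.0022, shown with the
`**` < 0.01 convention).

Single-sample analysis:

```r
sample1 <- bundle$samples[[1]]
an <- analyze_sample(sample1$image, rois = sample1$rois)
length(an$traits)      # 555 quantitative fibrosis traits over 3 compartments
head(an$records)       # one row per segmented fiber
```

A thin command-line wrapper over the same functions is included at
`inst/cli/fibroscope.R` (subcommands `synth`, `segment`, `fibers`,
`traits`, `run`).

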