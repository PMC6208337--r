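# msi3d

3D MALDI mass spectrometry imaging (MSI) analysis for serially sectioned
tissue, built around the spatiotemporal lipid chemistry of spinal cord
injury: long-chain acylcarnitines lining the lesion margin,
lysophosphatidylcholines and the heme b hemorrhage marker filling the
lesion core, and phosphatidylcholines defining healthy gray and white
matter.

The package implements the full analysis chain:

* **imzML I/O** — continuous and processed mode, with CSV/TIFF/NRRD
  exports for derived artifacts;
* **preprocessing** — baseline removal by the iterative min-of-smoothed
  convolution `b_{k+1} = min(b_k, b_k * G)` and total-ion-count (TIC)
  normalization;
* **peak picking** — orthogonal matching pursuit (OMP) over unit-norm
  Gaussian atoms with the linear resolution model `σ(m/z) = a + b·m/z` on
  the study mean spectrum, then per-pixel centroid-matching feature
  extraction;
* **spatial segmentation** — bisecting k-means (Euclidean metric,
  k-means++ restarts) with a divisive tree and depth cutting;
* **statistics** — Pearson co-localization against ion images or region
  masks, ROC AUC by the Mann–Whitney midrank identity for discriminative
  ions (with balanced reference subsampling), and grouped mean ± z·SD
  summaries with outlier flagging;
* **3D reconstruction** — automated rigid serial-section registration
  (rotation search + phase-correlation translation, NCC scoring), scalar
  ion volumes `D(x, y, z)`, virtual dissection along arbitrary planes, and
  multi-channel composites with maximum-intensity projections;
* **annotation** — molecular-formula parsing, monoisotopic adduct m/z
  (`[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+Li]+`, `[M]+.`), and matching of
  detected peaks against a bundled lipid candidate table. The calculator
  reproduces the canonical assignments: AC(16:0) 400.3, AC(16:1) 398.3,
  AC(18:1) 426.4, tetradecanoylcarnitine 372.3, lysoPC(16:0) 518.3 and
  lysoPC(18:1) 544.3 (sodiated), heme b 616.2, PC(16:0/20:4) 820.5
  (potassiated);
* **a synthetic phantom** — 3D spinal-cord studies with a butterfly gray
  matter, a "turnip"-shaped lesion shell whose margin thickens caudally,
  time-dependent lesion extent, baseline drift, TIC variation, noise and
  known per-section rigid misalignments, with complete ground truth. The
  default design is 36 sections × 3 segments (R1, L, C1) × 3 time points
  (days 3, 7, 10) = 324 sections.

See the methods vignette (`vignettes/msi3d-methods.Rmd`) for the models,
parameter meanings and design decisions.

## Worked example

```r
library(msi3d)

# a reduced day-3 phantom: 3 segments x 3 sections, 32 px grid
cfg <- phantom_config(grid_size = 32, sections_per_segment = 3,
                      timepoints = 3, mz_range = c(350, 900),
                      mz_bin_width = 0.1, seed = 11)
sim <- generate_study(cfg)

study <- preprocess_study(sim$study)
ms    <- remove_baseline(mean_spectrum(study), study$mz)
peaks <- detect_peaks_omp(ms, study$mz)
feats <- align_to_mean(study, peaks)

# annotate detected peaks against the bundled lipid table
head(match_peaks(peaks)[, c("peak_mz", "name", "adduct", "error_da")], 4)
#>    peak_mz                            name adduct      error_da
#> 1 372.3104 Tetradecanoylcarnitine AC(14:0) [M+H]+ -0.0004580030
#> 2 398.3271  Palmitoleoylcarnitine AC(16:1) [M+H]+  0.0006190278
#> 3 400.3423     Palmitoylcarnitine AC(16:0) [M+H]+  0.0001425632
#> 4 426.3563      Elaidic carnitine AC(18:1) [M+H]+ -0.0015305647

# which ions co-localize with the lesion margin?
margin <- as.numeric(truth_labels(sim$truth) == "lesion_margin")
head(pearson_colocalization(feats, margin), 4)
#>     center         r rank zero_variance
#> 1 400.3423 0.9672648    1         FALSE
#> 2 398.3271 0.9672057    2         FALSE
#> 3 426.3563 0.9671244    3         FALSE
#> 4 372.3104 0.9667983    4         FALSE

# which ions discriminate L from a balanced R1+C1 reference?
segs <- vapply(seq_len(nrow(feats$keys)), function(i)
  study$sections[[feats$keys$section[i]]]$meta$segment, character(1))
tissue <- truth_labels(sim$truth) != "background"
iL <- which(segs == "L" & tissue)
ref <- balanced_subsample(which(segs == "R1" & tissue),
                          which(segs == "C1" & tissue),
                          length(iL), seed = 2)
head(roc_discriminative(feats, iL, ref), 4)
#>     center       auc direction  n_A  n_B
#> 1 372.3104 0.9945309         A 1937 1937
#> 2 400.3423 0.9943448         A 1937 1937
#> 3 398.3271 0.9939184         A 1937 1937
#> 4 426.3563 0.9938726         A 1937 1937
```

The four detected peaks at m/z 372.3, 398.3, 400.3 and 426.4 are assigned
to the acylcarnitine class with sub-0.002 Da mass errors; those same four
ions rank highest in co-localization with the lesion-margin mask
(r ≈ 0.97) and discriminate the lesion segment from the balanced flanking
reference almost perfectly (AUC ≈ 0.99) — the phantom's planted chemistry,
recovered end to end by the pipeline.

The same chain is available as composable pipeline stages
(`run_pipeline()`, stages `simulate`, `preprocess`, `peaks`, `segment`,
`stats`, `register`, `volume`, `annotate`) driven by a YAML configuration,
and as a thin command-line wrapper at `inst/cli/msi3d`.

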