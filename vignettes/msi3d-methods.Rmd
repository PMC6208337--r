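---
title: "Methods: 3D MALDI-MSI analysis of spinal-cord-injury phantoms"
author: "msi3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D MALDI-MSI analysis of spinal-cord-injury phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`msi3d` implements a complete analysis chain for 3D MALDI mass spectrometry
imaging (MSI) of serially sectioned spinal cord: spectral preprocessing,
peak picking, spatial segmentation, co-localization and discriminative-ion
statistics, rigid serial-section registration into scalar ion volumes, and
molecular-formula based lipid annotation. Because no public MSI dataset
accompanies the biological study design the package emulates, a synthetic
phantom generator with complete ground truth (region masks, planted peaks,
per-section rigid transforms) is a first-class component: every stage of
the chain is validated against it.

This vignette documents the models, the tunable parameters and their
defaults, the design decisions taken where the underlying methods are
conventionally under-specified, and the known limitations. It states no
empirical result that the package's test suite does not itself compute.

# The phantom

## Geometry

Each section is a `grid_size × grid_size` pixel image (default 64 pixels at
40 µm). Five mutually exclusive regions partition it:

* **background** outside a circular cord boundary (radius 0.45 of the grid);
* **gray matter**: the classic "butterfly" built from four mirrored
  ellipses (two broad ventral horns, two slender dorsal horns) plus a
  central commissure band. Ellipse parameters were set so the gray:white
  pixel ratio is ≈ 0.4, visually consistent with segmented rodent cord
  sections;
* **white matter**: the remaining cord annulus;
* **lesion core** and **lesion margin**: inside the axial extent of the
  lesion, a central disk and the ring around it.

The lesion follows a "turnip" axial profile along the rostro-caudal axis.
With `t ∈ [0, 1]` the position between the rostral and caudal lesion ends,
the outer radius is `r_out(t) = (0.10 + 0.88 s(t)) R` where `s` is a
smoothstep trapezoid (`s = min(S(t/0.25), S((1−t)/0.25))`,
`S(x) = x²(3−2x)`): the distribution starts as a small dorsal spot, rises
to border essentially the whole cord girth across the central plateau, and
collapses back to a spot. The ring thickness
grows linearly from `0.14 R` at the rostral entry to `0.60 R` at `t = 0.8`
(the caudal thickening) and then collapses — so the margin is thin and
well-defined rostrally and thick caudally. The lesion center drifts
dorsally where the profile contracts, terminating at the dorsal column.

Axial extent depends on the time point: at day 3 the lesion spans all of
the lesion segment L and extends 6 % of the global axis into the caudal
end of R1 and the rostral end of C1; at days 7 and 10 it is confined to L
(insets of 4 % and 8 %). These extents, like all lesion radii, are free
parameters of the generator — the tissue literature gives verbal
descriptions, not dimensions — and their defaults were chosen to realize
that verbal description: full-girth coverage at the lesion center, small
spots at the ends, restriction to L at the later time points.

## Spectra

Spectra live on a shared m/z axis (default 300–1100 Da at 0.1 Da bins).
Each region has a template spectrum: planted peaks as Gaussian profiles
with the linear resolution model `σ(m/z) = 0.05 + 10⁻⁴·m/z` Da. Templates
are **bin-integrated** (each bin holds the profile's average over the bin),
so peak mass is conserved on axes coarser than the peak width; pointwise
sampling would silently lose sub-bin-width peaks.

The planted peak table (amplitudes in arbitrary units, peak height):

* lesion **margin**: the four acylcarnitines AC(14:0) (10), AC(16:1) (12),
  AC(16:0) (15), AC(18:1) (12) at their protonated theoretical m/z,
  computed by the package's own adduct calculator;
* lesion **core**: sodiated lysoPC(16:0) (12) and lysoPC(18:1) (10); the
  heme b radical cation, whose amplitude fades with time (10 at day 3,
  2 at day 7, 0.3 at day 10 — the hemorrhage marker disappears);
  25 % of the margin acylcarnitine amplitude (the "widespread, less
  confined to the margins" component seen caudally); and a 10–15 %
  residual of the gray/white signal;
* **gray matter**: potassiated PC(16:0/22:6) at m/z 844.5 (14) and a
  marker at 798.5 (10);
* **white matter**: markers at 768.55 (14) and 822.6 (10); the lesion
  margin retains 50 % and the core 15 % of this white signal.

The residual white-matter signal in lesion tissue is deliberate: the
margin ring sits in anatomical white matter and disruption of the lipid
content is partial, so lesion spectra resemble degraded white matter more
than gray matter. This is what makes a study-wide first clustering split
separate gray matter from a white-plus-lesion branch — the "loss of the
butterfly" appearance — rather than isolating the lesion.

On top of the weighted region mixture every pixel receives a smooth
decaying baseline (`amplitude · exp(−(m/z − m/z_min)/300)`, default
amplitude 2), non-negative noise (Gaussian truncated at zero, default
SD 0.3), and a multiplicative per-pixel TIC factor (log-normal, default
CV 0.15). Every section is finally resampled through a random rigid
transform (default at most 3 px translation and 5° rotation), recorded in
the ground truth. The ground truth stores both the ideal labels and the
*emitted* labels (the dominant region each acquired pixel actually
contains after that misalignment) with a per-pixel purity; evaluations
against ground truth use the emitted labels, since those describe what
the acquired spectra contain.

The default design is 36 sections per segment for segments R1, L, C1 at
days 3, 7 and 10 — 324 sections — with 204 µm between imaged sections
(one 12 µm section kept, 16 skipped).

# Preprocessing

Baseline removal uses the min-of-smoothed iterative convolution

\[ b_0 = x,\qquad b_{k+1}(i) = \min\{ b_k(i), (b_k * G)(i) \} \]

with a Gaussian kernel `G` (default σ = 5 Da), reflective boundaries, and
a fixed iteration count (default 30). Each iteration can only lower the
estimate, so the baseline ends below the input everywhere and settles on
the smooth envelope beneath the peaks. "Iterative convolution" is named
but not specified by the commercial software this emulates; this recursion
is a standard, monotone, parameter-light realization.

Two numerical notes:

* for whole studies the recursion is evaluated on a decimated bin grid
  (step ≈ σ/4, i.e. ≥ 4 baseline samples per kernel width) and linearly
  interpolated back; the baseline is smooth at the kernel scale by
  construction, so decimation changes the estimate by far less than the
  noise floor while cutting the cost by an order of magnitude;
* the reflective boundary mirrors a decaying baseline into an artificial
  ridge at the axis ends, so a residual bump within about one kernel width
  of each axis end is expected. Downstream peak evaluation therefore
  treats the outermost ~10 Da of the axis as an exclusion zone.

TIC normalization rescales each baseline-corrected pixel to a constant
total (default 1; only ratios matter downstream). Pixels whose corrected
spectrum is all zero are flagged and excluded from the mean spectrum,
feature extraction and statistics. The pre-normalization corrected TIC of
every pixel is retained — it is the only all-ion image that still carries
anatomical contrast after normalization.

The study mean spectrum is the arithmetic mean over non-flagged pixels.
Because the truncated noise has positive mean, the mean of corrected
spectra retains a small smooth pedestal; the peak picker's contract
expects a baseline-removed mean spectrum, so the pipeline baselines the
mean spectrum once more before peak detection.

# Peak picking and features

Peaks are detected on the mean spectrum by orthogonal matching pursuit
over a dictionary holding one unit-norm Gaussian atom per axis bin, with
σ from the same linear resolution model (defaults a = 0.05 Da,
b = 10⁻⁴). Each iteration selects the atom with the largest absolute
inner product with the residual, refits all selected amplitudes jointly by
least squares, and updates the residual — so the residual norm strictly
decreases and no atom is selected twice. Iteration stops when the
relative residual energy falls below `residual_fraction` (default 0.01) or
at `max_peaks` (default 60). Atoms whose joint amplitude is not positive
are dropped; centers are refined to the intensity-weighted centroid within
±2σ; peaks refining to within 2σ of each other are merged
(amplitude-weighted), since two Gaussians closer than 2σ do not produce
separate maxima at equal amplitudes and are unresolvable at the assumed
resolution.

Per-pixel features are extracted by centroid matching against the
mean-spectrum peaks: within ±max(0.2 Da, 2σ) of each peak center the local
maximum is located, its centroid computed, and intensity integrated
(trapezoidal) over centroid ±2σ. When a pixel shows no interior local
maximum the integral is taken at the nominal center — an honestly small
number rather than an imputed zero.

# Segmentation

Spatial segmentation is divisive bisecting k-means with Euclidean
distance: the leaf with the largest within-cluster sum of squares is split
by 2-means (k-means++ initialization, 5 restarts keeping the lowest WCSS,
Lloyd iterations) until the requested leaf count; ties in the
split-selection break toward the older node. Rows are processed in the
canonical order of their pixel keys, making the partition invariant to the
order pixels were supplied in. Leaves whose rows are identical are marked
terminal. `cut_tree()` yields the label map at any depth.

The study-wide overview protocol matters: on a single-time-point day-3
study the lesion occupies roughly 40 % of tissue pixels and no optimal
2-means split isolates gray matter — the first split then separates either
the lesion or white matter. The two-branch gray-versus-rest structure
appears when clustering all time points together, where lesion pixels are
a minority; the package's validation suite therefore evaluates depth-1
segmentation on a full three-time-point phantom, and on tissue pixels
(the measurement region in real acquisitions is the tissue).

# Statistics

Co-localization is Pearson correlation of each interval's pixel vector
against a reference — either a seed-ion image or a 0/1 region mask (the
point-biserial form); zero-variance intervals report r = 0 with a flag.
Discriminative ions use ROC AUC via the Mann–Whitney midrank identity
(exact under ties), oriented so AUC ≥ 0.5 with the higher group recorded;
the default report threshold for "discriminative" is 0.75. Comparisons of
L against the flanking segments use a balanced, seeded subsample of R1 and
C1 so that similar group sizes are compared. Grouped summaries report
per-interval mean, SD and the population band mean ± z·SD (default 95 %);
the band is an interval for observations — a standard-error band would
flag nearly every spectrum — and pixels outside it are reported as
outliers.

# Registration and volumes

Serial sections are registered rigidly (rotation + translation about the
grid center) and sequentially: each section aligns to its already
registered predecessor, because adjacent sections are anatomically most
similar; composed transforms map all sections into the first section's
frame. A single pair is solved by coarse-to-fine search: candidate
rotations (±10° in 0.5° steps, refined to 0.1°), translation per candidate
by phase correlation with quadratic subpixel refinement, candidate scoring
by normalized cross-correlation over the jointly valid region. The valid
mask of the warped predecessor is propagated into the score — resampling
borders otherwise bias the (shallow) rotation objective and the chain
drifts.

The registration image for a study is the per-pixel projection of the
spectrum onto the baseline-removed mean spectrum. This is an all-ion
content image in the same spirit as a TIC image, but broadband per-bin
noise — which integrates into a flat TIC pedestal across thousands of
bins and drowns anatomical contrast — is suppressed by the projection
weights, which concentrate on the peak-carrying bins.

Two limitations are inherent and documented rather than hidden: rotation
is unidentifiable on sections whose content is nearly rotationally
symmetric (mid-lesion sections reduced to an annulus), which is why the
registration accuracy checks run on an unlesioned stack where the
butterfly provides angular contrast; and sequential chaining accumulates
drift over very long stacks, bounded here by the phantom checks.

Ion volumes `D(x, y, z)` stack one interval's registered ion images
(trapezoidal integral over center ±2σ per pixel) at the configured
z-spacing, with optional linear inter-slice interpolation for
near-isotropic export. Virtual dissection resamples `D` trilinearly on a
regular lattice spanning an arbitrary plane (point + normal, µm); the
lattice is centered on the plane point so axis-aligned planes through
voxel centers reproduce array slices exactly. Composite rendering
min-max scales each channel, maps it to a color, adds overlapping
channels, and exports maximum-intensity projections; ray-traced emission
rendering is out of scope.

# Annotation

Formulas are parsed from Hill-like notation; monoisotopic masses use
CODATA/AME most-abundant-isotope values; adduct m/z adds the cation and
subtracts the electron mass (`[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+Li]+`,
and the radical cation `[M]+.`). The electron mass is irrelevant at
0.1 Da but kept for correctness. The bundled candidate table covers the
lipids relevant to the lesion chemistry — four acylcarnitines, three
lysoPCs (sodiated), heme b, and two potassiated PCs. The species at
nominal m/z 372.3 is listed as tetradecanoylcarnitine with formula
C21H41NO4: the saturated 14:0 species is what that mass and name imply,
although source tables sometimes label the same mass 14:1. A PC(16:0/16:0)
assignment at m/z 830.5 reported in the same literature matches no common
positive adduct of that species (the potassiated ion is 772.5, the
sodiated 756.6) and is deliberately absent from the table. Matching is
nearest-candidate within a tolerance (default 0.3 Da, TOF-appropriate),
with all candidates reported and flagged when several fall inside it.

# Reproducibility and problem sizes

Every stochastic stage draws from a seed derived by stable hashing of the
stage name from one global seed, so stages are independently reproducible
and a full pipeline run is deterministic up to manifest timestamps. The
validation suite exercises the chain on reduced phantoms chosen to keep
the full suite in the minutes range: a day-3 study at 32 px grid and
0.1 Da bins for peak picking and statistics; a three-time-point study at
0.25 Da bins for overview segmentation; a 48 px unlesioned stack at 1 Da
bins for registration; a 40 px day-3 stack at 1 Da bins for volume
reconstruction; and a 16 px, 2 Da study for the full 324-section design
(the section count is resolution-independent). Grid-size reductions
coarsen partial-volume effects at region boundaries; evaluations therefore
restrict to tissue pixels and, where stated, to pixels of ≥ 0.8 region
purity.

What passing these checks does and does not show: the phantom has
Gaussian peaks of known width, a single smooth baseline family,
independent truncated-Gaussian noise and purely rigid misalignment. Real
MALDI-MSI adds isotope envelopes, chemical noise that is structured in
m/z, matrix clusters, section tearing and non-rigid deformation, and
detector saturation — none of which are simulated. Passing the phantom
suite validates the implementation of each method under its stated model,
not the biology of any real tissue.
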