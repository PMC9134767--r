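---
title: "Quantifying asymmetric chromatin inheritance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric chromatin inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromasym)
```

## The biological problem

In the *Drosophila* male germ line, a germline stem cell (GSC) divides
asymmetrically into a self-renewing GSC and a differentiating gonialblast
(GB). Pre-existing ("old") and newly synthesized ("new") histones are
partitioned non-randomly between the two sets of sister chromatids:
old-histone-enriched chromatids segregate toward the stem side. The
downstream consequences measured by imaging are (i) unequal total histone
amounts between the two telophase chromatid masses, (ii) unequal
condensation of old- versus new-histone-enriched chromatin, (iii)
preferentially lagging-strand-depleted histone deposition visible on
chromatin fibers, (iv) asymmetric binding of the pre-replication-complex
licensing factor Cdc6, and (v) asynchronous S-phase entry of the two
post-mitotic daughters. Symmetrically dividing spermatogonial (SG) siblings
serve as the symmetric control throughout.

This package implements the complete quantification battery behind those
observations — nothing in it identifies cells or draws regions; cell labels
and regions of interest (ROIs) are always inputs, as they are drawn manually
in practice.

## Total fluorescence: the sum-of-slices model

For a region $s$ in a z-stack, the total background-subtracted fluorescence
is

$$F_s = \sum_{z=1}^{n} (R_{s,z} - B_{s,z})$$

where $R_{s,z}$ is the raw integrated density (sum of grey values) of the
signal circle on slice $z$ and $B_{s,z}$ the integrated density of an
*identically sized* circle drawn in a signal-free region. Two numerical
decisions matter:

* **Negative per-slice differences are kept.** The formula is a plain
  difference; clamping at zero would bias totals upward on low-signal
  slices. A warning is emitted only if the final $F_s$ is non-positive.
* **Area matching is enforced, not repaired.** The background ROI must
  rasterize to the signal ROI's pixel area within 1%; a larger mismatch
  raises an error rather than silently rescaling the background.

The sister ratio is the directed quotient $F_{\mathrm{stem}} /
F_{\mathrm{diff}}$. Nucleosome density is half the core-histone amount per
unit DNA, so between sister chromatid masses the halving factor and DNA
length cancel and the density ratio *is* the histone ratio;
`nucleosome_density_ratio()` exists to make that derivation explicit in the
provenance rather than to compute anything new.

### The asymmetry classifier

A ratio is called *asymmetric* when it exceeds the symmetric control's mean
plus one standard error, where SE uses the sample ($n-1$) standard
deviation — the convention matching "average ± SE" reporting. A ratio
exactly at the threshold is *symmetric* (strictly-greater rule). With the
published control summary for H2A in telophase (mean 1.059, SE 0.036) the
threshold is 1.095, and the published asymmetric-division mean ratio of
1.33 classifies as asymmetric:

```{r}
classify_asymmetry(1.33, control_summary = c(1.059, 0.036))
```

Figure legends round the same control to 1.06 ± 0.04; we treat the explicit
summary used in the methods text as authoritative and note the rounding
discrepancy here. Classification operates on raw ratios, not log2, matching
the worked example.

## The condensation assay

Chromosome condensation concentrates a fixed amount of histone fluorescence
into a smaller area. The per-cell pipeline is:

1. maximum-intensity project each channel;
2. crop the largest axis-aligned square inscribed in the nucleus mask
   (orientation of the "largest square" is unspecified in the source
   protocol; axis-aligned is chosen for determinism, with ties broken
   toward the smallest top-left corner);
3. rescale each channel so its minimum maps to 0 and its maximum to 65535
   (this makes the assay exactly invariant to gain and offset, i.e. to
   illumination, sample and photobleaching differences — `rescale_16bit()`
   rounds half away from zero, the behaviour of common imaging software);
4. threshold at 35% of the maximum scaled intensity. The threshold is
   integerized by `floor`, because $\lfloor 0.35 \times 65535 \rfloor =
   22937$ reproduces the published scaled threshold exactly;
5. report the **condensation parameter** (percentage of pixels *strictly
   below* the threshold) per channel, and the **compaction factor**
   $\mathrm{occupied}_{\mathrm{new}} / \mathrm{occupied}_{\mathrm{old}}$,
   where *occupied* means pixels at or above the threshold.

"Occupied area" is not defined in the source methods (only the results name
the compaction factor); defining occupied as the exact complement of the
below-threshold set uses the only threshold the protocol defines and makes
`condensation parameter + 100 × occupied/total = 100` an exact partition.

Published compaction summaries mix two conventions — averages of per-cell
ratios (e.g. 2.64) and back-transformed means of per-cell log2 factors
(e.g. $2^{1.27} \approx 2.41$) — which do not coincide. The package
reports both the factor and its log2 per cell and leaves aggregation to
`summarize_group()`, so either convention can be reproduced.

## Chromatin fibers

Fibers are measured in consecutive, non-overlapping 2 µm arc-length
segments along a user-supplied fiber axis polyline (the trailing remainder
is dropped). Within a segment, the *lagging* strand is the one with the
higher background-subtracted mean PCNA intensity; an exact PCNA tie is
flagged ambiguous and the segment is excluded, never guessed. The segment
statistic is

$$\log_2 \frac{\text{leading mean} - \text{background mean}}
              {\text{lagging mean} - \text{background mean}}$$

and segments with a non-positive subtracted intensity are flagged invalid
and counted in QC rather than imputed. `summarize_fibers()` reports
mean ± SE and a one-sample t test against the symmetric null $\log_2 = 0$.
Whether a published per-fiber value represents one segment or an average of
several is unstated; the package therefore reports per-segment values and
lets callers aggregate per fiber.

## Chromatin association and replication timing

The chromatin-bound share of a factor on a single slice (the slice with the
largest chromatin cross-section when a stack is given; ties go to the
lowest z) is

$$\text{bound ratio} = \frac{A_{\mathrm{chr}} \cdot \bar I_{\mathrm{chr}}}
  {A_{\mathrm{cell}} \cdot \bar I_{\mathrm{cell}} -
   A_{\mathrm{chr}} \cdot \bar I_{\mathrm{chr}}}$$

Both a raw and a background-subtracted variant are available (`background`
argument); the default is raw, since the source protocol does not mention a
subtraction step here.

Colocalization uses the Spearman rank correlation of pixel intensities over
a bounding box, with average ranks on ties (the conventional definition;
the tie handling of the original plugin is unstated). It is invariant under
strictly monotone transforms of either channel; constant channels are
flagged, not given a value.

Replication timing in post-mitotic sibling pairs is the log2 ratio of PCNA
or EdU total signal, GSC over GB. The log2 scale is deliberate: "negative
values" for GB-leading replication are impossible for a plain positive
ratio, so the directed quantity must be a log ratio. Nuclear size — either
the maximum single-slice area or the summed-slice area times z-step — is
the time-after-mitosis proxy, and `timing_curve()` only sorts by it, with
no smoothing.

## Statistics

* `mann_whitney()`: two-sided Mann–Whitney U (the test behind the
  "Mann-Whitney unpaired t-test" label in commercial software). The
  reported U is $\min(U_a, U_b)$. With no ties and $\min(n) \le 8$ the
  p-value is exact; otherwise a normal approximation with tie and
  continuity corrections is used. The exact branch is checked against an
  exhaustive permutation oracle in the tests.
* `one_sample_t()`: $t = (\bar x - \mu_0)/\mathrm{SE}$ with $n-1$ degrees
  of freedom, two-sided.
* Significance markers (`****` below $10^{-4}$, etc.) are annotations only;
  no multiple-testing correction is applied, matching the source reporting.

## The synthetic world

Every statistic is exercised by parameter recovery on generated images.
The generators state a fixed world; their defaults are not tuned to tests.

* **Noise model**: counts ~ Poisson(expected) plus Gaussian read noise
  (default SD 2–3 counts), rounded and clipped to the 16-bit range — the
  standard photon-plus-camera model; the source specifies none. With noise
  disabled the images carry the real-valued expectations, so noiseless
  checks are exact to floating tolerance rather than bounded by rounding.
* **Seeding**: one integer seed fans out to per-channel substreams through
  a counter scheme, so adding a channel does not perturb the others; the
  caller's RNG state is saved and restored.
* **Telophase pairs** (`pair_spec()`): two Gaussian-profile masses truncated
  at the ROI radius (12 px at 0.1 µm/px, i.e. ~2.4 µm masses), stem-side
  peak 400 counts over a 100-count background in an 8×96×96 stack — scales
  typical of spinning-disc germline movies. The default total-signal ratio
  is 1.5, the value reported for H3; truncation at the ROI radius makes the
  expected measured ratio equal the generated ratio exactly.
* **Condensation cells** (`condensation_spec()`): a chromatin disc inside a
  larger nucleus; each channel splits a photon budget between a broad
  diffuse component and six compact foci, with `cluster_fraction`
  controlling the split. Two geometric choices keep the assay's expected
  response clean: the diffuse component is a broad Gaussian rather than a
  flat plateau (a plateau makes all diffuse pixels cross the threshold at
  once, so the statistic would be a step function of the fraction), and one
  focus sits at the disc center so the image maximum stays in one place
  across the whole sweep. With the defaults (focus σ = 2 px), the fully
  clustered versus fully diffuse contrast gives a compaction factor near
  2.8, the scale reported for fixed mitotic GSCs. The new channel's
  peripheral foci are rotated half a step so the two channels are not
  pixel-identical; identical cluster fractions still give a factor within
  1 ± 0.05 after the square crop.
* **Fibers** (`fiber_spec()`): two parallel strands (3 px wide, 8 px apart
  at 0.04 µm/px — Airyscan-scale sampling) with PCNA confined to the
  lagging strand; intensities are specified above background so the
  background-subtracted log2 ratio is exact by construction.
* **Association cells** (`association_spec()`): a chromatin disc occupying
  25% of the cell area, with `bound_fraction` of the total signal placed
  uniformly on chromatin; the noiseless bound ratio is exactly
  $f/(1-f)$.

What a green recovery test establishes: the estimators are unbiased at
these noise levels and the pipeline plumbing (ROIs, rasterization,
projection, rescaling) preserves the generative signal. What it does not
establish: robustness to the features the generators deliberately omit —
real chromosome shapes, anisotropic optics beyond a Gaussian z-falloff,
sample drift, autofluorescence gradients, segmentation error in
hand-drawn ROIs, or cell-type misclassification.

## File formats and coordinates

No TIFF reader is assumed from the environment: the package carries a
minimal baseline TIFF codec (uncompressed greyscale, 8/16-bit, multi-page,
both byte orders on read). Channel names, voxel sizes and bit depth are
persisted in the ImageDescription tag as JSON, and plane-interleaved order
is assumed when that metadata is absent. The reader is validated in the
test suite against files produced by an independent implementation, frozen
as hex-encoded fixtures. CLI spec and config files are JSON for the same
reason (no YAML parser in the dependency set).

Pixels are addressed 1-based in R, with the pixel at matrix position
$(i, j)$ occupying the unit square $[i-1, i) \times [j-1, j)$ and centered
at $(i - 0.5, j - 0.5)$ in continuous ROI coordinates. A pixel belongs to a
region iff its center is inside; boundary points count as inside. Whether
background circles are redrawn per slice or shared across z is left to the
ROI's `slices` field (default: shared), since the source protocol does not
say.

## Known limitations

* No automatic segmentation, tracking, or fiber tracing; all regions are
  inputs.
* Only uncompressed baseline TIFF is supported; vendor formats (CZI/LIF)
  and compressed TIFFs must be converted first.
* The condensation assay analyses a single square window per cell; cells
  whose nucleus mask is extremely elongated will be summarized by a small
  window.
* The Mann–Whitney exact branch is limited to untied samples with
  $\min(n) \le 8$; beyond that the corrected normal approximation is used,
  as in standard software.
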