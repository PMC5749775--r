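---
title: "Chromosomal DNA sizing by image cytometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal DNA sizing by image cytometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmkaryo)
```

## The measurement model

Feulgen staining binds stoichiometrically to DNA, so under transmitted
light the absorbance of a chromosome region is proportional to the DNA it
contains. `icmkaryo` works on this single physical assumption, in three
layers:

1. **Densitometry.** A pixel's optical density is
   $OD(p) = \log_{10}(I_0 / I(p))$, with $I_0$ the clear-field intensity.
   The integrated optical density of a mask is
   $IOD = \sum_p OD(p)\,A_{px}$, identically equal to area × mean OD.
2. **Anchoring.** Absolute calibration of stain-to-picograms is not
   attempted. Instead the nuclear 2C amount comes from flow cytometry by
   the internal-standard peak ratio,
   $2C_s = 2C_{std} \cdot ch_s / ch_{std}$, averaged over replicate runs.
3. **Allocation.** The nuclear amount is distributed proportionally to
   pair-level IODs: $2C_c = 2C_n \, IOD_c / IOD_t$, and likewise per
   arm/satellite with the same denominator $IOD_t$. Because portion IODs
   partition pair IODs by construction, arms sum to chromosomes and
   chromosomes to $2C_n$ exactly — conservation is structural, not
   approximate, and the test suite asserts it to 1e-12.

Pair-level IOD is defined as the mean over metaphases of the two
homologs' summed IOD; the reported ± values are standard deviations of
the per-metaphase allocations, i.e. they describe between-metaphase
measurement spread, not biological variation.

## Why a synthetic generator, and what it emulates

The study design this package follows reports summary statistics of 51
metaphases but no raw images, so the image-facing stages cannot be
validated against archival data. The generator therefore produces
metaphase plates with *exact* ground truth, and every claim about the
analysis chain (segmentation counts, length/CI recovery, allocation
error) is made against it.

What it emulates:

* a maize-like diploid complement — ten pairs with published per-pair 2C
  DNA (summing to 6.10 pg at printed precision), two metacentric pairs
  (1, 5), eight submetacentric (2–4, 6–10), a satellite on the short arm
  of pair 6, and one interstitial knob block (density multiplier 1.8,
  0.8 µm) on each long arm of pairs 2–9;
* Beer–Lambert imaging on a 12-bit camera (background 3000 counts,
  Gaussian read noise sd 25, optional Poisson shot noise and a linear
  illumination gradient), at 0.065 µm/px;
* stepped-density and blank calibration targets, and two-component
  Gaussian G0/G1 flow histograms with peak CVs of 3.2 / 3.8%, the
  standard landing at channel 200.

What it deliberately does not emulate: chromatin texture, point-spread
blur, cytoplasmic debris, DAPI fluorescence, per-cell condensation
differences, or biological DNA variation between homologs. Passing the
recovery tests therefore shows the chain is *correct under the stated
imaging model*, not that it is robust to every real-slide artefact; on
real material the segmentation threshold, the constriction-depth
criterion and the knob-detection ratio are the knobs a user should
revisit first.

### Geometry choices

Absolute chromosome lengths are not published for this complement — only
relative morphometry and mean per-chromosome areas (9.478 µm² down to
4.652 µm², with pair 9 larger than pair 8). Default axis lengths are
those areas divided by the default chromatid width (1.2 µm, with a small
correction for tip taper), and arm ratios are placed mid-class (1.20 and
1.30 for the metacentrics; 1.61–2.60 for the submetacentrics) so that
measurement noise cannot push a pair across a class boundary. Tips taper
elliptically to zero inside the axis span, making rendered length equal
axis arc length.

Constrictions are Gaussian width dips of 40% depth and 0.3 µm sd. A
wider dip (sd near 1 µm) merges the primary constriction with the
pair-6 secondary constriction 1.6 µm away into a single minimum and
makes the satellite undetectable, so the narrower dip was adopted; it
also sharpens centromere localisation.

### DNA bookkeeping

Each pair's DNA is spread at a uniform baseline linear density ρ
(pg/µm), frozen when the spec is built, with knob blocks multiplied by
their density factor. Rendered OD is renormalised per arm/satellite
region so that the pixel-sum IOD equals `iod_per_pg ×` the region's true
mass exactly (default 26.6 OD·µm²/pg, chosen so mean chromosome OD is
about 1.1, matching the published densitometry range). Freezing ρ makes
the knob contract clean: raising a knob multiplier on an existing spec
adds DNA mass and IOD to that arm alone, leaving the other arm
untouched.

## Image analysis choices

The source protocol ran inside a commercial package and does not
describe its algorithms, so all image-analysis steps here are the
package's own, validated against the simulator:

* **Background**: mode of non-object intensities at unit-count bins,
  with a coarse Otsu split when no mask is given — robust to dark
  objects dominating the histogram. OD at zero-count pixels is capped at
  the density of half a count and flagged as saturated (dense knobs can
  floor a 12-bit camera).
* **Segmentation**: Otsu threshold on the OD map, connected components,
  then watershed splitting (on the distance transform, merge tolerance
  stepping down from 0.5× the component's inscribed radius) of
  components larger than 1.6× the median area, or of the largest
  components when fewer objects than 2n are found. Contact necks are
  thinner than primary constrictions, so they give way first.
* **Medial axis**: the centre-weighted geodesic between the two most
  distant mask pixels (8-connected graph, edge weights step/dt), smoothed
  and prolonged along its end tangents to the mask boundary; width per
  axis sample is twice the largest distance-transform value in the
  sample's cross-section slab, minus the half-pixel edge offset.
  Validated to ≤3% median arc-length error.
* **Centromere**: global minimum of the smoothed width profile within
  the central 60% of the axis (telomeric taper creates spurious minima
  outside it); a relative dip below 5%, or a minimum sitting on the
  search-window edge, is rejected as "no constriction".
* **Secondary constriction**: searched only on the short arm, away from
  tip (0.45 µm) and centromere (0.6 µm), accepted when at least half as
  deep as the primary dip; the distal segment is the satellite.
* **Arm partition**: every mask pixel joins the axis side of its nearest
  axis sample, giving a cut locally perpendicular to the axis; submasks
  are disjoint and exhaustive by construction, so portion IODs add up
  exactly.
* **Classification**: Levan-style thresholds (m < 1.5 ≤ sm < 3 ≤ st
  < 7 ≤ t), exposed as a configurable table since revisions of the
  nomenclature differ in the exact cuts; the satellite is excluded from
  the short-arm length used for the ratio.
* **Pairing and numbering**: greedy minimum-distance matching on
  z-scored (length, CI, IOD) — DNA amount is what separates
  morphologically similar pairs; numbering either by length rank or by
  nearest-neighbour mapping to a reference table, with satellite
  presence as a near-categorical extra feature and any length-rank
  disagreement flagged (the complement's pair 9 outsizing pair 8 is such
  an inversion).

## Flow-histogram fitting

G0/G1 peaks are local maxima exceeding both 5% of the histogram maximum
and 3× the median channel count (rejecting structureless noise), refined
by Gaussian fits on ±2.5 sd windows. With peak CVs of a few percent the
standard and sample peaks share tails, so overlapping windows are
refitted jointly as a sum of Gaussians; the joint fit is accepted only if
every component stays near its candidate (guarding against collapse onto
a single broad component) and otherwise falls back to iterated windowed
moments. CV comes from the fitted sd, not raw moments, so a debris floor
does not inflate it; fits with CV > 5% would be flagged rather than
rejected, the acceptable range in this protocol being 3.0–4.1%.
On simulated histograms at the study's own (overlapping) configuration
the estimator is unbiased within Monte-Carlo error.

## Numerical and scale choices

* Replicate averaging is the arithmetic mean; sd is 0 for a single
  replicate.
* The stepped filter defaults to 11 nominal ODs of 0.1–1.1: linear in
  the step index and keeping the darkest band well above the 12-bit
  noise floor, the regime in which the linearity R² ≥ 0.999 bar is
  meaningful.
* Uniformity CV is computed on 8×8 tile means, approximating
  field-illumination CV while suppressing pixel shot noise.
* Stability requires the rolling range over a 5-min window to stay
  within tolerance from the reported time onward, for at least one full
  window.
* Reported tables round pg and 1e9-bp values to 3 decimals, mirroring
  the reference formatting; full precision is kept internally.
* Test and pipeline problem sizes — 1024² px plates, 5 metaphases in the
  demo pipeline, 10 seeded plates in the recovery property — are the
  package's chosen validation scale; estimates stabilise well below the
  51 metaphases of the original design.

## Known limitations

* The medial axis assumes one dominant elongation; strongly bent or
  folded chromosomes beyond the simulated curvature range are not
  straightened.
* Homolog pairing assumes a euploid complement (2n objects of n pairs);
  B chromosomes or aneuploidy would need a different matching contract.
* Percent comparisons against other studies follow the convention that
  the named reference value is the denominator; both directions are
  reported to avoid ambiguity.
* The OD→DNA link holds only under stoichiometric staining; the package
  has no correction for glare, non-specific stain or hydrolysis
  variation beyond what the calibration tests detect.
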