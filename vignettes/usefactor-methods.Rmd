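---
title: "Computing gantry-angle use factors from RT Plan data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing gantry-angle use factors from RT Plan data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usefactor)
```

## The model

A vault's primary barriers are designed against *workload × use factor*:
the use factor of a direction is the fraction of primary-beam output (in
monitor units, MU) delivered with the gantry pointing into it. This
package estimates the per-direction use factors of a department from the
DICOM RT Plan files of its treated courses.

The angular schemes are equal bins of width $w \in \{90°, 45°, 30°, 10°\}$
centered on multiples of $w$; bin $k$ covers the half-open arc
$[kw - w/2,\ kw + w/2) \bmod 360°$, so the 90° bin of the 90° scheme is
$[45°, 135°)$. The use factor of bin $k$ is

$$U_k = \frac{\mathrm{MU}_k}{\sum_j \mathrm{MU}_j},$$

reported in percent. Gantry angles follow IEC 61217 (0° points the beam
down from above; angles increase clockwise seen from the couch) and are
normalized to $[0°, 360°)$.

### From plan to MU histogram

1. **Treatment beams.** Per-beam MU lives in the fraction group's
   referenced-beam entries, joined to the beam sequence by beam number. A
   beam counts as a treatment beam iff its entry carries a beam dose value
   *and* a positive meterset; setup and imaging fields fail this test. A
   `TreatmentDeliveryType` label that disagrees is logged but never
   overrides the rule.
2. **Technique.** `STATIC` beam type ⇒ 3D-CRT. `DYNAMIC` beams are split
   by gantry motion: constant angle across the control points (span below
   $10^{-6}$ degrees) ⇒ IMRT, varying angle ⇒ VMAT — rotation during
   delivery is the property that defines an arc. Plans mixing techniques
   are labelled `MIXED` at plan level, but stratification is per beam, so
   each beam lands in its own technique row regardless.
3. **Segments.** Each consecutive control-point pair $(i, i{+}1)$ carries
   $\mathrm{MU} = M \cdot f \cdot (w_{i+1} - w_i)/w_{\mathrm{final}}$,
   where $M$ is the beam meterset, $f$ the fraction weight and $w_i$ the
   cumulative meterset weights. Geometry runs from angle $a_i$ to
   $a_{i+1}$ along the recorded rotation direction, unwrapping through 0°
   when crossed. Equal angles give a point deposit.
4. **Binning.** Within a segment, MU is spread *uniformly per degree of
   travel* — simultaneous linear interpolation of angle and cumulative
   weight. DICOM does not record how the dose rate varied inside a
   control-point interval; the uniform model is the simplest consistent
   one, and control points in clinical arcs are dense enough (typically
   every 2–6°) that any within-segment modulation is far below bin width.
   Moving segments are split exactly at bin boundaries; travel of 360° or
   more is decomposed into full laps (uniform deposit) plus a remainder.

### Aggregation choices

* **MU pooling.** Strata are aggregated by summing MU histograms across
  beams and plans, then taking percentages — not by averaging per-patient
  percentages. A barrier cares about total MU, so a 30-fraction high-MU
  course must count for more than a single palliative field; averaging
  percentages would weight them equally.
* **Fraction weighting.** Each beam's meterset is multiplied by its plan's
  planned fraction count by default (`weight_fractions = TRUE`), so totals
  represent the delivered course. A global constant cancels out of the
  percentages; the switch only changes results when plans differ in
  fraction count.
* **Strata.** Every treatment beam contributes to (technique, site), both
  margins, and the (ALL, ALL) total. Zero-MU strata are omitted. Treatment
  site is not an RT Plan attribute, so it enters through an optional
  site-map CSV (`plan_uid,site` or `patient_key,site`); unmatched plans
  get `"other"`.

### Reference comparison

Built-in reference rows are stored exactly as published: NCRP 151 at 90°
(31.0/21.3/26.3/21.3%) and 45° (25.6/5.8/15.9/4.0/23.0/4.0/15.9/5.8%);
NCRP 49 at 90° (100/25/25/25% — a per-barrier worst case that sums to
175%, kept unnormalized and flagged); IAEA 47, ISO 16645 and IPEM 75-2
(uniform 25%). Requests for unsupported (report, width) pairs fail rather
than interpolate. Comparisons are arithmetic differences in percentage
points (computed − reference), the convention used in published
shielding-survey tables, not relative percent changes; the report carries
the maximum absolute difference and its bin.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `width_deg` | 90 | bin width, one of 90/45/30/10 degrees |
| `weight_fractions` | `TRUE` | weight beams by planned fraction count |
| `decimals` | 1 | display rounding (half-up, matching published tables) |
| `reference` | NCRP151 | comparison row |

## Numerical choices

* Half-open bins, lower edge closed: an angle exactly on an upper edge
  (135° in the 90° scheme) belongs to the next bin. Published interval
  notation does not specify edge ownership; a convention had to be fixed,
  and closed-lower is the one under which bin membership is
  `floor(((a + w/2) mod 360)/w)`.
* Segment/bin overlaps are computed analytically by splitting the
  unwrapped travel interval at every bin boundary, so MU conservation
  holds to floating-point accuracy (tested at $10^{-9}$ relative) and
  10°→30°→90° nesting is exact (45° does not nest and is excluded).
* Rounding for display is half-up (`round()` in R is half-even, which
  published tables do not use).
* Monotonicity of cumulative weights, rotation-direction consistency
  (`NONE` with a moving gantry is ambiguous — clockwise and
  counter-clockwise travel bin differently — and is rejected), and
  final-weight agreement are validated before binning; directory scans
  skip offending files with a warning rather than aborting a batch.

## The synthetic generator

`generate_plan()` / `generate_cohort()` emit conformant DICOM Part 10 RT
Plan files (explicit VR little endian) with known ground truth, emulating
a mixed caseload: a technique mix over 3D-CRT (2–4 static fields, 50–150
MU each), IMRT (5–9 fixed-gantry dynamic fields, 80–250 MU) and VMAT (1–2
arcs, full or 60–350° partial, 150–450 MU, 30–90 control points), fraction
counts drawn from {1, 5, 10, 15, 25, 30}, a site mix over the controlled
vocabulary, and optional setup fields that must be excluded by the
treatment-beam rule. Arcs deliver uniform MU per degree — matching the
binning model — but are written with *irregular* control-point spacing so
the reader and apportionment code are exercised on unequal weight
increments. Ground truth is computed analytically from the beam
descriptions, not through control points or DICOM bytes.

Cohorts are seeded per plan (`seed + index`), so single plans are
reproducible in isolation and cohorts are byte-identical across runs.

What the generator does **not** emulate: MLC apertures and field sizes
(so no aperture-weighted use factors), within-arc dose-rate modulation,
couch/collimator rotation, electron beams, multi-isocenter plans, and the
vendor-specific private tags of clinical exports. Passing tests therefore
demonstrate correct MU apportionment and aggregation for the delivery
geometries above — they do not certify the treatment-beam heuristics
against every vendor's setup-field conventions.

## Problem sizes used in the test suite

Property suites run on 1000 random in-memory beams (conservation), a
40-plan cohort at 45° for exact ground-truth recovery, and a 200-plan
cohort at 90° for end-to-end recovery within 2 percentage points. The
brute-force binning oracle discretizes each segment into $10^5$ equal
sub-steps; on geometry whose bin boundaries align with sub-step edges it
is exact and agreement is checked at $10^{-6}$ relative, on arbitrary
geometry agreement is checked against the oracle's own discretization
error bound.

## Known limitations

* Field size is ignored: a 2×2 cm and a 40×40 cm beam with equal MU count
  equally, though their barrier impact differs. Aperture weighting from
  MLC positions is the natural extension.
* Couch rotation is ignored; non-coplanar beams are binned by gantry
  angle alone.
* One fraction group per plan is assumed for the fraction count (the
  first is used); metersets are still merged across groups.
* Ring-gantry and robotic machines (Tomotherapy, Halcyon, CyberKnife) and
  MR-linacs deliver differently and are out of scope.
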