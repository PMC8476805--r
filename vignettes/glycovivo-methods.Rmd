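---
title: "Methods: quantifying the endothelial glycocalyx from intravital microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the endothelial glycocalyx from intravital microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycovivo)
```

## The measurement problem

The endothelial glycocalyx (GCX) is a carbohydrate-rich layer coating the
luminal surface of blood vessels. In sepsis it is shed, exposing adhesion
molecules and changing how leukocytes interact with the vessel wall. In a
mouse carrying a dorsal skinfold chamber, the GCX can be observed in vivo by
fluorescence microscopy: a lectin conjugate (FITC-WGA) binds glycocalyx
sugars and renders the vessel wall as a bright band, rhodamine 6G stains
circulating leukocytes, and a fluorescent 75-kDa dextran reports vascular
permeability by its interstitial accumulation.

`glycovivo` implements the quantification side of such an experiment: the
glycocalyx **thickness index** (TI) from wall regions of interest, leukocyte
**adhering / rolling / flowing** classification with counts calibrated to a
reference vessel, the **vascular permeability index** from interstitial
time-lapse ROIs, and the group statistics (one-way ANOVA with Dunnett
many-to-one comparisons against the baseline time point) used for all
endpoints. Because raw in-vivo recordings of this kind are rarely deposited,
the package ships a synthetic-data module that generates every input with
known ground truth, so each stage can be validated by parameter recovery.

## Thickness index

A rectangular ROI of 40 x 200 px is placed over one side of the vascular
endothelium, its 200-px long axis (75.4 um at the 0.377 um/px calibration)
following the blood flow direction. From the ROI's brightness histogram a
threshold

$$Th = F\,(I_{max} - I_{min}) + I_{min}$$

is computed, with $F = 0.7$ by default. Pixels at or above $Th$ are scored
as glycocalyx; their count divided by the 200-px axis length is the mean
band thickness in pixels, calibrated to micrometers by the pixel size:

$$TI = \frac{\#\{p : I(p) \ge Th\}}{200} \times 0.377\ \mu m/px.$$

Numerical choices that the formula alone does not fix:

* **Comparison convention.** Binarizing "according to Th" does not decide
  between $\ge$ and $>$; the package uses $\ge$ (configurable via
  `strict`). On 8-bit data with a fractional threshold the two differ only
  when $Th$ is an integer.
* **Unrounded threshold.** $Th$ is kept as an exact fraction; rounding to an
  integer gray level is available (`round_threshold`) but off by default.
* **Degenerate ROIs.** A flat ROI ($I_{max} = I_{min}$) would classify all
  8000 pixels as band under $\ge$. A uniform patch carries no band evidence,
  so the result is flagged degenerate and the TI reported as `NA`.
* **Nearest-neighbour resampling.** Rotated ROIs are extracted by
  nearest-neighbour lookup, which preserves the 8-bit histogram that
  $I_{max}$/$I_{min}$ depend on; bilinear interpolation would smooth the
  extremes and shift the threshold.
* **ROI placement is user-supplied** (anchor, angle). Automatic wall tracing
  is out of scope; on synthetic scenes `wall_roi()` derives the placement
  from ground truth.

A known limitation of any relative (min/max-based) threshold: in an ROI that
contains two well-separated intensity plateaus but *no* band (e.g. lumen and
background only), the brighter plateau exceeds $Th$ and the TI saturates at
the plateau's width. The TI is therefore meaningful only where a stained
band is actually present in the ROI, and the degenerate flag cannot catch
this case. The synthetic emulation floors generated band thicknesses at one
pixel for this reason: a sub-resolution band cannot be rendered, and a
bandless wall ROI measures the lumen edge rather than the glycocalyx.

The TI scale is reported in both px and um; um is the headline unit. The
package defines TI as directly proportional to physical band thickness and
makes no further interpretive claim about direction of change under
pathology.

## Leukocyte-endothelium interaction

Manual scoring rules — adhering cells "do not move" during the 15-s window,
rolling cells move slower than the blood — are made reproducible with three
documented tolerances (`classify_params()`):

* `displacement_epsilon` (2 um): maximum pairwise displacement over the
  window still counted as immobile; well below a leukocyte diameter.
* `rolling_fraction` (0.5): a moving cell slower than half the free-flow
  reference speed is rolling, otherwise flowing. The reference speed is
  supplied per video (vessels differ), e.g. estimated from freely flowing
  cells.
* Coverage guards: any track spanning less than 2% of the window is
  "indeterminate"; an *adhering* call additionally requires at least 90%
  coverage, because it asserts immobility over the whole window. Fast cells
  are classifiable from a short transit; immobility is not.

Mean speed is the net displacement projected on the vessel axis divided by
the observed time span, making the classification invariant under rigid
rotation and translation of the coordinate frame.

Counts are calibrated to a 100-um-long, 100-um-diameter reference vessel.
The calibration phrase "diameter and length of 100 um each" is ambiguous
between a one-factor and a two-factor correction; both are implemented,
`raw × (100/L) × (100/D)` is the default, and outputs record which was used.

The dual-stain test mirrors the two-color merge used to confirm tight
adherence: the leukocyte channel is captured 8 s after the glycocalyx
channel, and a cell detected within `match_radius` (default 5 um) of its
earlier position — "yellow" in the merged image — is tight-adherent. At
realistic cell densities (a dozen cells per field) chance coincidences are
rare; the test degrades if the field is densely populated.

## Vascular permeability

Three 30 x 30 um squares adjacent to the vessel are followed over frames at
0, 30, 60, 90 and 120 min. The permeability index of an ROI at time $t$ is
its mean intensity minus a control value. The protocol text does not define
"control value"; the package's default is the same ROI's mean at $t = 0$, so
the index starts at exactly zero and constant background shifts cancel. A
separate background ROI may be used instead (`control = "roi"`). ROI edge
lengths are converted to whole pixels (30 um at 0.377 um/px = 80 px).

**Trend testing.** The global statistics policy of the package is one-way
ANOVA, but baseline subtraction couples the indices: every index of one ROI
contains the same baseline-frame noise, giving a compound-symmetric
correlation of 0.5 between time points within an ROI. A naive one-way ANOVA
on such indices is conservative (simulated type-I error ~2% at nominal 5%).
`trend_test()` therefore defaults to a randomized-block ANOVA — index on
time with ROI as block, baseline time excluded since its indices are
identically zero — which absorbs the shared baseline term into the block
effect and is exactly calibrated (simulated 5.4% at nominal 5%, and the
package's acceptance checks re-measure ~5% over 1000 null time-lapses). The
naive one-way layout (`method = "oneway"`) and a regression slope test
(`method = "slope"`) remain available. All-identical indices skip the test
with `F = 0, p = 1` and a degenerate flag.

## Group statistics

All endpoints are summarized as mean ± SD (n−1 denominator) per scheduled
hour and tested with one-way fixed-effects ANOVA followed by Dunnett's
many-to-one comparisons against the 0-h control, two-sided, at α = 0.05.

The Dunnett adjusted p-values are evaluated from the joint equicorrelated
multivariate-t distribution of the comparison statistics
(`mvtnorm::pmvt`, quasi-Monte-Carlo with a fixed internal seed and absolute
tolerance 1e-3, hence deterministic), for balanced and unbalanced designs
alike; with one comparison this collapses exactly to the pooled two-sample
t-test. `multcomp::glht` serves as an independent cross-check in the test
suite, never as the implementation. Degenerate layouts are handled
explicitly: all observations identical gives `F = 0, p = 1` (flagged);
groups that differ with zero residual variance give `F = Inf, p = 0`.

By default the pipeline runs post-hoc comparisons only when the global ANOVA
is significant (`always_posthoc = FALSE` overrides), each endpoint is tested
separately with no correction across endpoints, and repeated measurements
from one animal are treated as independent — a deliberate simplification
matching how such endpoints are commonly analyzed, and a known limitation.

## The synthetic-data module

Every generator is a pure function of its spec (including the seed): same
spec, same bits.

* **Vessel scenes** (`render_vessel_scene`): a straight vessel — dark
  interstitium, brighter lumen, bright wall band of known thickness on both
  walls — plus i.i.d. Gaussian read-out noise (Poisson shot noise optional),
  rounded and clipped to 8 bits. The band is drawn in whole pixels
  perpendicular to the axis, so an axis-aligned scene has *exactly* the
  requested band thickness and recovery can be tested against an exact
  truth; oblique angles are exact to 1 px of discretization. Vessel
  curvature is deliberately not modelled: the ROI follows the flow
  direction, so curvature adds nothing to what the measurement test probes.
  Diameters outside the 20-50 um protocol window warn.
* **Leukocyte tracks** (`simulate_tracks`): three kinetic classes over the
  15-s window sampled at `frame_rate`. Jitter is *bounded uniform*
  (±`jitter_sd` per coordinate) rather than Gaussian, so an adhering track's
  displacement is hard-bounded by 2√2·`jitter_sd` and the adhering
  definition holds almost surely, not just typically. Cells faster than the
  segment allows enter at a random time and are observed only during
  transit, as in a real field of view.
* **Leakage time-lapses** (`simulate_leak_series`): interstitial intensity
  `baseline + leak_rate · t` plus per-pixel noise, observed through three
  80-px ROIs. With the default 0.5 gray-levels/min and no noise the index
  is exactly (0, 15, 30, 45, 60) at (0, 30, 60, 90, 120) min.
* **Cohorts** (`simulate_cohort`): per-hour normal draws (left-truncated at
  zero for concentrations and thicknesses) at the published group
  parameters where numbers are printed — plasma syndecan-1
  1.85 ± 0.48 ng/mL (0 h) rising to 3.83 ± 1.09 ng/mL (24 h) with return to
  baseline from 48 h, n = 3; arteriolar TI 1.28 ± 0.27 vs 1.79 ± 0.62 and
  venular 1.05 ± 0.39 vs 1.51 ± 0.56, n = 21. Body weight and blood
  pressure are published only graphically; the defaults (22.5 ± 1.0 g
  baseline with a minimum of 20.2 g at 48 h and recovery by 168 h, n = 8;
  85 ± 8 mmHg baseline with a minimum of 65 mmHg at 24 h and recovery by
  72 h, n = 5) are realistic BALB/c values consistent with the described
  course. The venular interaction surge (counts roughly tripling at 24 h
  and returning by 48 h) is likewise a qualitative pattern, emulated with
  Poisson-distributed per-video class counts.

What the generators do **not** emulate: point-spread blur, photobleaching,
motion artifacts, vessel curvature, heterogeneous staining, platelet
contamination of the rhodamine channel, or real hemodynamics. Passing
recovery tests therefore demonstrates that the *quantification* is correct
and calibrated, not that it is robust to every nuisance of real microscopy.

## Reported-value caveat

The source study's text describes GCX thickness as *decreasing* at 24 h
while its printed TI values *rise* (arteriole 1.28 → 1.79). The package
defines TI as directly proportional to band thickness, uses the printed
values verbatim as generator parameters, and documents the discrepancy
without attempting to reconcile it.

## Problem sizes and determinism of the validation

The package's own validation (test suite and `scripts/acceptance.R`) uses:
noise-free recovery at band thicknesses 1-20 px and a 6 × 50-seed noisy
sweep; 500-track classification cohorts; 1000 null time-lapses for trend
calibration; 2000 null replicates per k ∈ {2, 3, 5} for Dunnett familywise
error; 1000 seeded replicates of the syndecan-1 cohort for the
24-h-pattern check; and a full double emulation for byte-level determinism.
All randomness flows from explicit seeds; two runs with the same seed are
bit-identical down to the output CSVs.
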