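# glycovivo

Quantification of the vascular endothelial glycocalyx and its sequelae from
intravital fluorescence microscopy.

In sepsis models, the glycocalyx (GCX) — the carbohydrate layer coating the
luminal endothelium — is shed and later restored. Observed through a dorsal
skinfold chamber, this shows up in three measurable ways: the
lectin-stained wall band thins, leukocytes start rolling and adhering on
the exposed endothelium, and (if the second barrier fails too) fluorescent
dextran leaks into the interstitium. `glycovivo` implements the image- and
track-based quantification of all three endpoints, the group statistics
they are analyzed with, and a synthetic-data generator that produces every
input with known ground truth, so the whole pipeline is testable by
parameter recovery. It is aimed at microcirculation researchers who need a
reproducible, scriptable version of measurements that are usually done by
hand in ImageJ.

## The measurements

**Thickness index (TI).** A 40 × 200 px ROI is placed over one side of the
endothelium, its long axis (200 px = 75.4 µm at 0.377 µm/px) along the
flow. From the ROI histogram a threshold

    Th = F · (Imax − Imin) + Imin,   F = 0.7

is computed; pixels ≥ Th are scored as glycocalyx, and

    TI = (supra-threshold pixel count / 200) × pixel size  [µm].

**Leukocyte interaction.** Tracks over a 15-s window are classified as
*adhering* (displacement ≤ 2 µm over the window), *rolling* (mean
along-axis speed below half the free-flow reference), or *flowing*; counts
are calibrated to a 100 µm × 100 µm reference vessel,
`raw × (100/L) × (100/D)`. A dual-channel test with an 8-s lag separates
tight adherence from transit.

**Permeability index.** Mean intensity of three 30 × 30 µm interstitial
ROIs at 0–120 min, minus each ROI's own baseline (t = 0) value; a
block-ANOVA trend test (ROI as block) checks for a time-dependent increase
at exact nominal level.

**Group statistics.** Mean ± SD per scheduled hour, one-way ANOVA, and
Dunnett's many-to-one comparisons against 0 h via the equicorrelated
multivariate-t distribution, two-sided, α = 0.05.

## Worked example

Render a synthetic vessel (32 µm diameter, true band thickness 1.885 µm =
5 px), measure its TI, and run the statistics on a simulated syndecan-1
cohort:

```r
library(glycovivo)

sc <- render_vessel_scene(scene_spec(vessel_diameter = 32,
                                     gcx_thickness_true = 1.885,
                                     noise_sd = 5, seed = 42))
compute_ti(sc$frame, wall_roi(sc), F = 0.7)
#> <ti_result> TI = 1.885 um (5.000 px; 1000 px >= Th = 149.80)

tab <- simulate_cohort(cohort_spec("sdc1", seed = 42))
dunnett_vs_control(tab, control_hour = 0, alpha = 0.05)
#> Dunnett comparisons vs 0 h (alpha = 0.05); ANOVA F = 11.162, p = 0.003129
#>  hour n  mean mean_diff      t p_unadjusted p_adjusted significant
#>    24 3 4.168    2.1312 5.2541      0.00077   0.002089        TRUE **
#>    48 3 2.400    0.3625 0.8938      0.39752   0.710535       FALSE
#>    96 3 2.415    0.3775 0.9307      0.37925   0.687428       FALSE
```

The TI recovers the generated 5-px band exactly (1000 supra-threshold
pixels / 200 px axis × 0.377 µm/px = 1.885 µm). In the cohort — drawn from
the published group parameters (1.85 ± 0.48 ng/mL at 0 h, 3.83 ± 1.09 at
24 h, back to baseline afterwards, n = 3) — only the 24-h shedding peak is
significant after Dunnett adjustment, reproducing the transient-degradation
time course.

Track classification and count calibration:

```r
co <- simulate_tracks(track_spec(n_adhering = 4, n_rolling = 6,
                                 n_flowing = 8, seed = 42))
count_and_normalize(co, reference_speed = 100)
#> <classified_counts> adhering 4, rolling 6, flowing 8, indeterminate 0
#>   normalized (per 100 um, length_and_diameter): adhering 13.33, rolling 20.00
```

All 18 generated tracks are recovered in their true class; the normalized
counts rescale the 100-µm segment of a 30-µm vessel to the 100 × 100 µm
reference.

A command-line wrapper is installed with the package
(`exec/glycovivo`): `glycovivo simulate|ti|adhesion|permeability|stats|emulate`;
see `?glycovivo_cli`.

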