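# mcgkle

Kullback–Leibler entropy analysis of cardiac magnetic field maps.

Magnetocardiography (MCG) images the heart's magnetic field (~10 pT) over
the chest with SQUID sensors. On a common map format — a 6×6 grid over about
20 cm × 20 cm, 1,000 samples per averaged beat at 1,000 Hz, R peak at sample
333 — the spatial topology of the field during ventricular repolarisation
(the STT interval) separates subjects with suspected myocarditis from
healthy controls: healthy maps are all alike, while each pathological map is
distorted in its own way. `mcgkle` is for signal-processing and biomedical
researchers who want that entire analysis chain as tested, reproducible
building blocks, plus a synthetic cohort generator to calibrate and
stress-test it without patient data.

## The method

1. **Beat averaging** aligns all complete beats on their R peaks and
   averages per channel (noise shrinks as √n beats).
2. **Normalisation** divides the map by the mean absolute field strength
   over the closed QRS window,

   γ = (1/36) Σᵢ (1/t_QRS) Σₜ |Bᵢₜ|,

   cancelling sensor-to-heart distance differences.
3. **Segments**: an 80 ms window from QRS onset and a 250 ms window from STT
   onset (fixed), or the full segments length-normalised by linear
   resampling to 20 (QRS) / 40 (STT) samples.
4. **KLE features**: per time point, subject map slice P and reference map
   slice Q (the healthy-group average) become distributions over the 36
   positions, scored by KL(P, Q) = Σᵢ Pᵢ ln(Pᵢ/Qᵢ).
5. **Classification**: ridge-stabilised Fisher LDA on the KLE feature
   vectors, validated by leave-one-out cross-validation in which the
   reference map is rebuilt per fold from training-fold healthy subjects
   only. Mann–Whitney tests on heart rate and segment length guard against
   the obvious confounds.

See `vignettes/kle-cmfm-methods.Rmd` for assumptions, parameter defaults,
and what the synthetic generator does and does not emulate.

## Worked example

```r
library(mcgkle)

spec   <- cohort_spec(seed = 1)          # 57 healthy / 40 pathology, 30 beats
cohort <- simulate_cohort(spec)
maps   <- lapply(cohort$recordings, function(r) normalize_map(average_beats(r)))
stt    <- lapply(maps, extract_segment, segment = "STT", mode = "resampled")

kle_loocv(stt)
#> LOOCV KLE/LDA classification (STT:resampled; reference: healthy)
#>   n = 97 | SN 0.750  SP 0.754  ACC 0.753
#>   confusion: tp=30, fn=10, tn=43, fp=14

heart_rate_test(cohort)$p_value
#> [1] 0.9620074
```

The report reads: of 97 subjects, leave-one-out prediction recovered 30 of
40 pathology subjects (sensitivity 0.75) and 43 of 57 controls (specificity
0.75) from STT-segment topology alone, while heart rate carried no group
information (Mann–Whitney p = 0.96) — the classification rides on map
topology, not on tachycardia. Repeating with `segment = "QRS"` drops
accuracy to near chance (the synthetic pathology perturbs only
repolarisation), and building the reference from the pathology group
(`kle_loocv(stt, reference_group = "pathology")`) degrades accuracy toward
chance, because the heterogeneous pathological maps average into an
uninformative reference.

The same chain runs end-to-end with artefacts on disk via

```r
run_pipeline(spec, out_dir = "out")   # features.csv, report.json, pca.csv
```

or from a shell through `inst/scripts/mcgkle` (`simulate`, `run`,
`validate` subcommands on manifest + TSV cohorts).

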