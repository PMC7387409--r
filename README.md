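# ivmotility

Quantification of T-cell behavior in intravital two-photon time-lapse
imaging of solid tumors, for labs doing adoptive T-cell therapy and
checkpoint-inhibitor studies in mouse models.

Intravital movies show GFP-labelled cytotoxic T cells moving through a
tumor (mCherry) whose collagen-rich stromal margin is visible by second
harmonic generation (SHG). This package turns such multi-channel stacks —
or ground-truthed synthetic equivalents it can generate itself — into
quantitative readouts:

- **per-track motility**: displacement *d* (μm), path length *L*,
  displacement-based mean velocity *v = d/T* (μm/min) and meandering index
  *MI = d/L* ∈ [0, 1] (1 = a perfectly linear track);
- **behavioral quadrants**: each track classed by velocity and MI against
  cohort-wide mean thresholds (Q1 fast/returning, Q2 fast/directional, Q3
  low motility, Q4 non-sustained), the scheme used with thresholds
  2.16 μm/min and 0.45 in the assay this package operationalises;
- **morphology**: elongation index *E* = fitted-ellipse major/minor axis
  from second-order contour moments;
- **spatial heterogeneity**: Pearson kurtosis *K = m₄/m₂²* of cell
  positions along the periphery→core axis (uniform = 1.8, normal = 3),
  region counts, and Spearman vessel–cell correlation;
- **cohort statistics**: ellipsoid tumor volume *V = (π/6)abc*, a
  D'Agostino–Pearson-gated unpaired *t* / Mann–Whitney two-group test, and
  Kruskal–Wallis with Dunn's post-hoc comparisons, reported mean ± SEM.

The preprocessing chain mirrors standard intravital practice: maximum
intensity projection → mono-exponential debleaching → phase-correlation
rigid registration → Gaussian smoothing + Otsu thresholding + component
labelling for detection → greedy gated nearest-neighbour linking →
exclusion of tracks with ≤ 5 timepoints.

## Worked example

Simulate a three-arm cohort (vehicle control; anti-checkpoint monotherapy
at speed multiplier 0.4; combination at 0.5), compute metrics, classify
behavior and compare arms:

```r
library(ivmotility)

sim <- simulateCohort(defaultCohortSpec(seed = 11), nFrames = 61)
met <- cohortMetrics(sim$trackSets)
thr <- cohortThresholds(met)
thr
#> ClassifierThresholds: v* = 0.8633 um/min, MI* = 0.264
cl <- classifyBehavior(met, thr)
table(cl$arm, cl$quadrant)
#>           Q1 Q2 Q3 Q4
#>   combo    9 28 83  0
#>   control 20 17 35  0
#>   mono     6 28 86  0
round(tapply(cl$v_um_min, cl$arm, mean), 2)
#>   combo control    mono
#>    0.77    1.37    0.66
compareKGroups(split(cl$v_um_min, cl$arm))
#> StatResult: Kruskal-Wallis (combo vs control vs mono)
#>   statistic = 6.92457, p = 0.03136
#>   omnibus significant: Dunn post-hoc run
#>   post-hoc:
#>   group1  group2          z           p      p_adj
#>    combo control -1.9698598 0.048854445 0.14656334
#>    combo    mono  0.7191604 0.472042110 1.00000000
#>  control    mono  2.5926709 0.009523385 0.02857015
```

The control arm travels fastest (1.37 μm/min vs 0.77 and 0.66 in the
treated arms, whose cells are slower and more numerous by construction);
Kruskal–Wallis flags the arm effect and Dunn's adjusted comparisons locate
it in the control-vs-mono contrast. Treated cells pile up in Q3 (low
motility), the signature of target engagement.

A single worked track:

```r
tr <- Track("cell_1", frame = 1:11, x = seq(0, 10, 1),
            y = c(0, 1, 0, 2, 1, 3, 2, 4, 3, 5, 4))
trackMetrics(tr)
#>   cell_id     region n_points     d_um     L_um T_min v_um_min        MI
#> 1  cell_1 unassigned       11 10.77033 17.42955     5 2.154066 0.6179349
```

`runPipeline(demoConfig(seed))` runs the whole chain end-to-end on a
rendered synthetic cohort — simulation, rendering with bleaching/drift/
noise, projection, debleaching, registration, detection, linking,
filtering, region assignment, metrics, classification, spatial analysis
and statistics — writing CSV tables, PNG figures (quadrant scatter, track
plots, spatial histogram) and a JSON manifest of every parameter and seed.
A thin CLI wrapper lives at `inst/scripts/ivmotility.R`
(`demo` / `run --config study.yaml` / `simulate` subcommands).

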