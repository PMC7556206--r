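# dualhfo

Interictal high-frequency-oscillation (HFO) asymmetry analysis for
dual-pathology epilepsy.

Patients with *dual pathology* carry two potentially epileptogenic lesions —
one in the hippocampus, one in the temporal neocortex — and presurgical
evaluation must decide which of them generates the seizures. `dualhfo`
implements an interictal-biomarker pipeline for that question on
stereotactic EEG (SEEG): detect interictal epileptic spikes (IES), ripples
(80–250 Hz), ripples co-occurring with spikes (IES-ripples) and fast
ripples (250–500 Hz); compute, per patient and event type, the
lesion-asymmetry ratio of mean contact rates

    R = (hip − neo) / (hip + neo)  ∈ [−1, 1];

correlate R with the seizure-generating lesion (group 1 hippocampal,
2 both, 3 neocortical; Spearman); predict each patient's primary focus by
ranking the cohort on R_fast-ripple (with group sizes (n1, n2, n3): top n1
ranks → group 1, bottom n3 → group 3, middle → group 2); and assess the
accuracy of that rule with a one-sided permutation test that shuffles the
group-label multiset across rank positions — 100,000 Monte-Carlo shuffles
plus an exact enumeration oracle over all multiset arrangements
(for 5/7/4 labels: 16!/(5!·7!·4!) = 1,441,440, null mean Σnᵢ²/N = 5.625).

The package is aimed at clinical-neurophysiology researchers who want a
fully specified, reproducible reference implementation of this analysis:
every stage is an exported function, the detector is a classical
RMS-envelope threshold detector with all thresholds exposed
(`detection_params()`), and a synthetic SEEG cohort generator with known
ground truth (`sim_config()`, `simulate_rate_table()`,
`simulate_recording()`) validates the whole chain end to end. A packaged
16-patient cohort table (`load_fixture("table2")`) reproduces the published
per-patient analysis exactly. Minimal EDF input/output is included.

## Worked example

```r
library(dualhfo)

res <- reproduce_table_analysis(n_shuffles = 100000, seed = 7)
res$prediction
#> rank-based focus prediction: 11/16 correct (69%)
res$spearman
#> rho = -0.5117, p = 0.04275 (t approximation, df = n - 2; n = 16)
res$permutation
#> permutation test: 11 matches observed; p = 0.00737 (100000 shuffles; exact 0.00703)
```

Reading: ranking the 16 packaged patients on their fast-ripple ratio and
predicting the focus by rank zone assigns 11 of 16 correctly (69%); the
fast-ripple ratio decreases from hippocampal-onset to neocortical-onset
patients (rho < 0, p < 0.05); and 11 correct assignments are well beyond
what label shuffling achieves by chance (p < 0.01 against a null with mean
5.625).

A synthetic cohort under the same study conditions (16 patients split
5/7/4, ~60 hippocampal and ~124 neocortical contacts, 1-hour segments,
group asymmetries 0.6/0.1/−0.3):

```r
report <- run_pipeline(sim_config(seed = 11), tier = "rates")
report
#> pipeline report (tier rates, seed 11): 16 patients, 184 channels
#>   fast-ripple rho = -0.935 (p = 1.15e-07); prediction 16/16; permutation p = 0
```

(The configured asymmetries separate the groups more cleanly than clinical
data does; see the methods vignette for what the generator does and does
not emulate.)

The numbered scripts under `analysis/` run the same pipeline as a
narrative: `01_simulate.R` (synthetic cohort + one signal-level patient as
EDF), `02_detect.R` (event detection, scored against injected ground
truth), `03_rates_ratios.R`, `04_statistics.R`, `05_prediction.R`. Each
writes its tables under `results/`.

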