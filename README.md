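# sonopcnn

Firing-time enhancement of low-contrast renal ultrasound with a fire-once
pulse-coupled neural network (PCNN), and the downstream Doppler analytics
used to monitor acute kidney injury (AKI) in the ICU: the renal resistive
index, semiquantitative perfusion scores, a within-patient RRI time-slope
estimator, and ROC/AUC evaluation of RRI as a diagnostic marker. Seeded
generators simulate every input — speckled kidney phantoms, Doppler
velocity envelopes, longitudinal patient cohorts — so the full pipeline is
testable without patient data.

Who it is for: researchers prototyping ultrasound enhancement or
longitudinal renal-Doppler analyses who want a small, fully deterministic,
heavily tested reference implementation.

## The methods in brief

**Enhancement.** One neuron per pixel. Thresholds start at
`θ(0) = BPG − CPG` (BPG = brightest input pixel, CPG = 3×3 Laplacian
convolution, center weight 8, reflect padding) and decay by `exp(−τ)` per
iteration; a neuron fires once, when its activity
`U = F·(1 + α·R)` (feed `F` = pixel intensity, link `R` = neighborhood
pulse sum) exceeds its threshold. The firing-time matrix `S` maps to gray
via `BPG·exp(−τ_e·(S−1))`, min-max rescaled to `[0, 255]`. Defaults:
`α = 0.2`, `τ = 0.7`, `W_L = 1`, `W_F = 278`. Baselines: global histogram
equalization and linear contrast stretch, compared by histogram entropy,
dynamic range, and uniformity.

**Clinical.** `RRI = (SV − DV)/SV` per Doppler spectrum, averaged over the
4–6 spectra of one examination; DU perfusion scores (0–3) aggregated across
raters by rounded median; the common RRI drift per ICU day estimated by
within-patient centering (the fixed-effect target of a random-intercept
mixed model); ROC by threshold sweep with trapezoid AUC cross-checked
against the tie-corrected rank statistic, optimal cutoff by Youden's J.

## Worked example

```r
library(sonopcnn)

phantom <- make_phantom(phantom_spec(seed = 7))
phantom
#> <gray_image 128 x 128, 256 levels, range [62, 138]>

compare_methods(phantom)
#>    method entropy_bits dynamic_range uniformity
#> 1 hist_eq    4.8292419     0.9882353 0.04537177
#> 2  linear    4.8687598     1.0000000 0.04530999
#> 3    pcnn    0.9997516     1.0000000 0.49821203

cohort <- make_cohort(cohort_spec(seed = 1))
fit_time_slope(cohort)
#> RRI time slope: 0.01429 per day (se 0.00077, 95% CI 0.01278 to 0.01580)
#>   140 observations, 20 patients

roc_auc(cohort, day = 4)
#> ROC of RRI for AKI: AUC = 0.8300 (10 positive, 10 negative)
#>   optimal cutoff (Youden's J = 0.600): RRI >= 0.8190
```

Reading the numbers: the phantom is genuinely low-contrast (77 of 256
levels). All three enhancers stretch it to (nearly) the full range; the
PCNN output has low histogram entropy because it quantizes by firing time —
its value is salience ordering, not histogram filling. The simulated
cohort was generated with a true slope of 0.0135 RRI/day, which the
within-patient estimator recovers inside its CI, and day-4 RRI separates
AKI from non-AKI patients with AUC 0.83.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sonopcnn", package = "sonopcnn"))')
$CLI simulate phantom --seed 7 -o phantom.png
$CLI enhance --method pcnn --alpha 0.2 --tau 0.7 --wl 1 --wf 278 \
     --center 8 --max-iters 64 --dump-firing times.csv -o out.png phantom.png
$CLI compare -o report.csv phantom.png
$CLI simulate cohort --seed 7 -o cohort.csv
$CLI roc cohort.csv --day 4 -o roc.csv
$CLI slope cohort.csv
```

Subcommands: `enhance`, `compare`, `rri`, `roc`, `slope`, `simulate`.
Global flags: `--config PATH` (key=value file, overridden by CLI flags),
`--seed N`, `--verbose`, `--version`. Identical argv + seed ⇒
byte-identical outputs. Exit codes: 0 ok, 1 domain/file error, 2 usage or
parameter validation.

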