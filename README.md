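# hippoval

Automated, quantitative validation of hippocampal CA1 pyramidal-cell
models against experimental electrophysiology.

Detailed biophysical neuron models are typically tuned to reproduce one
or a few experimental paradigms; whether they generalize to other
aspects of cellular behavior is usually unknown. `hippoval` is an R
toolkit for modellers who want that question answered reproducibly. It
implements five validation tests that mimic standard experimental
protocols, extract electrophysiological features from the simulated
voltage traces, and score the model against experimental data:

| Test | Protocol | What is scored |
|---|---|---|
| Somatic features | step currents of several amplitudes | sub- and suprathreshold features (AP shape/timing, sag, ...) |
| Depolarization block | 1000 ms steps, 0–1.6 nA in 0.05 nA increments | `I_maxNumAP`, `I_below_depol_block`, `V_eq` |
| Back-propagating AP | spike train nearest 15 Hz, trunk recordings | AP1/APlast amplitudes at 50/150/250/350 ± 20 µm; strong vs weak propagation |
| PSP attenuation | EPSC-shaped inputs at random trunk locations | soma/dendrite peak-depolarization ratio at 100/200/300 ± 50 µm |
| Oblique integration | increasing clustered synaptic inputs | dendritic-spike threshold, degrees of nonlinearity, EPSP kinetics (9 features) |

## Scoring

Each feature is scored as the discrepancy between the model's value and
the experimental mean in units of the experimental standard deviation
(the feature **Z-score**):

```
Z = |x_model − μ_exp| / σ_exp
```

The final score of a test is the mean of the Z-scores of the evaluated
features, plus test-specific penalties: the depolarization-block test
adds 10 per examined 0.05 nA step separating `I_maxNumAP` from
`I_below_depol_block` (i.e. 200·|ΔI| with ΔI in nA), and returns a flat
100 for models that never enter depolarization block. Features that
cannot be evaluated (e.g. spiking features where the model does not
fire) never enter the average; they are counted among the attempted
features and listed in the log file.

Tests communicate with models only through a small capability contract
(step-current injection, synaptic activation, morphology access), so
any backend can be validated. The package ships a deterministic
phenomenological mock model (`mock_model()`) and a synthetic SWC
morphology generator (`generate_morphology()`); adapters around real
simulators implement the same generics (`step_current_response()`,
`synaptic_response()`, `model_morphology()`).

The morphology module also implements the multi-apical-point
classification of the apical arbor into trunk, oblique and tuft
sections, used by the dendritic tests on SWC reconstructions
(`read_swc()`, `find_apical_points()`, `classify_apical()`).

## Worked example

Score a mock model that enters depolarization block above 0.45 nA
against the bundled (synthetic) observation file:

```r
library(hippoval)

model <- mock_model_from_file(
  system.file("extdata", "mock_blocking.json", package = "hippoval"))
obs <- system.file("extdata", "obs_depol_block_synthetic.json",
                   package = "hippoval")
result <- run_depol_block_test(model, obs)
result
#> <depol_block> final score 0.47619 (penalty 0), 3/3 features evaluated
#>  notes: depolarization block above 0.45 nA; I_maxNumAP = 0.4 nA,
#>         I_below_depol_block = 0.4 nA (0 step(s) apart)
result$feature_scores[, c("feature_key", "model_value", "mean", "sd", "z")]
#>           feature_key model_value   mean   sd         z
#> 1          I_maxNumAP         0.4   0.45 0.07 0.7142857
#> 2 I_below_depol_block         0.4   0.45 0.07 0.7142857
#> 3                V_eq       -42.0  -42.00 3.00 0.0000000
```

The model fires most APs at 0.4 nA and first falls silent during the
last 100 ms of the stimulus one step higher, so both current features
equal 0.4 nA (0.71 SD below the experimental threshold current), the
equilibrium potential matches exactly, and the final score is the mean
of the three Z-scores, 0.476. `persist_result(result, "out/")` writes
the JSON result file and a plain-text log.

The same run from the shell, via the installed CLI
(`<library>/hippoval/exec/hippoval`):

```sh
hippoval depol-block --model mock_blocking.json \
  --observation obs_depol_block_synthetic.json --output out/
#> final score: 0.476190476190476
#> features evaluated: 3 of 3
```

Subcommands: `somatic-features`, `depol-block`, `bap`,
`psp-attenuation`, `oblique-integration`; shared flags `--model`,
`--observation`, `--config`, `--output`, `--seed`, `--jobs`,
`--specify-data-set`.

Bundled fixtures under `inst/extdata/`: the patch-clamp somatic feature
table (`obs_somatic_patch_table1.json`, values as published) and
synthetic observation files for the other four tests (labelled
`_synthetic`), plus example mock-model parameter files.

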