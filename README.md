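# spcdopa

Simulation and analysis of striatal dopamine photometry in a sensory
preconditioning task.

## What this package is for

Sensory preconditioning (SPC) probes whether animals learn the relational
structure of *value-neutral* events. Rats first hear blocked pairs of neutral
auditory cues (A→B, C→D) with no reward, then B is conditioned with sucrose
pellets while D goes unreinforced, and finally a probe presents A and C
alone: responding more to A than C reveals inference through the latent A→B
association. Recording dopamine with two-channel fiber photometry (470 nm
active / 415 nm isosbestic, 50 Hz per channel, trial-gated) during all three
phases exposes, in one task, prediction-error signals for neutral cues
(sensory prediction errors, SPEs), classic reward prediction errors (RPEs),
and inferred-value responses that depend on the lateral orbitofrontal cortex
(inactivated in an "OFCi" group before the probe).

`spcdopa` provides, for analysts working with this kind of data:

* a **synthetic-data generator** (`sim_config()`, `simulate_cohort()`):
  delta-rule cue-cue and cue-value learning
  (`V <- V + a(1 - V)`, `V <- V + a(lr - V)`), impulse amplitudes
  `g_N e^{-kn} + g_S (1 - V_pair) + g_R V_val` at cues and
  `g_R (l - V_val)` at rewards, a double-exponential sensor kernel with
  photobleaching, shared motion artifacts and noise, logistic food-port
  behavior, and full ground-truth latents;
* the **preprocessing chain** (`preprocess_photometry()`): 5-sample median
  filter, session-scope second-order polynomial isosbestic fit and
  subtraction, per-trial baseline z-scoring, session peak normalization;
* **quantification** (`quantify_responses()`, `phase_bins()`,
  `us_cs_difference()`, `align_trials()`): onset-aligned peaks (0–2 s),
  slow-component AUC (1–3 s), matched US windows, port occupancy;
* the task's **derived indices and statistics**
  (`difference_index()`, `include_subject()`, `suppression_ratio()`,
  `wilcoxon_signed_exact()` — exact by sign-flip enumeration,
  `chisq_2x2_one_sided()`, `linregress_with_test()`, `compare_slopes()`,
  `rm_anova()`, `correlate_spe_with_probe()`, `fit_alpha_assoc()`);
* a staged **pipeline** (`run_simulate()` → `run_preprocess()` →
  `run_quantify()` → `run_analyze()`, or `run_all()`) over documented
  CSV/YAML formats with run manifests, plus a thin command-line wrapper in
  `inst/scripts/spcdopa-cli.R`.

## Worked example

Simulate the default cohort (6 control + 8 OFCi rats, 2 preconditioning +
6 conditioning + probe sessions, NAcc site), run the full chain, and test
the probe:

```r
library(spcdopa)

cfg  <- sim_config(seed = 11)
ds   <- simulate_cohort(cfg, sites = "NAcc")
norm <- preprocess_photometry(ds$photometry)
rows <- quantify_responses(norm, ds$events, ds$port)
analyze_cohort(rows)
#> <spc_analysis>
#>   14 subjects analyzed, 0 excluded by the B >= 2D rule
#>   diff_BD_vs0_CTRL                 p = 0.03125 (n = 6)
#>   diff_AC_vs0_CTRL                 p = 0.03125 (n = 6)
#>   diff_BD_vs0_OFCi                 p = 0.007812 (n = 8)
#>   diff_AC_vs0_OFCi                 p = 0.7422 (n = 8)
#>   discriminators_CTRL_gt_OFCi      p = 0.0005969 (n = 14)
#>   probe_dop_A_CTRL_vs_OFCi         p = 4.322e-06 (n = 14)
#>   ...
```

Reading the output: both groups discriminate the food-paired cue B from D
(`diff_BD` above 0; with all subjects positive the exact Wilcoxon p-values
are the group-size minima 0.031 and 0.0078), but only controls discriminate
A from C (`diff_AC_vs0_CTRL` p = 0.031 versus 0.74 in OFCi) — the behavioral
signature of inference and its loss under orbitofrontal inactivation. The
same dissociation appears in the dopamine peak to cue A
(`probe_dop_A_CTRL_vs_OFCi`).

The preconditioning SPE signature:

```r
bins <- phase_bins(rows)
aggregate(peak ~ predictedness + bin, data = bins, FUN = mean)
#>   predictedness    bin      peak
#> 1     predicted  start 0.8774967
#> 2   unpredicted  start 0.9059219
#> 3     predicted middle 0.5094577
#> 4   unpredicted middle 0.7845672
#> 5     predicted    end 0.3258883
#> 6   unpredicted    end 0.7411517
```

Responses to all cues start similar and decline, but the *predicted* cues
(B, D — each preceded by its partner) are suppressed much further than the
unpredicted ones (A, C): an error signal about value-neutral events. And the
RPE transfer during conditioning, as the session-mean difference between the
US peak and the CS peak for cue B:

```r
d <- us_cs_difference(rows)
round(aggregate(us_cs_diff ~ session, data = d[d$cue == "B", ], FUN = mean)$us_cs_diff, 3)
#> [1]  0.237 -0.238 -0.515 -0.641 -0.708 -0.753
```

A monotone decline — the US response shrinking while the CS response grows —
is the classic signature of a reward prediction error moving from the
outcome to its predictor.

See `vignette("spcdopa-methods")` (source under `vignettes/`) for the model
equations, parameter choices, preprocessing conventions and limitations.

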