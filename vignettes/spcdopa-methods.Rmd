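---
title: "Models and methods behind spcdopa"
author: "spcdopa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spcdopa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcdopa)
```

## The experiment the package models

Sensory preconditioning (SPC) separates latent, value-neutral learning from
reward learning in three phases. In *preconditioning*, rats hear blocked
pairs of neutral auditory cues (A immediately followed by B; C by D) with no
reward. In *conditioning*, B is followed by two sucrose pellets while D goes
unreinforced. In the *probe*, a few rewarded B and unrewarded D reminder
trials are followed by blocked, unreinforced presentations of A and C. A rat
that responds more to A than to C can only be using the latent A→B
association to *infer* that A predicts food. Striatal dopamine is recorded
throughout with two-channel fiber photometry (470 nm dopamine-sensitive
signal, 415 nm isosbestic reference, 50 Hz per channel, gated to trials),
and one group receives a chemogenetic inactivation of the lateral
orbitofrontal cortex (OFCi) before the probe, which selectively removes
inference-based responding.

`spcdopa` implements the full analysis chain for such data and, because raw
recordings of this kind are rarely shareable, a generator that simulates the
experiment end to end with all ground-truth latents retained. Every analysis
stage is exercised against simulation; user data in the same CSV formats
flows through identical code paths.

## The generative model

### Associative learning

Each simulated subject carries a cue-cue association matrix $V_{X \to Y}$,
cached cue values $V_Y$, and exposure counts $n_Y$, updated by delta rules
after each trial:

$$V_{X\to Y} \leftarrow V_{X\to Y} + \alpha_{assoc}\,(1 - V_{X\to Y}),
\qquad
V_Y \leftarrow V_Y + \alpha_{value}\,(\lambda\,r - V_Y),$$

with $r \in \{0,1\}$ the reward indicator and $\lambda$ the asymptote. Both
quantities stay in $[0, \lambda]$ under any schedule. The cue-cue rate
varies across subjects (truncated normal, SD `alpha_assoc_sd`): individual
differences in latent learning are what give the suppression-vs-probe
correlation (below) its between-subject spread; without them every subject
would sit at the same point and the regression would be undefined.

### Dopamine impulses

The transient at a cue onset has three additive components — declining
novelty, a sensory prediction error (SPE), and a value-driven component:

$$a_{cue} = g_N e^{-\kappa\,n} \;+\; g_S\,(1 - p) \;+\; g_R\,V_{cue},$$

where $p = V_{X\to cue}$ if cue $X$ immediately preceded this cue within the
trial and $p = 0$ otherwise. The US transient is the classic reward
prediction error $a_{US} = g_R(\lambda - V_{CS})$. In the probe test, a cue
additionally receives the chained inferred value
$c \sum_X V_{cue\to X} V_X\, g_R$ with the pass-through $c$ (`chain_gain`)
set to zero in OFCi subjects during the probe — the only modeled group
difference, matching a drug given before the probe only.

These choices are the simplest forms that jointly reproduce the reported
phenomenology: initial responses are similar across cues and decline with
exposure; predicted cues decline faster and further (SPE); switching the
within-pair order instantly restores the suppressed responses; swapping the
predicted cues restores them in an identity-specific way; the US−CS peak
difference declines monotonically over conditioning; and the probe A response
carries an inferred-value component that vanishes under OFC inactivation.

One timing refinement follows the same phenomenology: when a cue violates a
*strong identity-specific* expectation (its predecessor strongly predicts a
different cue, $\max_Y V_{X\to Y} - V_{X\to cue} > 0.5$), the impulse is
delayed by `surprise_latency` (default 1.5 s). Disambiguating an unexpected
identity takes time, so the swap response develops over seconds rather than
at onset — which is also why the swap analysis integrates 1–3 s after onset
rather than reading the onset peak.

The DMS site applies a gain (0.6) and an effective-rate multiplier (0.5)
relative to NAcc, giving the weaker, slower dorsomedial effects; behavior is
driven by the unscaled (NAcc-rate) state.

### Forward model and behavior

Impulses are convolved with a double-exponential kernel (rise 0.15 s, decay
1.0 s, unit peak) into $\mathrm{dff}(t)$, then rendered as

$$F_{470}(t) = B_{470}\,e^{-T(t)/\tau}\,\bigl(1 + s\,\sigma\,\mathrm{dff}(t)\bigr)
  + m(t) + \varepsilon(t), \qquad
F_{415}(t) = B_{415}\,e^{-T(t)/\tau} + c_m\,m(t) + \varepsilon'(t),$$

with $T(t)$ cumulative *recorded* time (recording is trial-gated; bleaching
persists across epochs), $m(t)$ a Poisson train of smooth Gaussian motion
bumps shared between channels, $\varepsilon$ i.i.d. Gaussian noise, and
$s \in \{0, 1\}$ the sensor flag ($s = 0$ emulates a binding-dead sensor
variant whose fluorescence is independent of dopamine). The coupling
$\sigma$ (`dff_scale`, default 0.2 per z-unit) keeps transients in the
tens-of-percent dF/F range of modern dopamine sensors; much larger couplings
are unphysical and would let the session-long decline in transient amplitude
covary with bleaching and leak into the isosbestic fit.

Food-port behavior realizes an expected cue occupancy
$p = \mathrm{logistic}\bigl(b_0 + b_1 (V_{cue} + c\sum_X V_{cue\to X}V_X)\bigr)$
as alternating out/in intervals with exponential durations over a ~4 s entry
cycle. With $b_0 = -3, b_1 = 5$, naive occupancy sits near 5% and a fully
conditioned cue near 80%, in the range typical for this task.

### Default parameters

Cohort sizes (6 CTRL + 8 OFCi), session structure (2 preconditioning + 6
conditioning + probe; switch and swap variants with a third preconditioning
session), 10 s cues, ~6 min ITIs, 50 Hz sampling and the 10 s baseline are
the task's stated conditions. The free parameters were set once from the
qualitative orderings above: $\alpha_{assoc} = 0.15$ (SD 0.05) so cue-cue
learning spans the 12 preconditioning pairings; $\alpha_{value} = 0.06$ so
value learning spans the 36 conditioning trials; $g_N = 1.5$, $\kappa =
0.15$, $g_S = 1.0$, $g_R = 2.5$, `chain_gain` 0.8; noise 1.5 a.u. on
baselines of 100/95 a.u. with bleach $\tau = 3600$ s; motion bumps at
2/min, SD 3 a.u., width 0.3 s, fully coupled into the reference
($c_m = 1$). ITIs can be compressed (`time_compression`) for desk-scale
runs: recording is trial-gated, so no analyzed quantity depends on them.

### What the generator does not emulate

No spiking-level dopamine model (impulses are amplitudes, not rates); no
hardware artifacts beyond the bump model (no LED interleaving, no camera);
noise is i.i.d. Gaussian rather than 1/f; the two pellets are rendered as a
single US impulse at the first pellet (the analysis reads one US response
per trial); behavior has no latency, satiety or locomotor structure; and
between-subject variability enters only through the cue-cue learning rate.
Passing the packaged checks therefore demonstrates that the *pipeline*
recovers the structure this model plants — it does not validate the model
against real recordings.

## The preprocessing chain

Per subject, site and recording session, strictly in this order:

1. **Median filter**, order 4 — a centered 5-sample sliding median per
   channel within each epoch, edges by symmetric reflection. Filtering
   precedes z-scoring; a single-sample artifact removed here can no longer
   inflate a baseline SD (a regression test asserts the order).
2. **Isosbestic correction** — the 470 nm channel is least-squares fit on a
   second-order polynomial of the 415 nm channel over all gated epochs of
   the session, and the fit is subtracted: $dF = F_{470} - \hat f(F_{415})$.
   The session scope is deliberate: per-trial fits on 10–30 s of data are
   unstable. A near-constant reference (< 3 distinct values) degenerates to
   mean subtraction with a warning.
3. **Per-trial z-score** against the 10 s pre-trial baseline
   ($-10 \le t < 0$, first cue onset at $t = 0$). The SD convention is the
   sample estimator ($n - 1$); `sd_method = "population"` is available. A
   zero baseline SD is an error naming the epoch.
4. **Session normalization** $z_{norm} = (z - B)/(P - B)$ with $B$ the mean
   of all baseline samples in the session and $P$ the single largest sample,
   so each subject-session spans baseline 0 to peak 1. The probe reminder
   and test trials share one physical session and hence one scope. $P \le B$
   is an error; the transform is idempotent.

## Quantification conventions

* **Peak**: maximum of $z_{norm}$ in 0–2 s after cue onset (the peak-search
  window is not fixed by common practice, so it is a declared, configurable
  default). The US peak uses the same width after the first pellet.
* **Matched no-US window**: unreinforced trials get a "US" window starting
  0.5 s after cue offset — the same latency the pellets would have — so
  reinforced and unreinforced series are directly comparable. The US − CS
  difference per session is the RPE read-out.
* **AUC**: trapezoidal integral over 1–3 s after onset, the window used for
  the slow swap response.
* **Predictedness**: a cue is *predicted* iff its trained pair partner
  immediately preceded it within the trial, derived from the event log, not
  from the learned state.
* **Occupancy**: percentage of the cue window covered by port intervals,
  clipped to the window and invariant to splitting intervals.
* **Bins**: start/middle/end of preconditioning are repetitions 1–2, 6–7 and
  11–12 of the 12 presentations of each cue; missing repetitions drop out of
  the mean with a message rather than failing.

## Statistics

* **Exact Wilcoxon signed-rank** (`wilcoxon_signed_exact`): zeros dropped,
  midranks for ties, null distribution computed exactly by convolution over
  the doubled midranks (equivalent to enumerating all $2^n$ sign
  assignments), two-sided p twice the smaller tail capped at 1. At the
  probe's group sizes the smallest attainable values are $2/2^6 = 0.03125$
  and $2/2^8 = 0.0078125$. Beyond $n = 25$ a tie- and continuity-corrected
  normal approximation takes over (irrelevant at these cohort sizes).
* **One-sided 2×2 chi-square**: Pearson statistic without continuity
  correction, halved into a direction the caller declares *before* seeing
  the data; an observed association opposite to the declaration gives
  $1 - p/2$. The two one-sided p-values of a table and its row-transpose
  sum to 1.
* **Inclusion rule**: a subject enters the probe analysis iff reminder
  B-occupancy ≥ 2 × D-occupancy. "Twice as much" is read as a minimum, so
  the boundary is inclusive. The discriminator flag (A/C index > 0.1) is
  strict, reading "above 0.1" literally.
* **Suppression ratio**: late(11–12)/early(1–2) mean peak, so *smaller*
  means *more suppressed*; with this orientation the control-group
  correlation between predicted-cue suppression and probe A/C
  discrimination is negative.
* **Regression**: ordinary least squares with slope t-tests; between-group
  slope differences via the interaction term of a pooled model. Robust
  outlier-rejecting regression is intentionally not implemented: points with
  |studentized residual| > 3 are flagged and reported, never removed.
* **Repeated-measures ANOVA**: balanced within-subject designs only, via
  error-stratified `aov`; its F values are verified against hand-computed
  sums of squares on a 3-subject fixture. Unbalanced input is refused
  rather than silently approximated.

## Numerical and reproducibility choices

Epochs are gated to $[-10\,\mathrm{s}, \text{last event} + 20\,\mathrm{s}]$;
the time grid is exact multiples of $1/f_s$, validated to $10^{-6}$ s on
read. The kernel is truncated beyond 14 decay constants ($<10^{-6}$ of
peak). Structural randomness (schedules, learning-rate draws, behavior) and
photometry rendering use separate seeded RNG streams derived from the config
seed, so restricting rendering to a subset of phases or sites — the main
lever for fast large-seed sweeps — leaves the latents bit-identical.
`simulate_cohort` is a deterministic function of its configuration, and
`run_all` with one configuration produces byte-identical CSVs.

The packaged checks run cohorts at the study's sizes (14 subjects; 5 and 6
for the switch/swap variants; 20 per group for the correlation and recovery
analyses) over seed sweeps of 20–100 replicates, sized so the whole suite
runs on one CPU in tens of minutes; the sweep sizes are reported alongside
each result.

## Known limitations

Counterbalancing rotates cue-to-stimulus assignment and block order by
subject index (the real scheme is not stated anywhere authoritative); the
ITI distribution is a uniform $[0.5, 1.5] \times$ mean model of an "~6 min
average"; the behavioral renewal process only approximates its target
occupancy on a 10 s window; and the OFCi manipulation is a single scalar
(chain gain zeroed at probe), which deliberately ignores any off-target
drug effects. The parameter-recovery fit conditions on the generator's own
novelty parameters and recovers only $\alpha_{assoc}$; joint recovery of all
gains from one cohort is not identified at these trial counts.
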