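#' Simulation configuration for a sensory preconditioning cohort
#'
#' Builds the full parameter set driving [simulate_cohort()]: cohort
#' composition, delta-rule learning rates, dopamine impulse gains, the sensor
#' forward model (kernel, photobleaching, motion artifacts, noise), the task
#' timing, and the behavioral read-out. Defaults encode the task as run in the
#' field: 10 s auditory cues, ~6 min intertrial intervals, 50 Hz per-channel
#' acquisition, cohorts of 6 control and 8 OFC-inactivated subjects.
#'
#' @param n_ctrl,n_ofci Number of control / OFC-inactivated subjects.
#' @param seed Integer seed; the whole simulated dataset is a deterministic
#'   function of the configuration including this seed.
#' @param alpha_assoc Cue-cue (sensory-sensory) delta-rule learning rate,
#'   in (0, 1].
#' @param alpha_assoc_sd Between-subject SD of `alpha_assoc` (truncated normal,
#'   clipped to \[0.02, 1\]). Individual differences in latent learning are what
#'   give the suppression-ratio vs. probe-discrimination correlation its
#'   spread across subjects.
#' @param alpha_value Cue-reward (Rescorla-Wagner) learning rate, in (0, 1].
#' @param lambda_r Reward asymptote of the value update, z-units.
#' @param novelty_gain,novelty_decay Initial novelty transient amplitude
#'   (z-units) and its per-exposure exponential decay rate (>= 0).
#' @param spe_gain Sensory prediction error gain (z-units): the part of the
#'   cue transient that is scaled by 1 - V(predictor -> cue).
#' @param rpe_gain Reward prediction error gain (z-units): scales both the US
#'   response `rpe_gain * (lambda_r - V)` and the value-driven CS component
#'   `rpe_gain * V`.
#' @param chain_gain Inferred-value pass-through in \[0, 1\]: how much of
#'   V(cue -> X) * V_val(X) reaches the probe-test response. Forced to 0 for
#'   OFCi subjects during the probe session (the only group difference).
#' @param site_scale Named list of per-site `c(gain=, rate=)` multipliers.
#'   DMS defaults to gain 0.6 / rate 0.5: weaker transients and slower
#'   effective learning than NAcc.
#' @param dff_scale Fractional fluorescence change per z-unit of impulse
#'   amplitude (sensor dynamic range): the active channel carries
#'   `1 + dff_scale * dff(t)`. The default 0.2 puts a 2 z-unit transient at
#'   40% dF/F, in the range of modern dopamine sensors.
#' @param noise_sd Per-channel iid Gaussian measurement noise, a.u.
#' @param bleach_tau Photobleaching time constant, seconds of *recorded* time
#'   (recording is gated to trials, and bleaching persists across epochs).
#' @param artifact_rate,artifact_sd,artifact_width Motion artifact bump rate
#'   (events/min), amplitude SD (a.u.) and Gaussian width (s).
#' @param artifact_coupling Fraction (in \[0, 1\]) of each motion bump that
#'   appears in the 415 nm reference channel.
#' @param kernel_rise,kernel_decay Sensor impulse-response time constants (s);
#'   must satisfy `kernel_decay > kernel_rise > 0`.
#' @param surprise_latency Extra latency (s) of the dopamine impulse when a
#'   cue violates a strong identity-specific expectation (its predecessor
#'   strongly predicts a *different* cue): disambiguating the unexpected
#'   identity takes time, so the transient develops slowly over seconds
#'   rather than at onset. Applies when the strongest association from the
#'   predecessor exceeds its association to the presented cue by more than
#'   0.5.
#' @param fs Per-channel sampling rate, Hz.
#' @param cue_duration Cue length, s.
#' @param iti_mean Mean intertrial interval, s; ITIs are drawn uniformly on
#'   \[0.5, 1.5\] x `iti_mean / time_compression`.
#' @param time_compression Divisor applied to ITIs for desk-scale runs. ITIs
#'   are never analyzed (recording is trial-gated), so compression does not
#'   change any derived quantity.
#' @param baseline_len Pre-trial baseline recorded before the first cue, s.
#' @param post_window Recording kept after the last trial event, s.
#' @param b0,b1 Intercept and slope of the logistic mapping from (cached +
#'   chained) cue value to expected food-port occupancy during the cue.
#' @param f470_baseline,f415_baseline Unbleached fluorescence baselines, a.u.
#' @param sensor_functional `FALSE` emulates a binding-dead sensor variant:
#'   fluorescence no longer depends on dopamine impulses.
#'
#' @return An object of class `spc_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_ctrl = 2, n_ofci = 0, seed = 42)
#' cfg$fs
#' @export
sim_config <- function(n_ctrl = 6, n_ofci = 8, seed = 1,
                       alpha_assoc = 0.15, alpha_assoc_sd = 0.05,
                       alpha_value = 0.06, lambda_r = 1,
                       novelty_gain = 1.5, novelty_decay = 0.15,
                       spe_gain = 1.0, rpe_gain = 2.5,
                       chain_gain = 0.8,
                       site_scale = list(NAcc = c(gain = 1.0, rate = 1.0),
                                         DMS = c(gain = 0.6, rate = 0.5)),
                       dff_scale = 0.2, noise_sd = 1.5, bleach_tau = 3600,
                       artifact_rate = 2, artifact_sd = 3,
                       artifact_width = 0.3, artifact_coupling = 1,
                       kernel_rise = 0.15, kernel_decay = 1.0,
                       surprise_latency = 1.5,
                       fs = 50, cue_duration = 10,
                       iti_mean = 360, time_compression = 1,
                       baseline_len = 10, post_window = 20,
                       b0 = -3, b1 = 5,
                       f470_baseline = 100, f415_baseline = 95,
                       sensor_functional = TRUE) {
  cfg <- list(
    n_ctrl = n_ctrl, n_ofci = n_ofci, seed = seed,
    alpha_assoc = alpha_assoc, alpha_assoc_sd = alpha_assoc_sd,
    alpha_value = alpha_value, lambda_r = lambda_r,
    novelty_gain = novelty_gain, novelty_decay = novelty_decay,
    spe_gain = spe_gain, rpe_gain = rpe_gain, chain_gain = chain_gain,
    site_scale = site_scale,
    dff_scale = dff_scale, noise_sd = noise_sd, bleach_tau = bleach_tau,
    artifact_rate = artifact_rate, artifact_sd = artifact_sd,
    artifact_width = artifact_width, artifact_coupling = artifact_coupling,
    kernel_rise = kernel_rise, kernel_decay = kernel_decay,
    surprise_latency = surprise_latency,
    fs = fs, cue_duration = cue_duration,
    iti_mean = iti_mean, time_compression = time_compression,
    baseline_len = baseline_len, post_window = post_window,
    b0 = b0, b1 = b1,
    f470_baseline = f470_baseline, f415_baseline = f415_baseline,
    sensor_functional = sensor_functional
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  for (f in c("n_ctrl", "n_ofci", "seed", "alpha_assoc", "alpha_assoc_sd",
              "alpha_value", "lambda_r", "novelty_gain", "novelty_decay",
              "spe_gain", "rpe_gain", "chain_gain", "dff_scale", "noise_sd", "bleach_tau",
              "artifact_rate", "artifact_sd", "artifact_width",
              "artifact_coupling", "kernel_rise", "kernel_decay", "surprise_latency", "fs",
              "cue_duration", "iti_mean", "time_compression", "baseline_len",
              "post_window", "b0", "b1", "f470_baseline", "f415_baseline")) {
    stop_if(!num1(cfg[[f]]), sprintf("config field '%s' must be a single finite number", f))
  }
  stop_if(cfg$n_ctrl < 0 || cfg$n_ofci < 0, "subject counts must be non-negative")
  stop_if(!(cfg$alpha_assoc > 0 && cfg$alpha_assoc <= 1),
          "alpha_assoc must lie in (0, 1]")
  stop_if(!(cfg$alpha_value > 0 && cfg$alpha_value <= 1),
          "alpha_value must lie in (0, 1]")
  stop_if(cfg$alpha_assoc_sd < 0, "alpha_assoc_sd must be >= 0")
  stop_if(cfg$novelty_decay < 0, "novelty_decay must be >= 0")
  stop_if(cfg$chain_gain < 0 || cfg$chain_gain > 1,
          "chain_gain must lie in [0, 1]")
  stop_if(cfg$artifact_coupling < 0 || cfg$artifact_coupling > 1,
          "artifact_coupling must lie in [0, 1]")
  stop_if(cfg$fs <= 0, "fs must be positive")
  stop_if(!(cfg$kernel_decay > cfg$kernel_rise && cfg$kernel_rise > 0),
          "kernel time constants must satisfy kernel_decay > kernel_rise > 0")
  stop_if(cfg$surprise_latency < 0, "surprise_latency must be >= 0")
  stop_if(cfg$cue_duration <= 0, "cue_duration must be positive")
  stop_if(cfg$baseline_len <= 0, "baseline_len must be positive")
  stop_if(cfg$post_window < 0, "post_window must be >= 0")
  stop_if(cfg$iti_mean <= 0 || cfg$time_compression <= 0,
          "iti_mean and time_compression must be positive")
  stop_if(!is.list(cfg$site_scale) || is.null(names(cfg$site_scale)),
          "site_scale must be a named list of c(gain=, rate=) pairs")
  for (s in names(cfg$site_scale)) {
    sc <- cfg$site_scale[[s]]
    stop_if(!all(c("gain", "rate") %in% names(sc)),
            sprintf("site_scale[['%s']] needs 'gain' and 'rate'", s))
  }
  stop_if(!is.logical(cfg$sensor_functional) || length(cfg$sensor_functional) != 1L,
          "sensor_functional must be a single logical")
  structure(cfg, class = "spc_config")
}

#' @export
print.spc_config <- function(x, ...) {
  cat("<spc_config>\n")
  cat(sprintf("  cohort: %d CTRL + %d OFCi, seed %d\n",
              x$n_ctrl, x$n_ofci, as.integer(x$seed)))
  cat(sprintf("  learning: alpha_assoc %.3g (sd %.3g), alpha_value %.3g, lambda %.3g\n",
              x$alpha_assoc, x$alpha_assoc_sd, x$alpha_value, x$lambda_r))
  cat(sprintf("  gains: novelty %.3g (decay %.3g), SPE %.3g, RPE %.3g, chain %.3g\n",
              x$novelty_gain, x$novelty_decay, x$spe_gain, x$rpe_gain, x$chain_gain))
  cat(sprintf("  acquisition: %g Hz, cue %g s, baseline %g s, post %g s, sensor %s\n",
              x$fs, x$cue_duration, x$baseline_len, x$post_window,
              if (x$sensor_functional) "functional" else "dead"))
  invisible(x)
}

# fields that may appear in a config file; everything else is rejected
config_known_keys <- function() {
  names(formals(sim_config))
}
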