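#' Sensor impulse-response kernel
#'
#' Double-exponential rise/decay kernel normalized to unit peak:
#' `k(t) = (exp(-t / decay) - exp(-t / rise)) / k_max` for `t >= 0`, 0 before.
#'
#' @param t Times (s) at which to evaluate the kernel.
#' @param rise,decay Time constants (s), `decay > rise > 0`.
#' @return Kernel values, unit peak.
#' @export
photometry_kernel <- function(t, rise, decay) {
  stopifnot(decay > rise, rise > 0)
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  k_max <- exp(-t_peak / decay) - exp(-t_peak / rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / k_max
  out
}

#' Render one two-channel photometry epoch
#'
#' Forward model from dopamine impulses to raw fluorescence. The true
#' dopamine signal is `dff(t) = sum_i a_i * k(t - t_i)` with `k` the unit-peak
#' kernel. Channels:
#' \preformatted{
#'   f470(t) = B470 * exp(-T(t)/bleach_tau) * (1 + s * dff_scale * dff(t)) + m(t) + e(t)
#'   f415(t) = B415 * exp(-T(t)/bleach_tau) + c_m * m(t) + e'(t)
#' }
#' where `s` is 1 for a functional sensor and 0 for the binding-dead variant,
#' `m(t)` is a train of smooth Gaussian motion bumps shared between channels
#' (scaled by the coupling `c_m` in the reference), `e, e'` are independent
#' Gaussian noise, and `T(t)` is cumulative *recorded* time: photobleaching
#' persists across the trial-gated epochs, so the caller passes the recording
#' time already accumulated before this epoch.
#'
#' Draws from the current RNG stream; seed upstream for reproducibility.
#'
#' @param impulses Data frame with columns `time_s` and `amplitude`
#'   (epoch-relative impulse times and z-unit amplitudes); may have 0 rows.
#' @param epoch_start,epoch_end Epoch bounds, s (start is usually
#'   `-baseline_len`).
#' @param config An [sim_config()].
#' @param t_recorded Recorded time accumulated before this epoch, s.
#' @return A tibble with `time_s`, `f470`, `f415`, and the ground-truth
#'   latents `dff` and `artifact`.
#' @export
render_photometry <- function(impulses, epoch_start, epoch_end, config,
                              t_recorded = 0) {
  stopifnot(inherits(config, "spc_config"), epoch_end > epoch_start)
  fs <- config$fs
  n <- round((epoch_end - epoch_start) * fs) + 1L
  t <- epoch_start + (seq_len(n) - 1L) / fs

  dff <- numeric(n)
  if (!is.null(impulses) && nrow(impulses) > 0) {
    support <- 14 * config$kernel_decay  # kernel < 1e-6 of peak beyond this
    for (i in seq_len(nrow(impulses))) {
      ti <- impulses$time_s[i]
      idx <- which(t >= ti & t <= ti + support)
      if (length(idx) == 0) next
      dff[idx] <- dff[idx] + impulses$amplitude[i] *
        photometry_kernel(t[idx] - ti, config$kernel_rise, config$kernel_decay)
    }
  }

  # shared motion artifact: Poisson train of Gaussian bumps
  dur <- epoch_end - epoch_start
  m <- numeric(n)
  n_art <- stats::rpois(1, config$artifact_rate / 60 * dur)
  if (n_art > 0) {
    centers <- stats::runif(n_art, epoch_start, epoch_end)
    amps <- stats::rnorm(n_art, 0, config$artifact_sd)
    for (j in seq_len(n_art)) {
      m <- m + amps[j] * exp(-(t - centers[j])^2 / (2 * config$artifact_width^2))
    }
  }

  bleach <- exp(-(t_recorded + (t - epoch_start)) / config$bleach_tau)
  s <- as.numeric(config$sensor_functional)
  f470 <- config$f470_baseline * bleach * (1 + s * config$dff_scale * dff) + m +
    stats::rnorm(n, 0, config$noise_sd)
  f415 <- config$f415_baseline * bleach + config$artifact_coupling * m +
    stats::rnorm(n, 0, config$noise_sd)

  tibble::new_tibble(list(time_s = t, f470 = f470, f415 = f415, dff = dff,
                          artifact = m), nrow = n)
}

#' Simulate food-port behavior for one trial
#'
#' Expected occupancy during a cue is a logistic function of its total
#' (cached + chained) value:
#' `p = plogis(b0 + b1 * (V_val[cue] + chain * sum_X V_pair[cue -> X] V_val[X]))`
#' with `chain` zeroed for OFCi subjects during the probe session. The
#' expectation is realized as alternating out/in intervals with exponential
#' durations whose means are split `(1 - p, p)` over a ~4 s entry cycle, so
#' the long-run fraction of time in the port matches `p`.
#'
#' Draws from the current RNG stream.
#'
#' @param state An [assoc_state()].
#' @param cues Character vector of cues in this trial.
#' @param onsets Cue onsets (epoch-relative s), same length as `cues`.
#' @param phase Phase id (the probe phases gate the OFCi chain knock-out).
#' @param group `"CTRL"` or `"OFCi"`.
#' @param config An [sim_config()].
#' @return List with `intervals` (list of parallel vectors `cue`, `enter_s`,
#'   `exit_s`), `n` (number of intervals) and `p_occ` (named expected
#'   occupancy per cue).
#' @export
simulate_behavior <- function(state, cues, onsets, phase, group, config) {
  chain <- if (identical(group, "OFCi") && startsWith(phase, "probe")) 0
           else config$chain_gain
  cycle <- 4  # mean in+out renewal cycle, s
  cue_o <- character(0); enter_o <- numeric(0); exit_o <- numeric(0)
  p_occ <- stats::setNames(numeric(length(cues)), cues)
  for (i in seq_along(cues)) {
    cue <- cues[i]
    value <- state$V_val[[cue]] + chain * sum(state$V_pair[cue, ] * state$V_val)
    p <- stats::plogis(config$b0 + config$b1 * value)
    p_occ[i] <- p
    on <- onsets[i]
    off <- on + config$cue_duration
    t <- on
    inside <- FALSE
    while (t < off) {
      mean_dur <- if (inside) cycle * p else cycle * (1 - p)
      d <- stats::rexp(1, 1 / max(mean_dur, 1e-6))
      if (inside) {
        cue_o <- c(cue_o, cue)
        enter_o <- c(enter_o, t)
        exit_o <- c(exit_o, min(t + d, off))
      }
      t <- t + d
      inside <- !inside
    }
  }
  list(intervals = list(cue = cue_o, enter_s = enter_o, exit_s = exit_o),
       n = length(cue_o), p_occ = p_occ)
}
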