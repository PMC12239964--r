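#' Associative state of one simulated subject
#'
#' Tracks, per cue, the delta-rule quantities that drive both the simulated
#' dopamine transients and the simulated food-port behavior: the cue-cue
#' association matrix `V_pair` (predictor in rows, target in columns), the
#' cached cue values `V_val`, and the exposure counts `n_exp` that drive the
#' novelty decay.
#'
#' @param cues Character vector of cue identities.
#' @return Object of class `spc_state`.
#' @examples
#' st <- assoc_state()
#' st$V_pair["A", "B"]
#' @export
assoc_state <- function(cues = c("A", "B", "C", "D")) {
  structure(list(
    V_pair = matrix(0, length(cues), length(cues),
                    dimnames = list(predictor = cues, target = cues)),
    V_val = stats::setNames(numeric(length(cues)), cues),
    n_exp = stats::setNames(integer(length(cues)), cues)
  ), class = "spc_state")
}

#' Delta-rule update of a cue-cue association
#'
#' `V <- V + alpha_assoc * (1 - V)`: one trial of sensory-sensory learning for
#' the pair (predictor -> target). All other entries are untouched, so
#' strengths stay in \[0, 1\] under arbitrary schedules.
#'
#' @param state An [assoc_state()].
#' @param predictor,target Cue identities.
#' @param alpha_assoc Learning rate in (0, 1].
#' @return The updated state.
#' @export
update_pair <- function(state, predictor, target, alpha_assoc) {
  stopifnot(inherits(state, "spc_state"))
  if (!(alpha_assoc > 0 && alpha_assoc <= 1))
    stop("alpha_assoc must lie in (0, 1]", call. = FALSE)
  v <- state$V_pair[predictor, target]
  state$V_pair[predictor, target] <- v + alpha_assoc * (1 - v)
  state
}

#' Rescorla-Wagner update of a cached cue value
#'
#' `V <- V + alpha_value * (lambda_r * reward - V)`. With `reward_present =
#' FALSE` this is an extinction step toward zero.
#'
#' @param state An [assoc_state()].
#' @param cs Cue identity.
#' @param reward_present Logical: was the cue followed by reward?
#' @param alpha_value Learning rate in (0, 1].
#' @param lambda_r Reward asymptote (z-units).
#' @return The updated state.
#' @export
update_value <- function(state, cs, reward_present, alpha_value, lambda_r = 1) {
  stopifnot(inherits(state, "spc_state"))
  if (!(alpha_value > 0 && alpha_value <= 1))
    stop("alpha_value must lie in (0, 1]", call. = FALSE)
  v <- state$V_val[cs]
  state$V_val[cs] <- v + alpha_value * (lambda_r * as.numeric(reward_present) - v)
  state
}

#' Dopamine impulse amplitude at cue onset
#'
#' The cue transient is the sum of a declining novelty component, a sensory
#' prediction error component, and a value-driven component:
#'
#' `a = g_N * exp(-kappa_eff * n_exp) + g_S * (1 - p) + g_R * V_val`
#'
#' where `p = V_pair[predictor -> cue]` if a predictor cue immediately
#' preceded this cue within the trial and 0 otherwise, and `kappa_eff` is the
#' novelty decay scaled by the site's rate multiplier. The whole amplitude is
#' scaled by the site gain. `n_exp` is the exposure count *before* this
#' presentation; the caller increments it afterwards.
#'
#' @param state An [assoc_state()].
#' @param cue Cue identity.
#' @param predictor Cue that immediately preceded `cue` in this trial, or
#'   `NULL` if the cue opened the trial.
#' @param config An [sim_config()].
#' @param site Recording site name (indexes `config$site_scale`).
#' @return Impulse amplitude (z-units).
#' @export
cue_amplitude <- function(state, cue, predictor = NULL, config, site = "NAcc") {
  sc <- config$site_scale[[site]]
  if (is.null(sc)) stop(sprintf("unknown site '%s'", site), call. = FALSE)
  p <- if (!is.null(predictor)) state$V_pair[predictor, cue] else 0
  kap <- config$novelty_decay * sc[["rate"]]
  a <- config$novelty_gain * exp(-kap * state$n_exp[[cue]]) +
    config$spe_gain * (1 - p) +
    config$rpe_gain * state$V_val[[cue]]
  unname(a * sc[["gain"]])
}

#' Dopamine impulse amplitude at reward (US) delivery
#'
#' Classic reward prediction error: `a = g_R * (lambda_r - V_val[cs])`, scaled
#' by the site gain. Shrinks to zero as the CS value saturates; the
#' complementary value-driven CS component lives in [cue_amplitude()].
#'
#' @inheritParams cue_amplitude
#' @param cs The conditioned cue whose value discounts the US.
#' @return Impulse amplitude (z-units).
#' @export
reward_amplitude <- function(state, cs, config, site = "NAcc") {
  sc <- config$site_scale[[site]]
  if (is.null(sc)) stop(sprintf("unknown site '%s'", site), call. = FALSE)
  unname(config$rpe_gain * (config$lambda_r - state$V_val[[cs]]) * sc[["gain"]])
}

#' Inferred-value component of a probe-test cue response
#'
#' Value reaches a never-rewarded cue through the chained product of its
#' cue-cue association and the partner's cached value:
#' `chain_gain * sum_X V_pair[cue -> X] * V_val[X] * g_R`, scaled by the site
#' gain. `chain_gain` is zeroed for OFCi subjects (inference depends on intact
#' orbitofrontal cortex), which is the only modeled group difference.
#'
#' @inheritParams cue_amplitude
#' @param group `"CTRL"` or `"OFCi"`.
#' @return Additional impulse amplitude (z-units).
#' @export
inferred_amplitude <- function(state, cue, config, group = "CTRL", site = "NAcc") {
  sc <- config$site_scale[[site]]
  if (is.null(sc)) stop(sprintf("unknown site '%s'", site), call. = FALSE)
  cg <- if (identical(group, "OFCi")) 0 else config$chain_gain
  chained <- sum(state$V_pair[cue, ] * state$V_val)
  unname(cg * chained * config$rpe_gain * sc[["gain"]])
}
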