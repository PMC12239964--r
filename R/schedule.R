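#' Build the trial list for one session
#'
#' Generates the within-session trial structure of the sensory preconditioning
#' task. Phases:
#' \describe{
#'   \item{preconditioning}{12 trials: six contiguous A->B pairs and six
#'     contiguous C->D pairs (block order set by `block_order`), no reward.}
#'   \item{conditioning}{12 single-cue trials in randomized order: six B
#'     followed by two sucrose pellets, six D unreinforced.}
#'   \item{probe_reminder}{Six randomized reminder trials: three rewarded B,
#'     three unreinforced D.}
#'   \item{probe_test}{Blocked presentations, six each of A and C alone, no
#'     outcome.}
#'   \item{switch}{Per pair, three trials in the trained order then three with
#'     the order reversed (A->B, then B->A; C->D, then D->C).}
#'   \item{swap}{Per leading cue, three trials in the trained order then three
#'     with the predicted cues exchanged (A->B then A->D; C->D then C->B).}
#' }
#' Within a trial, cues abut: the first cue onsets at t = 0 (epoch-relative)
#' and each subsequent cue at the previous offset. Pellets are delivered 0.5 s
#' and 1.0 s after the rewarded cue's offset. Intertrial intervals are drawn
#' uniformly on \[0.5, 1.5\] x `iti_mean / time_compression` from the current
#' RNG stream.
#'
#' @param config An [sim_config()].
#' @param phase One of `"preconditioning"`, `"conditioning"`,
#'   `"probe_reminder"`, `"probe_test"`, `"switch"`, `"swap"`.
#' @param session_index Session number within the phase (>= 1).
#' @param block_order `"AB"` or `"CD"`: which cue pair (or lead cue) opens the
#'   blocked phases; used for counterbalancing across subjects.
#' @return A tibble with one row per trial: `phase`, `session`, `trial`,
#'   list-columns `cues`, `onsets`, `reward_times` (epoch-relative seconds),
#'   plus `iti_s`, `epoch_start` and `epoch_end`.
#' @examples
#' sch <- build_schedule(sim_config(), "preconditioning", 1)
#' nrow(sch)   # 12
#' @export
build_schedule <- function(config, phase, session_index, block_order = "AB") {
  stopifnot(inherits(config, "spc_config"))
  phases <- c("preconditioning", "conditioning", "probe_reminder",
              "probe_test", "switch", "swap")
  if (!(is.character(phase) && length(phase) == 1L && phase %in% phases))
    stop(sprintf("unknown phase '%s'; must be one of %s",
                 paste(phase, collapse = ","), paste(phases, collapse = ", ")),
         call. = FALSE)
  if (session_index < 1) stop("session_index must be >= 1", call. = FALSE)
  block_order <- match.arg(block_order, c("AB", "CD"))

  ab_first <- identical(block_order, "AB")
  seqs <- switch(phase,
    preconditioning = {
      ab <- rep(list(c("A", "B")), 6)
      cd <- rep(list(c("C", "D")), 6)
      if (ab_first) c(ab, cd) else c(cd, ab)
    },
    conditioning = {
      lead <- sample(rep(c("B", "D"), each = 6))
      lapply(lead, function(x) x)
    },
    probe_reminder = {
      lead <- sample(rep(c("B", "D"), each = 3))
      lapply(lead, function(x) x)
    },
    probe_test = {
      a <- rep(list("A"), 6)
      c_ <- rep(list("C"), 6)
      if (ab_first) c(a, c_) else c(c_, a)
    },
    switch = {
      ab <- c(rep(list(c("A", "B")), 3), rep(list(c("B", "A")), 3))
      cd <- c(rep(list(c("C", "D")), 3), rep(list(c("D", "C")), 3))
      if (ab_first) c(ab, cd) else c(cd, ab)
    },
    swap = {
      ab <- c(rep(list(c("A", "B")), 3), rep(list(c("A", "D")), 3))
      cd <- c(rep(list(c("C", "D")), 3), rep(list(c("C", "B")), 3))
      if (ab_first) c(ab, cd) else c(cd, ab)
    }
  )

  rewarded <- switch(phase,
    conditioning = vapply(seqs, function(s) s[[1]] == "B", logical(1)),
    probe_reminder = vapply(seqs, function(s) s[[1]] == "B", logical(1)),
    rep(FALSE, length(seqs))
  )

  dur <- config$cue_duration
  n <- length(seqs)
  onsets <- lapply(seqs, function(s) dur * (seq_along(s) - 1))
  reward_times <- vector("list", n)
  epoch_end <- numeric(n)
  for (i in seq_len(n)) {
    last_off <- onsets[[i]][length(onsets[[i]])] + dur
    if (rewarded[i]) {
      reward_times[[i]] <- last_off + c(0.5, 1.0)
      last_event <- last_off + 1.0
    } else {
      reward_times[[i]] <- numeric(0)
      last_event <- last_off
    }
    epoch_end[i] <- last_event + config$post_window
  }
  iti <- stats::runif(n, 0.5, 1.5) * config$iti_mean / config$time_compression

  tibble::tibble(
    phase = phase,
    session = as.integer(session_index),
    trial = seq_len(n),
    cues = seqs,
    onsets = onsets,
    reward_times = reward_times,
    iti_s = iti,
    epoch_start = -config$baseline_len,
    epoch_end = epoch_end
  )
}

# canonical epoch identifier: phase + session + trial
epoch_id_for <- function(phase, session, trial) {
  sprintf("%s_s%02d_t%03d", phase, as.integer(session), as.integer(trial))
}

# recording-session label: the probe reminder and test happen in one
# physical session and share one normalization scope
session_uid_for <- function(phase, session) {
  ifelse(startsWith(phase, "probe"), "probe",
         paste0(phase, "_s", sprintf("%02d", as.integer(session))))
}
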