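#' Peak response within a window
#'
#' Maximum of an aligned trace inside `[window[1], window[2]]` (inclusive),
#' with time 0 at the aligned event.
#'
#' @param time_s Times relative to the aligned event.
#' @param values Trace values (typically `znorm`).
#' @param window Two numbers, s.
#' @return Scalar peak.
#' @export
peak_response <- function(time_s, values, window = c(0, 2)) {
  idx <- time_s >= window[1] & time_s <= window[2]
  if (!any(idx)) stop("no samples inside the peak window", call. = FALSE)
  max(values[idx])
}

#' Area under the curve within a window
#'
#' Trapezoidal integral of the aligned trace over `[window[1], window[2]]`
#' (the slow post-onset component is quantified over 1-3 s by default).
#'
#' @inheritParams peak_response
#' @return Scalar AUC (value-units x s).
#' @export
auc_response <- function(time_s, values, window = c(1, 3)) {
  idx <- time_s >= window[1] & time_s <= window[2]
  if (sum(idx) < 2) stop("need at least 2 samples inside the AUC window", call. = FALSE)
  o <- order(time_s[idx])
  pracma::trapz(time_s[idx][o], values[idx][o])
}

#' Percentage of cue time spent in the food port
#'
#' Sums the overlap of port-entry intervals with the cue window and expresses
#' it as a percentage of the cue duration. Intervals are clipped to the cue
#' window, so the result is invariant to splitting an interval into abutting
#' pieces.
#'
#' @param enter_s,exit_s Entry/exit times of port intervals (any times;
#'   non-overlapping per trial).
#' @param cue_start,cue_end Cue window bounds, s.
#' @return Occupancy percentage in \[0, 100\].
#' @export
port_occupancy <- function(enter_s, exit_s, cue_start, cue_end) {
  stopifnot(cue_end > cue_start)
  if (length(enter_s) == 0) return(0)
  lo <- pmax(enter_s, cue_start)
  hi <- pmin(exit_s, cue_end)
  100 * sum(pmax(hi - lo, 0)) / (cue_end - cue_start)
}

# partner map of the trained pairs: used for the predictedness label
cue_partner <- c(A = "B", B = "A", C = "D", D = "C")

#' Align normalized trials to a cue's onset
#'
#' Extracts, for every trial containing `cue`, the normalized trace in a
#' window around that cue's onset, relabeled so the cue onset is t = 0.
#' Each trial carries a `predictedness` label: `"predicted"` iff the cue was
#' immediately preceded within the trial by its trained pair partner.
#'
#' @param norm An `spc_normalized` (from [preprocess_photometry()]) or its
#'   `trials` tibble.
#' @param events Event log tibble.
#' @param cue Cue identity to align on.
#' @param window Alignment window (s relative to the cue onset).
#' @return Tibble: `subject`, `site`, `phase`, `session`, `trial`, `cue`,
#'   `predictedness`, `rel_time`, `znorm`. Zero rows (with a warning) if the
#'   cue never occurs.
#' @export
align_trials <- function(norm, events, cue, window = c(-2, 12)) {
  trials <- if (inherits(norm, "spc_normalized")) norm$trials else norm
  cue_ev <- annotate_cue_events(events)
  cue_ev <- cue_ev[cue_ev$cue == cue, ]
  if (nrow(cue_ev) == 0) {
    warning(sprintf("cue '%s' not found in any trial", cue))
    return(tibble::tibble(subject = character(), site = character(),
                          phase = character(), session = integer(),
                          trial = integer(), cue = character(),
                          predictedness = character(), rel_time = numeric(),
                          znorm = numeric()))
  }
  dt <- data.table::as.data.table(trials)
  ev <- data.table::as.data.table(
    cue_ev[, c("subject", "epoch_id", "cue", "time_s", "predictedness",
               "phase", "session", "trial")])
  data.table::setnames(ev, "time_s", "onset_s")
  j <- merge(dt[, .(subject, site, epoch_id, time_s, znorm)], ev,
             by = c("subject", "epoch_id"), allow.cartesian = TRUE)
  j[, rel_time := time_s - onset_s]
  j <- j[rel_time >= window[1] & rel_time <= window[2]]
  out <- j[, .(subject, site, phase, session, trial, cue, predictedness,
               rel_time, znorm)]
  data.table::setorder(out, subject, site, phase, session, trial, rel_time)
  tibble::as_tibble(out)
}

# label each cue_onset event with its within-trial predecessor and
# predictedness (predicted iff preceded by its trained pair partner)
annotate_cue_events <- function(events) {
  ev <- as.data.frame(events[events$event_kind == "cue_onset", ])
  o <- order(ev$subject, ev$epoch_id, ev$time_s)
  ev <- ev[o, ]
  key <- paste(ev$subject, ev$epoch_id)
  prev_cue <- c(NA_character_, ev$cue[-nrow(ev)])
  prev_key <- c(NA_character_, key[-nrow(ev)])
  prev_cue[is.na(prev_key) | prev_key != key] <- NA_character_
  ev$predecessor <- prev_cue
  ev$predictedness <- ifelse(!is.na(prev_cue) & cue_partner[ev$cue] == prev_cue,
                             "predicted", "unpredicted")
  ev
}

#' Per-trial response rows
#'
#' The workhorse summary: one row per cue presentation with the peak of the
#' normalized response after cue onset, the AUC of the slow component, the
#' peak after reward delivery (or in a matched window after cue offset for
#' unreinforced trials, so reinforced and unreinforced series are
#' comparable), and the food-port occupancy during the cue.
#'
#' @param norm An `spc_normalized` or its `trials` tibble.
#' @param events Event log tibble.
#' @param port Port-entry interval tibble (`subject`, `epoch_id`, `enter_s`,
#'   `exit_s`); may be `NULL`, in which case `behavior_pct` is `NA`.
#' @param peak_window Post-onset window for cue peaks (s).
#' @param auc_window Window for the slow-component AUC (s).
#' @param us_window Window after the (first) reward delivery for the US peak
#'   (s); the matched no-US window starts `us_delay` after cue offset.
#' @param us_delay Delay from cue offset to the matched-window start (equal to
#'   the programmed delay from offset to the first pellet), s.
#' @return Tibble with columns `subject`, `group`, `site`, `phase`, `session`,
#'   `trial`, `cue`, `predictedness`, `peak`, `auc`, `us_peak`,
#'   `behavior_pct`. Every cue event contributes a row per rendered site;
#'   trials without photometry keep their behavior with `NA` response
#'   statistics.
#' @export
quantify_responses <- function(norm, events, port = NULL,
                               peak_window = c(0, 2), auc_window = c(1, 3),
                               us_window = c(0, 2), us_delay = 0.5) {
  trials <- if (inherits(norm, "spc_normalized")) norm$trials else norm
  dt <- data.table::as.data.table(trials)[, .(subject, site, epoch_id,
                                              time_s, znorm)]
  ev <- annotate_cue_events(events)
  grp <- unique(events[, c("subject", "group")])

  rew <- as.data.frame(events[events$event_kind == "reward", ])
  first_rew <- if (nrow(rew) > 0) {
    stats::aggregate(time_s ~ subject + epoch_id, data = rew, FUN = min)
  } else data.frame(subject = character(), epoch_id = character(),
                    time_s = numeric())
  names(first_rew)[names(first_rew) == "time_s"] <- "us_time"

  ev <- merge(ev, first_rew, by = c("subject", "epoch_id"), all.x = TRUE)
  # matched window for unreinforced trials: same offset after cue end
  ev$us_time <- ifelse(is.na(ev$us_time),
                       ev$time_s + ev$duration_s + us_delay, ev$us_time)

  ev_key <- paste(ev$subject, ev$epoch_id)
  ev_split <- split(ev[, c("phase", "session", "trial", "cue", "time_s",
                           "predictedness", "us_time")], ev_key)

  stats_dt <- dt[, {
    evs <- ev_split[[paste(subject[1], epoch_id[1])]]
    if (is.null(evs)) NULL else {
      ne <- nrow(evs)
      pk <- au <- us <- numeric(ne)
      for (r in seq_len(ne)) {
        rel <- time_s - evs$time_s[r]
        pk[r] <- peak_response(rel, znorm, peak_window)
        au[r] <- auc_response(rel, znorm, auc_window)
        relu <- time_s - evs$us_time[r]
        us[r] <- if (any(relu >= us_window[1] & relu <= us_window[2]))
          peak_response(relu, znorm, us_window) else NA_real_
      }
      list(cue = evs$cue, peak = pk, auc = au, us_peak = us)
    }
  }, by = .(subject, site, epoch_id)]

  # one row per cue event and rendered site; trials without photometry keep
  # their behavior columns with NA response statistics
  sites_present <- unique(dt$site)
  base <- ev[, c("subject", "epoch_id", "phase", "session", "trial", "cue",
                 "predictedness")]
  out <- dplyr::bind_rows(lapply(sites_present, function(st) {
    b <- base
    b$site <- st
    b
  }))
  out <- dplyr::left_join(out, tibble::as_tibble(stats_dt),
                          by = c("subject", "site", "epoch_id", "cue"))
  out <- dplyr::left_join(out, tibble::as_tibble(grp), by = "subject")

  # behavior: occupancy of each cue window
  if (!is.null(port) && nrow(port) > 0) {
    pd <- data.table::as.data.table(
      port[, c("subject", "epoch_id", "enter_s", "exit_s")])
    cues <- data.table::as.data.table(
      ev[, c("subject", "epoch_id", "cue", "time_s", "duration_s")])
    pj <- merge(cues, pd, by = c("subject", "epoch_id"),
                allow.cartesian = TRUE, all.x = TRUE)
    beh <- pj[, .(behavior_pct = port_occupancy(
      enter_s[!is.na(enter_s)], exit_s[!is.na(enter_s)],
      time_s[1], time_s[1] + duration_s[1])),
      by = .(subject, epoch_id, cue)]
    out <- dplyr::left_join(out, tibble::as_tibble(beh),
                            by = c("subject", "epoch_id", "cue"))
    out$behavior_pct[is.na(out$behavior_pct)] <- 0
  } else {
    out$behavior_pct <- NA_real_
  }
  dplyr::arrange(dplyr::select(out, subject, group, site, phase, session,
                               trial, cue, predictedness, epoch_id, peak, auc,
                               us_peak, behavior_pct),
                 subject, site, phase, session, trial)
}

#' Start / middle / end bins of the preconditioning peaks
#'
#' Averages per-subject, per-site, per-predictedness peak responses over the
#' concatenated 12 preconditioning presentations of each cue: start = reps
#' 1-2, middle = reps 6-7, end = reps 11-12. Missing repetitions simply drop
#' out of the mean (with a message).
#'
#' @param rows Output of [quantify_responses()].
#' @param bins Named list of repetition indices.
#' @return Tibble: `subject`, `site`, `predictedness`, `bin`, `peak`.
#' @export
phase_bins <- function(rows,
                       bins = list(start = 1:2, middle = 6:7, end = 11:12)) {
  pre <- rows[rows$phase == "preconditioning", ]
  if (nrow(pre) == 0) stop("no preconditioning rows", call. = FALSE)
  pre <- dplyr::arrange(pre, subject, site, cue, session, trial)
  pre <- dplyr::mutate(dplyr::group_by(pre, subject, site, cue),
                       rep = dplyr::row_number())
  pre <- dplyr::ungroup(pre)
  want <- sort(unique(unlist(bins)))
  if (!all(want %in% pre$rep))
    message("phase_bins: some requested repetitions are absent; using available trials")
  binned <- lapply(names(bins), function(b) {
    sel <- pre[pre$rep %in% bins[[b]], ]
    agg <- dplyr::summarise(
      dplyr::group_by(sel, subject, site, predictedness),
      peak = mean(peak), .groups = "drop")
    agg$bin <- b
    agg
  })
  out <- dplyr::bind_rows(binned)
  out$bin <- factor(out$bin, levels = names(bins))
  dplyr::arrange(out, subject, site, predictedness, bin)
}

#' US - CS peak difference per conditioning session
#'
#' For every subject, site, session and cue, the mean peak in the
#' post-delivery window minus the mean peak at cue onset. For the
#' unreinforced cue the "US" window is the matched post-offset window, so
#' both series live on the same scale. A progressive decline of this
#' difference for the reinforced cue is the signature of a reward prediction
#' error transferring from the US to the CS.
#'
#' @param rows Output of [quantify_responses()] (conditioning rows are used).
#' @return Tibble: `subject`, `site`, `session`, `cue`, `us_cs_diff`.
#' @export
us_cs_difference <- function(rows) {
  cond <- rows[rows$phase == "conditioning", ]
  if (nrow(cond) == 0) stop("no conditioning rows", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(cond, subject, site, session, cue),
    us_cs_diff = mean(us_peak) - mean(peak), .groups = "drop")
}
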