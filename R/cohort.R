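# derive a 32-bit sub-seed for an independent RNG stream
mix_seed <- function(seed, a, b = 0L) {
  as.integer((abs(seed) %% 100000L) * 977L + a * 131L + b * 151L) %% 2147483629L + 1L
}

# convert a data.table to a tibble without copying columns
dt_to_tbl <- function(dt) {
  data.table::setDF(dt)
  tibble::new_tibble(dt)
}

variant_sessions <- function(variant) {
  switch(variant,
    main = ,
    mutant = data.frame(
      phase = c("preconditioning", "preconditioning",
                rep("conditioning", 6), "probe_reminder", "probe_test"),
      session = c(1L, 2L, 1:6, 1L, 1L)
    ),
    switch = data.frame(
      phase = c("preconditioning", "preconditioning", "switch"),
      session = c(1L, 2L, 3L)
    ),
    swap = data.frame(
      phase = c("preconditioning", "preconditioning", "swap"),
      session = c(1L, 2L, 3L)
    )
  )
}

#' Simulate a complete sensory preconditioning cohort
#'
#' Runs the full experiment for every subject: two preconditioning sessions,
#' six conditioning sessions, and a probe session (reminder trials followed by
#' blocked A/C tests) for the `"main"` variant; the `"switch"` and `"swap"`
#' variants replace conditioning and probe with a third preconditioning
#' session whose second half reverses or exchanges the cue order; `"mutant"`
#' is the main schedule recorded with a binding-dead sensor
#' (`sensor_functional = FALSE`).
#'
#' Latent learning (delta-rule cue-cue and cue-value updates, exposure counts)
#' and food-port behavior are always simulated in full from an RNG stream
#' derived from `config$seed`, independent of which phases or sites are
#' rendered as photometry, so ground-truth latents are identical regardless of
#' `photometry_phases`/`sites`. The photometry forward model is then rendered
#' per subject and site from its own seeded stream.
#'
#' @param config An [sim_config()].
#' @param variant One of `"main"`, `"switch"`, `"swap"`, `"mutant"`.
#' @param sites Which recording sites to render (subset of
#'   `names(config$site_scale)`).
#' @param photometry_phases Phases to render as photometry, or `NULL` for all.
#'   Restricting rendering speeds up large seed sweeps without touching the
#'   simulated learning or behavior.
#' @param through_phase If non-`NULL`, simulate only the session prefix up to
#'   (and including) the last session of this phase. Structural randomness is
#'   drawn session by session, so the retained sessions are bit-identical to
#'   the same sessions of a full run; use this when an analysis only touches
#'   the early phases.
#' @return An object of class `spc_dataset`: a list with `config`, `variant`,
#'   `subjects`, `events`, `port`, `epochs`, `photometry` (including the
#'   ground-truth `dff` and `artifact` columns), `impulses`, and `latents`.
#' @examples
#' cfg <- sim_config(n_ctrl = 1, n_ofci = 0, seed = 7)
#' ds <- simulate_cohort(cfg, variant = "switch", sites = "NAcc")
#' table(ds$events$phase)
#' @export
simulate_cohort <- function(config, variant = c("main", "switch", "swap", "mutant"),
                            sites = names(config$site_scale),
                            photometry_phases = NULL, through_phase = NULL) {
  stopifnot(inherits(config, "spc_config"))
  variant <- match.arg(variant)
  if (config$n_ctrl + config$n_ofci == 0)
    stop("cohort is empty: n_ctrl + n_ofci must be > 0", call. = FALSE)
  if (!all(sites %in% names(config$site_scale)))
    stop("sites must be a subset of names(config$site_scale)", call. = FALSE)
  if (identical(variant, "mutant")) config$sensor_functional <- FALSE

  sess <- variant_sessions(variant)
  if (!is.null(through_phase)) {
    idx <- which(sess$phase == through_phase)
    if (length(idx) == 0)
      stop(sprintf("phase '%s' not part of variant '%s'", through_phase, variant),
           call. = FALSE)
    sess <- sess[seq_len(max(idx)), , drop = FALSE]
  }
  n_sub <- config$n_ctrl + config$n_ofci
  subjects <- tibble::tibble(
    subject = sprintf("rat%02d", seq_len(n_sub)),
    group = c(rep("CTRL", config$n_ctrl), rep("OFCi", config$n_ofci)),
    counterbalance = (seq_len(n_sub) - 1L) %% 4L
  )
  # ---- structural pass: schedules, learning, behavior (site-independent RNG)
  ev_l <- list(); port_l <- list(); lat_l <- list(); imp_l <- list()
  epo_l <- list(); alpha_sub <- numeric(n_sub)

  for (si in seq_len(n_sub)) {
    # one RNG substream per subject, so truncating later sessions (or adding
    # subjects) never shifts the draws of the sessions that are kept
    set.seed(mix_seed(config$seed, 2L, si))
    subj <- subjects$subject[si]
    group <- subjects$group[si]
    alpha_i <- min(max(stats::rnorm(1, config$alpha_assoc, config$alpha_assoc_sd),
                       0.02), 1)
    alpha_sub[si] <- alpha_i

    states <- stats::setNames(
      lapply(sites, function(s) assoc_state()), sites)
    beh <- assoc_state()  # behavioral learning at base (unscaled) rates

    for (se in seq_len(nrow(sess))) {
      phase <- sess$phase[se]
      s_idx <- sess$session[se]
      bo <- if ((si + se) %% 2L == 0L) "AB" else "CD"
      sched <- build_schedule(config, phase, s_idx, block_order = bo)

      for (tr in seq_len(nrow(sched))) {
        cues <- sched$cues[[tr]]
        onsets <- sched$onsets[[tr]]
        rew <- sched$reward_times[[tr]]
        eid <- epoch_id_for(phase, s_idx, sched$trial[tr])

        # impulse amplitudes per site, latents, then behavior, then updates
        prev <- NULL
        for (j in seq_along(cues)) {
          cue <- cues[j]
          for (site in sites) {
            a <- cue_amplitude(states[[site]], cue, prev, config, site)
            inf_a <- 0
            if (identical(phase, "probe_test")) {
              inf_a <- inferred_amplitude(states[[site]], cue, config, group, site)
              a <- a + inf_a
            }
            # identity violation: a strongly expected *other* cue delays the
            # transient (disambiguation takes time, cf. the slow swap response)
            delay <- 0
            if (!is.null(prev)) {
              vp <- states[[site]]$V_pair[prev, ]
              if (max(vp) - vp[[cue]] > 0.5) delay <- config$surprise_latency
            }
            imp_l[[length(imp_l) + 1L]] <- list(
              subject = subj, site = site, epoch_id = eid,
              time_s = onsets[j] + delay, amplitude = a, kind = "cue", cue = cue)
          }
          lat_l[[length(lat_l) + 1L]] <- list(
            subject = subj, phase = phase, session = s_idx,
            trial = sched$trial[tr], position = j, cue = cue,
            predictor = if (is.null(prev)) NA_character_ else prev,
            n_exp = beh$n_exp[[cue]],
            v_pair = if (is.null(prev)) NA_real_ else beh$V_pair[prev, cue],
            v_val = beh$V_val[[cue]],
            alpha_assoc = alpha_i)
          prev <- cue
        }

        rewarded_cs <- if (length(rew) > 0) cues[length(cues)] else NA_character_
        if (length(rew) > 0) {
          for (site in sites) {
            imp_l[[length(imp_l) + 1L]] <- list(
              subject = subj, site = site, epoch_id = eid,
              time_s = rew[1], amplitude = reward_amplitude(states[[site]],
                                                            rewarded_cs, config, site),
              kind = "us", cue = rewarded_cs)
          }
        }

        bh <- simulate_behavior(beh, cues, onsets, phase, group, config)
        if (bh$n > 0) {
          b <- bh$intervals
          port_l[[length(port_l) + 1L]] <- list(
            subject = rep(subj, bh$n), phase = rep(phase, bh$n),
            session = rep(s_idx, bh$n), trial = rep(sched$trial[tr], bh$n),
            epoch_id = rep(eid, bh$n),
            cue = b$cue, enter_s = b$enter_s, exit_s = b$exit_s)
        }

        # learning updates after the trial's events
        prev <- NULL
        for (j in seq_along(cues)) {
          cue <- cues[j]
          if (!is.null(prev)) {
            for (site in sites) {
              rate <- config$site_scale[[site]][["rate"]]
              states[[site]] <- update_pair(states[[site]], prev, cue,
                                            min(alpha_i * rate, 1))
            }
            beh <- update_pair(beh, prev, cue, alpha_i)
          }
          rp <- identical(cue, rewarded_cs)
          if (phase %in% c("conditioning", "probe_reminder")) {
            for (site in sites) {
              rate <- config$site_scale[[site]][["rate"]]
              states[[site]] <- update_value(states[[site]], cue, rp,
                                             min(config$alpha_value * rate, 1),
                                             config$lambda_r)
            }
            beh <- update_value(beh, cue, rp, config$alpha_value, config$lambda_r)
          }
          for (site in sites) {
            states[[site]]$n_exp[[cue]] <- states[[site]]$n_exp[[cue]] + 1L
          }
          beh$n_exp[[cue]] <- beh$n_exp[[cue]] + 1L
          prev <- cue
        }

        # event rows
        nc <- length(cues)
        ev_l[[length(ev_l) + 1L]] <- list(
          subject = rep(subj, nc), group = rep(group, nc),
          phase = rep(phase, nc), session = rep(s_idx, nc),
          trial = rep(sched$trial[tr], nc), event_kind = rep("cue_onset", nc),
          cue = cues, time_s = onsets,
          duration_s = rep(config$cue_duration, nc), epoch_id = rep(eid, nc))
        if (length(rew) > 0) {
          nr <- length(rew)
          ev_l[[length(ev_l) + 1L]] <- list(
            subject = rep(subj, nr), group = rep(group, nr),
            phase = rep(phase, nr), session = rep(s_idx, nr),
            trial = rep(sched$trial[tr], nr), event_kind = rep("reward", nr),
            cue = rep(rewarded_cs, nr), time_s = rew,
            duration_s = rep(0, nr), epoch_id = rep(eid, nr))
        }
        epo_l[[length(epo_l) + 1L]] <- list(
          subject = subj, phase = phase, session = s_idx,
          trial = sched$trial[tr], epoch_id = eid,
          epoch_start = sched$epoch_start[tr], epoch_end = sched$epoch_end[tr],
          session_uid = session_uid_for(phase, s_idx))
      }
    }
  }
  subjects$alpha_assoc <- alpha_sub

  events <- dt_to_tbl(data.table::rbindlist(ev_l))
  port <- dt_to_tbl(data.table::rbindlist(port_l))
  epochs <- dt_to_tbl(data.table::rbindlist(epo_l))
  impulses <- dt_to_tbl(data.table::rbindlist(imp_l))
  latents <- dt_to_tbl(data.table::rbindlist(lat_l))

  # ---- rendering pass: photometry per subject x site, own RNG streams
  render_phases <- if (is.null(photometry_phases)) unique(epochs$phase)
                   else photometry_phases
  phot_l <- list()
  imp_split <- split(impulses[, c("time_s", "amplitude")],
                     paste(impulses$subject, impulses$site, impulses$epoch_id))
  for (si in seq_len(n_sub)) {
    subj <- subjects$subject[si]
    epo_s <- epochs[epochs$subject == subj, ]
    for (k in seq_along(sites)) {
      site <- sites[k]
      set.seed(mix_seed(config$seed, 1000L + si, k))
      t_rec <- 0
      cols <- list(time_s = list(), f470 = list(), f415 = list(),
                   dff = list(), artifact = list())
      ids <- character(0); ns <- integer(0)
      for (e in seq_len(nrow(epo_s))) {
        dur <- epo_s$epoch_end[e] - epo_s$epoch_start[e]
        if (epo_s$phase[e] %in% render_phases) {
          imp <- imp_split[[paste(subj, site, epo_s$epoch_id[e])]]
          ep <- render_photometry(imp, epo_s$epoch_start[e], epo_s$epoch_end[e],
                                  config, t_recorded = t_rec)
          j <- length(ids) + 1L
          ids[j] <- epo_s$epoch_id[e]; ns[j] <- nrow(ep)
          cols$time_s[[j]] <- ep$time_s; cols$f470[[j]] <- ep$f470
          cols$f415[[j]] <- ep$f415; cols$dff[[j]] <- ep$dff
          cols$artifact[[j]] <- ep$artifact
        }
        t_rec <- t_rec + dur
      }
      if (length(ids) > 0) {
        nn <- sum(ns)
        phot_l[[length(phot_l) + 1L]] <- list(
          subject = rep(subj, nn), site = rep(site, nn),
          epoch_id = rep(ids, ns),
          time_s = unlist(cols$time_s, use.names = FALSE),
          f470 = unlist(cols$f470, use.names = FALSE),
          f415 = unlist(cols$f415, use.names = FALSE),
          dff = unlist(cols$dff, use.names = FALSE),
          artifact = unlist(cols$artifact, use.names = FALSE))
      }
    }
  }
  photometry <- dt_to_tbl(data.table::rbindlist(phot_l))

  structure(list(
    config = config, variant = variant, sites = sites,
    subjects = subjects, events = events, port = port, epochs = epochs,
    photometry = photometry, impulses = impulses, latents = latents
  ), class = "spc_dataset")
}

#' @export
print.spc_dataset <- function(x, ...) {
  cat("<spc_dataset>\n")
  cat(sprintf("  variant '%s': %d subjects (%d CTRL, %d OFCi), sites: %s\n",
              x$variant, nrow(x$subjects), sum(x$subjects$group == "CTRL"),
              sum(x$subjects$group == "OFCi"), paste(x$sites, collapse = ", ")))
  cat(sprintf("  %d trial epochs, %d photometry samples, %d port entries\n",
              nrow(x$epochs) / max(nrow(x$subjects), 1), nrow(x$photometry),
              nrow(x$port)))
  invisible(x)
}
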