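test_that("the main variant yields the full cohort and session structure", {
  ds <- tiny_main()
  expect_equal(nrow(ds$subjects), 3)
  expect_equal(sum(ds$subjects$group == "CTRL"), 2)
  # nine physical sessions: 2 preconditioning + 6 conditioning + 1 probe
  uids <- unique(session_uid_for(ds$epochs$phase, ds$epochs$session))
  expect_equal(length(uids), 9)
  # every event epoch has a matching photometry epoch with the right length
  for (i in sample(nrow(ds$epochs), 10)) {
    e <- ds$epochs[i, ]
    ph <- ds$photometry[ds$photometry$subject == e$subject &
                          ds$photometry$epoch_id == e$epoch_id, ]
    expect_equal(nrow(ph),
                 round((e$epoch_end - e$epoch_start) * ds$config$fs) + 1)
  }
})

test_that("identical configurations reproduce identical datasets", {
  cfg <- sim_config(n_ctrl = 1, n_ofci = 1, seed = 77)
  a <- simulate_cohort(cfg, sites = "NAcc", photometry_phases = "probe_test")
  b <- simulate_cohort(cfg, sites = "NAcc", photometry_phases = "probe_test")
  expect_identical(a$events, b$events)
  expect_identical(a$photometry, b$photometry)
  expect_identical(a$port, b$port)
  expect_identical(a$latents, b$latents)
})

test_that("latents do not depend on which phases are rendered", {
  cfg <- sim_config(n_ctrl = 1, n_ofci = 1, seed = 78)
  full <- simulate_cohort(cfg, sites = "NAcc",
                          photometry_phases = "preconditioning")
  part <- simulate_cohort(cfg, sites = "NAcc", photometry_phases = "probe_test")
  expect_identical(full$latents, part$latents)
  expect_identical(full$events, part$events)
  expect_equal(sort(unique(full$photometry$epoch_id)),
               sort(unique(full$epochs$epoch_id[full$epochs$phase ==
                                                  "preconditioning"])))
})

test_that("switch and swap variants append a third preconditioning session", {
  cfg <- sim_config(n_ctrl = 1, n_ofci = 0, seed = 5)
  ds <- simulate_cohort(cfg, variant = "switch", sites = "NAcc",
                        photometry_phases = "switch")
  expect_setequal(unique(ds$events$phase), c("preconditioning", "switch"))
  expect_equal(max(ds$events$session[ds$events$phase == "switch"]), 3)
  # second half of each pair block runs in reversed order
  sw <- ds$events[ds$events$phase == "switch" & ds$events$event_kind == "cue_onset", ]
  pairs <- stats::aggregate(cue ~ epoch_id, data = sw[order(sw$time_s), ],
                            FUN = paste, collapse = "")
  expect_setequal(unique(pairs$cue), c("AB", "BA", "CD", "DC"))
})

test_that("every rendered impulse is recoverable from the stored latents", {
  ds <- tiny_main()
  # isolated impulses: the true dff at the impulse peak equals its amplitude
  imp <- ds$impulses[ds$impulses$kind == "cue" &
                       ds$impulses$subject == "rat01", ]
  imp <- imp[sample(nrow(imp), 8), ]
  t_peak <- with(ds$config, kernel_rise * kernel_decay /
                   (kernel_decay - kernel_rise) * log(kernel_decay / kernel_rise))
  for (i in seq_len(nrow(imp))) {
    ph <- ds$photometry[ds$photometry$subject == imp$subject[i] &
                          ds$photometry$epoch_id == imp$epoch_id[i], ]
    sel <- abs(ph$time_s - (imp$time_s[i] + t_peak)) <= 2 / ds$config$fs
    expect_equal(max(ph$dff[sel]), imp$amplitude[i], tolerance = 0.02)
  }
})

test_that("expected amplitudes honor novelty decay and predictability", {
  # pure novelty (no SPE term): amplitude nonincreasing in exposure count
  cfg_nov <- sim_config(n_ctrl = 2, n_ofci = 0, seed = 31, spe_gain = 0,
                        alpha_assoc_sd = 0)
  ds <- simulate_cohort(cfg_nov, sites = "NAcc",
                        photometry_phases = "probe_test")
  imp <- ds$impulses[ds$impulses$kind == "cue" &
                       grepl("^preconditioning", ds$impulses$epoch_id), ]
  for (sb in unique(imp$subject)) {
    for (cu in c("A", "B")) {
      amps <- imp$amplitude[imp$subject == sb & imp$cue == cu]
      expect_true(all(diff(amps) <= 1e-9))
    }
  }
  # with the SPE term on, predicted cues sit at or below unpredicted cues
  ds2 <- tiny_main()
  lat <- ds2$latents
  pre <- lat[lat$phase == "preconditioning", ]
  imp2 <- ds2$impulses[ds2$impulses$kind == "cue", ]
  key <- paste(imp2$subject, imp2$epoch_id, imp2$cue)
  amp_of <- stats::setNames(imp2$amplitude, key)
  pre$amp <- amp_of[paste(pre$subject, epoch_id_for(pre$phase, pre$session,
                                                    pre$trial), pre$cue)]
  first_pair <- pre$trial <= 1
  pred <- pre$position == 2 & !first_pair
  unpred <- pre$position == 1 & !first_pair
  expect_lt(mean(pre$amp[pred]), mean(pre$amp[unpred]))
})

test_that("degenerate cohorts are rejected", {
  expect_error(simulate_cohort(sim_config(n_ctrl = 0, n_ofci = 0, seed = 1)),
               "empty")
  expect_error(simulate_cohort(tiny_config(), sites = "cortex"), "site")
})
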