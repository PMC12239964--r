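test_that("peak and AUC respect their windows", {
  t <- seq(-2, 12, by = 0.02)
  expect_equal(peak_response(t, rep(0, length(t))), 0)
  # two bumps; the larger one sits outside the peak window
  y <- exp(-(t - 1)^2 / 0.1) + 5 * exp(-(t - 6)^2 / 0.1)
  expect_equal(peak_response(t, y, c(0, 2)), max(y[t >= 0 & t <= 2]))
  expect_lt(peak_response(t, y, c(0, 2)), 2)
  # rectangle and signed area
  expect_equal(auc_response(t, rep(1, length(t)), c(1, 3)), 2)
  expect_equal(auc_response(t, rep(-0.5, length(t)), c(1, 3)), -1)
  # triangular bump centered at 2 with half-width 1: area 1
  tri <- pmax(0, 1 - abs(t - 2))
  expect_equal(auc_response(t, tri, c(1, 3)), 1, tolerance = 1 / 50)
  # invariance to samples outside the windows
  t2 <- c(t, 20, 21); y2 <- c(y, 100, 100)
  expect_equal(peak_response(t2, y2, c(0, 2)), peak_response(t, y, c(0, 2)))
  expect_equal(auc_response(t2, y2, c(1, 3)), auc_response(t, y, c(1, 3)))
  expect_error(peak_response(t, y, c(100, 101)), "no samples")
})

test_that("port occupancy clips, sums and splits correctly", {
  expect_equal(port_occupancy(numeric(0), numeric(0), 0, 10), 0)
  expect_equal(port_occupancy(-5, 50, 0, 10), 100)   # covers the whole cue
  expect_equal(port_occupancy(3, 8, 0, 10), 50)
  # splitting an interval into abutting parts changes nothing
  expect_equal(port_occupancy(c(3, 5.5), c(5.5, 8), 0, 10), 50)
  expect_equal(port_occupancy(c(3, 4, 7), c(4, 5.5, 8.5), 0, 10), 40)
})

test_that("alignment labels predictedness from the within-trial structure", {
  ds <- tiny_main()
  al <- align_trials(tiny_norm(), ds$events, "A", window = c(-2, 12))
  pre <- al[al$phase == "preconditioning", ]
  expect_true(all(pre$predictedness == "unpredicted"))
  # 12 preconditioning A-trials per subject (6 per session x 2 sessions)
  n_trials <- length(unique(paste(pre$subject, pre$session, pre$trial)))
  expect_equal(n_trials, 12 * nrow(ds$subjects))
  expect_true(all(al$rel_time >= -2 & al$rel_time <= 12))
  al_b <- align_trials(tiny_norm(), ds$events, "B")
  expect_true(all(al_b$predictedness[al_b$phase == "preconditioning"] ==
                    "predicted"))
  expect_warning(al_x <- align_trials(tiny_norm(), ds$events, "X"), "not found")
  expect_equal(nrow(al_x), 0)
})

test_that("response rows carry peaks, AUCs, US windows and behavior", {
  rows <- tiny_rows()
  expect_true(all(c("peak", "auc", "us_peak", "behavior_pct") %in% names(rows)))
  expect_true(all(rows$behavior_pct >= 0 & rows$behavior_pct <= 100))
  cond <- rows[rows$phase == "conditioning", ]
  expect_true(all(is.finite(cond$us_peak)))
  # reinforced trials show a US response clearly above the matched window of
  # unreinforced trials early in training
  s1 <- cond[cond$session == 1, ]
  expect_gt(mean(s1$us_peak[s1$cue == "B"]), mean(s1$us_peak[s1$cue == "D"]))
})

test_that("preconditioning bins average the stated trial ranges", {
  rows <- tiny_rows()
  b <- phase_bins(rows)
  expect_setequal(levels(b$bin), c("start", "middle", "end"))
  # constructed fixture: linearly decaying peaks 12..1 over the 12 trials
  fake <- tibble::tibble(
    subject = "r1", site = "NAcc", phase = "preconditioning",
    session = rep(1:2, each = 6), trial = rep(1:6, 2),
    cue = "A", predictedness = "unpredicted", peak = 12:1)
  fb <- phase_bins(fake)
  expect_equal(fb$peak[fb$bin == "start"], 11.5)
  expect_equal(fb$peak[fb$bin == "middle"], 6.5)
  expect_equal(fb$peak[fb$bin == "end"], 1.5)
  # constant peaks put every bin at the same level
  fake$peak <- 2
  expect_true(all(phase_bins(fake)$peak == 2))
  # a missing final trial degrades gracefully to the available trials
  expect_message(fb2 <- phase_bins(fake[-12, ]), "available")
  expect_equal(fb2$peak[fb2$bin == "end"], 2)
})

test_that("US - CS differences decline with conditioning", {
  rows <- tiny_rows()
  d <- us_cs_difference(rows)
  expect_setequal(unique(d$cue), c("B", "D"))
  db <- stats::aggregate(us_cs_diff ~ session, data = d[d$cue == "B", ],
                         FUN = mean)
  expect_gt(db$us_cs_diff[1], db$us_cs_diff[6])
  expect_error(us_cs_difference(rows[rows$phase != "conditioning", ]),
               "no conditioning rows")
})
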