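test_that("median filter removes isolated spikes and preserves structure", {
  expect_equal(median_filter(rep(3, 20)), rep(3, 20))          # constant
  expect_equal(median_filter(c(0, 0, 0, 10, 0, 0, 0)), rep(0, 7))  # spike
  ramp <- seq(0, 5, by = 0.25)
  expect_equal(median_filter(ramp)[3:19], ramp[3:19])          # linear interior
  expect_equal(length(median_filter(rnorm(50))), 50)
  expect_error(median_filter(1:3, order = 4), "longer than")
})

test_that("isosbestic correction recovers exact polynomial relations", {
  set.seed(1)
  ref <- 95 * exp(-seq(0, 1, length.out = 400)) + rnorm(400, 0, 0.5)
  fit <- isosbestic_correct(2 * ref + 3, ref)
  expect_equal(max(abs(fit$dF)), 0, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), c(3, 2, 0), tolerance = 1e-6)
  # reference equal to active: perfect fit, zero residual
  fit2 <- isosbestic_correct(ref, ref)
  expect_equal(max(abs(fit2$dF)), 0, tolerance = 1e-8)
})

test_that("isosbestic correction recovers a signal orthogonal to the reference", {
  set.seed(2)
  a <- 95 * exp(-seq(0, 0.5, length.out = 500)) + rnorm(500, 0, 0.3)
  raw <- rnorm(500, 0, 2)
  s <- unname(residuals(lm(raw ~ a + I(a^2))))   # orthogonal to {1, a, a^2}
  fit <- isosbestic_correct(s + 2 * a + 1, a)
  expect_equal(fit$dF, s, tolerance = 1e-8)
  expect_lt(abs(cor(fit$dF, a)), 1e-6)
})

test_that("degenerate references fall back to mean subtraction", {
  expect_warning(fit <- isosbestic_correct(c(1, 2, 3, 4), rep(5, 4)),
                 "degenerate")
  expect_equal(fit$dF, c(1, 2, 3, 4) - 2.5)
  expect_error(isosbestic_correct(1:5, 1:4), "equal length")
})

test_that("trial z-score uses the pre-onset baseline with the sample SD", {
  # baseline {1,2,3} has sample SD exactly 1, so the cue sample 5 maps to 3
  dF <- c(1, 2, 3, 5)
  t <- c(-3, -2, -1, 0.5)
  z <- trial_zscore(dF, t, baseline_window = c(-10, 0))
  expect_equal(z[4], 3)
  expect_equal(mean(z[1:3]), 0)
  expect_equal(sd(z[1:3]), 1)
  # population convention divides by n instead
  zp <- trial_zscore(dF, t, baseline_window = c(-10, 0),
                     sd_method = "population")
  expect_equal(zp[4], (5 - 2) / sqrt(2 / 3))
  expect_error(trial_zscore(rep(1, 10), seq(-5, 4), c(-10, 0)), "SD is zero")
  expect_error(trial_zscore(1:5, 1:5, c(-10, 0)), "no samples")
})

test_that("session normalization maps baseline to 0 and the session peak to 1", {
  z <- c(-1, 0, 1, 2, 4)
  base <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  zn <- session_normalize(z, base)
  expect_equal(zn[5], 1)                       # the session max
  expect_equal(mean(zn[base]), 0)              # baseline average
  expect_equal(zn[4], (2 - (-0.5)) / (4 - (-0.5)))
  # a sample at z = 2 with B = 0, P = 4 maps to 0.5
  expect_equal(session_normalize(c(0, 0, 2, 4), c(TRUE, TRUE, FALSE, FALSE))[3],
               0.5)
  # idempotence up to tolerance
  zn2 <- session_normalize(zn, base)
  expect_equal(zn2, zn, tolerance = 1e-12)
  expect_error(session_normalize(c(1, 1, 0), c(TRUE, TRUE, FALSE)), "peak")
})

test_that("the full chain normalizes every epoch and session as specified", {
  norm <- tiny_norm()
  tr <- norm$trials
  base <- tr[tr$time_s >= -10 & tr$time_s < 0, ]
  agg_m <- stats::aggregate(z ~ subject + epoch_id, data = base, FUN = mean)
  agg_s <- stats::aggregate(z ~ subject + epoch_id, data = base, FUN = sd)
  expect_lt(max(abs(agg_m$z)), 1e-9)
  expect_lt(max(abs(agg_s$z - 1)), 1e-9)
  sess_max <- stats::aggregate(znorm ~ subject + session_uid, data = tr, FUN = max)
  expect_lt(max(abs(sess_max$znorm - 1)), 1e-9)
  expect_equal(nrow(norm$fits), length(unique(paste(tr$subject, tr$session_uid))))
})

test_that("filtering precedes z-scoring in the implemented chain", {
  # single-sample spike in the baseline: filtering first removes it before it
  # can inflate the baseline SD; z-scoring first would carry it through
  cfg0 <- sim_config(n_ctrl = 1, n_ofci = 0, seed = 3, noise_sd = 0.5,
                     artifact_rate = 0)
  ds <- simulate_cohort(cfg0, sites = "NAcc", photometry_phases = "probe_test")
  ph <- ds$photometry[ds$photometry$epoch_id == ds$photometry$epoch_id[1], ]
  spike_i <- which(ph$time_s == -5)
  ph$f470[spike_i] <- ph$f470[spike_i] + 500
  norm <- preprocess_photometry(ph)
  z_impl <- norm$trials$z
  expect_lt(abs(z_impl[spike_i]), 5)   # spike gone before z-scoring

  # alternative order: z-score the unfiltered dF, then filter
  raw_fit <- isosbestic_correct(ph$f470, ph$f415)
  z_alt <- median_filter(trial_zscore(raw_fit$dF, ph$time_s, c(-10, 0)))
  # the spike inflates the alternative's baseline SD, shrinking its z-scale
  expect_gt(max(abs(z_impl - z_alt)), 1)
})
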