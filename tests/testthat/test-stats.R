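test_that("difference index is the bounded, antisymmetric contrast", {
  expect_equal(difference_index(0.3, 0.3), 0)
  expect_equal(difference_index(2, 0), 1)
  expect_equal(difference_index(0.6, 0.2), 0.5)
  for (xy in list(c(1, 3), c(0.2, 0.9), c(5, 5))) {
    expect_equal(difference_index(xy[1], xy[2]),
                 -difference_index(xy[2], xy[1]))
  }
  expect_error(difference_index(0, 0), "undefined")
  expect_error(difference_index(1, -2), "undefined")
})

test_that("inclusion and discrimination rules honor their boundaries", {
  expect_true(include_subject(40, 19))
  expect_true(include_subject(40, 20))    # boundary is inclusive
  expect_false(include_subject(30, 20))
  expect_true(discriminator_flag(0.2))
  expect_false(discriminator_flag(0.1))   # strictly above
  expect_false(discriminator_flag(-0.3))
})

test_that("suppression ratio divides late by early mean peaks", {
  expect_equal(suppression_ratio(c(2, 2), c(2, 2)), 1)
  expect_equal(suppression_ratio(c(4, 2), c(0, 0)), 0)
  expect_equal(suppression_ratio(c(4, 2), c(1, 2)), 0.5)
  expect_error(suppression_ratio(c(0, 0), c(1, 1)), "positive")
})

test_that("exact Wilcoxon matches the sign-flip enumeration oracle", {
  set.seed(7)
  cases <- list(
    c(1.2, 0.5, 2.2),                   # tiny n
    c(3, -1, 2, 5, -2, 4),              # mixed signs
    c(1, 1, -1, 2, 2, -2, 3),           # heavy midrank ties
    c(0, 1.5, -0.5, 2, 0, 3),           # exact zeros dropped
    rnorm(9), rnorm(10), rnorm(8) + 0.5
  )
  for (x in cases) {
    expect_equal(wilcoxon_signed_exact(x)$p_value, wilcoxon_enum_oracle(x),
                 tolerance = 1e-12)
  }
})

test_that("all-positive samples reach the exact minimum two-sided p", {
  expect_equal(wilcoxon_signed_exact(rep(1, 6) + runif(6))$p_value, 2 / 64)
  expect_equal(wilcoxon_signed_exact(rep(1, 8) + runif(8))$p_value, 2 / 256)
})

test_that("exact Wilcoxon agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:5) {
    x <- round(rnorm(7 + i), 3)
    x <- x[x != 0]
    if (anyDuplicated(abs(x))) next
    ref <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = TRUE))
    expect_equal(wilcoxon_signed_exact(x)$p_value, ref$p.value,
                 tolerance = 1e-10)
  }
})

test_that("degenerate Wilcoxon input returns p = 1 with a warning", {
  expect_warning(res <- wilcoxon_signed_exact(rep(0, 5)), "p = 1")
  expect_equal(res$p_value, 1)
})

test_that("one-sided chi-square halves the closed-form upper tail", {
  # zero association: both directions give exactly 0.5
  expect_equal(chisq_2x2_one_sided(5, 5, 5, 5, "positive")$p_value, 0.5)
  # hand-evaluated closed form for (4,2,0,8)
  chi2 <- 14 * (4 * 8 - 2 * 0)^2 / (6 * 8 * 4 * 10)
  res <- chisq_2x2_one_sided(4, 2, 0, 8, "positive")
  expect_equal(res$statistic, chi2)
  expect_equal(res$p_value, pchisq(chi2, 1, lower.tail = FALSE) / 2)
  # transposing the rows flips p to 1 - p
  res_fl <- chisq_2x2_one_sided(0, 8, 4, 2, "positive")
  expect_equal(res$p_value + res_fl$p_value, 1)
  expect_error(chisq_2x2_one_sided(0, 0, 1, 1, "positive"), "margins")
  expect_error(chisq_2x2_one_sided(-1, 1, 1, 1, "positive"), "non-negative")
})

test_that("regression matches the normal equations and exact fixtures", {
  x <- c(1, 2, 3, 4, 5)
  # lm warns about the essentially perfect fit; the exactness is the point
  res <- suppressWarnings(linregress_with_test(x, 2 * x))
  expect_equal(res$slope, 2)
  expect_equal(res$r_squared, 1)
  # constructed orthogonal response: slope exactly 0
  y0 <- c(1, -1, 0, 1, -1); y0 <- y0 - mean(y0)
  y0 <- y0 - sum(y0 * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  expect_equal(linregress_with_test(x, y0)$slope, 0, tolerance = 1e-12)
  # n = 7 random fixture against hand linear algebra
  set.seed(11)
  x7 <- rnorm(7); y7 <- rnorm(7)
  X <- cbind(1, x7)
  beta <- solve(t(X) %*% X, t(X) %*% y7)
  res7 <- linregress_with_test(x7, y7)
  expect_equal(res7$intercept, beta[1], tolerance = 1e-10)
  expect_equal(res7$slope, beta[2], tolerance = 1e-10)
})

test_that("slope comparison flags only genuinely different slopes", {
  set.seed(12)
  x1 <- rnorm(20); x2 <- rnorm(20)
  same <- compare_slopes(x1, 2 * x1 + rnorm(20, 0, 0.5),
                         x2, 2 * x2 + rnorm(20, 0, 0.5))
  diff <- compare_slopes(x1, 2 * x1 + rnorm(20, 0, 0.5),
                         x2, -2 * x2 + rnorm(20, 0, 0.5))
  expect_gt(same$p_value, 0.05)
  expect_lt(diff$p_value, 1e-6)
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 3 subjects x 2 cues x 3 bins, one observation per cell
  d <- expand.grid(subject = c("s1", "s2", "s3"),
                   cue = c("pred", "unpred"),
                   bin = c("b1", "b2", "b3"),
                   stringsAsFactors = FALSE)
  set.seed(13)
  d$y <- 2 + ifelse(d$cue == "unpred", 1.5, 0) +
    c(b1 = 1, b2 = 0, b3 = -1)[d$bin] +
    c(s1 = 0.2, s2 = -0.1, s3 = 0)[d$subject] + round(rnorm(18, 0, 0.3), 2)

  res <- rm_anova(d, "y", "subject", c("cue", "bin"))

  # independent hand computation from marginal means
  gm <- mean(d$y)
  m_c <- tapply(d$y, d$cue, mean); m_b <- tapply(d$y, d$bin, mean)
  m_s <- tapply(d$y, d$subject, mean)
  m_cs <- tapply(d$y, list(d$cue, d$subject), mean)
  m_bs <- tapply(d$y, list(d$bin, d$subject), mean)
  m_cb <- tapply(d$y, list(d$cue, d$bin), mean)
  ss_c <- 3 * 3 * sum((m_c - gm)^2)
  ss_cs <- 3 * sum((m_cs - outer(m_c, rep(1, 3)) -
                      outer(rep(1, 2), m_s) + gm)^2)
  ss_b <- 3 * 2 * sum((m_b - gm)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_b, rep(1, 3)) -
                      outer(rep(1, 3), m_s) + gm)^2)
  f_c <- (ss_c / 1) / (ss_cs / 2)
  f_b <- (ss_b / 2) / (ss_bs / 4)
  expect_equal(res$F[res$effect == "cue"], f_c, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "bin"], f_b, tolerance = 1e-8)
  expect_equal(res$p_value[res$effect == "cue"],
               pf(f_c, 1, 2, lower.tail = FALSE), tolerance = 1e-8)

  # all-equal data: every F reported as 0
  d$y <- 1
  res0 <- rm_anova(d, "y", "subject", c("cue", "bin"))
  expect_true(all(res0$F == 0))

  # unbalanced designs are refused
  expect_error(rm_anova(d[-1, ], "y", "subject", c("cue", "bin")),
               "unsupported design")
})

test_that("suppression-probe correlation errors on an empty group", {
  s <- tibble::tibble(group = "CTRL", suppression_BD = c(0.2, 0.5, 0.8),
                      diff_AC = c(0.9, 0.5, 0.2))
  res <- correlate_spe_with_probe(s)
  expect_lt(res$slope, 0)
  expect_error(correlate_spe_with_probe(s[0, ]))
})
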