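#' Per-subject derived summary
#'
#' Collapses per-trial response rows into one row per subject: probe behavior
#' and dopamine means per cue, difference indices, the predicted-cue
#' suppression ratio from preconditioning, and the inclusion/discriminator
#' flags. Behavioral B/D means come from the probe reminder trials (those
#' drive the inclusion rule), behavioral and dopamine A/C means from the
#' blocked probe test trials.
#'
#' @param rows Output of [quantify_responses()] on a full (main-variant) run.
#' @param site Recording site used for the dopamine columns.
#' @return Tibble, one row per subject: `subject`, `group`, `site`,
#'   behavior and peak means per cue, `diff_BD`, `diff_AC`,
#'   `suppression_BD`, `suppression_AC`, `included`, `discriminator`.
#' @export
subject_summaries <- function(rows, site = "NAcc") {
  r <- rows[rows$site == site, ]
  if (nrow(r) == 0) stop(sprintf("no rows for site '%s'", site), call. = FALSE)

  mean_of <- function(d, ph, cue, col) {
    v <- d[[col]][d$phase == ph & d$cue == cue]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  safe_index <- function(x, y) {
    tryCatch(difference_index(x, y), error = function(e) NA_real_)
  }

  # suppression ratios need the per-cue repetition index in preconditioning
  pre <- r[r$phase == "preconditioning", ]
  pre <- dplyr::arrange(pre, subject, cue, session, trial)
  pre <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(pre, subject, cue),
                                      rep = dplyr::row_number()))

  subs <- unique(r[, c("subject", "group")])
  out <- lapply(seq_len(nrow(subs)), function(i) {
    sb <- subs$subject[i]
    d <- r[r$subject == sb, ]
    p <- pre[pre$subject == sb, ]
    beh_B <- mean_of(d, "probe_reminder", "B", "behavior_pct")
    beh_D <- mean_of(d, "probe_reminder", "D", "behavior_pct")
    beh_A <- mean_of(d, "probe_test", "A", "behavior_pct")
    beh_C <- mean_of(d, "probe_test", "C", "behavior_pct")
    dop_B <- mean_of(d, "probe_reminder", "B", "peak")
    dop_D <- mean_of(d, "probe_reminder", "D", "peak")
    dop_A <- mean_of(d, "probe_test", "A", "peak")
    dop_C <- mean_of(d, "probe_test", "C", "peak")
    supp <- function(cls) {
      pp <- p[p$cue %in% cls, ]
      e <- pp$peak[pp$rep %in% 1:2]; l <- pp$peak[pp$rep %in% 11:12]
      if (length(e) == 0 || length(l) == 0) return(NA_real_)
      tryCatch(suppression_ratio(e, l), error = function(er) NA_real_)
    }
    diff_BD <- safe_index(beh_B, beh_D)
    diff_AC <- safe_index(beh_A, beh_C)
    tibble::tibble(
      subject = sb, group = subs$group[i], site = site,
      beh_A = beh_A, beh_B = beh_B, beh_C = beh_C, beh_D = beh_D,
      dop_A = dop_A, dop_B = dop_B, dop_C = dop_C, dop_D = dop_D,
      diff_BD = diff_BD, diff_AC = diff_AC,
      suppression_BD = supp(c("B", "D")), suppression_AC = supp(c("A", "C")),
      included = include_subject(beh_B, beh_D),
      discriminator = discriminator_flag(diff_AC))
  })
  dplyr::bind_rows(out)
}

#' Group-level analysis of a probe cohort
#'
#' Applies the inclusion rule, then runs the probe statistics per group:
#' one-sample exact Wilcoxon tests of the B/D and A/C behavioral difference
#' indices against 0, the one-sided chi-square comparison of discriminator
#' counts between groups, the two-sample comparison of the probe dopamine
#' peak to cue A, the within-subject behavioral regressions (A on B, A on C)
#' with between-group slope comparisons, and the suppression-vs-probe
#' correlation.
#'
#' @param rows Output of [quantify_responses()] on a main-variant run.
#' @param site Recording site for the dopamine contrasts.
#' @param apply_inclusion Drop subjects failing the B >= 2D reminder rule
#'   before group statistics (default TRUE, mirroring the task's design).
#' @return List of class `spc_analysis`: `summaries` (all subjects, with
#'   flags), `included` (post-inclusion summaries), `tests` (tidy tibble of
#'   test results), `excluded` (dropped subject ids).
#' @export
analyze_cohort <- function(rows, site = "NAcc", apply_inclusion = TRUE) {
  summaries <- subject_summaries(rows, site = site)
  inc <- if (apply_inclusion) summaries[summaries$included, ] else summaries
  excluded <- setdiff(summaries$subject, inc$subject)

  tests <- list()
  add <- function(tb, label) {
    tb$test <- label
    tests[[length(tests) + 1L]] <<- tb
  }

  for (g in unique(inc$group)) {
    s <- inc[inc$group == g, ]
    if (nrow(s) == 0) next
    add(wilcoxon_signed_exact(s$diff_BD[is.finite(s$diff_BD)]),
        paste0("diff_BD_vs0_", g))
    add(wilcoxon_signed_exact(s$diff_AC[is.finite(s$diff_AC)]),
        paste0("diff_AC_vs0_", g))
  }

  if (all(c("CTRL", "OFCi") %in% inc$group)) {
    sc <- inc[inc$group == "CTRL", ]
    so <- inc[inc$group == "OFCi", ]
    if (sum(sc$discriminator) + sum(!sc$discriminator) > 0 &&
        sum(so$discriminator) + sum(!so$discriminator) > 0) {
      add(chisq_2x2_one_sided(sum(sc$discriminator), sum(!sc$discriminator),
                              sum(so$discriminator), sum(!so$discriminator),
                              direction = "positive"),
          "discriminators_CTRL_gt_OFCi")
    }
    if (nrow(sc) >= 2 && nrow(so) >= 2 && any(is.finite(sc$dop_A)) &&
        any(is.finite(so$dop_A))) {
      tt <- stats::t.test(sc$dop_A, so$dop_A)
      add(tibble::tibble(method = "t_two_sample",
                         statistic = unname(tt$statistic),
                         p_value = tt$p.value, tails = "two-sided",
                         n = nrow(sc) + nrow(so),
                         notes = sprintf("mean CTRL %.4g vs OFCi %.4g",
                                         mean(sc$dop_A), mean(so$dop_A))),
          "probe_dop_A_CTRL_vs_OFCi")
    }
    if (nrow(sc) >= 3 && nrow(so) >= 3) {
      fb_c <- linregress_with_test(sc$beh_B, sc$beh_A)
      fb_o <- linregress_with_test(so$beh_B, so$beh_A)
      add(tibble::tibble(method = "ols_slope", statistic = fb_c$t,
                         p_value = fb_c$p_value, tails = "two-sided",
                         n = fb_c$n,
                         notes = sprintf("slope %.4g, r2 %.3f", fb_c$slope,
                                         fb_c$r_squared)),
          "beh_A_on_B_CTRL")
      add(tibble::tibble(method = "ols_slope", statistic = fb_o$t,
                         p_value = fb_o$p_value, tails = "two-sided",
                         n = fb_o$n,
                         notes = sprintf("slope %.4g, r2 %.3f", fb_o$slope,
                                         fb_o$r_squared)),
          "beh_A_on_B_OFCi")
      add(compare_slopes(sc$beh_B, sc$beh_A, so$beh_B, so$beh_A),
          "beh_A_on_B_slope_CTRLvsOFCi")
    }
    corr <- tryCatch(correlate_spe_with_probe(inc), error = function(e) NULL)
    if (!is.null(corr)) {
      for (i in seq_len(nrow(corr))) {
        add(tibble::tibble(method = "ols_slope", statistic = corr$t[i],
                           p_value = corr$p_value[i], tails = "two-sided",
                           n = corr$n[i],
                           notes = sprintf("slope %.4g", corr$slope[i])),
            paste0("suppression_vs_diffAC_", corr$group[i]))
      }
    }
  }

  structure(list(summaries = summaries, included = inc,
                 tests = dplyr::bind_rows(tests), excluded = excluded),
            class = "spc_analysis")
}

#' @export
print.spc_analysis <- function(x, ...) {
  cat("<spc_analysis>\n")
  cat(sprintf("  %d subjects analyzed, %d excluded by the B >= 2D rule\n",
              nrow(x$included), length(x$excluded)))
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-32s p = %.4g (n = %d)\n", t$test[i], t$p_value[i], t$n[i]))
  }
  invisible(x)
}

#' Recover the cue-cue learning rate from predicted-cue peaks
#'
#' Fits the generator's forward model of the predicted-cue peak series
#' (novelty decay plus SPE suppression,
#' `a_t = g_N exp(-kappa (t-1)) + g_S (1 - V_t)`, with
#' `V_t = 1 - (1 - alpha)^(t-1)`) to the cohort-mean peak per repetition by
#' least squares over `alpha`, profiling out one free scale per session
#' (session normalization rescales each session independently).
#'
#' @param rows Output of [quantify_responses()] on preconditioning data.
#' @param config The generating [sim_config()] (supplies the known gains).
#' @param site Recording site to fit.
#' @return List with `alpha` (the estimate) and `rss`.
#' @export
fit_alpha_assoc <- function(rows, config, site = "NAcc") {
  pre <- rows[rows$phase == "preconditioning" & rows$site == site &
                rows$predictedness == "predicted", ]
  if (nrow(pre) == 0) stop("no predicted-cue preconditioning rows", call. = FALSE)
  pre <- dplyr::arrange(pre, subject, cue, session, trial)
  pre <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(pre, subject, cue),
                                      rep = dplyr::row_number()))
  series <- dplyr::summarise(dplyr::group_by(pre, session, rep),
                             peak = mean(peak), .groups = "drop")
  series <- dplyr::arrange(series, rep)

  model_rss <- function(alpha) {
    v <- 1 - (1 - alpha)^(series$rep - 1)
    m <- config$novelty_gain * exp(-config$novelty_decay * (series$rep - 1)) +
      config$spe_gain * (1 - v)
    rss <- 0
    for (s in unique(series$session)) {
      i <- series$session == s
      sc <- sum(m[i] * series$peak[i]) / sum(m[i]^2)
      rss <- rss + sum((series$peak[i] - sc * m[i])^2)
    }
    rss
  }
  opt <- stats::optimize(model_rss, c(0.01, 0.99))
  list(alpha = opt$minimum, rss = opt$objective)
}
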