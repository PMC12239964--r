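#' Bounded discrimination index
#'
#' `(x - y) / (x + y)`: +1 when all responding goes to `x`, -1 when all goes
#' to `y`, 0 at indifference. Antisymmetric in its arguments.
#'
#' @param x,y Non-negative responses (e.g. occupancy percentages or peaks).
#' @return Index in \[-1, 1\].
#' @export
difference_index <- function(x, y) {
  if (!is.finite(x + y) || x + y <= 0)
    stop("difference index undefined: x + y must be > 0", call. = FALSE)
  (x - y) / (x + y)
}

#' Discriminative-conditioning inclusion rule
#'
#' A subject is included iff it responded at least twice as much to the
#' reinforced cue B as to the unreinforced cue D in the probe reminder trials
#' (`B_pct >= 2 * D_pct`, boundary inclusive).
#'
#' @param B_pct,D_pct Occupancy percentages during the reminder trials.
#' @return Logical flag.
#' @export
include_subject <- function(B_pct, D_pct) {
  isTRUE(B_pct >= 2 * D_pct)
}

#' Probe discrimination flag
#'
#' Marks subjects whose A/C discrimination index is strictly above 0.1
#' (at least a 10% higher relative response to A).
#'
#' @param diff_AC A/C difference index.
#' @return Logical flag.
#' @export
discriminator_flag <- function(diff_AC) {
  isTRUE(diff_AC > 0.1)
}

#' Late/early suppression ratio
#'
#' Mean peak over the last two preconditioning repetitions (11-12) divided by
#' the mean over the first two (1-2). Values below 1 indicate suppression;
#' the smaller the ratio the stronger the suppression.
#'
#' @param early_peaks,late_peaks Peak responses in the early and late bins.
#' @return Scalar ratio.
#' @export
suppression_ratio <- function(early_peaks, late_peaks) {
  e <- mean(early_peaks)
  if (!is.finite(e) || e <= 0)
    stop("early-bin mean peak must be positive", call. = FALSE)
  mean(late_peaks) / e
}

#' Exact one-sample Wilcoxon signed-rank test
#'
#' Tests whether paired differences are symmetric about `mu0`. Exact zeros
#' are dropped; ties in `|x - mu0|` get midranks. For `n <= exact_max_n` the
#' null distribution of the signed-rank sum is computed exactly over all
#' `2^n` sign assignments (by convolution over the doubled midranks, which
#' are integers); the two-sided p-value is twice the smaller tail, capped at
#' 1. Larger samples use a normal approximation with tie and continuity
#' corrections.
#'
#' All-positive configurations give the smallest attainable two-sided
#' p-values, `2 / 2^n`: 0.03125 at n = 6 and 0.0078125 at n = 8.
#'
#' @param values Numeric vector of (paired) differences.
#' @param mu0 Null center.
#' @param exact_max_n Largest n for which the exact distribution is used.
#' @return One-row tibble: `method`, `statistic` (positive-rank sum W),
#'   `p_value`, `tails`, `n`, `notes`.
#' @export
wilcoxon_signed_exact <- function(values, mu0 = 0, exact_max_n = 25) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all values equal mu0; p = 1")
    return(tibble::tibble(method = "wilcoxon_signed_exact", statistic = NA_real_,
                          p_value = 1, tails = "two-sided", n = 0L,
                          notes = "all values equal mu0"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))  # doubled midranks are integers
    # counts[k+1] = number of sign assignments with doubled rank sum k
    counts <- numeric(sum(r2) + 1L)
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    total <- 2^n
    sums <- seq_along(counts) - 1L
    w2 <- round(2 * w)
    p_ge <- sum(counts[sums >= w2]) / total
    p_le <- sum(counts[sums <= w2]) / total
    p <- min(1, 2 * min(p_ge, p_le))
    notes <- sprintf("exact over 2^%d sign assignments", n)
  } else {
    mu_w <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    z <- (w - mu_w - sign(w - mu_w) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    notes <- "normal approximation with tie/continuity correction"
  }
  tibble::tibble(method = "wilcoxon_signed_exact", statistic = w, p_value = p,
                 tails = "two-sided", n = as.integer(n), notes = notes)
}

#' One-sided chi-square test for a 2x2 table
#'
#' Pearson chi-square with 1 df and no continuity correction,
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, halved into the pre-declared
#' direction: if the observed association (sign of `ad - bc`) matches
#' `direction`, `p = P(X^2 > obs) / 2`; otherwise `p = 1 - P(X^2 > obs) / 2`.
#' The caller must declare the direction before looking at the data.
#'
#' @param a,b,c,d Counts, rows = groups, columns = outcome
#'   (`a`,`b` = group 1; `c`,`d` = group 2).
#' @param direction `"positive"` (group 1 enriched for the first column,
#'   `ad - bc > 0`) or `"negative"`.
#' @return One-row tibble (`method`, `statistic`, `p_value`, `tails`, `n`,
#'   `notes`).
#' @export
chisq_2x2_one_sided <- function(a, b, c, d, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all row and column margins must be > 0", call. = FALSE)
  delta <- a * d - b * c
  chi2 <- n * delta^2 / prod(margins)
  p_upper <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  obs_dir <- if (delta >= 0) "positive" else "negative"
  p <- if (delta == 0) 0.5
       else if (obs_dir == direction) p_upper / 2 else 1 - p_upper / 2
  tibble::tibble(method = "chisq_2x2_one_sided", statistic = chi2, p_value = p,
                 tails = paste0("one-sided (", direction, ")"),
                 n = as.integer(n), notes = "no continuity correction")
}

#' Simple linear regression with slope test
#'
#' Ordinary least squares of `y` on `x` with the usual t-test of the slope.
#' Instead of a robust outlier-rejecting fit, potential outliers are flagged
#' (|externally studentized residual| > 3) and reported without being
#' removed, so the fit stays reproducible and the flags stay auditable.
#'
#' @param x,y Numeric vectors.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `t`, `p_value`,
#'   `n`, `n_outliers`, and `outliers` (list column of flagged indices).
#' @export
linregress_with_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  flags <- which(abs(suppressWarnings(stats::rstudent(fit))) > 3)
  tibble::tibble(slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 t = co["x", "t value"],
                 p_value = co["x", "Pr(>|t|)"],
                 n = length(x),
                 n_outliers = length(flags),
                 outliers = list(as.integer(flags)))
}

#' Between-group slope comparison
#'
#' Tests whether two regressions have different slopes via the interaction
#' term of a pooled model `y ~ x * group`.
#'
#' @param x1,y1 First group's data.
#' @param x2,y2 Second group's data.
#' @return One-row tibble (`method`, `statistic` = interaction t, `p_value`,
#'   `tails`, `n`, `notes`).
#' @export
compare_slopes <- function(x1, y1, x2, y2) {
  g <- factor(c(rep("g1", length(x1)), rep("g2", length(x2))))
  x <- c(x1, x2); y <- c(y1, y2)
  fit <- stats::lm(y ~ x * g)
  co <- summary(fit)$coefficients
  row <- grep("^x:g", rownames(co))
  tibble::tibble(method = "compare_slopes", statistic = co[row, "t value"],
                 p_value = co[row, "Pr(>|t|)"], tails = "two-sided",
                 n = length(x), notes = "interaction term of pooled OLS")
}

#' Suppression ratio vs probe discrimination
#'
#' Within each group, regresses the probe A/C difference index on the
#' predicted-cue suppression ratio from preconditioning. A negative slope in
#' controls indicates that stronger suppression of predicted-cue responses
#' (more prediction-error-like signaling) predicts better expression of the
#' latent cue-cue learning in the probe.
#'
#' @param summaries Output of [subject_summaries()].
#' @return Tibble, one row per group: `group`, `slope`, `t`, `p_value`, `n`.
#' @export
correlate_spe_with_probe <- function(summaries) {
  if (nrow(summaries) == 0) stop("no subjects to correlate", call. = FALSE)
  groups <- unique(summaries$group)
  out <- lapply(groups, function(g) {
    s <- summaries[summaries$group == g, ]
    s <- s[is.finite(s$suppression_BD) & is.finite(s$diff_AC), ]
    if (nrow(s) == 0) stop(sprintf("group '%s' is empty", g), call. = FALSE)
    fit <- linregress_with_test(s$suppression_BD, s$diff_AC)
    tibble::tibble(group = g, slope = fit$slope, t = fit$t,
                   p_value = fit$p_value, n = fit$n)
  })
  dplyr::bind_rows(out)
}

#' Repeated-measures ANOVA (balanced within-subject designs)
#'
#' F and p per main effect and interaction for fully balanced within-subject
#' designs with one observation per cell, using `stats::aov` with
#' `Error(subject/(...))` strata. Unbalanced input is rejected. When an
#' effect's sum of squares is exactly zero the F statistic is reported as 0.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject column.
#' @param within Character vector of within-subject factor column names
#'   (one or two).
#' @return Tibble: `effect`, `df1`, `df2`, `F`, `p_value`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(length(within) %in% 1:2)
  d <- as.data.frame(data)
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  tab <- table(d[c(subject, within)])
  if (any(tab != 1))
    stop("unsupported design: need a balanced layout with exactly one ",
         "observation per subject x condition cell", call. = FALSE)
  rhs <- paste(within, collapse = " * ")
  err <- paste0("Error(", subject, "/(", rhs, "))")
  f <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(f, data = d)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    s <- stratum[[1]]
    terms <- rownames(s)
    res_i <- grep("Residuals", terms)
    if (length(res_i) == 0) next
    ss_res <- s[res_i, "Sum Sq"]; df_res <- s[res_i, "Df"]
    for (i in seq_len(nrow(s))) {
      if (i %in% res_i) next
      ss <- s[i, "Sum Sq"]; df1 <- s[i, "Df"]
      f_val <- if (ss < 1e-10) 0
               else (ss / df1) / (ss_res / df_res)
      p <- if (ss < 1e-10) 1
           else stats::pf(f_val, df1, df_res, lower.tail = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(
        effect = trimws(terms[i]), df1 = df1, df2 = df_res,
        F = f_val, p_value = p)
    }
  }
  dplyr::bind_rows(out)
}
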