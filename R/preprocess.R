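#' Sliding median filter
#'
#' Order-`order` median filter as used for raw photometry traces: a centered
#' sliding median of window length `order + 1` samples (rounded up to odd),
#' with edges handled by symmetric reflection so the output has the input's
#' length.
#'
#' @param trace Numeric vector.
#' @param order Filter order; the default 4 gives a 5-sample window.
#' @return Filtered vector, same length as `trace`.
#' @examples
#' median_filter(c(0, 0, 0, 10, 0, 0, 0))  # isolated spike removed
#' @export
median_filter <- function(trace, order = 4) {
  k <- as.integer(order) + 1L
  if (k %% 2L == 0L) k <- k + 1L  # runmed needs an odd window
  n <- length(trace)
  if (n <= order) stop("trace must be longer than the filter order", call. = FALSE)
  p <- k %/% 2L
  padded <- c(trace[p:1], trace, trace[n:(n - p + 1L)])
  out <- stats::runmed(padded, k, endrule = "keep")
  out[(p + 1L):(p + n)]
}

#' Isosbestic motion correction by polynomial fit
#'
#' Least-squares fit of the active (470 nm) channel on a second-order
#' polynomial of the isosbestic reference (415 nm), over all samples passed in
#' (typically every gated epoch of one recording session concatenated); the
#' corrected signal is the residual `dF = active - fitted`, which removes
#' bleaching and motion components shared between channels while leaving the
#' sensor-dependent signal.
#'
#' A constant (or near-constant, < 3 distinct values) reference cannot support
#' the polynomial; the fit then degenerates to subtracting the mean of the
#' active channel, with a warning.
#'
#' @param active,reference Equal-length numeric vectors.
#' @param degree Polynomial degree (default 2).
#' @return List with `dF` (residual vector) and `coefficients`
#'   (named `c0`, `c1`, `c2`).
#' @export
isosbestic_correct <- function(active, reference, degree = 2) {
  if (length(active) != length(reference))
    stop("active and reference must have equal length", call. = FALSE)
  if (length(unique(reference)) < 3) {
    warning("degenerate (near-constant) reference: falling back to mean subtraction")
    return(list(dF = active - mean(active),
                coefficients = c(c0 = mean(active), c1 = 0, c2 = 0)))
  }
  X <- stats::poly(reference, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), active)
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  list(dF = unname(fit$residuals),
       coefficients = stats::setNames(cf, paste0("c", 0:degree)))
}

#' Per-trial baseline z-score
#'
#' Standardizes a corrected trace against its own pre-trial baseline: samples
#' with `baseline_window[1] <= t < baseline_window[2]` (default the 10 s
#' before the first cue onset at t = 0) define the mean and SD.
#'
#' The SD convention defaults to the sample (n - 1) estimator; population
#' (divide by n) is available via `sd_method`.
#'
#' @param dF Corrected trace.
#' @param time_s Epoch-relative times, first cue onset at 0.
#' @param baseline_window Two numbers, `[start, end)` in s.
#' @param sd_method `"sample"` or `"population"`.
#' @return z-scored trace.
#' @export
trial_zscore <- function(dF, time_s, baseline_window = c(-10, 0),
                         sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  idx <- time_s >= baseline_window[1] & time_s < baseline_window[2]
  if (!any(idx))
    stop("baseline window contains no samples", call. = FALSE)
  b <- dF[idx]
  m <- mean(b)
  s <- if (sd_method == "sample") stats::sd(b)
       else sqrt(mean((b - m)^2))
  if (!is.finite(s) || s == 0)
    stop("baseline SD is zero; cannot z-score this epoch", call. = FALSE)
  (dF - m) / s
}

#' Session peak normalization
#'
#' Rescales the z-scored trials of one subject-site-session so the session's
#' baseline average maps to 0 and its single largest sample maps to 1:
#' `znorm = (z - B) / (P - B)` with `B` the mean of all baseline-window
#' samples in the session and `P` the session-wide maximum.
#'
#' @param z z-scored samples of one session (all trials concatenated).
#' @param is_baseline Logical vector marking baseline-window samples.
#' @return Normalized samples, same length as `z`.
#' @export
session_normalize <- function(z, is_baseline) {
  stopifnot(length(z) == length(is_baseline))
  if (!any(is_baseline)) stop("no baseline samples in session", call. = FALSE)
  B <- mean(z[is_baseline])
  P <- max(z)
  if (P <= B) stop("session peak does not exceed baseline average", call. = FALSE)
  (z - B) / (P - B)
}

#' Run the full preprocessing chain
#'
#' Applies, in order and per subject/site: (1) median filtering of each raw
#' channel within each epoch, (2) a session-scope second-order polynomial
#' isosbestic fit and subtraction, (3) per-trial baseline z-scoring, and
#' (4) session peak normalization. The probe reminder and test trials share
#' one recording session and hence one fit/normalization scope.
#'
#' @param photometry Photometry table (`subject`, `site`, `epoch_id`,
#'   `time_s`, `f470`, `f415`); extra columns are ignored.
#' @param baseline_len Baseline length in s; the z-score window is
#'   `[-baseline_len, 0)`.
#' @param filter_order Median filter order.
#' @param sd_method Passed to [trial_zscore()].
#' @return List of class `spc_normalized` with `trials` (tibble `subject`,
#'   `site`, `phase`, `session`, `session_uid`, `epoch_id`, `time_s`, `dF`,
#'   `z`, `znorm`) and `fits` (per subject-site-session polynomial
#'   coefficients).
#' @export
preprocess_photometry <- function(photometry, baseline_len = 10,
                                  filter_order = 4,
                                  sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  req <- c("subject", "site", "epoch_id", "time_s", "f470", "f415")
  miss <- setdiff(req, names(photometry))
  if (length(miss) > 0)
    stop("photometry table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(photometry[, req])

  uid <- unique(dt$epoch_id)
  parsed <- parse_epoch_id(uid)
  lut <- data.table::data.table(
    epoch_id = uid, phase = parsed$phase, session = parsed$session,
    session_uid = session_uid_for(parsed$phase, parsed$session))
  dt[lut, on = "epoch_id",
     `:=`(phase = i.phase, session = i.session, session_uid = i.session_uid)]

  # (1) median filter per channel within epoch
  dt[, `:=`(f470f = median_filter(f470, filter_order),
            f415f = median_filter(f415, filter_order)),
     by = .(subject, site, epoch_id)]

  # (2) session-scope isosbestic fit
  fits_l <- list()
  dt[, dF := {
    fit <- isosbestic_correct(f470f, f415f)
    fits_l[[length(fits_l) + 1L]] <<- data.frame(
      subject = subject[1], site = site[1], session_uid = session_uid[1],
      c0 = fit$coefficients[["c0"]], c1 = fit$coefficients[["c1"]],
      c2 = fit$coefficients[["c2"]])
    fit$dF
  }, by = .(subject, site, session_uid)]

  # (3) per-trial z-score against the pre-cue baseline
  dt[, z := trial_zscore(dF, time_s, c(-baseline_len, 0), sd_method),
     by = .(subject, site, epoch_id)]

  # (4) session peak normalization
  dt[, znorm := session_normalize(z, time_s >= -baseline_len & time_s < 0),
     by = .(subject, site, session_uid)]

  dt[, c("f470", "f415", "f470f", "f415f") := NULL]
  data.table::setcolorder(dt, c("subject", "site", "phase", "session",
                                "session_uid", "epoch_id", "time_s", "dF",
                                "z", "znorm"))
  trials <- dt_to_tbl(dt)
  fits <- tibble::as_tibble(data.table::rbindlist(fits_l))
  structure(list(trials = trials, fits = fits), class = "spc_normalized")
}

# split "phase_sNN_tNNN" identifiers back into their parts
parse_epoch_id <- function(epoch_id) {
  m <- regmatches(epoch_id, regexec("^(.*)_s(\\d+)_t(\\d+)$", epoch_id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("epoch_id not in '<phase>_sNN_tNNN' form: ",
         paste(utils::head(unique(epoch_id[bad]), 3), collapse = ", "),
         call. = FALSE)
  list(phase = vapply(m, `[`, "", 2L),
       session = as.integer(vapply(m, `[`, "", 3L)),
       trial = as.integer(vapply(m, `[`, "", 4L)))
}

#' @export
print.spc_normalized <- function(x, ...) {
  cat("<spc_normalized>\n")
  cat(sprintf("  %d samples across %d epochs (%d subject-site-sessions)\n",
              nrow(x$trials), length(unique(x$trials$epoch_id)), nrow(x$fits)))
  invisible(x)
}
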