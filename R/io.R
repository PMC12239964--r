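#' Write / read the event log
#'
#' The event log is a long CSV, one row per cue or reward event (`subject`,
#' `group`, `phase`, `session`, `trial`, `event_kind`, `cue`, `time_s`,
#' `duration_s`, `epoch_id`), with a companion CSV of food-port entry
#' intervals (`subject`, `phase`, `session`, `trial`, `epoch_id`, `cue`,
#' `enter_s`, `exit_s`). Times are epoch-relative seconds, first cue onset at
#' t = 0. `read_events` validates the invariants and names the offending
#' rows on failure.
#'
#' @param events Event tibble.
#' @param port Port-interval tibble (may have zero rows).
#' @param dir Directory to write into (created if needed).
#' @return `write_events` returns the two file paths invisibly;
#'   `read_events` returns `list(events=, port=)`.
#' @export
write_events <- function(events, port, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, "events.csv")
  pp <- file.path(dir, "port_entries.csv")
  data.table::fwrite(events, ep)
  data.table::fwrite(port, pp)
  invisible(c(events = ep, port = pp))
}

#' @rdname write_events
#' @export
read_events <- function(dir) {
  ep <- file.path(dir, "events.csv")
  pp <- file.path(dir, "port_entries.csv")
  if (!file.exists(ep)) stop("missing events.csv in ", dir, call. = FALSE)
  events <- tibble::as_tibble(data.table::fread(ep))
  req <- c("subject", "group", "phase", "session", "trial", "event_kind",
           "cue", "time_s", "duration_s", "epoch_id")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0)
    stop("events.csv is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  validate_events(events)
  port <- if (file.exists(pp)) tibble::as_tibble(data.table::fread(pp))
          else tibble::tibble(subject = character(), phase = character(),
                              session = integer(), trial = integer(),
                              epoch_id = character(), cue = character(),
                              enter_s = numeric(), exit_s = numeric())
  if (nrow(port) > 0) validate_port(port)
  list(events = events, port = port)
}

validate_events <- function(events) {
  cue <- events[events$event_kind == "cue_onset", ]
  if (any(cue$duration_s <= 0)) {
    bad <- which(cue$duration_s <= 0)[1]
    stop(sprintf("non-positive cue duration at events row %d (subject %s, epoch %s)",
                 bad, cue$subject[bad], cue$epoch_id[bad]), call. = FALSE)
  }
  key <- paste(cue$subject, cue$epoch_id)
  ord <- order(key, seq_len(nrow(cue)))
  cue <- cue[ord, ]; key <- key[ord]
  same <- c(FALSE, key[-1] == key[-length(key)])
  nonmono <- same & c(FALSE, diff(cue$time_s) <= 0)
  if (any(nonmono)) {
    bad <- which(nonmono)[1]
    stop(sprintf("non-monotone cue onsets in subject %s, epoch %s (row %d)",
                 cue$subject[bad], cue$epoch_id[bad], bad), call. = FALSE)
  }
  invisible(TRUE)
}

validate_port <- function(port) {
  bad <- which(port$exit_s < port$enter_s)
  if (length(bad) > 0)
    stop(sprintf("port interval with exit_s < enter_s at row %d (subject %s, epoch %s)",
                 bad[1], port$subject[bad[1]], port$epoch_id[bad[1]]),
         call. = FALSE)
  dt <- data.table::as.data.table(port)
  dt <- dt[order(subject, epoch_id, enter_s)]
  ov <- dt[, any(enter_s[-1] < exit_s[-.N] - 1e-9),
           by = .(subject, epoch_id)]
  if (nrow(ov) > 0 && any(ov$V1, na.rm = TRUE)) {
    w <- ov[which(ov$V1)[1], ]
    stop(sprintf("overlapping port intervals for subject %s, epoch %s",
                 w$subject, w$epoch_id), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a photometry table
#'
#' CSV with columns `subject`, `site`, `epoch_id`, `time_s`, `f470`, `f415`
#' (extra ground-truth columns from the simulator are dropped on write).
#' `read_photometry` validates that each epoch's time grid is uniform (to
#' 1e-6 s), has at least two samples, carries no duplicated time stamps and
#' only finite fluorescence values. Round trip is lossless to ~1e-15 relative
#' precision (values are written with 15 significant digits).
#'
#' @param photometry Photometry tibble.
#' @param path CSV path.
#' @return `write_photometry` returns `path` invisibly; `read_photometry`
#'   the validated tibble.
#' @export
write_photometry <- function(photometry, path) {
  cols <- c("subject", "site", "epoch_id", "time_s", "f470", "f415")
  miss <- setdiff(cols, names(photometry))
  if (length(miss) > 0)
    stop("photometry table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(photometry[, cols], path)
  invisible(path)
}

#' @rdname write_photometry
#' @export
read_photometry <- function(path) {
  if (!file.exists(path)) stop("missing photometry file ", path, call. = FALSE)
  ph <- data.table::fread(path)
  req <- c("subject", "site", "epoch_id", "time_s", "f470", "f415")
  miss <- setdiff(req, names(ph))
  if (length(miss) > 0)
    stop("photometry file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(ph$f470)) || !all(is.finite(ph$f415)))
    stop("photometry contains non-finite fluorescence values", call. = FALSE)
  chk <- ph[, {
    n <- .N
    if (n < 2) stop(sprintf("epoch %s / %s / %s has fewer than 2 samples",
                            subject[1], site[1], epoch_id[1]), call. = FALSE)
    dts <- diff(time_s)
    if (any(dts <= 0)) stop(sprintf("duplicated or non-increasing time_s in epoch %s / %s / %s",
                                    subject[1], site[1], epoch_id[1]), call. = FALSE)
    if (max(dts) - min(dts) > 1e-6)
      stop(sprintf("non-uniform time grid in epoch %s / %s / %s",
                   subject[1], site[1], epoch_id[1]), call. = FALSE)
    .(ok = TRUE)
  }, by = .(subject, site, epoch_id)]
  invisible(chk)
  tibble::as_tibble(ph)
}

#' Load / save a simulation configuration
#'
#' Configurations are YAML key-value files. Unknown keys are rejected,
#' missing keys fall back to the [sim_config()] defaults, and all range
#' invariants are re-validated. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @return `load_config` returns an `spc_config`; `save_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("missing config file ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- config_known_keys()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$site_scale)) {
    raw$site_scale <- lapply(raw$site_scale, function(x) unlist(x))
  }
  do.call(sim_config, raw)
}

#' @rdname load_config
#' @param config An `spc_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "spc_config"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- unclass(config)
  x$site_scale <- lapply(x$site_scale, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}
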