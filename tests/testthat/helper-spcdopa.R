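# shared fixtures: tiny cohorts, built once per test run and cached

.spc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.spc_cache[[key]])) .spc_cache[[key]] <- force(expr)
  .spc_cache[[key]]
}

tiny_config <- function(...) {
  sim_config(n_ctrl = 2, n_ofci = 1, seed = 101, ...)
}

# small main-variant dataset, NAcc only, all phases rendered
tiny_main <- function() {
  cached("tiny_main", simulate_cohort(tiny_config(), sites = "NAcc"))
}

tiny_norm <- function() {
  cached("tiny_norm", preprocess_photometry(tiny_main()$photometry))
}

tiny_rows <- function() {
  cached("tiny_rows", {
    ds <- tiny_main()
    quantify_responses(tiny_norm(), ds$events, ds$port)
  })
}

# run the simulate->preprocess->quantify chain on one configuration
run_pipe <- function(cfg, variant = "main", phases = NULL, sites = "NAcc",
                     through = NULL) {
  ds <- simulate_cohort(cfg, variant = variant, sites = sites,
                        photometry_phases = phases, through_phase = through)
  norm <- preprocess_photometry(ds$photometry)
  rows <- quantify_responses(norm, ds$events, ds$port)
  list(ds = ds, norm = norm, rows = rows)
}

# label each epoch of a session by its ordered cue composition ("AB", "AD", ...)
epoch_pair_label <- function(events) {
  ev <- events[events$event_kind == "cue_onset", ]
  ev <- ev[order(ev$subject, ev$epoch_id, ev$time_s), ]
  out <- stats::aggregate(cue ~ subject + epoch_id, data = ev,
                          FUN = function(x) paste(x, collapse = ""))
  names(out)[names(out) == "cue"] <- "pair"
  out
}

# brute-force signed-rank null: all 2^n sign assignments, two-sided p
wilcoxon_enum_oracle <- function(values, mu0 = 0) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W >= w_obs), mean(W <= w_obs)))
}
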