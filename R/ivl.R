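#' Detect spikes in a voltage trace
#'
#' A spike is recorded at each upward crossing of `threshold` separated
#' from the previous spike by at least `refractory`.  The amplitude of a
#' spike is the peak voltage within `peak_window` after the crossing
#' minus the mean subthreshold membrane potential of the trace (samples
#' outside spike-exclusion windows).
#'
#' @param v Voltage trace (mV).
#' @param time Time grid (ms), same length as `v`.
#' @param threshold Detection threshold (mV).
#' @param refractory Minimum spike separation (ms).
#' @param peak_window Window after the crossing searched for the peak (ms).
#' @param exclusion_halfwidth Half-width of the spike-exclusion window
#'   used for the subthreshold reference (ms).
#' @return A list of class `ivl_spikes`: `times`, `amplitudes`,
#'   `rate` (Hz over the trace span), `isi_cv` (coefficient of variation
#'   of inter-spike intervals; 0 with fewer than 3 spikes), `n`.
#' @export
detect_spikes <- function(v, time, threshold = -10, refractory = 3,
                          peak_window = 3, exclusion_halfwidth = 5) {
  if (any(!is.finite(v))) stop("non-finite samples in voltage trace",
                               call. = FALSE)
  stopifnot(length(v) == length(time))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- numeric(0)
  for (i in up) {
    if (length(times) == 0 || time[i] - times[length(times)] >= refractory) {
      times <- c(times, time[i])
    }
  }
  span <- (time[length(time)] - time[1]) / 1000
  dt <- if (length(time) > 1) time[2] - time[1] else 1
  amps <- numeric(0)
  if (length(times) > 0) {
    vsub <- subthreshold_mask(time, times, exclusion_halfwidth)
    vref <- if (any(vsub)) mean(v[vsub]) else mean(v)
    n <- length(v)
    wn <- max(1L, round(peak_window / dt))
    amps <- vapply(times, function(tt) {
      i0 <- round((tt - time[1]) / dt) + 1L
      max(v[i0:min(n, i0 + wn)]) - vref
    }, numeric(1))
  }
  st <- spike_train_stats(times, span * 1000)
  structure(
    list(times = times, amplitudes = amps,
         rate = st$rate, isi_cv = st$isi_cv,
         n = length(times), dt = dt),
    class = "ivl_spikes"
  )
}

#' Rate and interval statistics of a spike train
#'
#' The statistics stage of the spike pipeline, usable directly on event
#' times: rate over the span and the inter-spike-interval coefficient of
#' variation (SD/mean of the ISIs; 0 with fewer than 3 events).
#'
#' @param times Event times (ms), increasing.
#' @param duration Span used for the rate (ms); defaults to the time of
#'   the last event.
#' @return A list `rate` (Hz), `isi_cv`, `n`.
#' @export
spike_train_stats <- function(times, duration = NULL) {
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  isi <- diff(times)
  list(
    rate = if (duration > 0) length(times) / (duration / 1000) else 0,
    isi_cv = if (length(isi) >= 2) stats::sd(isi) / mean(isi) else 0,
    n = length(times)
  )
}

#' @export
print.ivl_spikes <- function(x, ...) {
  cat("<ivl_spikes> ", x$n, " spikes, rate ", format(round(x$rate, 2)),
      " Hz, ISI CV ", format(round(x$isi_cv, 3)), "\n", sep = "")
  invisible(x)
}

subthreshold_mask <- function(time, spike_times, exclusion_halfwidth) {
  keep <- rep(TRUE, length(time))
  n <- length(time)
  if (n > 1 && length(spike_times) > 0) {
    dt <- time[2] - time[1]
    wn <- max(0L, round(exclusion_halfwidth / dt))
    for (tt in spike_times) {
      i0 <- round((tt - time[1]) / dt) + 1L
      keep[max(1L, i0 - wn):min(n, i0 + wn)] <- FALSE
    }
  }
  keep
}

#' Subthreshold membrane-potential statistics
#'
#' Mean and standard deviation of the membrane potential over samples
#' outside the spike-exclusion windows.
#'
#' @inheritParams detect_spikes
#' @param spikes An `ivl_spikes` object (or numeric spike times).
#' @return A list `mean`, `sd`, `n_retained`, `fraction_retained`.
#' @export
subthreshold_stats <- function(v, time, spikes = NULL,
                               exclusion_halfwidth = 5) {
  st <- if (inherits(spikes, "ivl_spikes")) spikes$times
        else if (is.null(spikes)) numeric(0) else spikes
  keep <- subthreshold_mask(time, st, exclusion_halfwidth)
  if (!any(keep)) stop("spike exclusion removed every sample", call. = FALSE)
  list(mean = mean(v[keep]),
       sd = stats::sd(v[keep]),
       n_retained = sum(keep),
       fraction_retained = mean(keep))
}

#' Threshold set of the in vivo-like (IVL) state metric
#'
#' Defaults as used for OLM cells: mean subthreshold potential above
#' -70.588 mV (resting potential plus an approximate 3 mV in vivo
#' depolarization), subthreshold fluctuation above 2.2 mV, inter-spike
#' interval CV above 0.8, spike rate strictly between 3 and 25 Hz, and a
#' -5 penalty when the mean spike amplitude falls below 40 mV
#' (depolarization block).  All comparisons are strict inequalities.
#'
#' @param vm_mean,vm_sd,isi_cv,rate_lo,rate_hi,spike_amp Threshold values.
#' @export
ivl_thresholds <- function(vm_mean = -70.588, vm_sd = 2.2, isi_cv = 0.8,
                           rate_lo = 3, rate_hi = 25, spike_amp = 40) {
  list(vm_mean = vm_mean, vm_sd = vm_sd, isi_cv = isi_cv,
       rate_lo = rate_lo, rate_hi = rate_hi, spike_amp = spike_amp)
}

#' Score a simulated state with the IVL metric
#'
#' The IVL metric scores four criteria (one point each; strict
#' inequalities): depolarized mean subthreshold potential, large
#' subthreshold fluctuations, irregular spiking, and a spike rate inside
#' the in vivo band; five points are subtracted when the mean spike
#' amplitude indicates depolarization block.  A score of 4 marks an in
#' vivo-like state.  With no spikes, the amplitude penalty is not applied
#' (there is no amplitude evidence of block; the rate criterion already
#' fails).
#'
#' @param sub Subthreshold statistics (see [subthreshold_stats()]).
#' @param spk Spike-train statistics (see [detect_spikes()]).
#' @param thresholds See [ivl_thresholds()].
#' @return A list of class `ivl_score`: the five criterion booleans, the
#'   measured components and the integer `score`.
#' @export
ivl_score <- function(sub, spk, thresholds = ivl_thresholds()) {
  th <- thresholds
  amp_mean <- if (spk$n > 0) mean(spk$amplitudes) else NA_real_
  crit <- list(
    depolarized = sub$mean > th$vm_mean,
    fluctuating = sub$sd > th$vm_sd,
    irregular = spk$isi_cv > th$isi_cv,
    rate_band = spk$rate > th$rate_lo & spk$rate < th$rate_hi,
    amp_penalty = if (spk$n > 0) amp_mean < th$spike_amp else FALSE
  )
  score <- sum(unlist(crit[1:4])) - 5L * crit$amp_penalty
  structure(
    c(crit,
      list(vm_mean = sub$mean, vm_sd = sub$sd, isi_cv = spk$isi_cv,
           rate = spk$rate, amp_mean = amp_mean,
           score = as.integer(score))),
    class = "ivl_score"
  )
}

#' @export
print.ivl_score <- function(x, ...) {
  cat("<ivl_score> ", x$score, " (depol=", x$depolarized, " fluct=",
      x$fluctuating, " irreg=", x$irregular, " rate=", x$rate_band,
      " penalty=", x$amp_penalty, ")\n", sep = "")
  invisible(x)
}

tidy_score <- function(x) {
  tibble::tibble(
    depolarized = x$depolarized, fluctuating = x$fluctuating,
    irregular = x$irregular, rate_band = x$rate_band,
    amp_penalty = x$amp_penalty, vm_mean = x$vm_mean, vm_sd = x$vm_sd,
    isi_cv = x$isi_cv, rate = x$rate, amp_mean = x$amp_mean,
    score = x$score
  )
}

#' Tidy an IVL score
#' @param x An `ivl_score`.
#' @param ... Unused.
#' @export
tidy.ivl_score <- function(x, ...) tidy_score(x)

#' Score a voltage trace with the IVL metric
#'
#' Convenience wrapper: spike detection, subthreshold statistics and
#' [ivl_score()] on the analysis window of a trace.
#'
#' @param traces An `ivl_trace_set`.
#' @param site Site name (default soma).
#' @param discard Initial transient to discard (ms); the analysis window
#'   is the remainder of the trace (the last 9 s of a 10 s simulation by
#'   default).
#' @param thresholds See [ivl_thresholds()].
#' @param ... Passed to [detect_spikes()].
#' @export
score_trace <- function(traces, site = "S", discard = 1000,
                        thresholds = ivl_thresholds(), ...) {
  sel <- traces$time >= discard
  v <- traces$v[sel, site]
  tt <- traces$time[sel]
  spk <- detect_spikes(v, tt, ...)
  sub <- subthreshold_stats(v, tt, spk)
  ivl_score(sub, spk, thresholds = thresholds)
}

#' Simulate one bombardment realization and score it
#'
#' @param model An `ivl_neuron_model`.
#' @param params Input parameters ([input_params()]).
#' @param cfg An `ivl_input_config`.
#' @param duration Simulation duration (ms).
#' @param seed Seed for the bombardment realization.
#' @param weights Weight map (see [generate_trains()]).
#' @param discard Transient discarded before scoring (ms).
#' @param record_dt Recording interval (ms).
#' @param thresholds See [ivl_thresholds()].
#' @return An `ivl_score`.
#' @export
ivl_state_score <- function(model, params, cfg, duration = 10000, seed = 1,
                            weights = 1e-4, discard = 1000,
                            record_dt = 0.05,
                            thresholds = ivl_thresholds()) {
  bomb <- generate_trains(params, cfg, model, duration, seed,
                          weights = weights)
  pr <- stim_protocol(duration, record_dt = record_dt)
  pr <- add_bombardment(pr, bomb)
  tr <- simulate_cell(model, pr)
  score_trace(tr, discard = discard, thresholds = thresholds)
}

#' Ten-seed consistency rule for an IVL parameter set
#'
#' A parameter set is consistently IVL when, over `n_seeds` independent
#' re-randomizations of synaptic placements and presynaptic spike times,
#' the IVL metric equals 4 in at least half of the simulations and is at
#' least 3 in all of the rest.
#'
#' @inheritParams ivl_state_score
#' @param n_seeds Number of re-randomizations (10 by default).
#' @param scorer Optional scoring function `(params, seed) -> ivl_score`
#'   replacing the default simulation-based scorer.
#' @param early_abort Stop as soon as the verdict can no longer be true
#'   (a score below 3, or too few 4s attainable); the returned score
#'   table is then partial.
#' @param ... Passed to [ivl_state_score()] when the default scorer is
#'   used.
#' @return A list of class `ivl_consistency`: `scores` (tibble, one row
#'   per seed) and logical `verdict`.
#' @export
consistency_check <- function(model, params, cfg, n_seeds = 10,
                              duration = 10000, seed = 1, scorer = NULL,
                              early_abort = FALSE, ...) {
  stopifnot(n_seeds >= 1)
  if (is.null(scorer)) {
    scorer <- function(params, s) {
      ivl_state_score(model, params, cfg, duration = duration, seed = s,
                      ...)
    }
  }
  seeds <- derive_seeds(seed, n_seeds)
  need4 <- ceiling(n_seeds / 2)
  rows <- list()
  for (i in seq_len(n_seeds)) {
    sc <- scorer(params, seeds[i])
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(replicate = i, seed = seeds[i]), tidy_score(sc))
    if (early_abort) {
      got <- vapply(rows, function(r) r$score, integer(1))
      if (any(got < 3) || sum(got == 4) + (n_seeds - i) < need4) break
    }
  }
  scores <- dplyr::bind_rows(rows)
  verdict <- consistency_verdict(scores$score, n_seeds) &&
    nrow(scores) == n_seeds
  structure(
    list(scores = scores, verdict = verdict),
    class = "ivl_consistency"
  )
}

# the consistency rule: >= ceiling(n/2) scores of 4 and every other >= 3
consistency_verdict <- function(scores, n_seeds = length(scores)) {
  sum(scores == 4) >= ceiling(n_seeds / 2) && all(scores >= 3)
}

#' @export
print.ivl_consistency <- function(x, ...) {
  cat("<ivl_consistency> verdict:", x$verdict, "- scores:",
      paste(x$scores$score, collapse = " "), "\n")
  invisible(x)
}

#' Tidy a consistency verdict into its per-seed score table
#' @param x An `ivl_consistency`.
#' @param ... Unused.
#' @export
tidy.ivl_consistency <- function(x, ...) x$scores

#' One-row summary of a consistency verdict
#' @param x An `ivl_consistency`.
#' @param ... Unused.
#' @export
glance.ivl_consistency <- function(x, ...) {
  tibble::tibble(
    n_seeds = nrow(x$scores),
    n_score4 = sum(x$scores$score == 4),
    min_score = min(x$scores$score),
    verdict = x$verdict
  )
}
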