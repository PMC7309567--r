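#' Two-point frequency-current line
#'
#' Fits the line through two (holding current, spike rate) calibration
#' points; used to match in-vitro firing rates to bombardment-driven
#' rates.  F-I curves are close to linear above rheobase, which justifies
#' the two-point extrapolation.
#'
#' @param i1,f1,i2,f2 The two calibration points (pA, Hz).
#' @return An object of class `ivl_fi_line` with slope `m` (Hz/pA),
#'   intercept `b` (Hz) and the calibration points.
#' @export
fi_line_from_points <- function(i1, f1, i2, f2) {
  if (f1 == f2) {
    stop("identical rates at both calibration currents (zero slope)",
         call. = FALSE)
  }
  m <- (f2 - f1) / (i2 - i1)
  b <- f1 - m * i1
  structure(
    list(m = m, b = b,
         points = tibble::tibble(current = c(i1, i2), rate = c(f1, f2))),
    class = "ivl_fi_line"
  )
}

#' Calibrate the frequency-current line of a model
#'
#' Simulates the model without synapses at two somatic holding currents
#' above rheobase (rheobase + 60 pA and rheobase + 120 pA by default),
#' measures the resulting spike rates over the analysis window, and
#' returns the line through the two points.
#'
#' @param model An `ivl_neuron_model`.
#' @param rheo Rheobase (pA); computed via [rheobase()] when NULL.
#' @param extra Offsets above rheobase for the two calibration currents
#'   (pA).
#' @param duration Simulation duration (ms).
#' @param discard Transient discarded before rate measurement (ms).
#' @param ... Passed to [rheobase()] when `rheo` is NULL.
#' @return An `ivl_fi_line` (also carrying `rheobase`).
#' @export
fi_line <- function(model, rheo = NULL, extra = c(60, 120),
                    duration = 10000, discard = 1000, ...) {
  if (is.null(rheo)) rheo <- rheobase(model, ...)
  rates <- vapply(extra, function(dI) {
    measure_rate(model, rheo + dI, duration, discard)
  }, numeric(1))
  if (any(rates <= 0)) {
    stop("calibration current did not elicit spiking", call. = FALSE)
  }
  fl <- fi_line_from_points(rheo + extra[1], rates[1],
                            rheo + extra[2], rates[2])
  fl$rheobase <- rheo
  fl
}

measure_rate <- function(model, amp, duration = 10000, discard = 1000,
                         record_dt = 0.05) {
  pr <- stim_protocol(duration, record_dt = record_dt)
  pr <- add_current_step(pr, amp, 0, Inf, site = "S")
  tr <- simulate_cell(model, pr)
  sel <- tr$time >= discard
  spk <- detect_spikes(tr$v[sel, "S"], tr$time[sel])
  spk$rate
}

#' @export
print.ivl_fi_line <- function(x, ...) {
  cat("<ivl_fi_line> f = ", format(round(x$m, 4)), " * I + ",
      format(round(x$b, 3)), "  (Hz, pA)\n", sep = "")
  invisible(x)
}

#' Tidy the F-I calibration points
#' @param x An `ivl_fi_line`.
#' @param ... Unused.
#' @export
tidy.ivl_fi_line <- function(x, ...) x$points

#' One-row F-I line summary
#' @param x An `ivl_fi_line`.
#' @param ... Unused.
#' @export
glance.ivl_fi_line <- function(x, ...) {
  tibble::tibble(m = x$m, b = x$b,
                 rheobase = x$rheobase %||% NA_real_)
}

#' Holding current matching a target spike rate
#'
#' Inverts the F-I line: `I_hold = (f - b) / m`.
#'
#' @param f Target spike rate (Hz).
#' @param line An `ivl_fi_line`.
#' @return Holding current (pA).
#' @export
holding_current <- function(f, line) {
  (f - line$b) / line$m
}

#' Currentscape decomposition of membrane currents at a site
#'
#' Splits each channel/synapse current into its inward (negative) and
#' outward (positive) part per sample and expresses it as a fraction of
#' the total inward or outward current.  Samples where a pool total is
#' zero have undefined (NA) fractions for that pool.
#'
#' @param traces An `ivl_trace_set`.
#' @param site Site name.
#' @param include_synapses Include the synaptic current series in the
#'   pools (the default; set FALSE for intrinsic channels only).
#' @return An object of class `ivl_currentscape`: a tibble with columns
#'   `time`, `channel`, `pool` (`"inward"`/`"outward"`), `current` (pA),
#'   `fraction`, `pool_total` (pA).
#' @export
currentscape <- function(traces, site = "S", include_synapses = TRUE) {
  nm <- names(traces$currents)
  if (!include_synapses) nm <- setdiff(nm, c("syn_exc", "syn_inh"))
  m <- vapply(nm, function(x) traces$currents[[x]][, site],
              numeric(length(traces$time)))
  neg <- pmin(m, 0)
  pos <- pmax(m, 0)
  tot_in <- rowSums(neg)
  tot_out <- rowSums(pos)
  frac_in <- sweep(neg, 1, tot_in, "/")
  frac_out <- sweep(pos, 1, tot_out, "/")
  frac_in[tot_in == 0, ] <- NA_real_
  frac_out[tot_out == 0, ] <- NA_real_
  out <- dplyr::bind_rows(
    tibble::tibble(
      time = rep(traces$time, length(nm)),
      channel = rep(nm, each = length(traces$time)),
      pool = "inward", current = as.vector(neg),
      fraction = as.vector(frac_in),
      pool_total = rep(tot_in, length(nm))
    ),
    tibble::tibble(
      time = rep(traces$time, length(nm)),
      channel = rep(nm, each = length(traces$time)),
      pool = "outward", current = as.vector(pos),
      fraction = as.vector(frac_out),
      pool_total = rep(tot_out, length(nm))
    )
  )
  class(out) <- c("ivl_currentscape", class(out))
  out
}

#' Total transferred charge of a current trace
#'
#' Signed area under the current trace (trapezoidal rule; exact for
#' piecewise-linear inputs).  For outward currents, more positive values
#' indicate larger currents; for inward currents, more negative values
#' indicate larger currents.
#'
#' @param current Current samples (pA).
#' @param time Time grid (ms).
#' @return Charge in pA ms.
#' @export
total_charge <- function(current, time) {
  stopifnot(length(current) == length(time))
  if (length(time) < 2) return(0)
  sum(diff(time) * (utils::head(current, -1) + utils::tail(current, -1)) / 2)
}

#' Polarity convention for cross-correlation of ionic currents
#'
#' Inward-carrying currents (NaT, CaT, CaL, H and excitatory synaptic)
#' are reversed in polarity so that their activation aligns with the
#' polarity of voltage and outward-current activation.  The leak current
#' is exempt: although mostly inward at baseline, it becomes an outward
#' current during spikes.
#'
#' @param currents Named list (or named numeric matrix columns) of
#'   current traces.
#' @param inward_channels Channel names to negate.
#' @return The adjusted named list.
#' @export
polarity_adjust <- function(currents,
                            inward_channels = c("NaT", "CaT", "CaL", "H",
                                                "syn_exc")) {
  for (nm in names(currents)) {
    if (nm %in% inward_channels) currents[[nm]] <- -currents[[nm]]
  }
  currents
}

#' Normalized cross-correlation of two series
#'
#' Both series are centred; the first is scaled by its standard deviation
#' times its length and the second by its standard deviation, so the full
#' linear cross-correlation has magnitudes in [-1, 1] (the
#' autocorrelation at lag 0 is exactly 1).  The correlogram is trimmed to
#' `max_lag`.  Sign convention: when `a2` equals `a1` delayed by `d` ms,
#' the peak sits at lag `-d`.
#'
#' @param a1,a2 Numeric series on a shared time grid.
#' @param dt Sample interval (ms).
#' @param max_lag Maximum lag retained (ms).
#' @return An object of class `ivl_correlogram`: a tibble `lag` (ms),
#'   `value`, with attributes `peak_value` and `peak_lag`.
#' @export
normalized_xcorr <- function(a1, a2, dt = 1, max_lag = 20) {
  stopifnot(length(a1) == length(a2))
  n <- length(a1)
  # population SD, so the lag-0 autocorrelation is exactly 1
  s1 <- sqrt(mean((a1 - mean(a1))^2))
  s2 <- sqrt(mean((a2 - mean(a2))^2))
  if (s1 == 0 || s2 == 0) {
    stop("zero-variance input to normalized_xcorr", call. = FALSE)
  }
  x1 <- (a1 - mean(a1)) / (s1 * n)
  x2 <- (a2 - mean(a2)) / s2
  # full linear cross-correlation c(l) = sum_n x1[n] * x2[n - l]:
  # stats::convolve(x, y, type = "open") reverses y (usual convolution
  # definition), so z[k] = sum_j x1[j] x2[j - (k - n)] = c(k - n)
  z <- stats::convolve(x1, x2, type = "open")
  lags <- (seq_along(z) - n) * dt
  keep <- abs(lags) <= max_lag + 1e-9
  out <- tibble::tibble(lag = lags[keep], value = z[keep])
  ipk <- which.max(abs(out$value))
  attr(out, "peak_value") <- out$value[ipk]
  attr(out, "peak_lag") <- out$lag[ipk]
  class(out) <- c("ivl_correlogram", class(out))
  out
}

#' Peak of a correlogram
#' @param x An `ivl_correlogram`.
#' @param ... Unused.
#' @return One-row tibble `peak_value`, `peak_lag`.
#' @export
glance.ivl_correlogram <- function(x, ...) {
  tibble::tibble(peak_value = attr(x, "peak_value"),
                 peak_lag = attr(x, "peak_lag"))
}

#' Paired in-vitro / IVL state comparison
#'
#' Runs the full state-comparison protocol on a model: for each seed, a
#' bombardment (IVL) simulation is run and its spike rate measured; the
#' matching in-vitro simulation is run at the holding current that the
#' F-I line maps to that rate; total per-channel charge and
#' current-versus-voltage correlograms are computed at every recording
#' site over the analysis window for both states.
#'
#' @param model An `ivl_neuron_model`.
#' @param ivl_params Input parameters of the chosen IVL state.
#' @param cfg An `ivl_input_config`.
#' @param n_seeds Number of paired runs.
#' @param duration Simulation duration (ms).
#' @param discard Transient discarded from analyses (ms).
#' @param seed Master seed.
#' @param weights Weight map for bombardment synapses.
#' @param fi An `ivl_fi_line`; calibrated from the model when NULL.
#' @param xcorr Compute current-vs-voltage correlograms (slower).
#' @param max_lag Correlogram lag range (ms).
#' @param record_dt Recording interval (ms).
#' @return A list of class `ivl_state_comparison`: `rates` (per-seed
#'   f_IVL, I_hold, in-vitro rate), `charges` (per seed x state x site x
#'   channel total charge), `xcorr` (per seed x state x site x channel
#'   correlogram peaks; seeds 1..min(5, n_seeds)), `fi`.
#' @export
compare_states <- function(model, ivl_params, cfg, n_seeds = 10,
                           duration = 10000, discard = 1000, seed = 1,
                           weights = 1e-4, fi = NULL, xcorr = TRUE,
                           max_lag = 20, record_dt = 0.05) {
  if (is.null(fi)) fi <- fi_line(model, duration = duration,
                                 discard = discard)
  seeds <- derive_seeds(seed, n_seeds)
  rates <- list(); charges <- list(); xcs <- list()
  for (k in seq_len(n_seeds)) {
    bomb <- generate_trains(ivl_params, cfg, model, duration, seeds[k],
                            weights = weights)
    pr <- add_bombardment(stim_protocol(duration, record_dt = record_dt),
                          bomb)
    tr_ivl <- simulate_cell(model, pr)
    sel <- tr_ivl$time >= discard
    f_ivl <- detect_spikes(tr_ivl$v[sel, "S"], tr_ivl$time[sel])$rate
    i_hold <- holding_current(f_ivl, fi)
    feasible <- f_ivl > fi$b
    f_vitro <- NA_real_
    tr_vitro <- NULL
    if (feasible) {
      pv <- add_current_step(stim_protocol(duration,
                                           record_dt = record_dt),
                             i_hold, 0, Inf, site = "S")
      tr_vitro <- simulate_cell(model, pv)
      f_vitro <- detect_spikes(tr_vitro$v[sel, "S"],
                               tr_vitro$time[sel])$rate
    }
    rates[[k]] <- tibble::tibble(
      replicate = k, seed = seeds[k], f_ivl = f_ivl, i_hold = i_hold,
      feasible = feasible, f_vitro = f_vitro
    )
    for (state in c("ivl", "vitro")) {
      tr <- if (state == "ivl") tr_ivl else tr_vitro
      if (is.null(tr)) next
      tt <- tr$time[sel]
      for (site in tr$sites) {
        cur <- lapply(tr$currents, function(m) m[sel, site])
        ch_tb <- tibble::tibble(
          replicate = k, state = state, site = site,
          channel = names(cur),
          charge = vapply(cur, total_charge, numeric(1), time = tt)
        )
        charges[[length(charges) + 1]] <- ch_tb
        if (xcorr && k <= min(5, n_seeds)) {
          v <- tr$v[sel, site]
          adj <- polarity_adjust(cur)
          xc <- purrr::map_dfr(names(adj), function(nm) {
            if (stats::sd(adj[[nm]]) == 0 || stats::sd(v) == 0) {
              return(tibble::tibble(channel = nm,
                                    peak_value = NA_real_,
                                    peak_lag = NA_real_))
            }
            cg <- normalized_xcorr(adj[[nm]], v, dt = tr$dt,
                                   max_lag = max_lag)
            tibble::tibble(channel = nm,
                           peak_value = attr(cg, "peak_value"),
                           peak_lag = attr(cg, "peak_lag"))
          })
          xcs[[length(xcs) + 1]] <- dplyr::bind_cols(
            tibble::tibble(replicate = k, state = state, site = site),
            xc
          )
        }
      }
    }
  }
  structure(
    list(rates = dplyr::bind_rows(rates),
         charges = dplyr::bind_rows(charges),
         xcorr = dplyr::bind_rows(xcs),
         fi = fi, params = ivl_params, n_seeds = n_seeds, seed = seed),
    class = "ivl_state_comparison"
  )
}

#' @export
print.ivl_state_comparison <- function(x, ...) {
  cat("<ivl_state_comparison> ", x$n_seeds, " paired runs; mean f_IVL ",
      format(round(mean(x$rates$f_ivl), 2)), " Hz, mean in-vitro rate ",
      format(round(mean(x$rates$f_vitro, na.rm = TRUE), 2)), " Hz\n",
      sep = "")
  invisible(x)
}

#' Tidy the per-seed charge table of a state comparison
#' @param x An `ivl_state_comparison`.
#' @param ... Unused.
#' @export
tidy.ivl_state_comparison <- function(x, ...) x$charges

#' One-row summary of a state comparison
#' @param x An `ivl_state_comparison`.
#' @param ... Unused.
#' @export
glance.ivl_state_comparison <- function(x, ...) {
  tibble::tibble(
    n_seeds = x$n_seeds,
    mean_f_ivl = mean(x$rates$f_ivl),
    mean_f_vitro = mean(x$rates$f_vitro, na.rm = TRUE),
    n_feasible = sum(x$rates$feasible)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
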