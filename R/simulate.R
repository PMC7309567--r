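#' Build a neuron model from a morphology and a channel set
#'
#' @param morph An `ivl_morphology`.
#' @param channels An `ivl_channel_set`.
#' @param v_init Initial membrane potential (mV); defaults to the leak
#'   reversal so the passive subsystem starts at rest.
#' @return An object of class `ivl_neuron_model`.
#' @export
neuron_model <- function(morph, channels, v_init = NULL) {
  stopifnot(inherits(morph, "ivl_morphology"),
            inherits(channels, "ivl_channel_set"))
  if (is.null(v_init)) v_init <- channels$gating$leak$E
  structure(list(morph = morph, channels = channels, v_init = v_init),
            class = "ivl_neuron_model")
}

#' @export
print.ivl_neuron_model <- function(x, ...) {
  cat("<ivl_neuron_model>\n")
  print(x$morph)
  print(x$channels)
  invisible(x)
}

resolve_site <- function(morph, site) {
  if (is.character(site)) {
    i <- morph$sites[site]
    if (any(is.na(i))) stop("unknown recording site: ", site, call. = FALSE)
    unname(i)
  } else {
    as.integer(site)
  }
}

#' Create a stimulation/recording protocol
#'
#' @param duration Simulation duration (ms).
#' @param dt Integration step (ms).
#' @param record_dt Recording interval (ms); must be a multiple of `dt`.
#' @param theta Implicitness of the voltage update: 0.5 = Crank-Nicolson
#'   (default), 1 = backward Euler.
#' @return An object of class `ivl_protocol` that current steps, voltage
#'   clamps and synaptic event schedules can be attached to.
#' @export
stim_protocol <- function(duration, dt = 0.025, record_dt = dt, theta = 0.5) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  stride <- round(record_dt / dt)
  if (stride < 1 || abs(stride * dt - record_dt) > 1e-9) {
    stop("record_dt must be a positive multiple of dt", call. = FALSE)
  }
  structure(
    list(duration = duration, dt = dt, record_stride = as.integer(stride),
         theta = theta, iclamp = list(), vclamp = NULL, synapses = list()),
    class = "ivl_protocol"
  )
}

#' Attach a somatic/dendritic current step to a protocol
#'
#' @param protocol An `ivl_protocol`.
#' @param amp Step amplitude (pA).
#' @param onset,offset Step window (ms).
#' @param site Recording-site name (resolved against the morphology at
#'   simulation time) or compartment index.
#' @export
add_current_step <- function(protocol, amp, onset = 0, offset = Inf,
                             site = "S") {
  protocol$iclamp <- c(protocol$iclamp,
                       list(list(site = site, onset = onset,
                                 offset = offset, amp = amp)))
  protocol
}

#' Attach an ideal voltage clamp to a protocol
#'
#' The clamped compartment is held at `level`; the electrode (clamp)
#' current needed to hold it there is recorded in pA.
#'
#' @inheritParams add_current_step
#' @param level Holding potential (mV).
#' @export
add_voltage_clamp <- function(protocol, level, site = "S",
                              onset = 0, offset = Inf) {
  if (!is.null(protocol$vclamp)) {
    stop("protocol already carries a voltage clamp", call. = FALSE)
  }
  protocol$vclamp <- list(site = site, level = level,
                          onset = onset, offset = offset)
  protocol
}

#' Attach dual-exponential synaptic events to a protocol
#'
#' Each call adds one synapse-kinetics group at one compartment; events in
#' a group superpose linearly on shared rise/decay state variables.  The
#' event weights are peak conductances (uS): the dual-exponential waveform
#' is normalized so a single event of weight w reaches peak conductance w.
#'
#' @inheritParams add_current_step
#' @param tau_r,tau_d Rise and decay time constants (ms), `tau_d > tau_r`.
#' @param e_rev Synaptic reversal potential (mV).
#' @param times Event times (ms).
#' @param weights Event peak conductances (uS); recycled to `length(times)`.
#' @export
add_synapse_events <- function(protocol, site, tau_r, tau_d, e_rev,
                               times, weights) {
  if (tau_d <= tau_r || tau_r <= 0) {
    stop("need tau_d > tau_r > 0", call. = FALSE)
  }
  o <- order(times)
  protocol$synapses <- c(protocol$synapses, list(list(
    site = site, tau_r = tau_r, tau_d = tau_d, E = e_rev,
    ev_t = as.numeric(times[o]),
    ev_w = rep_len(as.numeric(weights), length(times))[o]
  )))
  protocol
}

#' Simulate a neuron model under a protocol
#'
#' Solves the compartmental membrane equation on the morphology tree with
#' a semi-implicit theta scheme (Crank-Nicolson by default) and a
#' Hines-ordered direct solve, exponential-Euler gating updates and
#' analytically decayed dual-exponential synapses.  Voltage and every
#' channel current (plus excitatory/inhibitory synaptic currents) are
#' recorded at the morphology's named sites; under voltage clamp the clamp
#' current is recorded as well.
#'
#' @param model An `ivl_neuron_model`.
#' @param protocol An `ivl_protocol`.
#' @return An `ivl_trace_set`: time grid (ms), per-site voltage (mV) and
#'   per-channel membrane currents (pA, inward negative / outward
#'   positive).
#' @export
simulate_cell <- function(model, protocol) {
  morph <- model$morph
  cm <- morph$compartments
  parent0 <- ifelse(is.na(cm$parent), -1L, cm$parent - 1L)

  eng_model <- list(
    parent = as.integer(parent0),
    area = cm$area,
    cap = membrane_capacitance(morph),
    g_axial = axial_conductance(morph),
    channels = channels_to_engine(model$channels, morph),
    ca = model$channels$ca,
    v_init = model$v_init
  )

  ic <- lapply(protocol$iclamp, function(s) {
    list(comp = resolve_site(morph, s$site) - 1L, onset = s$onset,
         offset = min(s$offset, protocol$duration), amp = s$amp / 1e3)
  })
  vc <- protocol$vclamp
  if (!is.null(vc)) {
    ccomp <- resolve_site(morph, vc$site)
    for (s in ic) {
      if (s$comp == ccomp - 1L) {
        stop("voltage clamp and current injection at the same site",
             call. = FALSE)
      }
    }
    vc <- list(comp = ccomp - 1L, level = vc$level, onset = vc$onset,
               offset = min(vc$offset, protocol$duration + protocol$dt))
  }
  sg <- lapply(protocol$synapses, function(s) {
    list(comp = resolve_site(morph, s$site) - 1L,
         tau_r = s$tau_r, tau_d = s$tau_d, E = s$E,
         ev_t = s$ev_t,
         ev_w = s$ev_w * dual_exp_factor(s$tau_r, s$tau_d))
  })

  eng_protocol <- list(
    dt = protocol$dt, duration = protocol$duration,
    record_stride = protocol$record_stride,
    record_sites = unname(morph$sites) - 1L,
    theta = protocol$theta,
    iclamp = ic, vclamp = vc, syn_groups = sg
  )

  out <- .engine_run(eng_model, eng_protocol)

  v <- out$v
  colnames(v) <- names(morph$sites)
  currents <- lapply(out$currents, function(m) {
    colnames(m) <- names(morph$sites)
    m
  })
  structure(
    list(time = out$time, sites = names(morph$sites), v = v,
         currents = currents, iclamp = out$iclamp,
         dt = protocol$dt * protocol$record_stride),
    class = "ivl_trace_set"
  )
}

#' @export
print.ivl_trace_set <- function(x, ...) {
  cat("<ivl_trace_set> ", length(x$time), " samples (",
      format(max(x$time)), " ms at ", format(x$dt), " ms), sites: ",
      paste(x$sites, collapse = ", "), "\n", sep = "")
  cat("series: v, ", paste(names(x$currents), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Convert a trace set to a long tibble
#'
#' @param x An `ivl_trace_set`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `site`, `series`, `value`, where
#'   `series` is `"v"` or a channel/synapse current name.
#' @export
as_tibble.ivl_trace_set <- function(x, ...) {
  series <- c(list(v = x$v), x$currents)
  purrr::map_dfr(names(series), function(nm) {
    m <- series[[nm]]
    tibble::tibble(
      time = rep(x$time, ncol(m)),
      site = rep(colnames(m), each = nrow(m)),
      series = nm,
      value = as.vector(m)
    )
  })
}

#' Total inward and outward membrane current at a site
#'
#' At every sample, the total inward current is the sum of all
#' negative-valued channel and synaptic currents at the site, and the
#' total outward current the sum of the positive-valued ones.
#'
#' @param traces An `ivl_trace_set`.
#' @param site Site name.
#' @return A tibble with `time`, `inward` (pA, <= 0), `outward` (pA, >= 0).
#' @export
total_current <- function(traces, site = "S") {
  m <- vapply(traces$currents, function(x) x[, site], numeric(length(traces$time)))
  tibble::tibble(
    time = traces$time,
    inward = rowSums(pmin(m, 0)),
    outward = rowSums(pmax(m, 0))
  )
}

#' Write / read a trace set as full-precision CSV
#'
#' The on-disk format is a plain CSV with a `time` column and one
#' `site.series` column per recorded trace, written with 17 significant
#' digits so that the round trip is bit-exact.
#'
#' @param traces An `ivl_trace_set`.
#' @param path Output file path.
#' @export
write_traces <- function(traces, path) {
  series <- c(list(v = traces$v), traces$currents)
  cols <- list(time = traces$time)
  for (nm in names(series)) {
    m <- series[[nm]]
    for (s in colnames(m)) cols[[paste(s, nm, sep = ".")]] <- m[, s]
  }
  if (!is.null(traces$iclamp)) cols[["clamp.i"]] <- traces$iclamp
  df <- as.data.frame(cols, check.names = FALSE)
  txt <- vapply(df, function(x) sprintf("%.17g", x), character(nrow(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- setdiff(names(df), c("time", "clamp.i"))
  parts <- strsplit(nm, ".", fixed = TRUE)
  sites <- unique(vapply(parts, `[`, "", 1))
  series <- unique(vapply(parts, function(p) paste(p[-1], collapse = "."), ""))
  get_mat <- function(sr) {
    m <- vapply(sites, function(s) df[[paste(s, sr, sep = ".")]],
                numeric(nrow(df)))
    colnames(m) <- sites
    m
  }
  currents <- lapply(setdiff(series, "v"), get_mat)
  names(currents) <- setdiff(series, "v")
  structure(
    list(time = df$time, sites = sites, v = get_mat("v"),
         currents = currents,
         iclamp = if ("clamp.i" %in% names(df)) df[["clamp.i"]] else NULL,
         dt = if (nrow(df) > 1) df$time[2] - df$time[1] else NA_real_),
    class = "ivl_trace_set"
  )
}
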