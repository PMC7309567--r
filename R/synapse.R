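#' Dual-exponential synaptic conductance
#'
#' Conductance waveform of a two-state kinetic synapse,
#' `g(t) = weight * factor * (exp(-t/tau_d) - exp(-t/tau_r))`, where
#' `factor` normalizes the peak conductance to `weight` exactly.  Multiple
#' events superpose linearly.
#'
#' @param t Time since the presynaptic event (ms); `t >= 0` (values are
#'   vectorized).
#' @param tau_r,tau_d Rise and decay time constants (ms), `tau_d > tau_r > 0`.
#' @param weight Peak conductance (uS).
#' @return Conductance (uS) at each `t`.
#' @export
dual_exp_conductance <- function(t, tau_r, tau_d, weight = 1) {
  if (tau_d <= tau_r || tau_r <= 0) {
    stop("need tau_d > tau_r > 0", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  weight * dual_exp_factor(tau_r, tau_d) *
    (exp(-t / tau_d) - exp(-t / tau_r))
}

# peak-normalization factor: 1 / (exp(-tp/tau_d) - exp(-tp/tau_r))
dual_exp_factor <- function(tau_r, tau_d) {
  tp <- dual_exp_peak_time(tau_r, tau_d)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' Time of peak of the dual-exponential conductance
#'
#' Solves `dg/dt = 0`: `t_peak = tau_r * tau_d / (tau_d - tau_r) *
#' log(tau_d / tau_r)`.
#'
#' @inheritParams dual_exp_conductance
#' @export
dual_exp_peak_time <- function(tau_r, tau_d) {
  if (tau_d <= tau_r || tau_r <= 0) {
    stop("need tau_d > tau_r > 0", call. = FALSE)
  }
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Ohmic synaptic current
#'
#' `i = g * (V - E)`, outward positive.
#'
#' @param g Conductance (uS).
#' @param v Membrane potential (mV).
#' @param e_rev Reversal potential (mV).
#' @return Current in pA.
#' @export
synaptic_current <- function(g, v, e_rev) {
  1e3 * g * (v - e_rev)
}

#' Target postsynaptic current features for OLM cell inputs
#'
#' Packaged target EPSC/IPSC features for the four input classes: IS3
#' (interneuron-specific 3 cells), MS (GABAergic medial-septum
#' projections), BIS (bistratified cells) and PYR (local pyramidal
#' cells).  Amplitudes are per synapse; the BIS amplitude derives from a
#' compound IPSC of 67.6 pA divided across 4 synapses per connection, and
#' the PYR per-synapse amplitude is the adopted table value (-12.14 pA).
#' Inhibitory classes are fit under voltage clamp at 0 mV (reversal
#' -80 mV), the excitatory class at -60 mV (reversal 0 mV).
#'
#' @return A tibble with columns `class`, `amplitude` (pA), `rise` (ms),
#'   `decay` (ms), `hold` (mV), `e_rev` (mV).
#' @export
psc_targets <- function() {
  tibble::tribble(
    ~class, ~amplitude, ~rise, ~decay, ~hold, ~e_rev,
    "IS3",   13.9,       1.6,   12.0,    0,    -80,
    "MS",    23.0,       1.1,   12.1,    0,    -80,
    "BIS",   16.9,       1.35,  12.05,   0,    -80,
    "PYR",  -12.14,      2.4,   12.7,  -60,      0
  )
}

#' Per-synapse amplitude of a compound postsynaptic current
#'
#' Divides a compound (multi-synapse) PSC amplitude evenly across the
#' synapses of one connection.
#'
#' @param compound_amplitude Compound PSC amplitude (pA).
#' @param synapses_per_connection Number of synapses per connection.
#' @export
per_synapse_amplitude <- function(compound_amplitude,
                                  synapses_per_connection) {
  compound_amplitude / synapses_per_connection
}

measure_psc_amplitude <- function(model, site, weight, target,
                                  event_at = 50, window = 100) {
  pr <- stim_protocol(event_at + window, dt = 0.025) |>
    add_voltage_clamp(target$hold, site = "S") |>
    add_synapse_events(site, target$rise, target$decay, target$e_rev,
                       times = event_at, weights = weight)
  tr <- simulate_cell(model, pr)
  i <- tr$iclamp
  baseline <- i[max(which(tr$time < event_at))]
  max(abs(i[tr$time >= event_at] - baseline))
}

#' Fit a synaptic weight to a target PSC amplitude under voltage clamp
#'
#' Implements the incremental weight-fitting procedure: with all
#' voltage-gated channels blocked and the leak reversal set to the clamp
#' potential, the weight of a single synapse is increased in fixed steps
#' until the peak somatic clamp-current deflection reaches the target
#' amplitude (within `tol`, relative), stopping after at most `max_iter`
#' increments.  Unconverged fits are flagged and the last weight returned.
#'
#' Because the fit circuit (passive cable under ideal clamp) is linear in
#' the weight, `method = "linear"` computes the identical discretized
#' answer from a single probe simulation; `method = "incremental"` runs
#' the literal loop.
#'
#' @param model An `ivl_neuron_model` (its active channels are blocked
#'   internally for the fit).
#' @param site Synapse location: site name or compartment index.
#' @param target One row of [psc_targets()] (or a list with `amplitude`,
#'   `rise`, `decay`, `hold`, `e_rev`).
#' @param step Weight increment (uS).
#' @param tol Relative convergence tolerance on the amplitude.
#' @param max_iter Maximum number of increments.
#' @param method `"incremental"` or `"linear"` (see Details).
#' @return A one-row tibble: `weight` (uS), `achieved` (pA, magnitude),
#'   `iterations`, `converged`.
#' @export
optimize_weight <- function(model, site, target, step = 1e-5, tol = 0.02,
                            max_iter = 100, method = c("incremental",
                                                       "linear")) {
  method <- match.arg(method)
  target <- as.list(target)
  drive <- target$hold - target$e_rev
  if (target$amplitude != 0 && sign(target$amplitude) != sign(drive)) {
    stop("target amplitude sign inconsistent with (V_hold - E)",
         call. = FALSE)
  }
  goal <- abs(target$amplitude)
  if (goal == 0) {
    return(tibble::tibble(weight = 0, achieved = 0, iterations = 0L,
                          converged = TRUE))
  }
  fit_model <- neuron_model(
    model$morph,
    block_active_channels(model$channels, e_leak = target$hold),
    v_init = target$hold
  )

  if (method == "linear") {
    probe <- measure_psc_amplitude(fit_model, site, step, target)
    k <- max(1L, as.integer(ceiling((1 - tol) * goal / probe - 1e-9)))
    if (k > max_iter) {
      return(tibble::tibble(weight = max_iter * step,
                            achieved = probe * max_iter,
                            iterations = as.integer(max_iter),
                            converged = FALSE))
    }
    return(tibble::tibble(weight = k * step, achieved = probe * k,
                          iterations = k, converged = TRUE))
  }

  amp <- 0
  for (k in seq_len(max_iter)) {
    amp <- measure_psc_amplitude(fit_model, site, k * step, target)
    if (amp >= (1 - tol) * goal) {
      return(tibble::tibble(weight = k * step, achieved = amp,
                            iterations = k, converged = TRUE))
    }
  }
  tibble::tibble(weight = max_iter * step, achieved = amp,
                 iterations = as.integer(max_iter), converged = FALSE)
}

#' Fit synaptic weights for every dendritic compartment and input class
#'
#' Runs [optimize_weight()] for each (input class, dendritic compartment)
#' pair of a model, producing the per-compartment weight map used when
#' placing bombardment synapses.
#'
#' @inheritParams optimize_weight
#' @param targets Tibble of per-class targets, defaults to [psc_targets()].
#' @param compartments Compartment indices to fit (default: all dendritic
#'   compartments plus the soma).
#' @return A tibble `class`, `comp`, `weight`, `achieved`, `iterations`,
#'   `converged`.
#' @export
fit_weight_profile <- function(model, targets = psc_targets(),
                               compartments = NULL, step = 1e-5,
                               tol = 0.02, max_iter = 100,
                               method = "linear") {
  cm <- model$morph$compartments
  if (is.null(compartments)) {
    compartments <- cm$comp[cm$region %in% c("soma", "dend")]
  }
  purrr::map_dfr(seq_len(nrow(targets)), function(r) {
    tg <- targets[r, ]
    purrr::map_dfr(compartments, function(ci) {
      fit <- optimize_weight(model, ci, tg, step = step, tol = tol,
                             max_iter = max_iter, method = method)
      dplyr::mutate(fit, class = tg$class, comp = ci, .before = 1)
    })
  })
}
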