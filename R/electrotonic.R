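#' Electrotonic attenuation profile along the morphology
#'
#' Measures signal attenuation as the accumulated `log10(voltage
#' upstream / voltage downstream)` of a small steady subthreshold
#' deflection, per compartment along the path from the injection site.
#' `out_of_soma` injects at the soma and follows the signal outward;
#' `into_soma` injects at the most distal terminal and follows it toward
#' the soma.  The attenuation at the injection site is 0 by construction.
#'
#' @param model An `ivl_neuron_model`.
#' @param direction `"out_of_soma"` or `"into_soma"`.
#' @param deflection Target steady deflection at the injection site (mV);
#'   kept small so no spiking is recruited.
#' @param settle Settling time before the deflection (ms).
#' @param window Deflection duration (ms); the steady response is read at
#'   its end.
#' @return A tibble `comp`, `path_distance`, `deflection` (mV),
#'   `attenuation` (log10 units).
#' @export
electrotonic_profile <- function(model, direction = c("out_of_soma",
                                                      "into_soma"),
                                 deflection = 1, settle = 1500,
                                 window = 1500) {
  direction <- match.arg(direction)
  cm <- model$morph$compartments
  inj <- if (direction == "out_of_soma") {
    1L
  } else {
    cm$comp[which.max(cm$path_distance)]
  }

  # record every compartment
  morph_all <- model$morph
  morph_all$sites <- stats::setNames(cm$comp, paste0("c", cm$comp))
  model_all <- neuron_model(morph_all, model$channels, model$v_init)

  run <- function(amp) {
    pr <- stim_protocol(settle + window, dt = 0.025, record_dt = 0.5)
    pr <- add_current_step(pr, amp, settle, Inf, site = inj)
    simulate_cell(model_all, pr)
  }

  # rest, then scale a probe current to the requested deflection
  tr0 <- run(0)
  v_rest <- tr0$v[nrow(tr0$v), ]
  probe <- 1  # pA
  tr1 <- run(probe)
  dv_probe <- tr1$v[nrow(tr1$v), inj] - v_rest[inj]
  amp <- probe * deflection / abs(dv_probe)
  tr <- run(amp)
  if (max(tr$v[, inj]) > -20) {
    stop("deflection recruited spiking; use a smaller amplitude",
         call. = FALSE)
  }
  dv <- tr$v[nrow(tr$v), ] - v_rest
  dv_inj <- dv[inj]
  # accumulated log attenuation telescopes to log10(dV_inj / dV_i)
  atten <- log10(abs(dv_inj) / pmax(abs(dv), .Machine$double.eps))
  atten[inj] <- 0
  tibble::tibble(
    comp = cm$comp,
    path_distance = cm$path_distance,
    deflection = unname(dv),
    attenuation = unname(atten)
  )
}

#' Rheobase of a model
#'
#' Minimal somatic holding current eliciting at least one spike within
#' the protocol window, found by bisection.
#'
#' @param model An `ivl_neuron_model`.
#' @param search_range Length-2 bracket (pA); must contain the threshold
#'   (no spike at the lower end, at least one at the upper end).
#' @param duration Protocol window (ms).
#' @param tol Bisection tolerance (pA).
#' @return Rheobase (pA).
#' @export
rheobase <- function(model, search_range = c(0, 500), duration = 1000,
                     tol = 1) {
  spikes_at <- function(amp) {
    pr <- stim_protocol(duration, record_dt = 0.05)
    pr <- add_current_step(pr, amp, 0, Inf, site = "S")
    tr <- simulate_cell(model, pr)
    detect_spikes(tr$v[, "S"], tr$time)$n > 0
  }
  lo <- search_range[1]
  hi <- search_range[2]
  if (spikes_at(lo)) {
    stop("lower end of search range already elicits spiking",
         call. = FALSE)
  }
  if (!spikes_at(hi)) {
    stop("no spike at the search-range maximum; range does not bracket ",
         "the threshold", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
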