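# shared fixtures, built in code; heavier ones memoized per test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

empty_densities <- function() {
  tibble::tibble(channel = character(), region = character(),
                 density = numeric())
}

# single passive compartment: g_leak 1 pS/um^2, soma 10 x 10 um
passive_soma_model <- function(g_leak = 1, e_leak = -70) {
  m <- build_chain_morphology(1, 10, 0, soma_length = 10)
  neuron_model(m, channel_set(empty_densities(), e_leak = e_leak,
                              g_leak = g_leak))
}

# uniform passive cable (soma matched to cable diameter so it is just
# another segment), for analytic cable-theory checks
passive_cable_model <- function(n_dend = 40, diam = 2, len = 400,
                                g_leak = 1, e_leak = -70,
                                axial_resistivity = 150) {
  m <- build_chain_morphology(
    2, c(diam, diam), c(0, len),
    soma_length = len / n_dend, n_dend = n_dend,
    axial_resistivity = axial_resistivity
  )
  neuron_model(m, channel_set(empty_densities(), e_leak = e_leak,
                              g_leak = g_leak))
}

ref_cell <- function(cell_id = 1) {
  memo(paste0("ref_cell_", cell_id), make_reference_cell(cell_id))
}

# synthetic voltage trace with triangular spikes at given times
synth_spike_trace <- function(spike_times, duration, dt = 0.1,
                              baseline = -70, peak = -5, width = 1) {
  time <- seq(0, duration, by = dt)
  v <- rep(baseline, length(time))
  half_n <- max(1L, round(width / 2 / dt))
  n <- length(time)
  for (tt in spike_times) {
    i0 <- round(tt / dt) + 1L
    sel <- max(1L, i0 - half_n):min(n, i0 + half_n)
    tri <- peak - (peak - baseline) * abs(sel - i0) / half_n
    v[sel] <- pmax(v[sel], tri)
  }
  list(time = time, v = v)
}

# scripted scorer for search tests: returns prescribed scores per
# parameter set (default score for unknown sets)
scripted_scorer <- function(table, default = 0) {
  function(params, seed) {
    key <- paste(params$n_exc, params$n_inh, params$f_exc, params$f_inh)
    score <- if (!is.null(table[[key]])) table[[key]] else default
    structure(
      list(depolarized = score >= 1, fluctuating = score >= 2,
           irregular = score >= 3, rate_band = score >= 4,
           amp_penalty = score < 0,
           vm_mean = -65, vm_sd = 3, isi_cv = 1, rate = 10,
           amp_mean = if (score < 0) 30 else 50,
           score = as.integer(score)),
      class = "ivl_score"
    )
  }
}
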