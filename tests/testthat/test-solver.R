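test_that("passive RC step matches the closed form within 1%", {
  mod <- passive_soma_model()
  area <- mod$morph$compartments$area
  g <- 1e-6 * area                 # uS
  rin <- 1 / g                     # Mohm
  tau <- area * 1e-5 / g           # ms
  amp <- 2                         # pA
  pr <- add_current_step(stim_protocol(5 * tau + 5, dt = 0.025), amp,
                         onset = 0, site = "S")
  tr <- simulate_cell(mod, pr)
  for (tq in c(tau, 5 * tau)) {
    i <- which.min(abs(tr$time - tq))
    expected <- -70 + amp * rin * 1e-3 * (1 - exp(-tr$time[i] / tau))
    defl <- tr$v[i, "S"] + 70
    expect_lt(abs(defl - (expected + 70)) / (expected + 70), 0.01)
  }
})

test_that("input resistance and membrane time constant are reproduced", {
  mod <- passive_soma_model()
  area <- mod$morph$compartments$area
  g <- 1e-6 * area
  rin_theory <- 1 / g
  tau_theory <- area * 1e-5 / g
  amp <- 2
  pr <- add_current_step(stim_protocol(200, dt = 0.01), amp, onset = 0,
                         site = "S")
  tr <- simulate_cell(mod, pr)
  defl <- tr$v[, "S"] + 70
  rin_meas <- defl[length(defl)] / (amp * 1e-3)
  expect_lt(abs(rin_meas - rin_theory) / rin_theory, 0.01)
  # tau: time to reach 1 - 1/e of the steady deflection
  i63 <- which(defl >= (1 - exp(-1)) * defl[length(defl)])[1]
  expect_lt(abs(tr$time[i63] - tau_theory) / tau_theory, 0.01)
})

test_that("zero conductance and no stimulus leave V constant", {
  m <- build_chain_morphology(2, c(10, 2), c(0, 100), n_dend = 5)
  ch <- channel_set(empty_densities(), e_leak = -65, g_leak = 0)
  tr <- simulate_cell(neuron_model(m, ch, v_init = -55),
                      stim_protocol(100))
  expect_equal(max(abs(tr$v - (-55))), 0)
})

test_that("halving dt changes active-model traces only marginally", {
  mod <- ref_cell(1)
  run_at <- function(dt) {
    pr <- add_current_step(stim_protocol(300, dt = dt, record_dt = 0.1),
                           mod$rheobase_bracket[2] * 0.4, 0, Inf, "S")
    simulate_cell(mod, pr)$v[, "S"]
  }
  v1 <- run_at(0.025)
  v2 <- run_at(0.0125)
  # subthreshold window (before first spike) converges tightly
  expect_lt(max(abs(v1[1:500] - v2[1:500])), 0.05)
})

test_that("charge is conserved at every sample of a passive simulation", {
  mod <- passive_soma_model()
  cap <- mod$morph$compartments$area * 1e-5   # nF
  amp <- 5
  pr <- add_current_step(stim_protocol(50, dt = 0.025), amp, onset = 0,
                         site = "S")
  tr <- simulate_cell(mod, pr)
  v <- tr$v[, "S"]
  ileak <- tr$currents$leak[, "S"]            # pA
  dt <- tr$dt
  # Crank-Nicolson balance: C dV/dt + mean(I_ion) = I_inj at midpoints
  icap <- cap * diff(v) / dt * 1e3            # pA
  imid <- (ileak[-1] + ileak[-length(ileak)]) / 2
  residual <- icap + imid - amp
  expect_lt(max(abs(residual)) / amp, 1e-6)
})

test_that("gating variables stay in [0, 1] and spikes stay finite", {
  mod <- ref_cell(1)
  pr <- add_current_step(stim_protocol(500, record_dt = 0.05), 250, 0,
                         Inf, "S")
  tr <- simulate_cell(mod, pr)     # engine aborts on gating escape
  expect_true(all(is.finite(tr$v)))
  expect_gt(max(tr$v[, "S"]), -20) # it actually spiked
})

test_that("voltage clamp at a synapse's reversal yields zero synaptic current", {
  mod <- passive_soma_model(e_leak = -80)
  pr <- stim_protocol(100, dt = 0.025)
  pr <- add_voltage_clamp(pr, level = -80, site = "S")
  pr <- add_synapse_events(pr, "S", tau_r = 1.6, tau_d = 12, e_rev = -80,
                           times = 20, weights = 1e-3)
  tr <- simulate_cell(mod, pr)
  expect_lt(max(abs(tr$currents$syn_inh[, "S"])), 1e-9)
})

test_that("clamp and current injection at the same site are rejected", {
  mod <- passive_soma_model()
  pr <- add_current_step(stim_protocol(50), 10, site = "S")
  pr <- add_voltage_clamp(pr, -60, site = "S")
  expect_error(simulate_cell(mod, pr), "same site")
})

test_that("trace sets round-trip bit-exactly through CSV", {
  mod <- ref_cell(1)
  pr <- add_current_step(stim_protocol(50, record_dt = 0.1), 180, 0, Inf,
                         "S")
  tr <- simulate_cell(mod, pr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(tr, path)
  tr2 <- read_traces(path)
  expect_identical(tr2$v[, "S"], unname(tr$v[, "S"]))
  expect_identical(tr2$currents$NaT[, "D4"], unname(tr$currents$NaT[, "D4"]))
  expect_identical(sort(names(tr2$currents)), sort(names(tr$currents)))
})

test_that("total inward/outward currents split by sign and sum exactly", {
  mod <- ref_cell(1)
  pr <- add_current_step(stim_protocol(100, record_dt = 0.1), 180, 0, Inf,
                         "S")
  tr <- simulate_cell(mod, pr)
  tc <- total_current(tr, "S")
  expect_true(all(tc$inward <= 0))
  expect_true(all(tc$outward >= 0))
  m <- sapply(tr$currents, function(x) x[, "S"])
  expect_equal(tc$inward + tc$outward, rowSums(m))
})
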