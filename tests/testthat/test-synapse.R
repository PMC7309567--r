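test_that("dual-exponential conductance is peak-normalized to the weight", {
  tg <- psc_targets()
  for (r in seq_len(nrow(tg))) {
    tr <- tg$rise[r]; td <- tg$decay[r]
    tp <- dual_exp_peak_time(tr, td)
    expect_equal(tp, tr * td / (td - tr) * log(td / tr))
    w <- 3.7e-4
    gpk <- dual_exp_conductance(tp, tr, td, w)
    expect_lt(abs(gpk - w) / w, 1e-9)
    # numerical max over a dense grid is bounded by the analytic peak
    g <- dual_exp_conductance(seq(0, 100, by = 0.001), tr, td, w)
    expect_lte(max(g), w * (1 + 1e-9))
    expect_gte(max(g), w * (1 - 1e-6))
  }
})

test_that("dual-exponential limits and error contract", {
  expect_equal(dual_exp_conductance(0, 1.6, 12), 0)
  expect_lt(dual_exp_conductance(1000, 1.6, 12), 1e-12)
  expect_error(dual_exp_conductance(1, 12, 1.6), "tau_d > tau_r")
  expect_error(dual_exp_conductance(-1, 1.6, 12), ">= 0")
})

test_that("events superpose linearly in the engine", {
  mod <- passive_soma_model(e_leak = -60)
  run <- function(times) {
    pr <- stim_protocol(120, dt = 0.025)
    pr <- add_voltage_clamp(pr, -60, "S")
    pr <- add_synapse_events(pr, "S", 1.6, 12, 0, times,
                             rep(1e-4, length(times)))
    simulate_cell(mod, pr)$currents$syn_exc[, "S"]
  }
  both <- run(c(20, 30))
  a <- run(20)
  b <- run(30)
  expect_equal(both, a + b, tolerance = 1e-9)
})

test_that("ohmic synaptic current arithmetic", {
  expect_equal(synaptic_current(0.17375e-3, 0, -80), 13.9)
  expect_equal(synaptic_current(1, -55, -55), 0)
  expect_equal(synaptic_current(0, 10, -80), 0)
})

test_that("ideal-clamp weight fit recovers target/(Vhold - E) within a step", {
  mod <- passive_soma_model()
  tg <- psc_targets()[psc_targets()$class == "IS3", ]
  step <- 1e-5
  fit <- optimize_weight(mod, "S", tg, step = step)
  ideal <- abs(tg$amplitude) / (abs(tg$hold - tg$e_rev) * 1e3)
  expect_true(fit$converged)
  expect_lt(abs(fit$weight - ideal), step + 1e-12)
  # incremental and linear methods agree exactly
  fit2 <- optimize_weight(mod, "S", tg, step = step,
                          method = "incremental")
  expect_equal(fit$weight, fit2$weight)
  expect_equal(fit$iterations, fit2$iterations)
})

test_that("weight fit edge cases: zero target, cap, sign mismatch", {
  mod <- passive_soma_model()
  tg0 <- list(class = "IS3", amplitude = 0, rise = 1.6, decay = 12,
              hold = 0, e_rev = -80)
  fit0 <- optimize_weight(mod, "S", tg0)
  expect_equal(fit0$weight, 0)
  expect_equal(fit0$iterations, 0L)
  expect_true(fit0$converged)
  # a tiny step cannot reach the target within the iteration cap
  tg <- psc_targets()[1, ]
  fit_cap <- optimize_weight(mod, "S", tg, step = 1e-8)
  expect_false(fit_cap$converged)
  expect_equal(fit_cap$iterations, 100L)
  tg_bad <- list(class = "X", amplitude = -5, rise = 1.6, decay = 12,
                 hold = 0, e_rev = -80)
  expect_error(optimize_weight(mod, "S", tg_bad), "sign")
})

test_that("achieved amplitude is monotone in weight under fixed clamp", {
  mod <- ref_cell(1)
  fitmod <- neuron_model(mod$morph,
                         block_active_channels(mod$channels, e_leak = 0),
                         v_init = 0)
  tg <- psc_targets()[1, ]
  amps <- vapply(c(1e-4, 2e-4, 4e-4, 8e-4), function(w) {
    olmivl:::measure_psc_amplitude(fitmod, "D3", w, tg)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("fitted weights grow with distance from soma on a thin cable", {
  mod <- passive_cable_model(n_dend = 10, diam = 0.6, len = 600)
  prof <- fit_weight_profile(
    mod, targets = psc_targets()[psc_targets()$class == "IS3", ],
    compartments = c(2, 5, 8, 11))
  expect_true(all(diff(prof$weight) >= 0))
  expect_gt(prof$weight[4], prof$weight[1])
})
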