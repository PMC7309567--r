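test_that("spike detection on flat and regular synthetic traces", {
  time <- seq(0, 1000, by = 0.1)
  flat <- rep(-70, length(time))
  s <- detect_spikes(flat, time)
  expect_equal(s$n, 0)
  expect_equal(s$rate, 0)
  # 10 identical triangular spikes over 1 s: rate 10 Hz, regular
  tr <- synth_spike_trace(seq(50, 950, by = 100), 1000, dt = 0.1,
                          peak = -25)  # 45 mV above baseline
  s <- detect_spikes(tr$v, tr$time, threshold = -30)
  expect_equal(s$n, 10)
  expect_equal(s$rate, 10, tolerance = 0.01)
  expect_equal(s$isi_cv, 0, tolerance = 1e-6)
  expect_equal(mean(s$amplitudes), 45, tolerance = 0.02)
  expect_error(detect_spikes(c(1, NA, 3), c(0, 1, 2)), "non-finite")
})

test_that("Poisson-timed spikes recover ISI CV near 1", {
  ev <- generate_renewal_train(5, 1, 2.1e5, seed = 4)
  ev <- ev[seq_len(min(1001, length(ev)))]
  tr <- synth_spike_trace(ev, max(ev) + 10, dt = 0.1)
  s <- detect_spikes(tr$v, tr$time, refractory = 1)
  expect_equal(s$isi_cv, 1, tolerance = 0.05)
})

test_that("subthreshold statistics with and without exclusion windows", {
  time <- seq(0, 1000, by = 0.1)
  st <- subthreshold_stats(rep(-65, length(time)), time)
  expect_equal(st$mean, -65)
  expect_equal(st$sd, 0)
  # sine of amplitude a: SD = a/sqrt(2)
  a <- 3
  v <- -65 + a * sin(2 * pi * time / 50)
  st <- subthreshold_stats(v, time)
  expect_equal(st$sd, a / sqrt(2), tolerance = 0.01)
  # statistics are invariant to spike peak heights (excluded)
  tr1 <- synth_spike_trace(c(200, 500, 800), 1000, peak = -5)
  tr2 <- synth_spike_trace(c(200, 500, 800), 1000, peak = 40)
  s1 <- subthreshold_stats(tr1$v, tr1$time, c(200, 500, 800))
  s2 <- subthreshold_stats(tr2$v, tr2$time, c(200, 500, 800))
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  expect_error(subthreshold_stats(v, time, seq(0, 1000, 5),
                                  exclusion_halfwidth = 10),
               "every sample")
})

test_that("IVL metric arithmetic matches the scoring rule", {
  mk_sub <- function(mean, sd) list(mean = mean, sd = sd)
  mk_spk <- function(rate, cv, amp, n = 100) {
    list(rate = rate, isi_cv = cv, amplitudes = rep(amp, n), n = n)
  }
  expect_equal(ivl_score(mk_sub(-65, 3), mk_spk(10, 1, 50))$score, 4)
  expect_equal(ivl_score(mk_sub(-65, 3), mk_spk(10, 1, 35))$score, -1)
  expect_equal(ivl_score(mk_sub(-75, 1), mk_spk(1, 0.5, 50))$score, 0)
})

test_that("metric boundaries are strict inequalities", {
  th <- ivl_thresholds()
  at_thresholds <- ivl_score(
    list(mean = th$vm_mean, sd = th$vm_sd),
    list(rate = th$rate_lo, isi_cv = th$isi_cv,
         amplitudes = rep(50, 10), n = 10))
  expect_equal(at_thresholds$score, 0)
  rate_hi <- ivl_score(list(mean = -60, sd = 3),
                       list(rate = th$rate_hi, isi_cv = 1,
                            amplitudes = rep(50, 10), n = 10))
  expect_false(rate_hi$rate_band)
})

test_that("score is monotone in fluctuation and amplitude penalty is -5", {
  spk <- list(rate = 10, isi_cv = 1, amplitudes = rep(50, 10), n = 10)
  scores <- vapply(c(1, 2.2, 2.3, 5), function(sd) {
    ivl_score(list(mean = -65, sd = sd), spk)$score
  }, integer(1))
  expect_true(all(diff(scores) >= 0))
  spk_blocked <- spk
  spk_blocked$amplitudes <- rep(39.9, 10)
  expect_equal(ivl_score(list(mean = -65, sd = 3), spk)$score -
                 ivl_score(list(mean = -65, sd = 3), spk_blocked)$score,
               5L)
})

test_that("no spikes means no amplitude penalty", {
  sc <- ivl_score(list(mean = -60, sd = 3),
                  list(rate = 0, isi_cv = 0, amplitudes = numeric(0),
                       n = 0))
  expect_false(sc$amp_penalty)
  expect_equal(sc$score, 2L)   # depolarized + fluctuating only
})

test_that("consistency rule: at least half 4s and all others >= 3", {
  scripted <- function(scores) {
    i <- 0
    function(params, seed) {
      i <<- i + 1
      structure(list(depolarized = TRUE, fluctuating = TRUE,
                     irregular = TRUE, rate_band = TRUE,
                     amp_penalty = FALSE, vm_mean = -65, vm_sd = 3,
                     isi_cv = 1, rate = 10, amp_mean = 50,
                     score = as.integer(scores[i])),
                class = "ivl_score")
    }
  }
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  run <- function(scores) {
    consistency_check(mod, input_params(1, 1, 1, 1), cfg,
                      n_seeds = length(scores),
                      scorer = scripted(scores))$verdict
  }
  expect_true(run(c(4, 4, 4, 4, 4, 3, 3, 3, 3, 3)))
  expect_false(run(c(4, 4, 4, 4, 3, 3, 3, 3, 3, 2)))
  expect_true(run(rep(4, 10)))
  expect_false(run(c(4, 4, 4, 4, 3, 3, 3, 3, 3, 3)))
})

test_that("consistency seeds are derived deterministically and extend stably", {
  s10 <- olmivl:::derive_seeds(99, 10)
  s5 <- olmivl:::derive_seeds(99, 5)
  expect_identical(s10[1:5], s5)
  expect_identical(olmivl:::derive_seeds(99, 10), s10)
  expect_false(identical(olmivl:::derive_seeds(100, 10), s10))
})

test_that("statistics stage recovers gamma-renewal CV across shapes", {
  # shape k gamma renewal => CV 1/sqrt(k); n = 1000 ISIs
  for (cv in c(0.5, 1.0, 1.5)) {
    ev <- generate_renewal_train(5, cv, 2.6e5, seed = 8)
    ev <- ev[seq_len(min(1001, length(ev)))]
    st <- spike_train_stats(ev)
    expect_equal(st$isi_cv, cv, tolerance = 0.05)
  }
})

test_that("voltage-level detection preserves regular-train statistics", {
  # a sub-Poisson train has no sub-millisecond ISIs, so the detector
  # recovers the same statistics as the event times
  ev <- generate_renewal_train(5, 0.5, 2.6e5, seed = 8)
  ev <- ev[seq_len(min(1001, length(ev)))]
  tr <- synth_spike_trace(ev, max(ev) + 10, dt = 0.1)
  s <- detect_spikes(tr$v, tr$time, refractory = 1)
  expect_equal(s$n, length(ev))
  expect_equal(s$isi_cv, spike_train_stats(ev)$isi_cv, tolerance = 0.01)
})
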