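test_that("inhibitory class allocation splits into thirds", {
  cfg1 <- cell_input_config(1)
  cfg2 <- cell_input_config(2)
  expect_equal(unname(allocate_inhibitory_classes(24, cfg1)), c(8, 8, 8))
  expect_equal(unname(allocate_inhibitory_classes(0, cfg1)), c(0, 0, 0))
  expect_equal(unname(allocate_inhibitory_classes(36, cfg2)),
               c(12, 12, 12))
  # remainders round-robin in class order
  expect_equal(unname(allocate_inhibitory_classes(25, cfg1)), c(9, 8, 8))
  expect_equal(unname(allocate_inhibitory_classes(26, cfg1)), c(9, 9, 8))
})

test_that("E/I balance and total input metrics", {
  p1 <- input_params(1268, 1254, 1.6, 8.7)
  p2 <- input_params(1503, 1532, 1.5, 8.0)
  expect_equal(ei_metric(p1), -8881.0)
  expect_equal(total_input(p1), 12938.6)
  expect_equal(ei_metric(p2), -10001.5)
  expect_equal(total_input(p2), 14510.5)
  p0 <- input_params(0, 0, 0, 0)
  expect_equal(ei_metric(p0), 0)
  expect_equal(total_input(p0), 0)
  # the documented cell-specific balance bands contain the reference sets
  expect_true(ei_metric(p1) >= -42685 && ei_metric(p1) <= -8785)
  expect_true(ei_metric(p2) >= -65700 && ei_metric(p2) <= -9990)
})

test_that("total/ei identities hold for random parameter sets", {
  set.seed(11)
  for (i in 1:20) {
    p <- input_params(sample(0:2000, 1), sample(0:2000, 1),
                      stats::runif(1, 0, 30), stats::runif(1, 0, 100))
    expect_equal(total_input(p) + ei_metric(p), 2 * p$n_exc * p$f_exc)
    expect_equal(total_input(p) - ei_metric(p), 2 * p$n_inh * p$f_inh)
  }
})

test_that("common-input grouping yields ceiling(N/size) trains per class", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  p <- input_params(1268, 1254, 1.6, 8.7)
  b <- generate_trains(p, cfg, mod, duration = 100, seed = 3)
  sy <- b$synapses
  n_exc_tr <- length(unique(sy$connection[sy$class == "PYR"]))
  expect_equal(n_exc_tr, ceiling(1268 / 7))
  classes <- allocate_inhibitory_classes(1254, cfg)
  for (cl in names(classes)) {
    expect_equal(length(unique(sy$connection[sy$class == cl])),
                 ceiling(classes[[cl]] / 8))
  }
  # group sizes equal synapses-per-connection except the last group
  sizes <- table(sy$connection[sy$class == "PYR"])
  expect_true(all(sizes <= 7))
  expect_equal(sum(sizes == 7), ceiling(1268 / 7) - 1)
  # placements restricted to dendrites
  dend <- mod$morph$compartments$comp[
    mod$morph$compartments$region == "dend"]
  expect_true(all(sy$comp %in% dend))
})

test_that("trains are seeded, reproducible, and empty at zero rate", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  p <- input_params(70, 48, 5, 10)
  b1 <- generate_trains(p, cfg, mod, duration = 1000, seed = 42)
  b2 <- generate_trains(p, cfg, mod, duration = 1000, seed = 42)
  expect_identical(b1$synapses, b2$synapses)
  expect_identical(b1$trains, b2$trains)
  b3 <- generate_trains(p, cfg, mod, duration = 1000, seed = 43)
  expect_false(identical(b1$trains, b3$trains))
  p0 <- input_params(70, 48, 0, 10)
  b0 <- generate_trains(p0, cfg, mod, duration = 1000, seed = 1)
  expect_equal(sum(lengths(b0$trains[
    unique(b0$synapses$connection[b0$synapses$class == "PYR"])])), 0)
})

test_that("empirical Poisson train rate is within 3 standard errors", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  # one excitatory connection at 10 Hz for 100 s
  p <- input_params(7, 0, 10, 0)
  b <- generate_trains(p, cfg, mod, duration = 1e5, seed = 9)
  n <- length(b$trains[[1]])
  expected <- 10 * 100
  se <- sqrt(expected)
  expect_lt(abs(n - expected), 3 * se)
})

test_that("synapse placement follows membrane area", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  counts <- NULL
  for (s in 1:30) {
    b <- generate_trains(input_params(200, 0, 1, 0), cfg, mod,
                         duration = 10, seed = s)
    counts <- c(counts, b$synapses$comp)
  }
  cm <- mod$morph$compartments
  dend <- cm[cm$region == "dend", ]
  obs <- tabulate(factor(counts, levels = dend$comp))
  expect_gt(stats::chisq.test(obs, p = dend$area / sum(dend$area))$p.value,
            0.01)
})

test_that("grid search has the right shape and is deterministic", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  grids <- list(n_exc = c(35, 70), n_inh = c(24, 48), f_exc = c(5, 10),
                f_inh = c(10, 20))
  scorer <- scripted_scorer(list(`70 24 10 10` = 4), default = 2)
  g1 <- grid_search(mod, cfg, grids, seed = 5, scorer = scorer)
  expect_equal(nrow(g1), 16)
  expect_true(all(g1$score %in% -5:4))
  expect_equal(g1$score[g1$n_exc == 70 & g1$n_inh == 24 &
                          g1$f_exc == 10 & g1$f_inh == 10], 4)
  g2 <- grid_search(mod, cfg, grids, seed = 5, scorer = scorer)
  expect_identical(g1, g2)
  expect_error(grid_search(mod, cfg, list(n_exc = 1e6, n_inh = 1,
                                          f_exc = 1, f_inh = 1)),
               "maxima")
})

test_that("zero-input grid point cannot reach a full IVL score", {
  mod <- ref_cell(1)
  sc <- ivl_state_score(mod, input_params(0, 0, 0, 0),
                        cell_input_config(1), duration = 2500, seed = 1,
                        weights = mod$weights)
  expect_false(sc$rate_band)
  expect_lte(sc$score, 3)
})

test_that("sparse search returns the minimal-total consistent set", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  # engineered surrogate: only (10, 10, 5, 5) is consistently IVL
  scorer <- scripted_scorer(list(`10 10 5 5` = 4), default = 2)
  res <- sparse_search(
    mod, cfg, ei_range = c(-100, 100),
    bounds = list(n_exc = c(9, 11), n_inh = c(9, 11),
                  f_exc = c(4, 6), f_inh = c(4, 6)),
    scorer = scorer, n_seeds = 10, seed = 2)
  expect_true(res$found)
  expect_equal(unlist(res$params),
               c(n_exc = 10, n_inh = 10, f_exc = 5, f_inh = 5))
  # exhaustive post-check: no admissible candidate with lower total input
  ei <- ei_metric(res$params)
  expect_true(ei >= -100 && ei <= 100)
  grd <- tidyr::expand_grid(n_exc = 9:11, n_inh = 9:11, f_exc = 4:6,
                            f_inh = 4:6)
  grd <- grd[ei_metric(grd) >= -100 & ei_metric(grd) <= 100, ]
  admissible <- grd[total_input(grd) < total_input(res$params), ]
  keys <- paste(admissible$n_exc, admissible$n_inh, admissible$f_exc,
                admissible$f_inh)
  expect_false("10 10 5 5" %in% keys[-(1:nrow(admissible))])
  # every lower-total candidate was visited and rejected
  expect_true(all(total_input(res$verdicts)[-res$n_candidates] <=
                    total_input(res$params)))
})

test_that("sparse search reports not-found when the band excludes all", {
  mod <- ref_cell(1)
  cfg <- cell_input_config(1)
  res <- sparse_search(
    mod, cfg, ei_range = c(1e7, 2e7),
    bounds = list(n_exc = c(0, 5), n_inh = c(0, 5), f_exc = c(0, 5),
                  f_inh = c(0, 5)),
    scorer = scripted_scorer(list(), default = 0))
  expect_false(res$found)
  expect_null(res$params)
})
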