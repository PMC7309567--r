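test_that("two-point F-I line and holding-current inversion", {
  fl <- fi_line_from_points(60, 8, 120, 14)
  expect_equal(fl$m, 0.1)
  expect_equal(fl$b, 2)
  expect_error(fi_line_from_points(60, 8, 120, 8), "identical rates")
  expect_equal(holding_current(12, fi_line_from_points(0, 2, 10, 3)),
               100)
  expect_equal(holding_current(2, fi_line_from_points(0, 2, 10, 3)), 0)
})

test_that("currentscape fractions reconstruct every channel current", {
  set.seed(21)
  n <- 500
  fake <- structure(
    list(time = seq(0, 49.9, by = 0.1), sites = "S",
         v = matrix(-60, n, 1, dimnames = list(NULL, "S")),
         currents = list(
           A = matrix(rnorm(n), n, 1, dimnames = list(NULL, "S")),
           B = matrix(rnorm(n), n, 1, dimnames = list(NULL, "S")),
           C = matrix(rnorm(n), n, 1, dimnames = list(NULL, "S"))),
         dt = 0.1),
    class = "ivl_trace_set")
  cs <- currentscape(fake, "S")
  wide <- tidyr::pivot_wider(cs, names_from = "pool",
                             values_from = c("current", "fraction",
                                             "pool_total"))
  # reconstruction: fraction * pool total equals the signed part, and the
  # two parts sum to the original current
  rec_in <- wide$fraction_inward * wide$pool_total_inward
  rec_out <- wide$fraction_outward * wide$pool_total_outward
  rec_in[is.na(rec_in)] <- 0
  rec_out[is.na(rec_out)] <- 0
  orig <- c(fake$currents$A[, 1], fake$currents$B[, 1],
            fake$currents$C[, 1])
  expect_lt(max(abs(rec_in + rec_out - orig)), 1e-9)
  # fractions sum to 1 wherever a pool is defined
  sums <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cs, !is.na(.data$fraction)),
                    .data$time, .data$pool),
    s = sum(.data$fraction))
  expect_lt(max(abs(sums$s - 1)), 1e-9)
  expect_true(all(cs$fraction >= -1e-12 | is.na(cs$fraction)))
})

test_that("single-channel and symmetric currentscape cases", {
  n <- 10
  one <- structure(
    list(time = 1:n, sites = "S",
         v = matrix(-60, n, 1, dimnames = list(NULL, "S")),
         currents = list(
           K = matrix(2, n, 1, dimnames = list(NULL, "S")),
           M = matrix(2, n, 1, dimnames = list(NULL, "S")),
           Na = matrix(0, n, 1, dimnames = list(NULL, "S"))),
         dt = 1),
    class = "ivl_trace_set")
  cs <- currentscape(one, "S")
  out <- dplyr::filter(cs, .data$pool == "outward")
  expect_equal(unique(out$fraction[out$channel %in% c("K", "M")]), 0.5)
  # zero inward pool: undefined fractions, marked NA
  inw <- dplyr::filter(cs, .data$pool == "inward")
  expect_true(all(is.na(inw$fraction)))
})

test_that("trapezoidal charge is exact for the expected cases", {
  t <- seq(0, 100, by = 0.5)
  expect_equal(total_charge(rep(3, length(t)), t), 300)
  one_period <- sin(2 * pi * t / 100)
  expect_lt(abs(total_charge(one_period, t)), 1e-9 * 100)
  ramp <- t / 100 * 5
  expect_equal(total_charge(ramp, t), 5 * 100 / 2)
})

test_that("polarity rules: inward channels negated, leak exempt", {
  x <- list(NaT = 1:5, leak = 1:5, Kdrf = 1:5, H = 1:5, CaT = 1:5,
            CaL = 1:5, syn_exc = 1:5, syn_inh = 1:5)
  adj <- polarity_adjust(x)
  expect_equal(adj$NaT, -(1:5))
  expect_equal(adj$H, -(1:5))
  expect_equal(adj$CaT, -(1:5))
  expect_equal(adj$CaL, -(1:5))
  expect_equal(adj$syn_exc, -(1:5))
  expect_equal(adj$leak, 1:5)
  expect_equal(adj$Kdrf, 1:5)
  expect_equal(adj$syn_inh, 1:5)
  # double application restores non-leak channels
  expect_equal(polarity_adjust(adj)$NaT, 1:5)
})

test_that("normalized cross-correlation matches a brute-force oracle", {
  set.seed(31)
  a1 <- rnorm(40)
  a2 <- rnorm(40)
  n <- length(a1)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  x1 <- (a1 - mean(a1)) / (psd(a1) * n)
  x2 <- (a2 - mean(a2)) / psd(a2)
  brute <- function(l) {
    s <- 0
    for (i in seq_len(n)) {
      j <- i - l
      if (j >= 1 && j <= n) s <- s + x1[i] * x2[j]
    }
    s
  }
  cg <- normalized_xcorr(a1, a2, dt = 1, max_lag = 10)
  for (l in c(-10, -3, 0, 5, 10)) {
    expect_equal(cg$value[cg$lag == l], brute(l), tolerance = 1e-9)
  }
})

test_that("autocorrelation is 1 at lag zero and bounded by 1", {
  set.seed(32)
  a <- rnorm(500)
  cg <- normalized_xcorr(a, a, dt = 0.5, max_lag = 10)
  expect_equal(cg$value[cg$lag == 0], 1, tolerance = 1e-9)
  expect_lte(max(abs(cg$value)), 1 + 1e-9)
  expect_equal(attr(cg, "peak_lag"), 0)
  expect_error(normalized_xcorr(rep(1, 100), a[1:100], 1), "variance")
})

test_that("a delayed copy peaks at minus the delay", {
  t <- seq(0, 200, by = 0.5)
  base <- sin(2 * pi * t / 40) * exp(-((t - 100) / 50)^2)
  delay <- 6                      # ms, 12 samples
  a2 <- c(rep(0, 12), base[1:(length(base) - 12)])
  cg <- normalized_xcorr(base, a2, dt = 0.5, max_lag = 20)
  expect_equal(attr(cg, "peak_lag"), -delay)
})

test_that("cross-correlation mirror symmetry", {
  set.seed(33)
  a <- rnorm(200)
  b <- as.numeric(stats::filter(rnorm(200), rep(0.3, 4), sides = 1))
  b[is.na(b)] <- 0
  ab <- normalized_xcorr(a, b, dt = 1, max_lag = 15)
  ba <- normalized_xcorr(b, a, dt = 1, max_lag = 15)
  expect_equal(ab$value, rev(ba$value), tolerance = 1e-9)
})

test_that("correlograms are invariant to pre-negated inward channels", {
  set.seed(34)
  v <- rnorm(300)
  nat <- rnorm(300)
  adj <- polarity_adjust(list(NaT = nat))$NaT
  c1 <- normalized_xcorr(adj, v, dt = 1, max_lag = 10)
  c2 <- normalized_xcorr(-nat, v, dt = 1, max_lag = 10)
  expect_equal(c1$value, c2$value)
})
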