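toy_series <- function(N, t = seq_along(N) - 1) data.frame(t = t, N = N)

test_that("replicate aggregation gives pointwise means and sds", {
  s <- data.frame(t = 0:4, N = c(3, 5, 2, 8, 1))
  agg <- aggregate_replicates(list(s, s))
  expect_equal(agg$mean_N, s$N)
  expect_equal(agg$sd_N, rep(0, 5))
  expect_identical(attr(agg, "n_replicates"), 2L)

  a <- data.frame(t = 0:2, N = rep(1, 3))
  b <- data.frame(t = 0:2, N = rep(3, 3))
  agg2 <- aggregate_replicates(list(a, b))
  expect_equal(agg2$mean_N, rep(2, 3))
  expect_equal(agg2$sd_N, rep(stats::sd(c(1, 3)), 3))

  expect_error(aggregate_replicates(list(a, data.frame(t = 0:3, N = 0:3))),
               "unequal lengths")
  expect_error(aggregate_replicates(list(a, data.frame(t = 0:2, X = 0:2))),
               "different columns")
})

test_that("aggregated Monte-Carlo replicates recover the generating rate", {
  set.seed(77)
  reps <- lapply(1:500, function(i) toy_series(rpois(50, 4)))
  agg <- aggregate_replicates(reps)
  grand_se <- sqrt(4 / (500 * 50))
  expect_lt(abs(mean(agg$mean_N) - 4), 3 * grand_se)
  expect_true(all(abs(agg$mean_N - 4) < 5 * sqrt(4 / 500)))
})

test_that("the stable window drops the leading burn-in", {
  long <- data.frame(t = 0:9999, N = 1)
  w <- stable_window(long, 0.5)
  expect_identical(nrow(w), 5000L)
  expect_identical(w$t[1], 5000L)
  expect_identical(stable_window(1:10, 0), 1:10)
  expect_identical(stable_window(1:10, 0.9), 10L)
  expect_error(stable_window(1:10, 1), "fraction")
  expect_error(stable_window(numeric(0), 0.5), "empty")
})

test_that("lagged cross-correlation recovers shifts and flags degeneracy", {
  x <- sin(2 * pi * (0:299) / 50)
  expect_equal(tlcc(x, x, 10)$r[11], 1)      # lag 0 of a series with itself

  k0 <- 7L
  y <- c(rep(0, k0), x)[1:300]               # y_t = x_{t-7}
  lc <- tlcc(x, y, 30)
  expect_identical(lc$lag[which.max(lc$r)], k0)
  expect_true(all(abs(lc$r[lc$defined]) <= 1 + 1e-12))

  flat <- tlcc(x, rep(2, 300), 5)
  expect_true(all(!flat$defined))
  expect_true(all(is.na(flat$r)))

  set.seed(5)
  a <- rnorm(120); b <- rnorm(120)
  expect_equal(tlcc(a, b, 15)$r, rev(tlcc(b, a, 15)$r), tolerance = 1e-12)

  expect_error(tlcc(a, b[-1], 5), "differ in length")
  expect_error(tlcc(a, b, 60), "too short")
})

test_that("the spectrum isolates sinusoidal components at their amplitudes", {
  t <- 0:499
  N <- 1000 + 100 * sin(2 * pi * t / 50)     # relative amplitude 0.1
  sp <- population_spectrum(N)
  peak <- which.max(sp$amplitude)
  expect_equal(sp$freq[peak], 1 / 50)
  expect_equal(sp$amplitude[peak], 0.1, tolerance = 1e-6)
  expect_lt(max(sp$amplitude[-peak]), 1e-9)
  expect_lt(sp$amplitude[sp$freq == 0], 1e-12)

  expect_true(all(population_spectrum(rep(7, 64))$amplitude < 1e-12))

  # two tones keep their amplitude ratio
  N2 <- 500 + 60 * sin(2 * pi * t[1:400] / 50) +
        20 * sin(2 * pi * t[1:400] / 20)
  sp2 <- population_spectrum(N2)
  a50 <- sp2$amplitude[which.min(abs(sp2$freq - 1 / 50))]
  a20 <- sp2$amplitude[which.min(abs(sp2$freq - 1 / 20))]
  expect_equal(a50 / a20, 3, tolerance = 1e-9)
  expect_equal(a50, 60 / 500, tolerance = 1e-9)
})

test_that("spectrum amplitudes satisfy Parseval's identity", {
  set.seed(31)
  for (n in c(64, 101)) {
    N <- 50 + rpois(n, 20)
    z <- (N - mean(N)) / mean(N)
    sp <- population_spectrum(N)
    amp <- sp$amplitude
    nyq <- (n %% 2 == 0)
    power <- sum(amp[-1]^2) / 2
    if (nyq) power <- power + amp[length(amp)]^2 / 2  # undo halving
    expect_equal(power, mean(z^2), tolerance = 1e-6)
  }
  expect_error(population_spectrum(rep(0, 32)), "mean is 0")
  expect_error(population_spectrum(1:4), "too short")
})

test_that("non-social runs never report cooperation", {
  p <- sim_params(R00 = 6, scenario = "non_social", N_init = 100,
                  n_groups = 20, T = 120)
  ser <- run_simulation(p, seed = 2)
  expect_true(all(ser$prop_coop == 0))
  expect_true(all(ser$mean_degree == 0))
  expect_true(all(ser$n_coop == 0L))
})

test_that("replicate-level synchrony and spectra exclude degenerate runs", {
  t <- 0:199   # stable window = 100 steps = 2 cycles of the period-50 tone
  env <- 4 + 2 * sin(2 * pi * t / 50)
  mk <- function(N) data.frame(t = t, R0 = env, N = N)
  good1 <- mk(round(300 + 150 * sin(2 * pi * t / 50)))
  good2 <- mk(round(280 + 140 * sin(2 * pi * (t - 3) / 50)))
  dead <- mk(c(rep(50, 20), rep(0, 180)))   # extinct stable window

  sy <- fluctuation_synchrony(list(good1, good2, dead), max_lag = 40)
  expect_identical(attr(sy, "n_used"), 2L)
  expect_identical(attr(sy, "n_excluded"), 1L)
  expect_gt(max(abs(sy$r)), 0.9)            # phase-locked inputs

  sp <- fluctuation_spectrum(list(good1, good2, dead))
  expect_identical(attr(sp, "n_excluded"), 1L)
  expect_equal(sp$freq[which.max(sp$amplitude)], 1 / 50)
})
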