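# small helper: hand-built state
mk_state <- function(phi, age, gid, n_groups, t = 0L) {
  structure(list(phi = as.numeric(phi), age = as.integer(age),
                 gid = as.integer(gid), n_groups = as.integer(n_groups),
                 t = as.integer(t), extinct = FALSE),
            class = "population_state")
}

test_that("initialization places N_init individuals per scenario rules", {
  p <- sim_params(N_init = 300, n_groups = 90, T = 10)
  st <- initialize_population(p, rng_stream(1))
  expect_length(st$phi, 300)
  expect_true(all(st$gid >= 1 & st$gid <= 90))
  expect_true(all(st$age == 0L))
  expect_identical(st$t, 0L)
  expect_true(all(st$phi %in% p$trait_levels))
  expect_gt(length(unique(st$phi)), 1)  # drawn across levels, not constant

  pn <- sim_params(N_init = 300, scenario = "non_social", T = 10)
  stn <- initialize_population(pn, rng_stream(1))
  expect_true(all(stn$phi == 0))

  pu <- sim_params(N_init = 40, n_groups = 1, scenario = "non_structured",
                   T = 10)
  stu <- initialize_population(pu, rng_stream(1))
  expect_true(all(stu$gid == 1L))

  p2 <- sim_params(N_init = 12, n_groups = 4, T = 10)
  s1 <- initialize_population(p2, rng_stream(5))
  s2 <- initialize_population(p2, rng_stream(5))
  expect_identical(s1, s2)
})

test_that("mutation keeps, redraws uniformly, or locks the trait", {
  p0 <- sim_params(m = 0, T = 10)
  phi <- rep(c(0, 0.3, 1), 10)
  expect_identical(mutate_degree(phi, p0, rng_stream(1)), phi)

  pl <- sim_params(m = 0.5, scenario = "non_social", T = 10)
  expect_identical(mutate_degree(rep(0, 5), pl, rng_stream(1)), rep(0, 5))

  # m = 1: every offspring redraws; each level at frequency 1/11 +- 3 s.e.
  p1 <- sim_params(m = 1, T = 10)
  out <- mutate_degree(rep(0.5, 1e5), p1, rng_stream(3))
  freq <- tabulate(match(out, p1$trait_levels), 11) / 1e5
  se <- sqrt((1 / 11) * (10 / 11) / 1e5)
  expect_true(all(abs(freq - 1 / 11) < 3 * se + 1e-12))
})

test_that("dispersal is uniform over all slots including empty ones", {
  expect_identical(disperse(5, 1, rng_stream(1)), rep(1L, 5))
  expect_identical(disperse(0, 90, rng_stream(1)), integer())
  counts <- tabulate(disperse(1e5, 90, rng_stream(2)), 90)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("group reproduction is Poisson around the shared-resource rates", {
  p <- sim_params(alpha = 2, beta = 1, M = 1, Ks = 1, T = 10)
  # three free-riders sharing R = 4: s = 4/3, F = 2 * (1/3)/(4/3) = 0.5 each
  rng <- rng_stream(8)
  tot <- numeric(10000)
  for (i in seq_along(tot)) {
    rep_out <- reproduce_group(c(0, 0, 0), 4, p, rng)
    expect_equal(rep_out$rate, rep(0.5, 3))
    tot[i] <- sum(rep_out$n_offspring)
  }
  se <- sqrt(1.5 / length(tot))  # Poisson total with mean (= var) 1.5
  expect_lt(abs(mean(tot) - 1.5), 3 * se)

  # starvation: share at or below metabolic consumption never reproduces
  out <- reproduce_group(c(0, 0.5), 2, p, rng)  # s = 1 = M
  expect_identical(out$rate, c(0, 0))
  expect_identical(out$n_offspring, c(0L, 0L))
  expect_length(out$offspring_phi, 0)
})

test_that("survival is binomial at the age-specific rates and ages advance", {
  p <- sim_params(c = 1, age_standard = 1e9, T = 10)
  st <- mk_state(rep(0.5, 50), rep(3, 50), rep(1, 50), 2)
  out <- apply_survival(st, p, rng_stream(1))
  expect_identical(out$deaths, 0L)
  expect_true(all(out$state$age == 4L))

  pc <- sim_params(c = 0.9, T = 10)
  newborns <- mk_state(numeric(1e4), integer(1e4), rep(1L, 1e4), 1)
  out2 <- apply_survival(newborns, pc, rng_stream(2))
  survivors <- length(out2$state$phi)
  se <- sqrt(1e4 * 0.9 * 0.1)
  expect_lt(abs(survivors - 9000), 3 * se)
  expect_true(all(out2$state$age == 1L))
})

test_that("a step conserves bookkeeping and the scripted micro-path exactly", {
  # starving free-rider population produces no births
  p <- sim_params(scenario = "non_social", m = 0, T = 10)
  st <- mk_state(numeric(6), integer(6), rep(1:2, each = 3), 2)
  out <- step_population(st, 2.9, p, rng_stream(1))  # s = 2.9/3 < M = 1
  expect_identical(out$record$births, 0L)

  # extinction is absorbing and flagged
  empty <- mk_state(numeric(0), integer(0), integer(0), 3)
  oute <- step_population(empty, 5, p, rng_stream(1))
  expect_true(oute$state$extinct)
  expect_identical(oute$record$N, 0L)
  expect_identical(oute$state$t, 1L)
})

test_that("per-step population bookkeeping is exact over a whole run", {
  p <- sim_params(R00 = 5, bK = 3, N_init = 120, n_groups = 30, T = 250)
  ser <- run_simulation(p, seed = 4)
  expect_identical(nrow(ser), 250L)
  prevN <- c(p$N_init, ser$N[-nrow(ser)])
  expect_identical(ser$N, as.integer(prevN + ser$births - ser$deaths))
})

test_that("with no mutation the set of trait values never gains members", {
  p <- sim_params(R00 = 4, bK = 5, m = 0, T = 150, n_groups = 20,
                  N_init = 60)
  rng <- rng_stream(9)
  st <- mk_state(rep(c(0, 0.5), 30), integer(60),
                 rep(1:20, 3), 20)
  levels0 <- unique(st$phi)
  for (i in 1:150) {
    st <- step_population(st, 4, p, rng)$state
    expect_true(all(st$phi %in% levels0))
    expect_identical(st$n_groups, 20L)  # slots never change
    if (length(st$phi) == 0) break
  }
})

test_that("runs are reproducible from the seed and extinct series stay at zero", {
  p <- sim_params(R00 = 6, N_init = 80, n_groups = 20, T = 60)
  a <- run_simulation(p, seed = 11)
  b <- run_simulation(p, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- run_simulation(p, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))

  ph <- sim_params(R00 = 1, scenario = "non_social", T = 120)
  ser <- run_simulation(ph, seed = 1)
  expect_identical(nrow(ser), 120L)
  firstzero <- match(0L, ser$N)
  expect_false(is.na(firstzero))       # harsh non-social dies out
  expect_true(all(ser$N[firstzero:120] == 0L))
  expect_true(all(ser$births[firstzero:120] == 0L))
  expect_true(attr(ser, "extinct"))
})

test_that("group snapshots report the reproduction-stage surface", {
  p <- sim_params(R00 = 6, N_init = 60, n_groups = 10, T = 8)
  ser <- run_simulation(p, seed = 3, snapshot_steps = c(0, 3))
  gs <- attr(ser, "group_snapshots")
  expect_true(all(c("t", "group_id", "size", "sum_phi", "R_group",
                    "total_offspring", "per_capita_offspring") %in%
                  names(gs)))
  expect_setequal(unique(gs$t), c(0, 3))
  g0 <- gs[gs$t == 0, ]
  expect_identical(sum(g0$size), 60L)          # everyone counted pre-survival
  expect_identical(as.integer(sum(g0$total_offspring)), ser$births[1])
  expect_equal(g0$per_capita_offspring, g0$total_offspring / g0$size)
  # group resources never fall below the baseline
  expect_true(all(g0$R_group >= 6))
})
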