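test_that("deterministic reproduction multiplies by N*pg each life cycle", {
  tr <- simulate_population(life_cycle(4, 0.5), generations = 5)
  expect_equal(tr$population[nrow(tr)], 32)   # (N*pg)^5 = 2^5
  expect_equal(tr$time[nrow(tr)], 5 * 2)      # 5 cycles of tau = 2
  expect_true(all(diff(tr$time) > 0))
  # doubling the horizon squares the growth factor (pure exponential)
  tr2 <- simulate_population(life_cycle(4, 0.5), generations = 10)
  expect_equal(tr2$population[nrow(tr2)], tr$population[nrow(tr)]^2)
})

test_that("trajectory ordering reproduces more-germ-grows-faster", {
  final <- vapply(c(1, 0.5, 0.25), function(pg) {
    tr <- simulate_population(life_cycle(100, pg), generations = 10)
    tr$population[nrow(tr)]
  }, numeric(1))
  expect_true(final[1] > final[2] && final[2] > final[3])
})

test_that("fitted rate recovers the closed-form intrinsic rate exactly", {
  tr <- simulate_population(life_cycle(2048, 8 / 2048), generations = 5)
  expect_equal(fit_rate(tr), log(8) / 11, tolerance = 1e-9)
  expect_equal(fit_rate(simulate_population(life_cycle(64, 1), generations = 4)),
               log(2), tolerance = 1e-9)
  flat <- simulate_population(life_cycle(4, 0.25), generations = 6)
  expect_equal(fit_rate(flat), 0, tolerance = 1e-12)
  expect_error(fit_rate(flat[1, ]), "at least 2")

  set.seed(21)
  for (i in 1:200) {
    N <- exp(runif(1, log(2.1), log(1e5)))
    pg <- exp(runif(1, log(1 / N) + 0.05, 0))
    tr <- simulate_population(life_cycle(N, pg), generations = 3)
    r <- growth_rate(N, pg)
    if (abs(r) > 1e-6)
      expect_equal(fit_rate(tr), r, tolerance = 1e-9)
    else expect_lt(abs(fit_rate(tr) - r), 1e-9)
  }
})

test_that("stress trajectories match the population equation at commensurate horizons", {
  p <- survival_params(0.5, 1, 5)
  lc <- life_cycle(1024, 2 / 3)           # tau = 10, ts = 5 divides it
  tr <- simulate_population(lc, survival = p, generations = 5)
  horizon <- 5 * 10
  expect_equal(tr$population[nrow(tr)],
               closed_form_population(1024, 2 / 3, horizon,
                                      sg = 0.5, ss = 1, ts = 5),
               tolerance = 1e-9)
  expect_equal(fit_rate(tr, method = "endpoint"),
               net_growth_rate(lc, params = p), tolerance = 1e-9)

  # random commensurate scenarios: ts = tau * g / j
  set.seed(22)
  for (i in 1:50) {
    k <- sample(2:8, 1); N <- 2^k
    pg <- runif(1, max(0.05, 2 / N), 1)
    ss <- runif(1, 0.5, 1); sg <- runif(1, 0.2, ss)
    g <- sample(2:5, 1); j <- sample(1:4, 1)
    ts <- k * g / j          # the horizon g*k is an exact multiple of ts
    prm <- survival_params(sg, ss, ts)
    tr <- simulate_population(life_cycle(N, pg), survival = prm,
                              generations = g)
    expect_equal(tr$population[nrow(tr)],
                 closed_form_population(N, pg, g * k, sg = sg, ss = ss,
                                        ts = ts),
                 tolerance = 1e-9)
  }
})

test_that("stochastic mode is unbiased and reproducible from its seed", {
  lc <- life_cycle(16, 0.5)
  p <- survival_params(0.6, 0.9, 2)
  det <- simulate_population(lc, survival = p, p0 = 10, generations = 3)
  expected <- det$population[nrow(det)]
  finals <- vapply(seq_len(1000), function(i) {
    tr <- simulate_population(lc, survival = p, p0 = 10, generations = 3,
                              mode = "stochastic", seed = 1e6 + i)
    tr$population[nrow(tr)]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)

  a <- simulate_population(lc, p0 = 5, generations = 4, mode = "stochastic",
                           seed = 99)
  b <- simulate_population(lc, p0 = 5, generations = 4, mode = "stochastic",
                           seed = 99)
  expect_identical(a$population, b$population)
})

test_that("stochastic extinction truncates with a flag instead of erroring", {
  lc <- life_cycle(2, 0.5)              # one propagule per cycle on average
  p <- survival_params(0.05, 0.1, 0.5)  # near-lethal recurrent stress
  died <- FALSE
  for (s in 1:20) {
    tr <- simulate_population(lc, survival = p, p0 = 1, generations = 10,
                              mode = "stochastic", seed = s)
    if (isTRUE(attr(tr, "extinct"))) {
      died <- TRUE
      expect_equal(tr$population[nrow(tr)], 0)
      expect_true(all(tr$population[-nrow(tr)] > 0))
      break
    }
  }
  expect_true(died)
})

test_that("simulate() generic draws seeded replicate trajectories", {
  reps <- simulate(life_cycle(8, 0.5), nsim = 3, seed = 5, p0 = 2,
                   generations = 2)
  expect_length(reps, 3)
  expect_s3_class(reps[[1]], "trajectory")
})
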