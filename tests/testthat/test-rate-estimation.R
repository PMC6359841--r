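test_that("fit_mu_max recovers the generator growth rate from noise-free batches", {
  for (mu in c(0.353, 0.266, 0.15)) {
    s <- simulate_batch(batch_scenario(mu = mu))
    f <- fit_mu_max(s)
    expect_equal(f$mu, mu, tolerance = 1e-9)
    expect_gte(f$r_squared, 0.999999)
  }
})

test_that("fit_mu_max returns 0 for constant biomass and errors on bad input", {
  s <- bioreactor_series("batch", time = 0:10, biomass = rep(2, 11))
  expect_equal(fit_mu_max(s)$mu, 0)
  s2 <- bioreactor_series("batch", time = 0:1, biomass = c(1, 2))
  expect_error(fit_mu_max(s2, window = c(0, 1)), "insufficient data")
  s3 <- bioreactor_series("batch", time = 0:4, biomass = c(1, 2, 0, 4, 8))
  expect_error(fit_mu_max(s3, window = c(0, 4)), "non-positive biomass")
})

test_that("fit_mu_max under multiplicative noise stays near the truth", {
  set.seed(101)
  mus <- replicate(20, {
    s <- simulate_batch(batch_scenario(mu = 0.266, noise_cv = 0.05, dt = 1))
    fit_mu_max(s)$mu
  })
  expect_true(all(mus > 0.24 & mus < 0.29))
})

test_that("fit_specific_rate recovers generator rates and handles edge cases", {
  s <- simulate_batch(batch_scenario())
  mu <- fit_mu_max(s)$mu
  expect_equal(fit_specific_rate(s, "glucose", mu), -14.42, tolerance = 1e-6)
  expect_equal(fit_specific_rate(s, "acetate", mu), 0.61, tolerance = 1e-6)
  # constant concentration -> zero rate
  s$concentrations$acetate <- rep(1, length(s$time))
  expect_equal(fit_specific_rate(s, "acetate", mu), 0)
  expect_error(fit_specific_rate(s, "citrate", mu), "missing channel")
  expect_error(fit_specific_rate(s, "glucose", mu = -1), "mu must be")
})

test_that("noisy acetate rate estimates fall within replicate-level dispersion", {
  set.seed(55)
  qs <- replicate(20, {
    s <- simulate_batch(batch_scenario(
      mu = 0.266, q = reference_physiology("xfpk", "batch")$q,
      noise_cv = 0.02))
    batch_physiology(s)$q[["acetate"]]
  })
  expect_true(all(abs(qs - 1.38) < 0.03 * 3))
})

test_that("gas_rates inverts the off-gas forward model exactly", {
  s <- simulate_batch(batch_scenario())
  g <- gas_rates(s)
  expect_equal(g[["q_co2"]], 30.01, tolerance = 1e-6)
  expect_equal(g[["q_o2"]], -5.49, tolerance = 1e-6)
  # chemostat gas rates
  sc <- simulate_chemostat(chemostat_scenario(q_co2 = 3.34, q_o2 = -3.35))
  gc <- gas_rates(sc)
  expect_equal(gc[["q_co2"]], 3.34, tolerance = 1e-6)
  expect_equal(gc[["q_o2"]], -3.35, tolerance = 1e-6)
})

test_that("gas_rates returns zero when outlet equals inlet, errors without aeration", {
  n <- 5
  s <- bioreactor_series(
    "batch", time = 1:n, biomass = rep(1, n),
    offgas = data.frame(y_co2 = rep(0.0004, n), y_o2 = rep(0.2095, n)),
    aeration = 36, volume = 0.6
  )
  expect_equal(unname(gas_rates(s)), c(0, 0))
  s$aeration <- 0
  expect_error(gas_rates(s), "aeration")
})

test_that("gas_rates is intensive: doubling volume and biomass leaves q unchanged", {
  sc1 <- batch_scenario()
  s1 <- simulate_batch(sc1)
  sc2 <- batch_scenario(x0 = 2 * sc1$x0, volume = 2 * sc1$volume)
  s2 <- simulate_batch(sc2)
  w <- c(0, min(max(s1$time), max(s2$time)))
  expect_equal(gas_rates(s1, w), gas_rates(s2, w), tolerance = 1e-9)
})

test_that("chemostat_rates recovers the steady-state balance quantities", {
  s <- simulate_chemostat(chemostat_scenario())
  r <- chemostat_rates(s)
  expect_equal(r$mu, 0.1)
  expect_equal(r$yield_biomass, 0.479, tolerance = 1e-9)
  # q_glc = -D (S_feed - S_res) 1000 / (M X), X = 0.479 * 7.5
  q_glc_expected <- -0.1 * 7.5 * 1000 / (180.156 * 0.479 * 7.5)
  expect_equal(r$q[["glucose"]], q_glc_expected, tolerance = 1e-4)
  expect_equal(r$q[["co2"]], 2.91, tolerance = 1e-6)
  expect_equal(r$q[["o2"]], -2.61, tolerance = 1e-6)
  # chemostat q_glc magnitude consistent with the printed value
  expect_equal(abs(r$q[["glucose"]]), 1.18, tolerance = 0.05)
})

test_that("chemostat washout limit: residual = feed gives zero uptake", {
  s <- simulate_chemostat(chemostat_scenario())
  s$concentrations$glucose <- rep(s$feed[["glucose"]], length(s$time))
  r <- chemostat_rates(s)
  expect_equal(r$q[["glucose"]], 0)
  expect_true(is.na(r$yield_biomass))
})

test_that("chemostat_rates rejects drifting cultures", {
  s <- simulate_chemostat(chemostat_scenario())
  s$biomass <- s$biomass * exp(0.02 * s$time)  # ~35% drift per residence time
  expect_error(chemostat_rates(s), "steady-state violation")
})

test_that("steady_state_check accepts flat series and rejects growth", {
  flat <- simulate_chemostat(chemostat_scenario())
  chk <- steady_state_check(flat)
  expect_true(chk$passed)
  expect_equal(chk$drift_biomass, 0)
  growing <- flat
  growing$biomass <- growing$biomass * exp(0.05 * growing$time)
  expect_false(steady_state_check(growing)$passed)
  # controlled drift below threshold passes: 3% per residence time vs 5%
  drifting <- flat
  span_h <- 1 / drifting$dilution_rate
  drifting$biomass <- drifting$biomass * (1 + 0.03 * drifting$time / span_h)
  chk3 <- steady_state_check(drifting)
  expect_true(chk3$passed)
  expect_equal(chk3$drift_biomass, 0.03, tolerance = 0.05)
  expect_false(steady_state_check(drifting, threshold = 0.02)$passed)
  # insufficient span errors
  short <- flat
  keep <- short$time <= 2
  short$time <- short$time[keep]; short$biomass <- short$biomass[keep]
  short$concentrations <- lapply(short$concentrations, `[`, keep)
  short$offgas <- short$offgas[keep, ]
  expect_error(steady_state_check(short), "insufficient data")
})

test_that("pool_replicates averages fields with sample standard deviation", {
  mk <- function(mu) physiology_result("batch", mu = mu, yield_biomass = 0.13,
                                       q = c(glucose = -14, co2 = 30))
  pooled <- pool_replicates(lapply(c(0.35, 0.36, 0.34, 0.37), mk))
  expect_equal(pooled$mu, 0.355)
  expect_equal(pooled$dispersion$mu, 0.0129, tolerance = 1e-2)
  expect_equal(pooled$dispersion$mu, sd(c(0.35, 0.36, 0.34, 0.37)))
  expect_equal(pooled$n_replicates, 4)
  # identical replicates -> zero dispersion
  same <- pool_replicates(lapply(rep(0.35, 4), mk))
  expect_equal(same$dispersion$mu, 0)
  expect_equal(unname(same$dispersion$q), c(0, 0))
  expect_error(pool_replicates(list(mk(0.35))), ">= 2")
  chemo <- physiology_result("chemostat", mu = 0.1, q = c(glucose = -1.2))
  expect_error(pool_replicates(list(mk(0.35), chemo)), "incompatible")
})

test_that("bioreactor_series validates its invariants", {
  expect_error(bioreactor_series("batch", time = c(0, 1, 1), biomass = 1:3),
               "strictly increasing")
  expect_error(bioreactor_series("batch", time = 0:1, biomass = c(-1, 1)),
               "biomass")
  expect_error(bioreactor_series("batch", time = 0:1, biomass = c(1, 1),
                                 volume = 0), "volume")
  expect_error(bioreactor_series("chemostat", time = 0:1, biomass = c(1, 1)),
               "dilution_rate")
})
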