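ref_cb <- reference_physiology("control", "batch")
ref_xb <- reference_physiology("xfpk", "batch")
fm_cb <- suppressWarnings(normalize_fluxes(ref_cb))
fm_xb <- suppressWarnings(normalize_fluxes(ref_xb))

test_that("normalized fluxes express each rate as percent of glucose C-uptake", {
  # glucose itself is 100% by definition
  expect_equal(fm_cb$table$normalized_pct[fm_cb$table$compound == "glucose"], 100)
  # acetate overflow: ~3.8% for the phosphoketolase strain, ~1.4% control
  expect_equal(fm_xb$table$normalized_pct[fm_xb$table$compound == "acetate"],
               100 * 1.38 * 2 / (12.19 * 6), tolerance = 1e-12)
  expect_equal(fm_cb$table$normalized_pct[fm_cb$table$compound == "acetate"],
               100 * 0.61 * 2 / (14.42 * 6), tolerance = 1e-12)
  # all production fluxes are non-negative
  expect_true(all(fm_cb$table$normalized_pct >= 0))
})

test_that("normalize_fluxes handles zero products and missing glucose", {
  r0 <- physiology_result("batch", mu = 0.3,
                          q = c(glucose = -10, ethanol = 0, acetate = 0))
  fm0 <- suppressWarnings(normalize_fluxes(r0))
  prod <- fm0$table$compound %in% c("ethanol", "acetate")
  expect_true(all(fm0$table$normalized_pct[prod] == 0))
  r_bad <- physiology_result("batch", mu = 0.3, q = c(ethanol = 10))
  expect_error(normalize_fluxes(r_bad), "normalization error")
})

test_that("normalize_fluxes is scale-invariant", {
  scaled <- ref_cb
  scaled$q <- scaled$q * 3.7
  scaled$q_biomass <- scaled$q_biomass * 3.7
  fm_scaled <- suppressWarnings(normalize_fluxes(scaled))
  expect_equal(fm_scaled$table$normalized_pct, fm_cb$table$normalized_pct,
               tolerance = 1e-12)
  expect_equal(fm_scaled$balance_closure, fm_cb$balance_closure,
               tolerance = 1e-12)
})

test_that("carbon balance closure reproduces the published closures", {
  expect_equal(suppressWarnings(carbon_balance(ref_cb)), 107, tolerance = 0.01)
  expect_equal(carbon_balance(reference_physiology("control", "chemostat")),
               99, tolerance = 0.01)
  expect_equal(carbon_balance(reference_physiology("xfpk", "chemostat")),
               92, tolerance = 0.02)
  # closure equals the sum of normalized output fluxes
  expect_equal(suppressWarnings(carbon_balance(ref_cb)), fm_cb$balance_closure)
})

test_that("carbon balance flags incomplete inputs and out-of-band closures", {
  no_co2 <- physiology_result("batch", mu = 0.3,
                              q = c(glucose = -10, ethanol = 15))
  expect_error(carbon_balance(no_co2), "CO2")
  no_bio <- physiology_result("batch", mu = 0.3,
                              q = c(glucose = -10, co2 = 30))
  no_bio$q_biomass <- NA_real_
  expect_error(carbon_balance(no_bio), "biomass")
  inflated <- physiology_result("batch", mu = 0.3,
                                q = c(glucose = -10, co2 = 30, ethanol = 20))
  expect_warning(normalize_fluxes(inflated), "90-110")
})

test_that("respiration partition splits CO2 into fermentative and respiratory", {
  rp <- respiration_partition(fm_cb, ref_cb)
  expect_equal(rp$respiratory_co2, 30.01 - 21.46)  # 8.55 C-mmol/gCDW/h
  expect_equal(rp$fermentative_co2, 21.46)
  # partition completeness: respiratory + fermentative = total CO2 C-flux
  expect_equal(rp$respiratory_co2 + rp$fermentative_co2,
               to_cmol_flux(ref_cb$q[["co2"]], "co2"))
  # ~50% relative increase in respiratory fraction for the xfpk strain
  rp_x <- respiration_partition(fm_xb, ref_xb)
  rel <- 100 * (rp_x$respiratory_fraction / rp$respiratory_fraction - 1)
  expect_equal(rel, 50, tolerance = 0.06)
})

test_that("respiration partition without ethanol is fully respiratory", {
  ref_cc <- reference_physiology("control", "chemostat")
  fm_cc <- normalize_fluxes(ref_cc)
  rp <- respiration_partition(fm_cc, ref_cc)
  expect_equal(rp$respiratory_co2, to_cmol_flux(ref_cc$q[["co2"]], "co2"))
  expect_equal(rp$fermentative_co2, 0)
})

test_that("inconsistent inputs (ethanol CO2 exceeding total) are flagged", {
  bad <- physiology_result("batch", mu = 0.3,
                           q = c(glucose = -10, ethanol = 20, co2 = 5))
  fm <- suppressWarnings(normalize_fluxes(bad))
  expect_warning(rp <- respiration_partition(fm, bad), "exceeds")
  expect_lt(rp$respiratory_co2, 0)
})

test_that("flux_difference returns percentage-point differences", {
  expect_equal(flux_difference(fm_xb, fm_cb, "acetate"), 2.4, tolerance = 0.04)
  expect_equal(flux_difference(fm_cb, fm_cb, "ethanol"), 0)
  expect_equal(flux_difference(fm_xb, fm_cb, "glucose"), 0)  # both 100%
  expect_error(flux_difference(fm_xb, fm_cb, "citrate"), "missing")
})

test_that("edge-list rendering suppresses sub-threshold fluxes but data retains them", {
  edges <- fluxmap_edges(fm_cb, min_pct = 0.1)
  expect_true(all(edges$percent >= 0.1))
  expect_true(all(edges$source == "glucose"))
  # succinate (0.02 mmol -> ~0.09%) is suppressed in display, kept in data
  expect_false("succinate" %in% edges$sink)
  expect_true("succinate" %in% fm_cb$table$compound)
})
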