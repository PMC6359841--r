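make_panel <- function(strain, values_by_met) {
  rows <- do.call(rbind, lapply(names(values_by_met), function(m) {
    data.frame(replicate = seq_along(values_by_met[[m]]), metabolite = m,
               value = values_by_met[[m]])
  }))
  metabolite_panel(strain, rows)
}

test_that("fold_changes returns percent of control means", {
  ctrl <- make_panel("control", list(X5P = c(1, 1.1, 0.9, 1),
                                     E4P = c(0.05, 0.06, 0.05, 0.04)))
  same <- fold_changes(ctrl, ctrl)
  expect_true(all(same$fold_change_pct == 100))
  test <- make_panel("test", list(X5P = c(0.26, 0.286, 0.234, 0.26),
                                  E4P = c(0.271, 0.3252, 0.271, 0.2168)))
  fc <- fold_changes(test, ctrl)
  expect_equal(fc$fold_change_pct[fc$metabolite == "X5P"], 26, tolerance = 1e-9)
  expect_equal(fc$fold_change_pct[fc$metabolite == "E4P"], 542, tolerance = 1e-9)
})

test_that("fold_changes recovers generator fold-changes in expectation", {
  sc <- panel_scenario(cv = 0.05, n = 200)
  p <- simulate_panel(sc, seed = 11)
  fc <- fold_changes(p$test, p$control)
  got <- fc$fold_change_pct[match(names(sc$fold_change), fc$metabolite)] / 100
  expect_equal(got, unname(sc$fold_change), tolerance = 0.03)
  # X5P at its configured 26% and E4P at 542% of control
  expect_equal(fc$fold_change_pct[fc$metabolite == "X5P"], 26, tolerance = 0.05)
  expect_equal(fc$fold_change_pct[fc$metabolite == "E4P"], 542, tolerance = 0.05)
})

test_that("fold_changes is invariant to a common unit rescaling", {
  p <- simulate_panel(panel_scenario(), seed = 3)
  fc1 <- fold_changes(p$test, p$control)
  p$test$data$value <- p$test$data$value * 1000
  p$control$data$value <- p$control$data$value * 1000
  fc2 <- fold_changes(p$test, p$control)
  expect_equal(fc2$fold_change_pct, fc1$fold_change_pct, tolerance = 1e-12)
})

test_that("welch_test matches the from-scratch Welch/Satterthwaite oracle", {
  set.seed(202)
  for (i in 1:50) {
    x <- rlnorm(sample(2:8, 1), 0, 0.3)
    y <- rlnorm(sample(2:8, 1), 0.2, 0.5)
    got <- welch_test(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("welch_test tiers and degenerate cases", {
  w <- welch_test(c(10, 11, 9, 10), c(20, 21, 19, 20))
  expect_lt(w$p_value, 0.001)
  expect_identical(w$tier, "**")
  # two identical zero-variance groups: no evidence of difference
  same <- welch_test(rep(5, 4), rep(5, 4))
  expect_equal(same$p_value, 1)
  expect_identical(same$tier, "")
  expect_error(welch_test(1, c(1, 2)), "insufficient replicates")
  expect_error(welch_test(rep(1, 3), rep(2, 3)), "zero variance")
  expect_identical(significance_tier(c(0.2, 0.04, 0.0005)), c("", "*", "**"))
})

test_that("compare_panels assembles fold-change, dispersion, p and tier", {
  p <- simulate_panel(panel_scenario(), seed = 9)
  res <- compare_panels(p$test, p$control)
  expect_setequal(res$metabolite, sugar_phosphates)
  expect_true(all(c("fold_change_pct", "sd_test", "p_value", "tier") %in%
                    names(res)))
  # strongly perturbed metabolites reach significance at n = 4, cv 10%
  expect_true(all(res$tier[res$metabolite %in% c("X5P", "E4P")] != ""))
  adj <- compare_panels(p$test, p$control, adjust = TRUE)
  expect_true(all(adj$p_adjusted >= adj$p_value))
})

test_that("equilibrium fold-change requirement solves the K-invariance equation", {
  aldolase <- equilibrium_relation("aldolase", c("DHAP", "GAP"), "FBP")
  expect_equal(equilibrium_required_foldchange(c(DHAP = 2, GAP = 2), aldolase), 4)
  expect_equal(equilibrium_required_foldchange(c(DHAP = 1, GAP = 1), aldolase), 1)
  expect_equal(equilibrium_required_foldchange(c(DHAP = 3, GAP = 0.5), aldolase), 1.5)
  # solving for a product instead of a reactant
  expect_equal(equilibrium_required_foldchange(c(DHAP = 2, FBP = 4), aldolase), 2)
  expect_error(equilibrium_required_foldchange(c(DHAP = 2), aldolase),
               "underdetermined")
  expect_error(equilibrium_required_foldchange(c(DHAP = -2, GAP = 2), aldolase),
               "> 0")
})

test_that("equilibrium requirement is multiplicative under composed fold-changes", {
  rel <- equilibrium_relation("aldolase", c("DHAP", "GAP"), "FBP")
  a <- c(DHAP = 1.5, GAP = 2)
  b <- c(DHAP = 2, GAP = 0.8)
  expect_equal(
    equilibrium_required_foldchange(a * b, rel),
    equilibrium_required_foldchange(a, rel) * equilibrium_required_foldchange(b, rel),
    tolerance = 1e-12
  )
})

test_that("TPI ratio check measures log-fold deviation from the 20:1 equilibrium", {
  at_eq <- tpi_ratio_check(20, 1)
  expect_equal(at_eq$ratio, 20)
  expect_equal(at_eq$log2_deviation, 0)
  off <- tpi_ratio_check(10, 1)
  expect_equal(off$ratio, 10)
  expect_equal(off$log2_deviation, -1)
  # scale invariance
  expect_equal(tpi_ratio_check(40, 2)$ratio, 20)
  expect_error(tpi_ratio_check(0, 1), "> 0")
})

test_that("metabolite_panel validates pools and replicate counts", {
  expect_error(metabolite_panel("s", data.frame(replicate = 1:2,
                                                metabolite = "X5P",
                                                value = c(1, -1))),
               "positive")
  expect_error(metabolite_panel("s", data.frame(replicate = 1,
                                                metabolite = "X5P",
                                                value = 1)),
               "insufficient replicates")
})
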