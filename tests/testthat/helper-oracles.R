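# Independent oracles used to cross-check package implementations.

# Welch two-sample t-test from the textbook formulas (statistic, Welch-
# Satterthwaite degrees of freedom, two-sided p) -- deliberately independent
# of stats::t.test.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p_value = p)
}

# hand-summed molar mass from atom counts (independent of the registry)
oracle_molar_mass <- function(c = 0, h = 0, o = 0, n = 0, p = 0, s = 0) {
  c * 12.011 + h * 1.008 + o * 15.999 + n * 14.007 + p * 30.974 + s * 32.06
}
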