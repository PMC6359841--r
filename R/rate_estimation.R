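# Specific-rate and yield estimation from bioreactor time-series.

# molar volume of an ideal gas (L/mol) at temperature t_celsius and 1 atm
gas_molar_volume <- function(t_celsius = 30) {
  0.0820573661 * (t_celsius + 273.15)
}

# default inlet gas composition: air
default_gas_inlet <- c(y_co2 = 0.0004, y_o2 = 0.2095)

#' Construct a bioreactor time-series
#'
#' Container for one cultivation's time-resolved liquid- and gas-phase
#' measurements. Biomass may be supplied as gCDW/L directly or as OD600
#' together with a `od_to_cdw` conversion factor (gCDW per OD unit).
#'
#' @param mode `"batch"` or `"chemostat"`.
#' @param time Sampling times, h; strictly increasing.
#' @param biomass Biomass concentration over time, gCDW/L (after applying
#'   `od_to_cdw`); must be >= 0.
#' @param concentrations Named list or data.frame of extracellular
#'   concentrations (g/L) over time, one element per compound.
#' @param offgas Optional data.frame with columns `y_co2`, `y_o2`: off-gas
#'   mole fractions over time.
#' @param aeration Gas inflow, L/h (>= 0).
#' @param volume Working volume, L (> 0).
#' @param pH Set-point pH (metadata).
#' @param temperature Broth temperature, degrees C (for the ideal-gas
#'   conversion of the aeration rate).
#' @param gas_inlet Named vector `c(y_co2 = , y_o2 = )` of inlet mole
#'   fractions; default atmospheric air (0.04% CO2, 20.95% O2).
#' @param dilution_rate Chemostat dilution rate D, h^-1 (required for
#'   chemostat mode).
#' @param feed Named vector of feed concentrations, g/L (chemostat mode;
#'   typically `c(glucose = 7.5)`).
#' @param replicate_id,strain Metadata labels.
#' @param od_to_cdw Scalar gCDW per OD600 unit applied to `biomass`;
#'   default 1 (biomass already in gCDW/L).
#' @return Object of class `bioreactor_series`.
#' @export
bioreactor_series <- function(mode = c("batch", "chemostat"),
                              time, biomass, concentrations = list(),
                              offgas = NULL, aeration = 0, volume = 1,
                              pH = NA_real_, temperature = 30,
                              gas_inlet = default_gas_inlet,
                              dilution_rate = NULL, feed = NULL,
                              replicate_id = NA_character_,
                              strain = NA_character_,
                              od_to_cdw = 1) {
  mode <- match.arg(mode)
  time <- as.numeric(time)
  if (length(time) < 1 || any(diff(time) <= 0)) {
    stop("time must be strictly increasing")
  }
  biomass <- as.numeric(biomass) * od_to_cdw
  if (length(biomass) != length(time)) stop("biomass length must match time")
  if (any(biomass < 0)) stop("biomass must be >= 0")
  if (!is.numeric(volume) || volume <= 0) stop("volume must be > 0")
  if (!is.numeric(aeration) || aeration < 0) stop("aeration must be >= 0")
  concentrations <- lapply(as.list(concentrations), as.numeric)
  for (nm in names(concentrations)) {
    if (length(concentrations[[nm]]) != length(time)) {
      stop("concentration series '", nm, "' length must match time")
    }
  }
  if (!is.null(offgas)) {
    offgas <- as.data.frame(offgas)
    stopifnot(all(c("y_co2", "y_o2") %in% names(offgas)),
              nrow(offgas) == length(time))
  }
  if (mode == "chemostat") {
    if (is.null(dilution_rate) || dilution_rate <= 0) {
      stop("chemostat mode requires dilution_rate > 0")
    }
    if (is.null(feed)) feed <- c(glucose = NA_real_)
  }
  structure(
    list(mode = mode, time = time, biomass = biomass,
         concentrations = concentrations, offgas = offgas,
         aeration = aeration, volume = volume, pH = pH,
         temperature = temperature, gas_inlet = gas_inlet,
         dilution_rate = dilution_rate, feed = feed,
         replicate_id = replicate_id, strain = strain),
    class = "bioreactor_series"
  )
}

#' @export
print.bioreactor_series <- function(x, ...) {
  cat(sprintf(
    "<bioreactor_series> %s, %d samples over %.2f h, compounds: %s%s\n",
    x$mode, length(x$time), diff(range(x$time)),
    paste(names(x$concentrations), collapse = ", "),
    if (!is.null(x$offgas)) ", off-gas" else ""
  ))
  invisible(x)
}

window_idx <- function(series, window) {
  if (is.null(window)) return(seq_along(series$time))
  which(series$time >= window[1] & series$time <= window[2])
}

# slope, intercept and R2 of y ~ x by least squares; R2 defined as 1 for a
# perfectly flat response (zero total variance)
ls_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- if (sxx > 0) sxy / sxx else 0
  res <- y - my - slope * (x - mx)
  sst <- sum((y - my)^2)
  r2 <- if (sst <= .Machine$double.eps * n * max(1, my^2)) 1 else 1 - sum(res^2) / sst
  list(slope = slope, intercept = my - slope * mx, r2 = r2, n = n)
}

# longest contiguous window (>= min_n points) with R2 of ln(biomass) ~ time
# at least r2_min; ties broken by R2. Falls back to the full series if no
# window qualifies.
auto_exp_window <- function(series, r2_min = 0.995, min_n = 4) {
  t <- series$time
  x <- series$biomass
  ok <- x > 0
  best <- NULL
  n <- length(t)
  for (i in seq_len(n)) {
    if (!ok[i] || i + min_n - 1 > n) next
    for (j in (i + min_n - 1):n) {
      if (!all(ok[i:j])) break
      f <- ls_fit(t[i:j], log(x[i:j]))
      if (f$r2 >= r2_min) {
        len <- j - i + 1
        if (is.null(best) || len > best$len ||
            (len == best$len && f$r2 > best$r2)) {
          best <- list(i = i, j = j, len = len, r2 = f$r2)
        }
      }
    }
  }
  if (is.null(best)) return(range(t[ok]))
  c(t[best$i], t[best$j])
}

#' Fit the maximum specific growth rate
#'
#' Least-squares slope of ln(biomass) versus time over an exponential-phase
#' window. With `window = NULL` the window is chosen automatically as the
#' longest contiguous stretch of >= 4 points whose log-linear fit has
#' R^2 >= 0.995 (falling back to all positive-biomass points if none
#' qualifies).
#'
#' @param series A [bioreactor_series()].
#' @param window Numeric `c(t_start, t_end)` in hours, or `NULL` for
#'   automatic selection.
#' @return List of class `mu_fit`: `mu` (h^-1), `r_squared`, `window`,
#'   `n_points`.
#' @export
fit_mu_max <- function(series, window = NULL) {
  stopifnot(inherits(series, "bioreactor_series"))
  if (is.null(window)) window <- auto_exp_window(series)
  idx <- window_idx(series, window)
  if (length(idx) < 3) stop("insufficient data: need >= 3 biomass observations in window")
  x <- series$biomass[idx]
  if (any(x <= 0)) stop("non-positive biomass in window")
  f <- ls_fit(series$time[idx], log(x))
  structure(list(mu = f$slope, r_squared = f$r2,
                 window = window, n_points = f$n),
            class = "mu_fit")
}

#' @export
print.mu_fit <- function(x, ...) {
  cat(sprintf("<mu_fit> mu = %.4f 1/h (R2 = %.4f, %d points, window %.2f-%.2f h)\n",
              x$mu, x$r_squared, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Fit a specific consumption/production rate
#'
#' During balanced exponential growth every extracellular concentration is
#' linear in biomass: dS/dX = q M / (1000 mu). The rate is therefore
#' estimated as `q = mu * slope(S ~ X) * 1000 / M`, avoiding numerical
#' differentiation of noisy time-series. Signs follow the data: consumed
#' species give negative q, produced species positive.
#'
#' @param series A [bioreactor_series()].
#' @param compound Compound name (must be in `series$concentrations` and in
#'   the registry).
#' @param mu Specific growth rate, h^-1 (> 0), typically from
#'   [fit_mu_max()].
#' @param window Time window `c(t0, t1)`; `NULL` = automatic exponential
#'   window.
#' @param registry Compound registry (for the molar mass).
#' @return q in mmol gCDW^-1 h^-1.
#' @export
fit_specific_rate <- function(series, compound, mu, window = NULL,
                              registry = compound_registry()) {
  stopifnot(inherits(series, "bioreactor_series"))
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (!compound %in% names(series$concentrations)) {
    stop("missing channel: no concentration series for '", compound, "'")
  }
  cp <- get_compound(registry, compound)
  if (is.null(window)) window <- auto_exp_window(series)
  idx <- window_idx(series, window)
  if (length(idx) < 3) stop("insufficient data in window")
  f <- ls_fit(series$biomass[idx], series$concentrations[[compound]][idx])
  mu * f$slope * 1000 / cp$molar_mass
}

#' Gas exchange rates from off-gas analysis
#'
#' Carbon dioxide evolution and oxygen uptake from off-gas mole fractions
#' and the inlet gas flow. The molar gas flow is obtained from the ideal
#' gas law at the series temperature and 1 atm; the balance uses the inlet
#' flow for both streams (the outlet-flow change is negligible at
#' respiratory quotients near 1):
#' `CER = n_in (y_co2_out - y_co2_in)`, `OUR = n_in (y_o2_in - y_o2_out)`.
#' Rates are normalised per gCDW pointwise and averaged over the window.
#'
#' @param series A [bioreactor_series()] with off-gas data.
#' @param window Time window; `NULL` = whole series.
#' @return Named vector `c(q_co2 = , q_o2 = )` in mmol gCDW^-1 h^-1;
#'   q_o2 is negative for net consumption.
#' @export
gas_rates <- function(series, window = NULL) {
  stopifnot(inherits(series, "bioreactor_series"))
  if (is.null(series$offgas)) stop("series has no off-gas data")
  if (series$aeration <= 0) stop("undefined rate: aeration is zero")
  idx <- window_idx(series, window)
  if (length(idx) < 1) stop("empty window")
  n_in <- series$aeration / gas_molar_volume(series$temperature) * 1000 # mmol/h
  xv <- series$biomass[idx] * series$volume                             # gCDW
  if (any(xv <= 0)) stop("non-positive biomass in window")
  cer <- n_in * (series$offgas$y_co2[idx] - series$gas_inlet[["y_co2"]])
  our <- n_in * (series$gas_inlet[["y_o2"]] - series$offgas$y_o2[idx])
  c(q_co2 = mean(cer / xv), q_o2 = -mean(our / xv))
}

#' Steady-state check for chemostat series
#'
#' A chemostat sample window is accepted as steady state when the relative
#' drift of both the biomass signal and the off-gas CO2 signal over `span`
#' residence times is below `threshold`. Drift is the fitted linear trend
#' times the span length, relative to the window mean.
#'
#' @param series A chemostat [bioreactor_series()].
#' @param span Length of the evaluation window in residence times (1/D);
#'   default 1.
#' @param threshold Maximum tolerated relative drift; default 0.05.
#' @return List of class `steady_state`: `passed` (logical),
#'   `drift_biomass`, `drift_co2`, `span_h`.
#' @export
steady_state_check <- function(series, span = 1, threshold = 0.05) {
  stopifnot(inherits(series, "bioreactor_series"))
  if (series$mode != "chemostat") stop("steady_state_check requires chemostat mode")
  span_h <- span / series$dilution_rate
  t_end <- max(series$time)
  idx <- which(series$time >= t_end - span_h)
  if (diff(range(series$time)) < span_h || length(idx) < 3) {
    stop("insufficient data: series must cover at least ", span,
         " residence time(s) (", signif(span_h, 3), " h)")
  }
  drift_of <- function(y) {
    f <- ls_fit(series$time[idx], y)
    m <- mean(y)
    if (m == 0) 0 else abs(f$slope) * span_h / abs(m)
  }
  db <- drift_of(series$biomass[idx])
  dc <- if (!is.null(series$offgas)) drift_of(series$offgas$y_co2[idx]) else 0
  structure(list(passed = db < threshold && dc < threshold,
                 drift_biomass = db, drift_co2 = dc, span_h = span_h),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %s (biomass drift %.3f, CO2 drift %.3f over %.1f h)\n",
              if (x$passed) "PASSED" else "FAILED",
              x$drift_biomass, x$drift_co2, x$span_h))
  invisible(x)
}

#' Physiology result container
#'
#' The computational twin of one column of a physiological-characterisation
#' table: growth rate, biomass yield and signed specific rates for one
#' strain/condition.
#'
#' @param mode `"batch"` or `"chemostat"`.
#' @param mu Specific growth rate, h^-1.
#' @param yield_biomass Biomass yield on glucose, gCDW per g.
#' @param q Named numeric vector of specific rates, mmol gCDW^-1 h^-1
#'   (consumption negative, production positive).
#' @param q_biomass Biomass formation rate, C-mmol gCDW^-1 h^-1; defaults
#'   to `mu * 1000 / cmol_mass` when a `composition` is given.
#' @param dispersion Optional list of standard deviations (fields `mu`,
#'   `yield_biomass`, `q`, `q_biomass`).
#' @param window Time window used for fitting (metadata).
#' @param n_replicates Number of replicates pooled into this result.
#' @param strain Strain label.
#' @param composition Biomass composition used for `q_biomass` when not
#'   supplied.
#' @return Object of class `physiology_result`.
#' @export
physiology_result <- function(mode, mu, yield_biomass = NA_real_, q,
                              q_biomass = NULL, dispersion = NULL,
                              window = NULL, n_replicates = 1L,
                              strain = NA_character_,
                              composition = biomass_composition()) {
  stopifnot(is.numeric(q), !is.null(names(q)))
  if (is.null(q_biomass)) q_biomass <- mu * 1000 / cmol_mass(composition)
  structure(
    list(mode = mode, mu = mu, yield_biomass = yield_biomass, q = q,
         q_biomass = q_biomass, dispersion = dispersion, window = window,
         n_replicates = n_replicates, strain = strain),
    class = "physiology_result"
  )
}

#' @export
print.physiology_result <- function(x, ...) {
  cat(sprintf("<physiology_result> %s%s: mu = %.3f 1/h, Y(x/s) = %.3f g/g\n",
              if (!is.na(x$strain)) paste0(x$strain, ", ") else "",
              x$mode, x$mu, x$yield_biomass))
  print(round(c(x$q, biomass_cmol = x$q_biomass), 3))
  invisible(x)
}

#' Full physiological characterisation of a batch series
#'
#' Convenience wrapper running [fit_mu_max()], [fit_specific_rate()] for
#' every concentration channel, [gas_rates()] when off-gas is present, and
#' the biomass yield on glucose (from the slope of biomass versus glucose
#' over the window).
#'
#' @inheritParams fit_specific_rate
#' @param composition Biomass composition for `q_biomass`.
#' @return A [physiology_result()].
#' @export
batch_physiology <- function(series, window = NULL,
                             registry = compound_registry(),
                             composition = biomass_composition()) {
  stopifnot(inherits(series, "bioreactor_series"))
  if (series$mode != "batch") stop("batch_physiology requires batch mode")
  if (is.null(window)) window <- auto_exp_window(series)
  fit <- fit_mu_max(series, window)
  q <- vapply(names(series$concentrations), function(cp) {
    fit_specific_rate(series, cp, fit$mu, window, registry)
  }, numeric(1))
  if (!is.null(series$offgas)) {
    q <- c(q, gas_rates(series, window))
    names(q)[names(q) == "q_co2"] <- "co2"
    names(q)[names(q) == "q_o2"] <- "o2"
  }
  yield <- NA_real_
  if ("glucose" %in% names(series$concentrations)) {
    idx <- window_idx(series, window)
    f <- ls_fit(series$concentrations$glucose[idx], series$biomass[idx])
    yield <- -f$slope  # gCDW formed per g glucose consumed
  }
  physiology_result(mode = "batch", mu = fit$mu, yield_biomass = yield,
                    q = q, window = window, strain = series$strain,
                    composition = composition)
}

#' Physiological characterisation of a chemostat steady state
#'
#' At steady state the specific growth rate equals the dilution rate D.
#' Glucose uptake follows the chemostat balance
#' `q_glc = -D (S_feed - S_residual) * 1000 / (M_glc * X)`, the biomass
#' yield is `X / (S_feed - S_residual)`, other dissolved products use
#' `q_i = D * C_i * 1000 / (M_i * X)`, and gas rates come from
#' [gas_rates()]. If residual glucose is not measured it defaults to 0 g/L
#' (glucose-limited assumption) with a warning.
#'
#' @param series A chemostat [bioreactor_series()].
#' @param check_steady Require [steady_state_check()] to pass (default
#'   TRUE).
#' @param span,threshold Passed to [steady_state_check()].
#' @param registry Compound registry.
#' @param composition Biomass composition for `q_biomass`.
#' @return A [physiology_result()].
#' @export
chemostat_rates <- function(series, check_steady = TRUE, span = 1,
                            threshold = 0.05,
                            registry = compound_registry(),
                            composition = biomass_composition()) {
  stopifnot(inherits(series, "bioreactor_series"))
  if (series$mode != "chemostat") stop("chemostat_rates requires chemostat mode")
  if (check_steady) {
    ss <- steady_state_check(series, span, threshold)
    if (!ss$passed) {
      stop(sprintf(
        "steady-state violation: biomass drift %.3f, CO2 drift %.3f exceed threshold %.3f",
        ss$drift_biomass, ss$drift_co2, threshold))
    }
  }
  D <- series$dilution_rate
  X <- mean(series$biomass)
  s_feed <- series$feed[["glucose"]]
  if (is.na(s_feed)) stop("chemostat series must carry feed glucose concentration")
  if ("glucose" %in% names(series$concentrations)) {
    s_res <- mean(series$concentrations$glucose)
  } else {
    warning("residual glucose not measured; assuming 0 g/L (glucose-limited)")
    s_res <- 0
  }
  m_glc <- get_compound(registry, "glucose")$molar_mass
  q <- c(glucose = -D * (s_feed - s_res) * 1000 / (m_glc * X))
  for (cp in setdiff(names(series$concentrations), "glucose")) {
    m <- get_compound(registry, cp)$molar_mass
    q[cp] <- D * mean(series$concentrations[[cp]]) * 1000 / (m * X)
  }
  if (!is.null(series$offgas)) {
    g <- gas_rates(series)
    q["co2"] <- g[["q_co2"]]
    q["o2"] <- g[["q_o2"]]
  }
  yield <- if (s_feed > s_res) X / (s_feed - s_res) else NA_real_
  physiology_result(mode = "chemostat", mu = D, yield_biomass = yield,
                    q = q, strain = series$strain,
                    composition = composition)
}

#' Pool replicate physiology results
#'
#' Field-wise mean and sample standard deviation (n - 1 denominator) across
#' replicate cultivations of the same mode.
#'
#' @param results List of >= 2 [physiology_result()] objects, same mode.
#' @return A pooled [physiology_result()] with `dispersion` filled in.
#' @export
pool_replicates <- function(results) {
  stopifnot(is.list(results), all(vapply(results, inherits, TRUE, "physiology_result")))
  if (length(results) < 2) stop("need >= 2 replicates to pool")
  modes <- unique(vapply(results, `[[`, "", "mode"))
  if (length(modes) != 1) stop("incompatible replicates: mixed cultivation modes")
  qn <- unique(unlist(lapply(results, function(r) names(r$q))))
  qmat <- vapply(results, function(r) r$q[qn], numeric(length(qn)))
  qmat <- matrix(qmat, nrow = length(qn), dimnames = list(qn, NULL))
  mus <- vapply(results, `[[`, 0, "mu")
  ys <- vapply(results, `[[`, 0, "yield_biomass")
  qb <- vapply(results, `[[`, 0, "q_biomass")
  physiology_result(
    mode = modes, mu = mean(mus), yield_biomass = mean(ys),
    q = rowMeans(qmat), q_biomass = mean(qb),
    dispersion = list(mu = stats::sd(mus), yield_biomass = stats::sd(ys),
                      q = apply(qmat, 1, stats::sd), q_biomass = stats::sd(qb)),
    n_replicates = length(results),
    strain = results[[1]]$strain
  )
}
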