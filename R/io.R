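# CSV I/O and pipeline orchestration.

# expected unit per channel class
channel_unit <- function(channel) {
  if (channel == "biomass") return("gCDW/L")
  if (channel %in% c("y_co2", "y_o2")) return("mole_fraction")
  "g/L"
}

#' Write a bioreactor series to CSV
#'
#' Long format with columns `time_h, channel, value, unit, replicate,
#' strain`; series metadata (mode, aeration, volume, pH, temperature,
#' dilution rate, feed, inlet gas fractions) is stored in `# key=value`
#' header comment lines so the file round-trips through
#' [read_timeseries()].
#'
#' @param series A [bioreactor_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "bioreactor_series"))
  meta <- c(
    mode = series$mode, aeration_L_h = series$aeration,
    volume_L = series$volume, pH = series$pH,
    temperature_C = series$temperature,
    y_co2_in = series$gas_inlet[["y_co2"]],
    y_o2_in = series$gas_inlet[["y_o2"]]
  )
  if (!is.null(series$dilution_rate)) {
    meta <- c(meta, dilution_rate_h = series$dilution_rate,
              feed_glucose_g_L = series$feed[["glucose"]])
  }
  chans <- list(biomass = series$biomass)
  chans <- c(chans, series$concentrations)
  if (!is.null(series$offgas)) {
    chans$y_co2 <- series$offgas$y_co2
    chans$y_o2 <- series$offgas$y_o2
  }
  long <- do.call(rbind, lapply(names(chans), function(ch) {
    data.frame(time_h = series$time, channel = ch, value = chans[[ch]],
               unit = channel_unit(ch), replicate = series$replicate_id,
               strain = series$strain)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' Read a bioreactor series from CSV
#'
#' Reads the long-format schema written by [write_timeseries()]. Units are
#' validated strictly: a channel carrying an unexpected unit (e.g. `g/L`
#' where `gCDW/L` is required) is a parse error naming the channel, and
#' non-monotone time is rejected.
#'
#' @param path CSV file path.
#' @return A [bioreactor_series()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  required <- c("time_h", "channel", "value", "unit")
  if (!all(required %in% names(df))) {
    stop("parse error: expected columns ", paste(required, collapse = ", "))
  }
  for (ch in unique(df$channel)) {
    expected <- channel_unit(ch)
    seen <- unique(df$unit[df$channel == ch])
    if (!identical(seen, expected)) {
      stop("parse error: channel '", ch, "' has unit '",
           paste(seen, collapse = "/"), "', expected '", expected, "'")
    }
  }
  time <- sort(unique(df$time_h))
  get_channel <- function(ch) {
    sub <- df[df$channel == ch, ]
    if (nrow(sub) != length(time) || any(sub$time_h != time)) {
      if (any(duplicated(sub$time_h))) {
        stop("parse error: non-monotone or duplicated time in channel '", ch, "'")
      }
      stop("parse error: channel '", ch, "' does not cover the common time grid")
    }
    sub$value
  }
  # reject files whose raw time ordering is non-monotone per channel
  for (ch in unique(df$channel)) {
    tt <- df$time_h[df$channel == ch]
    if (any(diff(tt) <= 0)) {
      stop("parse error: time not strictly increasing in channel '", ch, "'")
    }
  }
  chans <- unique(df$channel)
  if (!"biomass" %in% chans) stop("parse error: biomass channel missing")
  conc_names <- setdiff(chans, c("biomass", "y_co2", "y_o2"))
  conc <- lapply(stats::setNames(conc_names, conc_names), get_channel)
  offgas <- NULL
  if (all(c("y_co2", "y_o2") %in% chans)) {
    offgas <- data.frame(y_co2 = get_channel("y_co2"),
                         y_o2 = get_channel("y_o2"))
  }
  num <- function(key, default = NA_real_) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  mode <- if (is.null(meta$mode)) "batch" else meta$mode
  bioreactor_series(
    mode = mode, time = time, biomass = get_channel("biomass"),
    concentrations = conc, offgas = offgas,
    aeration = num("aeration_L_h", 0), volume = num("volume_L", 1),
    pH = num("pH"), temperature = num("temperature_C", 30),
    gas_inlet = c(y_co2 = num("y_co2_in", default_gas_inlet[["y_co2"]]),
                  y_o2 = num("y_o2_in", default_gas_inlet[["y_o2"]])),
    dilution_rate = if (mode == "chemostat") num("dilution_rate_h") else NULL,
    feed = if (mode == "chemostat") c(glucose = num("feed_glucose_g_L")) else NULL,
    replicate_id = if ("replicate" %in% names(df)) as.character(df$replicate[1]) else NA_character_,
    strain = if ("strain" %in% names(df)) as.character(df$strain[1]) else NA_character_
  )
}

#' Write / read a metabolite panel CSV
#'
#' Columns: `strain, replicate, metabolite, value`.
#'
#' @param panel A [metabolite_panel()].
#' @param path File path.
#' @return `path` (write) or a [metabolite_panel()] (read).
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "metabolite_panel"))
  df <- cbind(strain = panel$strain, panel$data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  required <- c("strain", "replicate", "metabolite", "value")
  if (!all(required %in% names(df))) {
    stop("parse error: expected columns ", paste(required, collapse = ", "))
  }
  strains <- unique(df$strain)
  if (length(strains) != 1) stop("panel file must contain a single strain")
  metabolite_panel(strains, df[c("replicate", "metabolite", "value")])
}

#' Serialise a physiology result as a tidy CSV table
#'
#' One row per parameter (`mu`, `yield_biomass`, each `q_*`, `q_biomass`)
#' with value, dispersion (if pooled), unit and mode.
#'
#' @param result A [physiology_result()].
#' @return data.frame (also written to `path` if given).
#' @param path Optional output path.
#' @export
physiology_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "physiology_result"))
  disp <- result$dispersion
  sd_of <- function(field, sub = NULL) {
    if (is.null(disp)) return(NA_real_)
    v <- disp[[field]]
    if (!is.null(sub)) v <- v[sub]
    if (is.null(v) || length(v) == 0) NA_real_ else unname(v)
  }
  rows <- rbind(
    data.frame(parameter = "mu", value = result$mu, sd = sd_of("mu"),
               unit = "1/h"),
    data.frame(parameter = "yield_biomass", value = result$yield_biomass,
               sd = sd_of("yield_biomass"), unit = "gCDW/gGlucose"),
    do.call(rbind, lapply(names(result$q), function(nm) {
      data.frame(parameter = paste0("q_", nm), value = result$q[[nm]],
                 sd = sd_of("q", nm), unit = "mmol/gCDW/h")
    })),
    data.frame(parameter = "q_biomass", value = result$q_biomass,
               sd = sd_of("q_biomass"), unit = "C-mmol/gCDW/h")
  )
  rows$mode <- result$mode
  rows$strain <- result$strain
  rows$n_replicates <- result$n_replicates
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}

#' Run the full analysis pipeline
#'
#' Executes rate estimation, flux accounting, carbon balance, energetics
#' and (optionally) metabolite-panel analysis on a configuration, writing
#' tidy CSV outputs plus a run log into `out_dir`. The configuration is a
#' list (or path to a YAML file with the same keys):
#' \describe{
#'   \item{series}{Character vector of time-series CSV paths, or a list of
#'     [bioreactor_series()] objects. Batch series are characterised with
#'     [batch_physiology()], chemostat series with [chemostat_rates()].}
#'   \item{panel_test, panel_control}{Optional metabolite panel CSV paths
#'     (or panel objects); when both present the panel comparison runs,
#'     otherwise the stage is skipped with a logged notice.}
#'   \item{pH, pKa}{Optional weak-acid speciation inputs (defaults 5,
#'     4.76).}
#'   \item{mixing}{Optional list/vector with `q_ref_glucose`,
#'     `q_ref_acetate`, `q_observed` for the mixing model.}
#'   \item{seed}{Seed recorded in the log (the pipeline itself is
#'     deterministic; the seed matters when scenario simulation is part of
#'     the config upstream).}
#' }
#' Outputs: `physiology.csv`, `fluxmap.csv`, `edges.csv`,
#' `energetics.csv`, `metabolites.csv` (if panels given), `warnings.csv`,
#' `log.txt`.
#'
#' @param config List or YAML path as described above.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("physioflux pipeline run: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
    paste0("config: ", paste(utils::capture.output(utils::str(config)),
                             collapse = " | "))
  )
  warn_rows <- list()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  collect_warning <- function(stage, msg) {
    warn_rows[[length(warn_rows) + 1]] <<- data.frame(stage = stage,
                                                      message = msg)
    note("WARNING [", stage, "]: ", msg)
  }

  series_in <- config$series
  if (is.character(series_in)) series_in <- lapply(series_in, read_timeseries)
  results <- list(); fluxmaps <- list()
  phys_tables <- list(); flux_tables <- list(); edge_tables <- list()
  for (i in seq_along(series_in)) {
    s <- series_in[[i]]
    label <- if (!is.na(s$strain)) s$strain else paste0("series_", i)
    res <- withCallingHandlers(
      if (s$mode == "batch") batch_physiology(s) else chemostat_rates(s),
      warning = function(w) {
        collect_warning(paste0("rates:", label), conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    note("rates [", label, "]: mu = ", signif(res$mu, 4),
         if (s$mode == "batch") paste0(", window ", res$window[1], "-",
                                       signif(res$window[2], 4), " h") else "")
    fm <- withCallingHandlers(
      normalize_fluxes(res),
      warning = function(w) {
        collect_warning(paste0("fluxmap:", label), conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    note("balance [", label, "]: closure ", signif(fm$balance_closure, 4), "%")
    results[[label]] <- res
    fluxmaps[[label]] <- fm
    pt <- physiology_table(res); pt$series <- label
    ft <- fm$table; ft$series <- label
    ft$balance_closure <- fm$balance_closure
    et <- fluxmap_edges(fm)
    if (nrow(et)) et$series <- label
    phys_tables[[label]] <- pt
    flux_tables[[label]] <- ft
    edge_tables[[label]] <- et
  }
  if (length(phys_tables)) {
    utils::write.csv(do.call(rbind, phys_tables),
                     file.path(out_dir, "physiology.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, flux_tables),
                     file.path(out_dir, "fluxmap.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, edge_tables),
                     file.path(out_dir, "edges.csv"), row.names = FALSE)
  }

  # energetics ledger
  pH <- if (is.null(config$pH)) 5 else config$pH
  pKa <- if (is.null(config$pKa)) 4.76 else config$pKa
  ledgers <- lapply(c("native", "xfpk", "pta"), atp_cost)
  en <- data.frame(
    quantity = c(paste0("net_atp_per_acetate_", vapply(ledgers, `[[`, "", "route")),
                 "fraction_HA"),
    value = c(vapply(ledgers, `[[`, 0, "net_cost"), acid_speciation(pH, pKa)),
    detail = c(rep("mol ATP / mol acetate", 3),
               paste0("pH ", pH, ", pKa ", pKa))
  )
  if (!is.null(config$mixing)) {
    mx <- config$mixing
    fit <- solve_mixing(mx$q_ref_glucose, mx$q_ref_acetate, mx$q_observed)
    if (fit$extrapolation) collect_warning("energetics", "mixing solution extrapolates outside [0, 1]")
    en <- rbind(en, data.frame(quantity = "mixing_fraction_acetate",
                               value = fit$fraction_acetate,
                               detail = "fraction of carbon from acetate"))
    note("energetics: mixing fraction = ", signif(fit$fraction_acetate, 4))
  }
  utils::write.csv(en, file.path(out_dir, "energetics.csv"), row.names = FALSE)

  metabolites <- NULL
  if (!is.null(config$panel_test) && !is.null(config$panel_control)) {
    pt <- config$panel_test
    pc <- config$panel_control
    if (is.character(pt)) pt <- read_panel(pt)
    if (is.character(pc)) pc <- read_panel(pc)
    metabolites <- compare_panels(pt, pc)
    utils::write.csv(metabolites, file.path(out_dir, "metabolites.csv"),
                     row.names = FALSE)
    note("metabolites: ", sum(metabolites$tier != ""), " of ",
         nrow(metabolites), " metabolites significant")
  } else {
    note("metabolites: no panel supplied; stage skipped")
  }

  warn_df <- if (length(warn_rows)) do.call(rbind, warn_rows) else
    data.frame(stage = character(), message = character())
  utils::write.csv(warn_df, file.path(out_dir, "warnings.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(physiology = results, fluxmaps = fluxmaps,
                 energetics = en, metabolites = metabolites,
                 warnings = warn_df, log = log_lines))
}
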