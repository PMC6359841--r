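# C-mol flux maps, carbon-balance closure and respiration partitioning.

#' Normalise specific rates to the glucose-uptake C-flux
#'
#' Converts every specific rate of a [physiology_result()] into C-mmol
#' gCDW^-1 h^-1 and expresses it as a percentage of the glucose uptake
#' carbon flux: `normalized_i = 100 |q_i| C_i / (|q_glc| * 6)`. Biomass
#' uses `q_biomass` directly (already C-mmol). Glucose itself is 100% by
#' definition. Fluxes below 0.1% are retained in the data; suppression is a
#' rendering decision only (see [fluxmap_edges()]).
#'
#' @param result A [physiology_result()] containing a `glucose` rate.
#' @param registry Compound registry resolving every rate.
#' @return Object of class `flux_map`: `table` (data.frame with compound,
#'   q_mmol, q_cmol, normalized_pct, direction), `balance_closure` (%),
#'   `respiration_fraction` (% of glucose carbon, when CO2 is present) and
#'   `q_glc_cmol`.
#' @examples
#' normalize_fluxes(reference_physiology("xfpk", "batch"))
#' @export
normalize_fluxes <- function(result, registry = compound_registry()) {
  stopifnot(inherits(result, "physiology_result"))
  if (!"glucose" %in% names(result$q) || result$q[["glucose"]] == 0) {
    stop("normalization error: glucose uptake rate missing or zero")
  }
  q_glc_cmol <- abs(to_cmol_flux(result$q[["glucose"]], "glucose", registry))
  rows <- lapply(names(result$q), function(nm) {
    qc <- to_cmol_flux(result$q[[nm]], nm, registry)
    data.frame(
      compound = nm,
      q_mmol = result$q[[nm]],
      q_cmol = qc,
      normalized_pct = 100 * abs(qc) / q_glc_cmol,
      direction = if (result$q[[nm]] < 0) "consumed" else "produced",
      row.names = NULL
    )
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(
    compound = "biomass", q_mmol = NA_real_, q_cmol = result$q_biomass,
    normalized_pct = 100 * result$q_biomass / q_glc_cmol,
    direction = "produced"
  ))
  out_rows <- tab$direction == "produced" & is_carbonaceous(tab$compound, registry)
  closure <- sum(tab$normalized_pct[out_rows])
  resp <- NA_real_
  if ("co2" %in% tab$compound) {
    q_etoh <- if ("ethanol" %in% names(result$q)) result$q[["ethanol"]] else 0
    resp_cmol <- to_cmol_flux(result$q[["co2"]], "co2", registry) -
      0.5 * to_cmol_flux(q_etoh, "ethanol", registry)
    resp <- 100 * resp_cmol / q_glc_cmol
  }
  fm <- structure(
    list(table = tab, balance_closure = closure,
         respiration_fraction = resp, q_glc_cmol = q_glc_cmol),
    class = "flux_map"
  )
  if (closure < 90 || closure > 110) {
    warning(sprintf("carbon-balance closure %.1f%% outside the 90-110%% band", closure))
  }
  fm
}

is_carbonaceous <- function(compounds, registry) {
  vapply(compounds, function(nm) get_compound(registry, nm)$carbon_number > 0,
         logical(1))
}

#' @export
print.flux_map <- function(x, ...) {
  cat(sprintf("<flux_map> closure %.1f%%, respiration %.1f%% of glucose C\n",
              x$balance_closure, x$respiration_fraction))
  tab <- x$table
  tab$q_cmol <- round(tab$q_cmol, 3)
  tab$normalized_pct <- round(tab$normalized_pct, 2)
  print(tab)
  invisible(x)
}

#' Carbon-balance closure
#'
#' Percentage of the glucose carbon uptake recovered in all measured
#' carbon-containing products plus biomass:
#' `closure = 100 * sum(C-mmol output fluxes) / (6 |q_glc|)`. Glucose is
#' assumed to be the sole carbon input (minimal medium). Biomass and CO2
#' dominate the balance, so both must be present.
#'
#' @param result A [physiology_result()].
#' @param registry Compound registry.
#' @return Closure in percent.
#' @examples
#' carbon_balance(reference_physiology("control", "batch"))  # ~107
#' @export
carbon_balance <- function(result, registry = compound_registry()) {
  stopifnot(inherits(result, "physiology_result"))
  if (!"glucose" %in% names(result$q) || result$q[["glucose"]] == 0) {
    stop("incomplete balance: glucose uptake rate missing or zero")
  }
  if (!"co2" %in% names(result$q)) {
    stop("incomplete balance: CO2 rate missing (dominates the balance)")
  }
  if (is.null(result$q_biomass) || is.na(result$q_biomass)) {
    stop("incomplete balance: biomass rate missing (dominates the balance)")
  }
  q_glc_cmol <- abs(to_cmol_flux(result$q[["glucose"]], "glucose", registry))
  prods <- names(result$q)[result$q > 0]
  prods <- prods[is_carbonaceous(prods, registry)]
  out <- sum(vapply(prods, function(nm) {
    to_cmol_flux(result$q[[nm]], nm, registry)
  }, numeric(1))) + result$q_biomass
  100 * out / q_glc_cmol
}

#' Partition CO2 production into fermentative and respiratory components
#'
#' During aerobic fermentation, one CO2 is released per pyruvate
#' decarboxylated towards ethanol, i.e. the fermentative CO2 C-flux equals
#' half the ethanol C-flux. The respiratory CO2 flux is the remainder:
#' `q_CO2_cmol - 0.5 * q_EtOH_cmol`. (CO2 released alongside acetate via the
#' same decarboxylation step is attributed to the respiratory term here;
#' the partition convention charges decarboxylation CO2 to ethanol only.)
#' A negative remainder signals inconsistent inputs and is returned with a
#' warning.
#'
#' @param fluxmap A [normalize_fluxes()] result (used for the glucose
#'   normalisation).
#' @param result The matching [physiology_result()] (CO2 and, optionally,
#'   ethanol rates).
#' @param registry Compound registry.
#' @return List: `respiratory_co2` (C-mmol gCDW^-1 h^-1),
#'   `respiratory_fraction` (% of glucose carbon), `fermentative_co2`
#'   (C-mmol gCDW^-1 h^-1).
#' @examples
#' r <- reference_physiology("control", "batch")
#' respiration_partition(normalize_fluxes(r), r)  # 30.01 - 21.46 = 8.55
#' @export
respiration_partition <- function(fluxmap, result,
                                  registry = compound_registry()) {
  stopifnot(inherits(fluxmap, "flux_map"), inherits(result, "physiology_result"))
  if (!"co2" %in% names(result$q)) stop("CO2 rate missing")
  q_etoh <- if ("ethanol" %in% names(result$q)) result$q[["ethanol"]] else 0
  ferm <- 0.5 * to_cmol_flux(q_etoh, "ethanol", registry)
  resp <- to_cmol_flux(result$q[["co2"]], "co2", registry) - ferm
  if (resp < 0) {
    warning("ethanol-derived CO2 exceeds total CO2 flux; inputs are inconsistent")
  }
  list(respiratory_co2 = resp,
       respiratory_fraction = 100 * resp / fluxmap$q_glc_cmol,
       fermentative_co2 = ferm)
}

#' Difference of normalised fluxes between two flux maps
#'
#' @param map_a,map_b [normalize_fluxes()] results.
#' @param compound Compound present in both maps.
#' @return `normalized_a - normalized_b` in percentage points.
#' @examples
#' a <- normalize_fluxes(reference_physiology("xfpk", "batch"))
#' b <- normalize_fluxes(reference_physiology("control", "batch"))
#' flux_difference(a, b, "acetate")  # ~2.4 points
#' @export
flux_difference <- function(map_a, map_b, compound) {
  stopifnot(inherits(map_a, "flux_map"), inherits(map_b, "flux_map"))
  pick <- function(m) {
    i <- match(compound, m$table$compound)
    if (is.na(i)) stop("compound '", compound, "' missing from flux map")
    m$table$normalized_pct[i]
  }
  pick(map_a) - pick(map_b)
}

#' Flux map as an edge list
#'
#' Renders a flux map as (source, sink, percent) edges from glucose to each
#' carbon-containing product, for diagram tools. Fluxes below `min_pct`
#' (default 0.1%, the usual display convention) are omitted from the
#' rendering; the underlying data are unaffected.
#'
#' @param fluxmap A [normalize_fluxes()] result.
#' @param min_pct Display threshold in percent.
#' @return data.frame with columns source, sink, percent.
#' @export
fluxmap_edges <- function(fluxmap, min_pct = 0.1) {
  stopifnot(inherits(fluxmap, "flux_map"))
  tab <- fluxmap$table
  keep <- tab$direction == "produced" & tab$normalized_pct >= min_pct &
    tab$compound != "glucose"
  data.frame(source = "glucose", sink = tab$compound[keep],
             percent = tab$normalized_pct[keep], row.names = NULL)
}
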