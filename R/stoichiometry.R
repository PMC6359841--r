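# Elemental bookkeeping: compounds, biomass composition, reactions.

#' Standard atomic masses (g mol^-1)
#'
#' IUPAC 2021 conventional atomic weights for the elements tracked by the
#' compound registry. Fixed constants so molar masses are bit-stable.
#'
#' @format Named numeric vector (C, H, O, N, P, S).
#' @export
atomic_masses <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06
)

#' Define a compound
#'
#' A compound carries integer (or, for the biomass pseudo-compound,
#' fractional) atom counts, from which its carbon number, molar mass and
#' degree of reduction are computed. The degree of reduction uses the
#' standard convention (4C + H - 2O - 3N electrons per molecule, ammonia as
#' nitrogen reference) and is reported per C-mol; it is a diagnostic only.
#'
#' @param name Compound identifier (lower-case by convention).
#' @param c,h,o,n,p,s Atom counts per molecule (or per C-mol unit for
#'   biomass-like pseudo-compounds).
#' @return An object of class `compound` with fields `name`, `formula`,
#'   `carbon_number`, `molar_mass` and `degree_of_reduction` (per C-mol;
#'   `NA` for carbon-free species).
#' @examples
#' compound("glucose", c = 6, h = 12, o = 6)
#' @export
compound <- function(name, c = 0, h = 0, o = 0, n = 0, p = 0, s = 0) {
  formula <- c(C = c, H = h, O = o, N = n, P = p, S = s)
  if (any(!is.finite(formula)) || any(formula < 0)) {
    stop("invalid formula for '", name, "': atom counts must be finite and >= 0")
  }
  gamma <- 4 * c + h - 2 * o - 3 * n
  structure(
    list(
      name = name,
      formula = formula,
      carbon_number = unname(formula[["C"]]),
      molar_mass = unname(sum(formula * atomic_masses)),
      degree_of_reduction = if (c > 0) gamma / c else NA_real_
    ),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf(
    "<compound> %s: C%g H%g O%g N%g, M = %.3f g/mol, %g C/molecule\n",
    x$name, x$formula[["C"]], x$formula[["H"]], x$formula[["O"]],
    x$formula[["N"]], x$molar_mass, x$carbon_number
  ))
  invisible(x)
}

#' Biomass elemental composition
#'
#' Biomass is treated as a pseudo-compound of one carbon per formula unit
#' with stoichiometric indices for H, O and N per carbon. The default
#' CH1.8O0.5N0.2 is the composition commonly assumed for yeast. The C-mol
#' mass is computed from the indices (ash-free), never hard-coded.
#'
#' @param h_per_c,o_per_c,n_per_c Atoms per carbon; all must be >= 0.
#' @return Object of class `biomass_composition` with the indices and the
#'   computed `cmol_mass` (g per C-mol).
#' @examples
#' biomass_composition()            # CH1.8O0.5N0.2, ~24.63 g/C-mol
#' biomass_composition(2, 1, 0)     # CH2O, ~30.03 g/C-mol
#' @export
biomass_composition <- function(h_per_c = 1.8, o_per_c = 0.5, n_per_c = 0.2) {
  idx <- c(h = h_per_c, o = o_per_c, n = n_per_c)
  if (any(!is.finite(idx)) || any(idx < 0)) {
    stop("invalid biomass composition: indices must be finite and >= 0")
  }
  out <- structure(
    list(h_per_c = h_per_c, o_per_c = o_per_c, n_per_c = n_per_c),
    class = "biomass_composition"
  )
  out$cmol_mass <- cmol_mass(out)
  out
}

#' C-mol mass of a biomass composition
#'
#' Formula weight per carbon of a CHx Oy Nz composition:
#' `12.011 + x*1.008 + y*15.999 + z*14.007`.
#'
#' @param composition A [biomass_composition()] object.
#' @return Mass in g per C-mol.
#' @examples
#' cmol_mass(biomass_composition())  # ~24.63
#' @export
cmol_mass <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  atomic_masses[["C"]] +
    composition$h_per_c * atomic_masses[["H"]] +
    composition$o_per_c * atomic_masses[["O"]] +
    composition$n_per_c * atomic_masses[["N"]]
}

#' Default compound registry
#'
#' The extracellular species balanced in the carbon accounting (glucose,
#' ethanol, acetate, glycerol, pyruvate, succinate, CO2, O2, biomass) plus
#' the intracellular species needed to express the phosphoketolase,
#' phosphotransacetylase and acetyl-CoA synthetase reactions. Organic acids
#' are registered as their free-acid forms (HPLC quantifies total acid).
#' Biomass is a pseudo-compound of carbon number 1 with molar mass equal to
#' the C-mol mass of `composition`.
#'
#' @param composition Biomass composition, default [biomass_composition()].
#' @param extra Optional list of additional [compound()] objects (or a
#'   data.frame as produced by `as.data.frame()` on a registry) merged over
#'   the defaults, so users can extend or override entries.
#' @return Named list of `compound` objects, class `compound_registry`.
#' @export
compound_registry <- function(composition = biomass_composition(), extra = NULL) {
  cs <- list(
    compound("glucose",   c = 6, h = 12, o = 6),
    compound("ethanol",   c = 2, h = 6,  o = 1),
    compound("acetate",   c = 2, h = 4,  o = 2),
    compound("glycerol",  c = 3, h = 8,  o = 3),
    compound("pyruvate",  c = 3, h = 4,  o = 3),
    compound("succinate", c = 4, h = 6,  o = 4),
    compound("co2",       c = 1, o = 2),
    compound("o2",        o = 2),
    compound("biomass",
             c = 1, h = composition$h_per_c,
             o = composition$o_per_c, n = composition$n_per_c),
    # intracellular species: used in reaction checks only, never in
    # extracellular balances
    compound("x5p",        c = 5,  h = 11, o = 8,  p = 1),
    compound("f6p",        c = 6,  h = 13, o = 9,  p = 1),
    compound("gap",        c = 3,  h = 7,  o = 6,  p = 1),
    compound("e4p",        c = 4,  h = 9,  o = 7,  p = 1),
    compound("acetyl_p",   c = 2,  h = 5,  o = 5,  p = 1),
    compound("pi",         h = 3,  o = 4,  p = 1),
    compound("h2o",        h = 2,  o = 1),
    compound("coa",        c = 21, h = 36, o = 16, n = 7, p = 3, s = 1),
    compound("acetyl_coa", c = 23, h = 38, o = 17, n = 7, p = 3, s = 1)
  )
  names(cs) <- vapply(cs, `[[`, "", "name")
  if (!is.null(extra)) {
    if (is.data.frame(extra)) extra <- registry_from_df(extra)
    stopifnot(all(vapply(extra, inherits, TRUE, "compound")))
    names(extra) <- vapply(extra, `[[`, "", "name")
    cs[names(extra)] <- extra
  }
  structure(cs, class = "compound_registry")
}

registry_from_df <- function(df) {
  needed <- c("name", "C", "H", "O", "N")
  stopifnot(all(needed %in% names(df)))
  if (!"P" %in% names(df)) df$P <- 0
  if (!"S" %in% names(df)) df$S <- 0
  lapply(seq_len(nrow(df)), function(i) {
    compound(df$name[i], c = df$C[i], h = df$H[i], o = df$O[i],
             n = df$N[i], p = df$P[i], s = df$S[i])
  })
}

#' @export
as.data.frame.compound_registry <- function(x, ...) {
  do.call(rbind, lapply(x, function(cp) {
    data.frame(
      name = cp$name,
      C = cp$formula[["C"]], H = cp$formula[["H"]], O = cp$formula[["O"]],
      N = cp$formula[["N"]], P = cp$formula[["P"]], S = cp$formula[["S"]],
      carbon_number = cp$carbon_number,
      molar_mass = cp$molar_mass,
      degree_of_reduction = cp$degree_of_reduction,
      row.names = NULL
    )
  }))
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("<compound_registry> with", length(x), "compounds\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Look up a compound in a registry
#'
#' @param registry A [compound_registry()].
#' @param name Compound name.
#' @return The `compound` object.
#' @export
get_compound <- function(registry, name) {
  if (inherits(name, "compound")) return(name)
  cp <- registry[[name]]
  if (is.null(cp)) {
    stop("unknown compound '", name, "': not in registry")
  }
  cp
}

#' Convert a molar specific rate to a C-mol flux
#'
#' Multiplies a specific rate (mmol gCDW^-1 h^-1) by the compound's carbon
#' number, giving C-mmol gCDW^-1 h^-1. The sign convention is preserved:
#' consumption negative, production positive.
#'
#' @param q Specific rate, mmol gCDW^-1 h^-1 (vectorised).
#' @param compound Compound name or [compound()] object.
#' @param registry Compound registry used to resolve names.
#' @return C-mmol gCDW^-1 h^-1, same sign as `q`.
#' @examples
#' to_cmol_flux(21.46, "ethanol")  # 42.92
#' to_cmol_flux(-5.49, "o2")       # 0: carbon-free
#' @export
to_cmol_flux <- function(q, compound, registry = compound_registry()) {
  cp <- get_compound(registry, compound)
  q * cp$carbon_number
}

#' Define a reaction
#'
#' @param name Reaction identifier.
#' @param stoich Named numeric vector mapping compound names to signed
#'   stoichiometric coefficients (substrates negative, products positive).
#' @param atp_net Net ATP equivalents per formula turnover. ATP -> ADP
#'   counts 1 equivalent, ATP -> AMP counts 2.
#' @return Object of class `reaction`.
#' @export
reaction <- function(name, stoich, atp_net = 0) {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
  structure(list(name = name, stoich = stoich, atp_net = atp_net),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]
  rhs <- x$stoich[x$stoich > 0]
  fmt <- function(s) paste(ifelse(abs(s) == 1, names(s),
                                  paste0(abs(s), " ", names(s))), collapse = " + ")
  cat(sprintf("<reaction> %s: %s -> %s (net ATP %+g)\n",
              x$name, fmt(lhs), fmt(rhs), x$atp_net))
  invisible(x)
}

#' Default reaction registry
#'
#' The reactions around cytosolic acetyl-CoA formation:
#' * `xfpk_x5p` — phosphoketolase on xylulose-5-phosphate:
#'   X5P + Pi -> GAP + acetyl-phosphate.
#' * `xfpk_f6p` — phosphoketolase on fructose-6-phosphate:
#'   F6P + Pi -> E4P + acetyl-phosphate.
#' * `pta` — phosphotransacetylase: acetyl-P + CoA -> acetyl-CoA + Pi.
#' * `acp_hydrolysis` — promiscuous phosphatase (Gpp1/Gpp2) hydrolysis of
#'   acetyl-phosphate to acetate.
#' * `acs` — acetyl-CoA synthetase activation of acetate (ATP -> AMP,
#'   i.e. 2 ATP equivalents consumed; `atp_net = -2`).
#' * `glycolysis_pyruvate` — lumped glycolysis per pyruvate-equivalent
#'   (0.5 glucose -> pyruvate, net +1 ATP).
#'
#' @return Named list of [reaction()] objects, class `reaction_registry`.
#' @export
default_reactions <- function() {
  rs <- list(
    reaction("xfpk_x5p",
             c(x5p = -1, pi = -1, gap = 1, acetyl_p = 1)),
    reaction("xfpk_f6p",
             c(f6p = -1, pi = -1, e4p = 1, acetyl_p = 1)),
    reaction("pta",
             c(acetyl_p = -1, coa = -1, acetyl_coa = 1, pi = 1)),
    reaction("acp_hydrolysis",
             c(acetyl_p = -1, h2o = -1, acetate = 1, pi = 1)),
    reaction("acs",
             c(acetate = -1, coa = -1, acetyl_coa = 1), atp_net = -2),
    reaction("glycolysis_pyruvate",
             c(glucose = -0.5, pyruvate = 1), atp_net = 1)
  )
  names(rs) <- vapply(rs, `[[`, "", "name")
  structure(rs, class = "reaction_registry")
}

#' Check carbon conservation of a reaction
#'
#' @param rxn A [reaction()].
#' @param registry Compound registry resolving every participant.
#' @return `TRUE` iff the signed carbon sum is zero (to 1e-9).
#' @examples
#' reaction_carbon_check(default_reactions()$xfpk_x5p)
#' @export
reaction_carbon_check <- function(rxn, registry = compound_registry()) {
  stopifnot(inherits(rxn, "reaction"))
  cn <- vapply(names(rxn$stoich), function(nm) {
    get_compound(registry, nm)$carbon_number
  }, numeric(1))
  abs(sum(rxn$stoich * cn)) < 1e-9
}
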