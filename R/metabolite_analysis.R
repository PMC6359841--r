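# Sugar-phosphate fold-change statistics and thermodynamic consistency
# checks.

#' Default sugar-phosphate roster
#'
#' The twelve sugar phosphates quantified by the LC-MS/MS panel. Note that
#' acetyl-phosphate is deliberately absent: it is not quantifiable with
#' this kind of method.
#'
#' @format Character vector of metabolite abbreviations.
#' @export
sugar_phosphates <- c("G1P", "G6P", "F6P", "DHAP", "GAP", "3PGA",
                      "2PGA", "Ru5P", "R5P", "X5P", "E4P", "S7P")

#' Construct a metabolite panel
#'
#' Replicate metabolite pool sizes for one strain, in any consistent
#' per-biomass unit (e.g. umol gCDW^-1). Pool sizes must be positive and
#' each metabolite needs at least two replicates for testing.
#'
#' @param strain Strain label.
#' @param data data.frame with columns `replicate`, `metabolite`, `value`.
#' @return Object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(strain, data) {
  stopifnot(is.data.frame(data),
            all(c("replicate", "metabolite", "value") %in% names(data)))
  if (any(!is.finite(data$value)) || any(data$value <= 0)) {
    stop("all pool sizes must be positive and finite")
  }
  n_rep <- table(data$metabolite)
  if (any(n_rep < 2)) {
    stop("insufficient replicates: need >= 2 per metabolite, got ",
         min(n_rep), " for ", names(n_rep)[which.min(n_rep)])
  }
  structure(list(strain = strain, data = data), class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("<metabolite_panel> strain %s: %d metabolites x %d replicates\n",
              x$strain, length(unique(x$data$metabolite)),
              length(unique(x$data$replicate))))
  invisible(x)
}

panel_values <- function(panel, metabolite) {
  panel$data$value[panel$data$metabolite == metabolite]
}

#' Per-metabolite fold-changes between two panels
#'
#' Fold-change of arithmetic replicate means, expressed as percent of the
#' control: `100 * mean(test) / mean(control)`. Set `log_scale = TRUE` to
#' use geometric means instead.
#'
#' @param test,control [metabolite_panel()] objects sharing a metabolite
#'   roster.
#' @param log_scale Use geometric means (default FALSE).
#' @return data.frame with metabolite, mean_test, mean_control,
#'   fold_change_pct.
#' @export
fold_changes <- function(test, control, log_scale = FALSE) {
  stopifnot(inherits(test, "metabolite_panel"),
            inherits(control, "metabolite_panel"))
  mets <- intersect(unique(control$data$metabolite),
                    unique(test$data$metabolite))
  if (length(mets) == 0) stop("panels share no metabolites")
  avg <- if (log_scale) function(v) exp(mean(log(v))) else mean
  rows <- lapply(mets, function(m) {
    mt <- avg(panel_values(test, m))
    mc <- avg(panel_values(control, m))
    if (mc == 0) stop("undefined fold-change: zero control mean for ", m)
    data.frame(metabolite = m, mean_test = mt, mean_control = mc,
               fold_change_pct = 100 * mt / mc)
  })
  do.call(rbind, rows)
}

#' Significance tier from a p-value
#'
#' `**` for p < 0.001, `*` for p < 0.05, empty string otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", ""))
}

#' Welch's two-sample t-test with significance tiers
#'
#' Two-sided t-test with unequal variances assumed (Welch-Satterthwaite
#' degrees of freedom), as used for replicate metabolite-pool comparisons.
#' Wraps [stats::t.test()]. The degenerate case of two zero-variance groups
#' with equal means returns p = 1 (no evidence of difference); unequal
#' constant groups are an error.
#'
#' @param x,y Replicate values, >= 2 each.
#' @return List of class `welch_result`: `statistic`, `df`, `p_value`,
#'   `tier`.
#' @examples
#' welch_test(c(10, 11, 9, 10), c(20, 21, 19, 20))
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("insufficient replicates: need >= 2 values per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(statistic = 0, df = NA_real_, p_value = 1,
                            tier = ""), class = "welch_result"))
    }
    stop("zero variance in both groups with unequal means: test undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, tier = significance_tier(tt$p.value)),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.3f, df = %.2f, p = %.3g %s\n",
              x$statistic, x$df, x$p_value, x$tier))
  invisible(x)
}

#' Compare two metabolite panels
#'
#' The full panel comparison: per-metabolite means, standard deviations,
#' fold-change (% of control), Welch p-value and significance tier
#' (* p < 0.05, ** p < 0.001). Raw per-metabolite p-values are reported by
#' default, mirroring the usual presentation of small targeted panels; set
#' `adjust = TRUE` for Benjamini-Hochberg adjusted values in an extra
#' column.
#'
#' @inheritParams fold_changes
#' @param adjust Add a `p_adjusted` (Benjamini-Hochberg) column.
#' @return data.frame, one row per metabolite.
#' @export
compare_panels <- function(test, control, adjust = FALSE) {
  fc <- fold_changes(test, control)
  stats_rows <- lapply(fc$metabolite, function(m) {
    vt <- panel_values(test, m)
    vc <- panel_values(control, m)
    w <- welch_test(vt, vc)
    data.frame(sd_test = stats::sd(vt), sd_control = stats::sd(vc),
               p_value = w$p_value)
  })
  out <- cbind(fc, do.call(rbind, stats_rows))
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$tier <- significance_tier(out$p_value)
  out
}

#' Define an equilibrium relation
#'
#' A mass-action equilibrium `K = prod(products) / prod(reactants)`, e.g.
#' the aldolase equilibrium `K = [DHAP][GAP]/[FBP]`.
#'
#' @param name Reaction label.
#' @param products,reactants Character vectors of species names.
#' @return Object of class `equilibrium_relation`.
#' @export
equilibrium_relation <- function(name, products, reactants) {
  stopifnot(length(products) >= 1, length(reactants) >= 1)
  structure(list(name = name, products = products, reactants = reactants),
            class = "equilibrium_relation")
}

#' Fold-change required to preserve an equilibrium
#'
#' Given measured fold-changes for all but one species of an equilibrium
#' relation, returns the fold-change the remaining species would need for
#' the mass-action ratio K to stay at its reference value. For
#' `K = [DHAP][GAP]/[FBP]`, a twofold increase of both DHAP and GAP
#' requires a fourfold increase of FBP.
#'
#' @param measured Named numeric vector of fold-changes (ratios, not
#'   percent), all > 0, covering every relation species except one.
#' @param relation An [equilibrium_relation()].
#' @return Required fold-change of the unmeasured species (a ratio).
#' @examples
#' rel <- equilibrium_relation("aldolase", c("DHAP", "GAP"), "FBP")
#' equilibrium_required_foldchange(c(DHAP = 2, GAP = 2), rel)  # 4
#' @export
equilibrium_required_foldchange <- function(measured, relation) {
  stopifnot(inherits(relation, "equilibrium_relation"),
            is.numeric(measured), !is.null(names(measured)))
  if (any(measured <= 0)) stop("fold-changes must be > 0")
  species <- c(relation$products, relation$reactants)
  unknown <- setdiff(species, names(measured))
  if (length(unknown) != 1) {
    stop("underdetermined: exactly one relation species must be unmeasured, got ",
         length(unknown))
  }
  fc <- function(nm) if (nm %in% names(measured)) measured[[nm]] else 1
  prod_fc <- prod(vapply(relation$products, fc, numeric(1)))
  react_fc <- prod(vapply(relation$reactants, fc, numeric(1)))
  # K-invariance: prod_fc / react_fc == 1 after inserting the unknown
  if (unknown %in% relation$reactants) prod_fc / react_fc else react_fc / prod_fc
}

#' Triose-phosphate-isomerase equilibrium check
#'
#' The isomerisation GAP <-> DHAP equilibrates at a DHAP:GAP ratio of about
#' 20:1. Returns the observed ratio and its log2 deviation from that
#' equilibrium value.
#'
#' @param dhap,gap Pool sizes (> 0), any consistent unit.
#' @param equilibrium_ratio Literature DHAP:GAP equilibrium ratio; default
#'   20.
#' @return List: `ratio` (DHAP/GAP), `log2_deviation`
#'   (`log2(ratio / equilibrium_ratio)`).
#' @examples
#' tpi_ratio_check(20, 1)  # at equilibrium
#' tpi_ratio_check(10, 1)  # deviation -1
#' @export
tpi_ratio_check <- function(dhap, gap, equilibrium_ratio = 20) {
  if (any(dhap <= 0) || any(gap <= 0)) stop("pool sizes must be > 0")
  ratio <- dhap / gap
  list(ratio = ratio, log2_deviation = log2(ratio / equilibrium_ratio))
}
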