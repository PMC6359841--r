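---
title: "Quantitative physiology of acetate-overflowing yeast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative physiology of acetate-overflowing yeast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioflux)
```

# The problem

Expressing a heterologous phosphoketolase (Xfpk) in *Saccharomyces
cerevisiae* opens a carbon-efficient route to cytosolic acetyl-CoA: the
enzyme cleaves xylulose-5-phosphate (or fructose-6-phosphate) into
glyceraldehyde-3-phosphate (or erythrose-4-phosphate) plus
acetyl-phosphate. In a strain without a phosphotransacetylase, endogenous
phosphatases hydrolyse the acetyl-phosphate to acetate, so Xfpk expression
manifests physiologically as an acetate overflow with knock-on costs:
extra ATP to activate and respire the acetate, a proton-decoupling futile
cycle at low pH, reduced biomass yield, and perturbed sugar-phosphate
pools.

`physioflux` implements the quantitative analysis used to characterise
such strains from bioreactor data: black-box rate and yield estimation,
C-mol carbon accounting, respiration partitioning, weak-acid/ATP
energetics, a two-substrate gas-flux mixing model, and replicate
metabolite-panel statistics — together with a synthetic-data generator
that produces bioreactor series and metabolite panels with the statistical
structure the estimators assume.

# Stoichiometric foundations

All carbon accounting runs through a compound registry storing elemental
formulas; carbon numbers and molar masses are computed from fixed standard
atomic masses, never entered by hand. Biomass is a pseudo-compound
CH~1.8~O~0.5~N~0.2~ of carbon number 1, the composition commonly assumed
for yeast; its C-mol mass is

```{r}
cmol_mass(biomass_composition())  # g per C-mol, ash-free
```

We compute this ash-free (the composition carries no ash fraction) and use
it wherever growth rate is converted to a biomass carbon flux,
$q_{biomass} = \mu \cdot 1000 / M_{CDW}$ (C-mmol gCDW^-1^ h^-1^).

Organic acids (acetate, pyruvate, succinate) are registered as free acids,
matching HPLC quantification of total acid. The registry also carries the
intracellular species of the phosphoketolase (`xfpk_x5p`, `xfpk_f6p`),
phosphotransacetylase (`pta`), acetyl-phosphate hydrolysis and acetyl-CoA
synthetase (`acs`) reactions so each can be checked for carbon
conservation; these species never enter extracellular balances. ATP
bookkeeping counts ATP→ADP as 1 equivalent and ATP→AMP (the Acs reaction)
as 2.

# Rate estimation

## Batch mode

During balanced exponential growth, $X(t) = X_0 e^{\mu t}$ and every
extracellular concentration is an affine function of biomass,
$dS/dX = q_S M_S / (1000\,\mu)$. The estimators exploit this:

* `fit_mu_max()` is the least-squares slope of $\ln X$ versus time.
* `fit_specific_rate()` regresses concentration against *biomass* (not
  time) and converts the slope: $q_S = \mu \cdot \mathrm{slope} \cdot
  1000 / M_S$. Regressing on biomass avoids numerically differentiating
  noisy time-series and is exact under balanced growth; the trade-off is
  that it assumes the window really is exponential, which is why window
  selection matters.
* The exponential window, when not user-supplied, is the longest
  contiguous stretch of at least 4 points whose log-linear biomass fit has
  R² ≥ 0.995. This mirrors the usual practice of computing rates "during
  the exponential phase" while making the choice reproducible. A perfectly
  flat biomass series is defined to have R² = 1 (zero residual variance),
  so a non-growing culture yields $\mu = 0$ rather than an error.

## Gas exchange

`gas_rates()` converts off-gas mole fractions to CER and OUR using the
inlet molar gas flow from the ideal-gas law (default 30 °C, 1 atm, inlet
air with 20.95% O~2~ and 0.04% CO~2~):
$\mathrm{CER} = n_{in}(y_{CO_2,out} - y_{CO_2,in})$ and analogously for
OUR. We deliberately use the inlet flow for both streams rather than an
inert-gas balance: at respiratory quotients near 1 the outlet-flow
correction is far below sensor accuracy, and using the same linear model
in the simulator and the estimator makes parameter recovery exact —
a property the test suite checks to 10^-6^ relative error. Oxygen uptake
is reported negative (consumption), matching the sign convention of the
rate tables: consumption negative, production positive.

## Chemostat mode

At steady state $\mu = D$ by definition, glucose uptake follows the
balance $q_{glc} = -D(S_{feed} - S_{res}) \cdot 1000 / (M_{glc} X)$, and
the biomass yield is $X/(S_{feed}-S_{res})$. Residual glucose defaults to
0 g/L under glucose limitation, with a warning so the assumption is
visible in logs. `steady_state_check()` accepts a window as steady when
the fitted linear drift of both biomass and off-gas CO~2~ over one
residence time is below 5% (configurable) — the computational analogue of
requiring stable OD and CO~2~ profiles before sampling.

Replicate cultivations are pooled by `pool_replicates()` with field-wise
means and sample standard deviations (n−1 denominator).

# Carbon accounting

`normalize_fluxes()` expresses every rate as a percentage of the glucose
uptake carbon flux, $100\,|q_i| C_i / (6\,|q_{glc}|)$; biomass enters via
$q_{biomass}$ directly. The carbon-balance closure is the sum of all
normalised carbon-containing output fluxes; values outside 90–110% raise
a warning. Published closures for these cultivations run from 92% to 107%;
we report closure exactly as computed, without bias correction, because
the accounting should expose measurement bias rather than absorb it.

The respiration partition follows the convention that fermentative CO~2~
equals half the ethanol C-flux (one CO~2~ per pyruvate decarboxylated
towards ethanol):
$q_{CO_2,resp} = q_{CO_2,cmol} - \tfrac{1}{2} q_{EtOH,cmol}$. CO~2~
released by the same decarboxylation step en route to *acetate* is not
subtracted — the partition charges decarboxylation CO~2~ to ethanol only.
This is a simplification (acetate flux is ~30-fold smaller than ethanol
flux in these cultures, so the error is well under the gas-measurement
noise), and we reproduce it rather than "improve" it so that the partition
means the same thing it does in the physiology literature. A negative
respiratory remainder is returned with a warning, not an error: it signals
inconsistent inputs, which the caller should see.

With the bundled reference parameters, the respiratory fraction of glucose
carbon rises from about 9.9% (control) to about 14.9% (Xfpk strain) — a
roughly 50% relative increase — while the acetate flux rises from 1.4% to
3.8% of glucose carbon:

```{r}
ctrl <- reference_physiology("control", "batch")
xfpk <- reference_physiology("xfpk", "batch")
fm_c <- normalize_fluxes(ctrl); fm_x <- normalize_fluxes(xfpk)
respiration_partition(fm_c, ctrl)$respiratory_fraction
respiration_partition(fm_x, xfpk)$respiratory_fraction
flux_difference(fm_x, fm_c, "acetate")
```

# Energetics

## Weak-acid speciation and proton decoupling

Acetic acid crosses the membrane in its undissociated HA form. The HA
fraction follows Henderson–Hasselbalch,
$f_{HA} = (1 + 10^{pH - pK_a})^{-1}$ with pK~a~ 4.76: about 85% at pH 4
and 5% at pH 6, which is why the decoupling burden is a low-pH phenomenon.

`decoupling_atp_demand()` makes the futile-cycle argument quantitative
with the minimal defensible model: ATP demand = leak rate × HA fraction ×
per-cycle export cost. It is labelled a model, not a measurement. The
per-cycle cost (proton plus anion re-export) is not established; we
default to 1 ATP equivalent and expose it as an argument, since the
qualitative pH contrast — a ~16-fold higher burden at pH 4 than pH 6 for
the same leak — is insensitive to that constant.

## ATP route ledgers

`atp_cost()` derives net ATP per mole of acetate metabolized from the
reaction registry rather than hard-coding the answer: activation by Acs
costs 2 equivalents (ATP→AMP); acetate made the native way (via pyruvate)
has already earned 1 glycolytic ATP upstream, net cost 1; acetate made via
the phosphoketolase bypasses lower glycolysis, earns nothing, net cost 2.
A phosphotransacetylase route (acetyl-phosphate → acetyl-CoA directly)
avoids Acs entirely, net 0 — which is the engineering argument for pairing
Xfpk with Pta.

## Two-substrate mixing model

When a strain co-consumes glucose-derived carbon and its own acetate, its
specific gas flux can be treated as a linear mixture of the fluxes under
pure glucose and pure acetate limitation:
$q_{obs} = q_{glc}(1-y) + q_{ace}\,y$. `solve_mixing()` inverts this for
the acetate carbon fraction and flags solutions outside [0, 1] as
extrapolation. The reference coefficients (2.8, 7.4, 3.35) ship as
`reference_mixing()` and give y ≈ 0.12; the references are caller-supplied
arguments, not constants, because they are condition-specific
measurements. The source of the worked example does not state
unambiguously whether 2.8/7.4 are CO~2~ or O~2~ fluxes (both gases give
almost the same pair under those conditions); the model is indifferent as
long as one gas is used consistently.

# Metabolite panels

`compare_panels()` reproduces the standard targeted-panel analysis:
fold-changes as percent of control computed on arithmetic replicate means
(a log-scale option exists but is off by default, matching how such panels
are usually plotted as means ± sd), Welch's two-sided unequal-variance
t-test per metabolite, and significance tiers `*` (p < 0.05) and `**`
(p < 0.001). No multiple-testing correction is applied by default —
a deliberate mirror of how small targeted panels are conventionally
reported — but `adjust = TRUE` adds Benjamini–Hochberg adjusted values.
Internal-standard normalisation is assumed to have happened upstream as a
per-sample scalar division; since fold-changes are ratios of means, any
common scalar cancels (a property the tests check).

Two thermodynamic consistency helpers accompany the panel:
`equilibrium_required_foldchange()` solves a mass-action invariance
equation for the single unmeasured species (e.g. DHAP ×2 and GAP ×2
require F-1,6-BP ×4 to hold K = [DHAP][GAP]/[FBP] constant), and
`tpi_ratio_check()` reports the DHAP:GAP ratio against the ~20:1
triose-phosphate-isomerase equilibrium.

# The synthetic-data generator

The generator is a forward model of exactly the assumptions the
estimators make, so that parameter recovery is a meaningful end-to-end
test.

* **Batch** (`simulate_batch()`): exponential biomass, concentrations
  integrating $dS/dt = q_S X M_S/1000$, off-gas fractions from the same
  inlet-flow gas balance the estimator inverts, simulation ending at
  glucose exhaustion. Default parameters are the control strain's batch
  physiology (µ = 0.353 h^-1^, 20 g/L glucose, pH 5, 36 L/h aeration,
  0.6 L working volume, 0.25 h sampling).
* **Chemostat** (`simulate_chemostat()`): a constant steady-state window
  of ≥ 1 residence time satisfying the chemostat balances exactly at noise
  0; defaults are the control steady state (D = 0.1 h^-1^, 7.5 g/L feed,
  yield 0.479 gCDW/g).
* **Panels** (`simulate_panel()`): quadruplicate log-normal pools,
  parameterised so the arithmetic expectation equals the configured mean
  (meanlog = log(m) − sdlog²/2), hence the expected fold-change equals the
  configured map. Default fold-changes encode the phosphoketolase
  signature (X5P 0.26, F6P 0.74, GAP 2.08, E4P 5.42, DHAP 2.0, with
  secondary decreases of Ru5P, S7P and 2PGA set to 0.7/0.6/0.75 as
  plausible values where only the direction is established). Control pool
  magnitudes are order-of-magnitude plausible (µmol/gCDW scale); no
  analysis result depends on absolute pools, only on ratios.

Noise is multiplicative Gaussian per channel (CV-parameterised),
independent across channels and time points, applied in a fixed documented
order (biomass, concentrations in rate order, then the two off-gas
enrichments) so that output depends only on (scenario, seed). Replicates
are independent — replicate correlation structure is unknown and not
modelled. Off-gas noise perturbs the *enrichment* above inlet rather than
the raw fraction, keeping noisy fractions physically sensible.

Because the published batch rate set closes the carbon balance at ~107%,
the batch generator has two balance modes. `"as-printed"` uses the rates
as given, so the accountant reproduces the ~107% closure; `"closed"`
rescales the CO~2~ rate to force exact conservation, which is the mode for
conservation-property tests (closure = 100% to 10^-9^). Keeping both
modes lets the package reproduce the printed numbers *and* keep its
conservation properties testable, without pretending the printed rates
are self-consistent.

# Numerical choices and edge cases

* Atomic masses are fixed constants (IUPAC 2021 values) so molar masses
  and everything downstream are bit-stable across platforms.
* Least-squares fits are closed-form (no iterative optimisation); R² of a
  zero-variance response is defined as 1.
* Carbon conservation of reactions is checked to 1e-9; mixing-model
  singularity (equal references) is detected at 100 machine epsilons.
* Zero-variance Welch inputs: identical constant groups return p = 1
  (no evidence of difference); constant groups with different means are an
  error, since the statistic is undefined.
* Glucose trajectories are floored at 0 to avoid negative concentrations
  from floating-point undershoot at the exhaustion point.
* Steady-state drift uses a fitted linear trend rather than endpoint
  differences, so single-sample noise cannot flip the verdict.

# Problem sizes used in the test suite

The package's statistical checks run at desk scale: type-I error of the
Welch test is estimated from 10,000 null simulations at n = 4 (accepting
rates in [0.03, 0.07], since small-sample Welch is mildly conservative);
power to flag the X5P depletion (×0.26, CV 10%, n = 4) from 1,000 seeded
draws (≥ 95% required); closure-under-noise from 200 simulated batches.
These sizes make the Monte-Carlo error small relative to the acceptance
bands while keeping the whole suite at around a quarter of a minute.

# What passing tests do and do not show

The generator emulates balanced exponential growth, ideal chemostat steady
states and log-normal replicate noise. Real cultivations deviate:
diauxic/ethanol-phase kinetics (the generator can append a second
exponential segment, but this is cosmetic), ethanol stripping into the
off-gas (ignored here, as in the source analysis), CO~2~
dissolution/bicarbonate buffering, sensor drift, and correlated replicate
structure. Parameter recovery on synthetic data therefore validates the
*estimators' algebra and implementation*, not the field accuracy of the
measurements; the carbon-balance closure is the built-in diagnostic that
will flag real-world violations of the assumptions.

# Known limitations

* Black-box accounting only: no metabolic-network flux estimation (no FBA,
  no ^13^C-MFA).
* No fed-batch mode, no pH/titrant dynamics, no Monod/Crabtree switching
  kinetics.
* The decoupling ATP model is intentionally minimal; it quantifies a
  mechanism, not a fitted burden.
* Balance closure error propagation is not performed by default; replicate
  dispersion is carried through `pool_replicates()` instead.
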