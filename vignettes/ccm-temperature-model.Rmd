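---
title: "Modeling diatom CCM inorganic-carbon fluxes across temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling diatom CCM inorganic-carbon fluxes across temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmflux)
```

`ccmflux` analyses membrane-inlet mass spectrometry (MIMS) experiments on
the biophysical carbon concentrating mechanism (CCM) of a small marine
diatom acclimated to different temperatures, and embeds the measurements in
a steady-state compartment model of cellular inorganic-carbon (C~i~)
fluxes. This vignette is the package's own account of the science: the
models, their assumptions, the parameters that matter, and what the
synthetic-data tests do and do not demonstrate.

## Units

Concentrations are mol m^-3^ internally (numerically equal to mM; µM at
user interfaces where noted), time is seconds, temperature is Celsius at
every interface and Kelvin internally. Mass-transfer coefficients are
volume per cell per second (m^3^ cell^-1^ s^-1^), so `flux = f * dC` is
mol cell^-1^ s^-1^. Per-cell rates are mol cell^-1^ s^-1^ throughout.

## Carbonate system at clamped pH

The chamber and culture media are buffered (25 mM HEPES), so pH is treated
as clamped and CO~2~⇌HCO~3~^-^ interconversion becomes pseudo-first-order:
hydration at `kf` (s^-1^, acting on CO~2~) and dehydration at `kr` (s^-1^,
acting on HCO~3~^-^). `kf` combines the direct hydration channel
(Johnson's temperature law) with the hydroxylation channel
`k(CO2+OH-)*[OH-]`; `kr` is then *derived* from the equilibrium ratio
`Keq = [HCO3-]/[CO2] = K1/[H+]` by detailed balance, so `kf/kr == Keq`
holds exactly rather than to formulation accuracy.

Two stoichiometric constant sets are selectable by name and recorded in
every pipeline report:

* `"mehrbach"` (default) — the original Mehrbach constants on the **NBS pH
  scale**. The default because culture pH in this kind of experiment is set
  with a bench electrode calibrated against NBS buffers, and because it
  places the equilibrium ratio at pH 8.10, S = 35 in the ~100–130 range
  across 10–25 °C, the scale on which the rest of the analysis (e.g.
  converting a CO~2~ half-saturation into an HCO~3~^-^ one) relies.
* `"lueker"` — the Lueker refit on the total scale, for users whose pH
  measurements are total-scale. Its K~1~ is ~0.13 pK units smaller, which
  raises the implied HCO~3~^-^/CO~2~ ratio by ~35%; the model's sensitivity
  to the formulation is therefore mostly a relabeling of the pH scale, and
  we report the choice rather than resolve it.

CO~3~^2-^ is tracked in speciation (components always sum to DIC exactly)
but treated as a kinetic spectator at clamped pH: protonation equilibria
are fast relative to hydration/dehydration.

## Rate extraction from chamber traces

Per-cell rates are linear-regression slopes over the *quasi-steady tail* of
a dark or light segment — by default the final 60% of the segment, a
configurable choice standing in for "until quasi-steady state was reached".
Sign convention: evolution into the chamber positive, consumption negative.

Daily net O~2~ under a 16 h:8 h photoperiod is `(2/3)*P_light +
(1/3)*R_dark`. Gross O~2~ evolution is `net - R_dark` (respiration assumed
equal in light and dark), a stated assumption rather than a measurement.

CO~2~ vs HCO~3~^-^ uptake partitioning at light steady state (extracellular
CA inhibited) corrects the observed CO~2~ drawdown for uncatalyzed chamber
chemistry: `u_co2 = (kr*B - kf*C - dC/dt) / density`. The bulk HCO~3~^-^
series `B(t)` is reconstructed by DIC bookkeeping — the DIC loaded into the
chamber, minus carbon fixed since loading (read off the O~2~ channel at a
photosynthetic quotient of 1, exposed as `pq`), minus measured CO~2~. This
bookkeeping matters: assuming chemical equilibrium (`B = Keq*C`) would zero
the correction term by construction and misattribute nearly all CO~2~
uptake. Total C~i~ uptake is set equal to net O~2~ evolution (PQ = 1) and
`u_hco3` is the remainder, so carbon is conserved by construction. Negative
`u_hco3` beyond 5% of the total is flagged, never clipped.

Cytosolic CO~2~ follows the diffusive balance
`[CO2]cyt = [CO2]bulk - u_co2/fc`; a negative estimate is flagged as
inconsistent inputs and returned unclipped.

## The ¹⁸O/¹³C isotope-exchange model

The CA assay spikes ¹⁸O,¹³C-labeled bicarbonate (~2 mM) into unlabeled
seawater and follows the CO~2~ isotopologues at m/z 45/47/49. The forward
model tracks, per compartment (chamber, intracellular): the three labeled
CO~2~ isotopologues explicitly, and the labeled HCO~3~^-^ pool as a
concentration plus an ¹⁸O atom-count (well-scrambled pool assumption).
Every hydration carries the CO~2~ oxygens into HCO~3~^-^ plus one unlabeled
water oxygen; every dehydration removes one oxygen to water at the pool's
atom fraction and emits CO~2~ with a binomial isotopologue distribution.
Consequences, both enforced as invariants: labeled carbon is conserved
(there is no fixation in the assay model), and total ¹⁸O in the DIC pool is
non-increasing — the loss rate is exactly `kr * (HCO3 ¹⁸O atoms) / 3`,
since one of three oxygens leaves per dehydration event.

CA activity is parameterized as a catalytic acceleration `a >= 0` *added
to* the uncatalyzed rate: total rate `(1+a)*k_uncat`, identical multiplier
on both directions (CA does not shift the equilibrium). `a = 0` therefore
means "no CA, uncatalyzed chemistry persists", which is the correct reading
for compartments that simply lack the enzyme. Extracellular CA is fixed at
0 during fitting (acetazolamide present); it is a free parameter only for
inhibitor-free scenarios.

Transport couples the compartments at `fc*dC` per cell for CO~2~ (each
isotopologue independently) and `fb*dB` for HCO~3~^-^ (atoms carried in
proportion). During the cell-free phase the intracellular pools are inert.

**Estimation.** `estimate_params()` fits the forward model to the three
observed isotopologue series over (`fc`, `fb`, `ca_intracellular`) on log
scale by Levenberg–Marquardt. Residuals are weighted by signal magnitude
floored at 10% of the largest observed value — the relative-error weighting
appropriate to MIMS noise, which also keeps the decayed tails from being
ignored. Because the residual surface has a plateau in `fc` (once membrane
transfer outpaces chamber chemistry, faster transfer is invisible), the
optimizer is started from a coarse grid over (`fc`, `ca`). The
finite-difference step is set well above the ODE solver's noise floor
(`epsfcn = 1e-6`); with the default step the Jacobian would be dominated by
integration error and the fit stalls. Identifiability is reported via the
condition number of the fitted Jacobian; a cell-free trace, where the
cellular parameters have no effect, is the canonical flagged case.

**Assay design.** The packaged scenario runs 30 minutes (cells added at
300 s) with 300 samples and ~3.5×10^6^ cells mL^-1^. The duration was
chosen by a design analysis: in short (~15 min) assays `fc` is only weakly
identified at realistic noise, while the 30-minute design — typical for
this assay — separates `fc` from CA activity.

## The four-compartment steady-state flux model

Topology (fixed): bulk → surface (periplasm + frustule) → cytosol →
chloroplast stroma → pyrenoid. CO~2~ diffuses at every boundary
(coefficients `fc[...]`); HCO~3~^-^ crosses the frustule diffusively, the
plasmalemma and chloroplast envelope by irreversible Michaelis–Menten
transporters (both K~0.5~ defaults 50 µM — the data bracket them below
100 µM without pinning them — plus optional tiny passive coefficients, 0 by
default at the envelope), and moves diffusively from stroma to pyrenoid (no
membrane). Each compartment has well-mixed chemistry
`(1+a)*(kr*B - kf*C)*V`; the stroma and surface have `a = 0` (no CA — the
stroma's *uncatalyzed* conversion is retained and is what makes the
mass-balance identity below non-trivial). RuBisCO is a Michaelis–Menten
CO~2~ sink in the pyrenoid (`kcatC * abundance * C/(KC + C)`);
mitochondrial respiration is a fixed CO~2~ source in the cytosol. The model
represents the illuminated steady state only.

**Solving.** Eight unknown concentrations; the solver runs damped Newton on
log-concentrations (positivity by construction) with a numerical Jacobian,
a log-space trust region and backtracking, initialized from bulk speciation
in every compartment. If Newton stalls it falls back to time integration to
stationarity followed by a Newton polish; the integration limit from the
fixed initial condition also resolves any multiple-root ambiguity
deterministically. Convergence is declared at a maximum node residual below
10^-12^ of the largest flux magnitude; the time-integration route doubles
as an independent cross-check in the tests (agreement to <10^-6^ on random
parameter sets). A genuinely infeasible configuration — e.g. an envelope
pump capacity exceeding RuBisCO capacity into a sealed pyrenoid, which has
no steady state — errors with the residual rather than returning a
pseudo-solution.

**Derived metrics and the leak identity.** With `P` the envelope HCO~3~^-^
flux (pump plus any passive term), `F` fixation, `L_p` the net CO~2~ efflux
from the pyrenoid, and `D_st` the stroma's net dehydration, the chloroplast
balances give exactly

> `(P/F) * (1 - L_p/P) - 1 = D_st / F`.

`derived_metrics()` therefore defines `leak_per_pump` with the *pyrenoid*
CO~2~ efflux and reports the identity residual (`identity_gap`, zero to
solver precision on every converged run). The CO~2~ efflux from the
chloroplast as a whole differs from `L_p` by `D_st` — small in typical
parameterizations but, as the sealed-pyrenoid test shows, not guaranteed
to be — and is reported separately (`leak_chloroplast`).

**Calibration.** `calibrate()` adjusts only the two transporter capacities
(log scale, Levenberg–Marquardt) to reproduce observed net O~2~ evolution
and the CO~2~/HCO~3~^-^ uptake split; everything measurable (f~c~, f~b~,
CA, RuBisCO kinetics, respiration) stays fixed. Recovery of self-generated
capacities is exact to optimizer precision on clean observations and within
15% under 5% observation noise.

**Presets.** `ccm_preset(10 | 18 | 25)` are calibrated demonstration sets
reproducing the qualitative temperature pattern: CO~2~ permeability and
effective CA rates rising with temperature, ~0.7 mM cytosolic HCO~3~^-^
across temperatures, chloroplast HCO~3~^-^ rising from ~15 mM (10 °C) to
~30 mM (25 °C), pump-per-fixation ~1.6–1.8 with ~2:1 total transport per
fixation, and a shift from ~80% CO~2~ supply in the cold to ~50% warm.
Compartment volume fractions (0.5 cytosol / 0.3 stroma / 0.02 pyrenoid,
0.1 surface) are assumptions, not measurements, and are flagged as such in
every report. The transporter capacities and CA accelerations in the
presets are calibrations — the observables constrain them only jointly.

## RuBisCO kinetics across temperature

Temperature dependence uses the Arcus form `ln k = a*lnT + b/T + c`, fitted
by linear least squares in the log domain (exact through three points;
`a = 0` reduces to Arrhenius). The packaged kinetic table carries measured
assay endpoints at 10 and 25 °C (k~catC~ 0.9 → 3.3 s^-1^; K~Cair~ 22 →
55 µM) and an 18 °C row interpolated with the Arrhenius member — two
endpoints cannot constrain all three Arcus constants — flagged
`"interpolated"` in the table. Saturation arithmetic is
`s = gross/(kcat*abundance)` (an error beyond `s > 1.05`, demand exceeding
capacity); the CO~2~ concentration at RuBisCO is the Michaelis–Menten
inversion `KC*s/(1-s)`. Percent saturations are reported to the nearest
integer and concentrations to the nearest µM, matching the precision of the
source measurements.

## Transport energetics

`transport_dG()` computes `R*T*ln(ratio) + z*F*dpsi` in kJ/mol with an
explicit convention: `ratio` is destination/source, `dpsi` is destination
minus source, charge is signed, and positive ΔG means energy input is
required. For an anion entering a compartment 20 mV negative relative to
its source, the electrical term opposes entry — the convention that makes
the uphill 40-fold chloroplast case and the downhill-but-electrically-
opposed plasmalemma case both come out positive. The default temperature is
298.15 K unless a run temperature is supplied. `ccm_cost()` sums active
HCO~3~^-^ fluxes weighted by an ATP-per-ion stoichiometry table (0.5 or 1
per membrane in the literature; default 0.5 both) over fixation.

## What the synthetic data do and do not show

The generators produce dark–light–dark drawdown cycles (optionally with
stepwise DIC additions 0.08–2 mM), and isotope-exchange decays, by forward
simulation with additive (and for exchange, multiplicative) Gaussian noise
under a mandatory seed; identical scenario + seed is byte-identical. Light
rates come either from the compartment model itself (`rate_model = "ccm"`)
or from an explicit Michaelis–Menten dependence on bulk CO~2~
(`rate_model = "mm"`), the latter keeping the generating half-saturation an
explicit known truth for recovery tests.

Passing recovery tests on these data shows the estimators invert the
package's own forward models correctly under the stated noise; it does not
validate the forward models against real instruments. Real MIMS data add
features deliberately out of scope: instrument drift and calibration error,
gas consumption by the inlet, temperature transients, pH drift under
imperfect buffering, and boundary-layer chemical enhancement outside the
cell. The noise model (Gaussian, per channel) is the simplest consistent
with MIMS scatter.

## Numerical choices

* Exchange ODE: `lsoda`, rtol 10^-8^, atol 10^-12^ (configurable); the
  mixed fast-chemistry/slow-transport system is mildly stiff.
* Steady-state: Newton tolerance 10^-12^ relative to flux scale; fallback
  integration horizons 5×10^3^ then 10^5^ s.
* Optimizers: `minpack.lm` Levenberg–Marquardt on log-parameters
  everywhere; MM curve fits via `nlsLM` with self-starting values.
* All JSON report floats are serialized with 12 significant digits so rerun
  determinism is checkable.
* Problem sizes in the test-suite: exchange fits use 300-sample traces;
  solver cross-checks use 5 jittered parameter sets; titrations use 8 DIC
  steps — sizes at which every check runs in seconds on one core.

## Known limitations

* Well-mixed compartments; no spatial reaction–diffusion, no explicit
  boundary layer (the bulk–surface coefficient lumps frustule and boundary
  layer).
* The intracellular pool of the exchange assay model is a single
  compartment; the full four-compartment structure exists only in the
  steady-state model, matching the granularity at which each is
  constrained by data.
* Absolute per-arrow flux values depend on the calibrated transporter and
  CA parameters, which observations constrain only jointly; the package
  reproduces flux *structure and ratios*, and its presets are labeled
  calibrations.
* No alkalinity solving, pressure correction or freshwater carbonate
  chemistry; oxygenase kinetics and CO~2~/O~2~ specificity of RuBisCO are
  out of scope.
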