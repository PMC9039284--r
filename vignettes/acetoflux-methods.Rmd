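---
title: "Methods: chemostat rate analysis, carbon balancing and core-model FBA for gas-fermenting acetogens"
author: "acetoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemostat rate analysis, carbon balancing and core-model FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetoflux)
```

## Scope

`acetoflux` analyses steady-state chemostat cultures of gas-fermenting
acetogens (the model organism being *Clostridium autoethanogenum* grown on CO
or syngas). It covers four stages — off-gas rate inversion, C-mol carbon
balancing, core-network flux balance analysis (FBA), and growth
rate-dependent transcriptome statistics — plus a forward simulator that
generates complete synthetic datasets with known ground truth. The simulator
is first-class code: every downstream stage is validated against it, so the
whole pipeline is testable without any external data.

## Off-gas analysis

A chemostat fed at `F_in` mL/min with feed mole fractions `y_in` consumes CO
and H2 and produces CO2 and (stripped) ethanol. Because argon is inert, its
molar flow is conserved, which fixes the unknown outflow:

$$F_{out} = F_{in} \, y_{Ar,in} / y_{Ar,out}.$$

The specific rate of species $i$ then follows from the molar flow difference,
normalised by biomass:

$$q_i = \frac{|F_{in} y_{i,in} - F_{out} y_{i,out}| \cdot 60}{V_m \, V \, X}
\quad \text{(mmol/gDCW/h)},$$

with $V_m$ the molar volume, $V$ the working volume (L) and $X$ the biomass
concentration (gDCW/L). Rates are stored as positive magnitudes with an
explicit uptake/production role, so a species that switches direction across
conditions cannot silently flip sign. Flows are interpreted at 0 °C and
1 atm ($V_m = 22.414$ mL/mmol); the convention is exposed as a parameter
because metered flows are instrument-specific. Mass-spectrometer calibration
(intensity to mole fraction) is upstream of this package: inputs are already
mole fractions. Measured fractions are renormalised over the monitored
species before inversion; the inert-balance products $F_{out} y_i$ are
invariant under that rescaling.

Steady-state acceptance follows the usual practice of averaging the last
window of the trace (default four residence times, the midpoint of the
customary three-to-five working volumes) and flagging stability when every
species' coefficient of variation is at or below 2 %.

## Biomass, liquid rates and carbon balance

Biomass is derived from optical density via the strain calibration
$X = K \cdot \mathrm{OD}_{600}$ with $K = 0.23$ gDCW/L per OD unit. At
steady state a dissolved product at concentration $c$ (mM) leaves with the
liquid outflow, so $q = (D/24)\, c / X$ with the dilution rate $D$ in 1/day.
Two corrections matter for closing carbon:

* **Ethanol stripping** — volatile ethanol leaves with the off-gas; the
  stripped flux measured from the off-gas ethanol fraction is added back to
  the liquid-phase ethanol rate.
* **Dissolved CO2** — Henry's law ($K_H = 0.0246$ M/atm at 37 °C) plus the
  bicarbonate fraction $10^{\mathrm{pH} - pK_{a1}}$ ($pK_{a1} = 6.30$). At
  the cultivation pH of ~5 the bicarbonate term is a ≤ 6 % correction. The
  liquid-phase CO2 outflow is added to the CO2 product term (rather than
  subtracted from the gas-phase rate); either bookkeeping closes the same
  balance, and the product-side convention keeps all outputs non-negative.

The C-mol balance distributes substrate carbon (CO, plus cysteine when fed;
carbon counts CO = CO2 = 1, acetate = ethanol = 2, 2,3-butanediol = 4,
cysteine = 3) over products. The biomass term uses a carbon content of
0.0417 C-mol/gDCW (24 g/C-mol, generic CH1.8O0.5N0.2); the value is
config-exposed because elemental composition is strain- and
condition-dependent. Recovery is the summed product fraction; normalised
fractions rescale to exactly 100 % so distributions are comparable across
conditions. Cysteine uptake defaults to zero with a configuration hook,
since medium-specific uptake is usually small and rarely measured.

## The core metabolic model

Instead of a full genome-scale reconstruction, the package builds a curated
~35-reaction model of the Wood-Ljungdahl pathway (WLP) and its redox/energy
periphery, at the resolution at which the flux story of CO/syngas
fermentation is usually told:

* CO oxidation: `CODH` (CO + H2O + Fd_ox → CO2 + Fd_red + 2 H+).
* Methyl branch: CO2 → formate either through NADPH-dependent formate
  dehydrogenase (`rxn00103_c0`) or directly with H2 through the
  formate-H2-lyase activity of the HytA-E/FdhA complex (`rxn08518_c0`);
  then formate → formyl-THF (ATP) → methylene-THF (NADPH) → methyl-THF via
  the NADH-dependent, ferredoxin-reducing methylene-THF reductase
  (electron-bifurcating MTHFR).
* `leq000001`: the electron-bifurcating hydrogenase
  (2 H2 + Fd_ox + NADP+ → Fd_red + NADPH + H+).
* Acetyl-CoA synthase (`ACS`), PTA/ACK (substrate-level ATP), AOR + ADH
  (ethanol via acetate, the dominant route in acetogens), ADHE (direct
  acetyl-CoA route), PFOR and ALS/ALDC/BDH for 2,3-butanediol.
* Energy conservation: Rnf translocating 2 H+ per Fd_red oxidised, ATP
  synthase at 4 H+/ATP, Nfn transhydrogenase, and an ATP-maintenance drain.

Reaction identifiers `rxn00103_c0`, `rxn08518_c0` and `leq000001` are kept
as the community database names of these activities. ADH and BDH default to
NADPH (primary–secondary alcohol dehydrogenase chemistry) with a switch to
NADH. All internal reactions are irreversible in their physiological
direction; this removes transhydrogenation futile cycles that would
otherwise make "maximise ATP dissipation" ill-posed on a model without
thermodynamic constraints.

Every metabolite carries carbon atoms and a degree of reduction
(electrons per mole, with CO2/H2O/H+/NH3/H2S as zero references: CO and H2
carry 2, acetate 8, ethanol 12, 2,3-butanediol 22). Every internal reaction
is checked for exact carbon and electron balance at build time, and the
biomass pseudo-reaction balances by construction, so electron conservation
over the exchange fluxes is a theorem, not an aspiration — the test suite
verifies it on optimal solutions.

### Biomass composition

One gDCW drains 15 mmol acetyl-CoA + 3.9 mmol pyruvate (0.0417 C-mol),
12 mmol NADPH and 85 mmol ATP. The ATP coefficient bundles polymerisation
and anabolic costs; published growth-associated maintenance values for
bacteria span roughly 40–100 mmol/gDCW, and 85 was calibrated once from the
closed-form cofactor balance at the reference steady states so that the
estimated non-growth maintenance lands in the experimentally reported range
(about 10 mmol ATP/gDCW/h at fast growth, with maintenance ~30 % of total
ATP production). Absolute maintenance numbers inherit this
composition uncertainty; relative trends across conditions do not.

### FBA procedures

`fba()` solves max/min of one flux subject to $S v = 0$, bounds and extra
linear constraints. Because FBA optima are typically degenerate, a secondary
minimisation of $\sum_i |v_i|$ among the optima makes the reported flux
vector reproducible. The LP itself is solved by a dense two-phase primal
simplex with Bland's anti-cycling rule implemented in the package; fixed
variables are eliminated and the conserved-moiety rank deficiency of $S$ is
removed by QR row reduction, with dropped rows re-checked on the returned
solution. Solver correctness is pinned against a brute-force
vertex-enumeration oracle on toy networks in the tests. Tolerances:
steady-state residual ≤ 1e-6, bounds respected to 1e-9; infeasibility and
unboundedness are explicit statuses, never silent.

* **Flux estimation** (`estimateFluxes`): all measured exchange rates and
  the growth rate are fixed within a relative band (default ±2 %; measured
  rates never close balances exactly), and ATP dissipation (the maintenance
  flux) is maximised. The optimal maintenance flux is the reported
  maintenance-ATP estimate.
* **Phenotype prediction** (`predictPhenotype`): substrate uptake ceilings
  and a fixed maintenance flux; biomass maximised. Without further
  constraints this predicts no reduced by-products (all carbon to acetate,
  the ATP-optimal solution) — reproducing a known failure mode of
  unconstrained acetogen FBA. The documented fix couples carbon and redox
  metabolism of H2: `rxn00103_c0` is zeroed and
  `rxn08518_c0 = r · leq000001`. The default $r = q_{H2}/q_{CO}$ normalises
  H2 availability per CO consumed, but on this core model that mapping pins
  the methyl-branch flux so low that the maintenance load cannot be carried
  and the LP correctly reports infeasibility; `couplingRatio` is therefore
  exposed, and feasible couplings (for example $q_{CO}/q_{H2}$) yield
  predictions with non-zero ethanol. The exact functional form is an open
  interpretation, and the package treats it as such.
* **Theoretical CO2 dissipation** (`theoreticalCO2Loss`): biomass off, one
  product open, product maximised at fixed feed. The electron balance alone
  dictates the classic results — ethanol from pure CO emits 2/3 of the
  carbon as CO2 (6 CO + 3 H2O → ethanol + 4 CO2), at CO:H2 = 2 exactly half
  (4 CO + 2 H2 → ethanol + 2 CO2), and acetate from pure CO half
  (4 CO + 2 H2O → acetate + 2 CO2); the FBA reproduces them from the
  network rather than from the shortcut arithmetic.

Derived statistics summarise redox and energy provenance: the CODH share of
total ferredoxin reduction, the ATPase:acetate-kinase ratio of the two
ATP-producing fluxes, the maintenance share of total ATP production and the
WLP (ACS) flux. One resolution effect deserves note: with the 2 H+/Fd_red
and 4 H+/ATP stoichiometries, maximal ATP dissipation routes methyl-branch
CO2 reduction through NADPH-FdhA rather than the H2-dependent lyase on
syngas (the two differ by 0.125 ATP per formate on this network), so
estimate-mode flux maps carry the FdhA route; the H2 route appears under
the prediction-mode coupling constraint.

## The synthetic-data generator

The generator's defaults are the study conditions: 23 steady states across
two feed gases (CO: 60 % CO/40 % Ar; syngas: 50 % CO, 20 % H2, 20 % CO2,
10 % Ar), three dilution rates (~1.0, 2.0, 2.8 1/day) at 50/72/72 mL/min
feed flow, 0.75 L working volume, biomass held near 1.4–1.7 gDCW/L, with
4/3/3 and 6/3/4 bioreplicates.

A condition's ground truth is built by closure, not by free choice: the
inputs are mu, the substrate uptake rates, the molar acetate/ethanol ratio
and the 2,3-butanediol rate (chosen once to track the reference study's
magnitudes: CO uptake rising from ~32 to ~70 and ~25 to ~73 mmol/gDCW/h,
H2 from 7 to 21, acetate/ethanol falling with mu, 2,3-butanediol rising on
syngas). The degree-of-reduction balance then fixes total acetate + ethanol,
the carbon balance fixes CO2, and closed-form cofactor bookkeeping of the
core network (full AOR ethanol route; under maximal ATP dissipation the
NADPH route for CO2 reduction) yields the maintenance ATP. This hand
derivation is independent of the LP solver, so "maintenance recovered
within 2 %" is a genuine dual-route check, and the carbon fractions sum to
1 exactly, so noise-free recovery must be 100 ± 0.5 %.

Measurement noise is multiplicative Gaussian (default 2 % relative SD,
matching the few-percent replicate scatter typical of steady-state
chemostats) applied per MS channel and HPLC value; noise-free traces
satisfy the mole balances exactly. A configurable 5 % of produced ethanol
is stripped to the off-gas so the stripping correction is exercised; the
real stripped share depends on gassing rate and temperature and is not a
reported quantity.

RNA-seq counts are negative binomial (default dispersion 0.01 — steady-state
chemostat replicates are highly reproducible) with library sizes uniform on
5.6–9.3 million reads. Gene classes: flat; up/down genes whose log2
expression is linear in mu with the same slope on both gases (the
tight-control truth); and gas-divergent genes with opposite slopes. Planted
full-range effects of 1.5–3 log2 units with this dispersion give an oracle
t-test power above 0.9 for the extreme-mu comparison, which is the
calibration rule used for the defaults. The default gene count is 2,000
(desk scale) against the organism's ~4,000; annotation mocks provide 50
GO-like terms (5–200 genes) with a known enriched subset among the slope
genes, and random COG letters.

What the generator does *not* emulate: transcript-level coverage biases,
TMM-style composition normalisation (library-size CPM only), gas-transfer
dynamics (kLa), transients, and correlated replicate effects. Passing tests
therefore demonstrate algorithmic correctness against a clean generative
model, not robustness to every artefact of real sequencing or off-gas data.
One such artefact is deliberately present: gas-divergent genes shift the
CPM normalisation differently per gas, a composition bias that the
slope-equality test detects at very low dispersion.

## Transcriptome statistics

RPKM is `counts * 1e9 / (librarySize * length)`; genes with > 10 RPKM in at
least two samples (strict inequality) enter testing. Differential calls use
a Welch t-test on log2(CPM + 0.5) between mu levels within one gas
(cross-gas comparisons are refused by design), Benjamini-Hochberg
adjustment, and the DEG rule |FC| > 1.5 with q < 0.05. This is a
deliberately simplified engine relative to moderated-statistics packages:
validation is against synthetic truth (null false-positive fraction ≤ 1 %,
recall ≥ 0.8 and precision ≥ 0.9 on planted effects), not bit-parity with
any particular implementation. The 0.5 pseudo-count is the conventional
log-offset choice.

Expression profiles of DEGs are row-z-scored and clustered with Ward.D2 on
Euclidean distance; the cluster count is chosen at the sharpest relative
drop of the dendrogram merge heights (ties resolve to the smaller count),
and zero-variance profiles are excluded with a warning before z-scoring.
Enrichment is classic one-sided Fisher (hypergeometric tail) per term with
BH adjustment and a q < 0.05 significance label; elim/weight-style GO
algorithms are out of scope, and COG classes reuse the same machinery with
letters as terms.

Tight-control selection (genes whose expression tracks mu identically on
both gases) proceeds in three steps: (1) DEG in both consecutive
comparisons on both gases with one monotone direction; (2) per-gas OLS
slope of log2 CPM against mu (log scale, since effects are multiplicative);
(3) a slope-equality t-test with Welch-Satterthwaite degrees of freedom.
Whether "same trend on both gases" should retain genes for which slope
equality is *not* rejected (p ≥ 0.05) or the opposite is a genuine design
choice; the non-rejection reading matches the selection's intent and is the
default, while the alternative is available via `polarity = "different"`.

## Pipeline and problem sizes

`runPipeline()` executes simulate → rates → balance → fluxes →
transcriptome → report with a single global seed; identical seeds give
byte-identical payloads, and failures abort naming the stage. All
thresholds live in the configuration with the defaults above. The default
desk-scale run (2,000 genes, 3 RNA replicates per condition, 23 chemostat
replicates) completes in well under a minute; the test suite's shared
fixtures use 400–2,000 genes, which is where the statistical checks
stabilise without waste.

## Known limitations

* Absolute maintenance-ATP values carry biomass-composition uncertainty
  (see above); cross-condition trends are the robust output.
* The coupling-constraint mapping for H2-dependent CO2 reduction is an
  interpretation; the default reproduces the documented wording and may be
  infeasible on this core network.
* The DEG engine is unmoderated; for small replicate numbers with real
  data, moderated-variance methods will be more powerful.
* No thermodynamic or kinetic constraints: product inhibition at high
  ethanol/acetate is outside the model.
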