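---
title: "Model, estimation and sensitivity methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimation and sensitivity methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vegftrap)
```

`vegftrap` simulates VEGF transport and kinetics in a mouse bearing a
human tumor xenograft, and the action of the decoy receptor VEGF Trap
(aflibercept). This vignette is the package's account of the science:
the model and its assumptions, the parameters that matter, the
numerical choices, what the synthetic-data machinery does and does not
establish, and the known limitations.

## Compartment structure

The body is reduced to three well-mixed pools — normal tissue (taken to
be skeletal muscle), blood (plasma), and tumor — exchanging soluble
species across the endothelium. For a tissue with vessel surface
density $S$ (cm$^2$/cm$^3$) and available interstitial fluid fraction
$K_{av}$, the transendothelial flux of a species with permeability
$k_p$ (cm/s) is

$$J = k_p\, S\, \bigl(C_{blood} - C_{tissue}/K_{av}\bigr)$$

per cm$^3$ of tissue; lymphatic drainage returns interstitial fluid to
blood at $k_L$ (cm$^3$/s per cm$^3$ tissue, one-way), plasma clearance
removes soluble species from blood ($c_V$ for VEGF, $c_A$ for the free
drug, $c_{VA}$ for the drug complex), and free interstitial VEGF is
proteolysed at $k_{deg}$. Well-mixedness is a modelling commitment:
there is no spatial capillary-spacing model, and intra-tissue gradients
are invisible by construction.

Concentrations are carried internally as mol/cm$^3$ of the owning
compartment's reference volume (tissue volume for interstitial and
surface species, plasma volume for blood). Interstitial binding is
corrected by $K_{av}$ so that rates operate on concentrations in the
fluid actually accessible to VEGF.

## Species and reactions

The network is generated by rules, not written by hand. Mouse isoforms
VEGF120/164 and human VEGF121/165 circulate everywhere; the longer
isoforms carry the heparin-binding domain, which is what licenses
binding to neuropilins and to matrix glycosaminoglycan (GAG) sites in
the extracellular matrix and the endothelial/parenchymal basement
membranes — the short isoforms never acquire those reactions.
Cell-surface receptors (VEGFR1, VEGFR2, NRP1, and NRP2 on tumor cells)
bind all four isoforms through a rate table keyed by interaction
*class*, so mouse/human cross-pairings share rates. VEGFR2–NRP coupling
is generated through both association routes with rates chosen so the
thermodynamic cycle closes exactly; VEGFR1–NRP coupling reuses the
unligated class rates for the ligated routes for the same reason.
Soluble VEGFR1 is secreted by endothelium and sequesters VEGF in every
fluid phase; alpha-2-macroglobulin (native and protease-activated) is
confined to blood by its size; the Trap forms 1:1 complexes with all
four isoforms wherever it reaches. `validate_network()` checks
component mass balance of every generated reaction, the absence of
orphan species, and the consistency of each reaction's $K_d$ with the
configured table.

### The enumeration convention

The canonical xenograft configuration enumerates 53 species for the
normal compartment, 126 for blood and 79 for the tumor — 258 state
equations, with the tumor volume as one additional equation. Because
species bookkeeping conventions are never unique in this model family,
the convention is explicit and auditable (`network_audit()` prints
every locale with its members):

- *Normal (53)*: 14 interstitial soluble species (4 VEGF, Trap, 4
  Trap complexes, sVEGFR1, 4 sVEGFR1 complexes), 3 matrix species in
  each of ECM/EBM/PBM, and 15 species on each of the myocyte and
  abluminal endothelial surfaces.
- *Blood (126)*: 24 plasma species (the 14 above plus two
  alpha-2-macroglobulin forms and their 8 VEGF complexes), and, per
  endothelial bed (normal-tissue and tumor vasculature), a luminal
  surface of 17 species — the 15-species surface set plus VEGFR1–NRP1
  coupling and sVEGFR1 captured on NRP1 — mirrored by explicit
  endosomal and recycling pools (3 × 17 × 2 beds). Endothelial
  receptor trafficking is assigned to blood because the endothelium is
  part of the vasculature; parenchymal surfaces treat internalization
  as a first-order sink balanced by basal insertion.
- *Tumor (79)*: 14 soluble + 9 matrix species as in normal tissue; an
  abluminal tumor-EC surface of 20 species (the base set plus
  VEGFR1–NRP1 coupling with its four ligated complexes); and a
  36-species tumor-cell surface carrying NRP1 and NRP2 with
  VEGFR1–NRP coupling, sVEGFR1–NRP capture, and heparin-mediated
  anchoring of VEGF/sVEGFR1 complexes.

The choice of which optional interaction classes are active on which
surface is a reconstruction of a published structural audit, not a
claim about unique biology: the generator supports every class on any
surface, and the manifest hash pins the enumeration so any change is
visible.

## Geometry

All tumor-compartment geometric parameters are derived from primitive
measurements and carried unrounded: a 12 µm cell gives 905 µm³ and a
dodecahedral surface of 497 µm²; a 13.94 µm capillary lumen with 0.5 µm
endothelium and a 23% non-circularity correction gives a 57.7 µm true
perimeter; a 10% intravascular fraction then fixes 655 capillaries/mm²,
a 1.5% endothelial wall fraction, 53.5% tumor cells, and surface
densities of 378 (vessels) and 2939 (tumor cells) cm²/cm³. Interstitial
sub-regions contribute available fluid volumes as the product (volume
fraction) × (fluid fraction) × (partition coefficient); the package
computes these from the formula (ECM 0.2855, EBM 5.10 × 10⁻³, PBM
9.45 × 10⁻⁴ cm³/cm³) rather than asserting any printed triple, because
published available-volume triples in this model family are not always
consistent with their own stated fractions. Normal-compartment geometry
is not re-derived; it is prior-model configuration.

## Tumor growth and dosing

Tumor volume grows exponentially from an inoculation volume of
10⁻⁶ cm³; the *average* profile reaches the 100 mm³ dosing trigger in
14 days ($k = \ln 10^5/14$ d⁻¹) and the *fast* profile in 10 days.
These rate constants are the package's own calibration of the growth
window, exposed in the configuration. Composition fractions are held
constant as the tumor grows, so every tumor species (including
surface-bound) receives a dilution term $-\dot V C/V$; under pure
growth, amounts $CV$ are conserved exactly, which the tests assert.
Dosing is a 1-minute intravenous infusion: a dose $D$ (mg/kg) delivers
$D \cdot BW/MW$ moles (0.543 nmol at 2.5 mg/kg for a 25 g mouse and a
115 kDa drug) as a constant molar inflow into plasma; body weight,
molecular weight and plasma volume (~1 cm³) are configuration defaults
since the estimation, which works in moles, is insensitive to them.
Integration is restarted exactly at every infusion start and stop.

## Numerical choices

The right-hand side is compiled (Rcpp) from index arrays — bilinear
mass-action fluxes, general linear terms, zero-order sources, dilution
— and integrated with the stiff sparse solver `lsodes` at relative
tolerance 10⁻⁸ and absolute tolerance 10⁻³ pM (10⁻²¹ mol/cm³) by
default. Blood-side fluxes across the growing tumor interface scale
with $V(t)$ inside the right-hand side, so no re-assembly is needed
during growth. Steady states are found by integrating with growth
frozen over geometrically increasing horizons until the largest
relative rate of change falls below 10⁻¹² s⁻¹. The drug-free steady
state initializes every protocol; a restart test verifies it is a fixed
point. A dedicated audit state accumulates the moles of drug removed by
plasma clearance, so total drug mass (free + complexed, all
compartments, plus the cleared integral) can be checked against the
infused amount to solver tolerance.

Fitting minimizes $\mathrm{WSSR}(\theta) = \sum_i W_i (C_{exp,i} -
C_{sim,i}(\theta))^2$, $W_i = 1/C_{exp,i}$, pooling all points of all
doses with these weights only. Optimization runs in log₁₀ parameter
space under box constraints (bounded Levenberg–Marquardt,
`minpack.lm::nls.lm`) from `n_starts` log-uniform draws; the default
bounds are 1.5 × 10⁻⁶–2 molecules/cell/s for secretion (the lower bound
is the ELISA detection floor), one order of magnitude around
1.6 × 10⁻⁴ min⁻¹ for drug clearances (the 72 h serum half-life), 0.25–5
pM for the Trap $K_d$, and one order of magnitude around the baseline
permeabilities. Two numerical details matter. First, the
finite-difference step for the jacobian is set to about 1% in log₁₀
space (`epsfcn = 1e-4`): the library default of `sqrt(.Machine
$double.eps)` falls below the ODE solver's noise floor and produces
spurious convergence. Second, outcomes of individual restarts on a flat
objective (see below) are sensitive at the last floating-point digit,
which is precisely why the estimate is reported as mean ± SD over
restarts rather than as a single optimum; non-convergent runs are
excluded from the summary but counted in the report.

## Synthetic data and what recovery does (and does not) show

No experimental measurements ship with the package. The
`generate_plasma_dataset()` module simulates the dosing protocol at a
known truth and samples plasma free Trap and the mouse- and human-VEGF
complexes on a twice-weekly, two-week design at 2–3 reads per week,
with mean-preserving multiplicative log-normal noise (concentrations
are positive and assay CVs are roughly proportional; the noise model is
this package's choice). The default truth for recovery experiments is
the A673-like secretion triple (0.011, 0.009, 0.009 molecules/cell/s
for muscle, endothelium, tumor).

Recovery on this synthetic data validates the estimation *machinery*:
with zero noise, the tumor secretion rate is recovered to well under 1%
with restart SDs of order 10⁻⁵, because the human-VEGF complex in
plasma is a direct, monotone readout of tumor secretion that nothing
else can produce. Muscle secretion, by contrast, is structurally
unidentifiable from plasma data — endothelial secretion can compensate
for it almost exactly; sweeping it from 0 to 0.02 molecules/cell/s
changes the objective by a vanishing fraction of the weighted data
magnitude, and restarts either scatter over orders of magnitude or run
to a bound with an equally good fit. Passing these tests shows the
estimator and the identifiability structure behave correctly *within
the model*; it says nothing about how well the model's rate table or
geometry describe any particular animal, and noiseless recovery bounds
are not error bars for real assays.

## eFAST sensitivity analysis

The extended Fourier Amplitude Sensitivity Test drives each parameter
along a sinusoidal search curve through its range,
$x(s) = \tfrac12 + \tfrac1\pi \arcsin(\sin(\omega s + \varphi))$, with
the parameter of interest at a high frequency $\omega_{max}$ and the
complementary set at low frequencies. The partial variance at the
interest frequency is $D_i = 2\sum_{p=1}^{M}(A_{p\omega}^2 +
B_{p\omega}^2)$ from the Fourier cosine/sine coefficients, the total
variance is the same sum over the full spectrum, and the indices are
$S_i = D_i/D_{total}$ and $S_{Ti} = 1 - D_{c i}/D_{total}$ where the
complementary variance is read below $\omega_{max}/2$. Defaults are
$M = 4$ harmonics, the Nyquist-minimal $N_s = 4M\omega_{max} + 1$
samples per curve, and $N_r = 5$ random-phase resample curves.
Complementary frequencies are spread over $[1, \omega_{max}/(4M)]$
rather than the customary $[1, \omega_{max}/(2M)]$: the tighter cap
keeps low-order combination tones of complementary parameters below
$\omega_{max}/2$, which removes a bias in $S_{Ti}$ that appears for
strongly interacting test functions. The estimator reproduces analytic
first-order indices of additive linear models to well under 0.02 and
the closed-form indices of the standard three-parameter oscillatory
benchmark to 0.03.

The modular analysis (`run_module_analysis()`) applies eFAST to the
steady-state mouse/human VEGF and sVEGFR1 concentrations per
compartment, over editable parameter groups (receptor expression,
transport, kinetics) spanning one order of magnitude either side of
baseline on a log scale, with the tumor held at the trigger volume.
Because each sample is a full steady-state solve, its default design is
deliberately small ($\omega_{max} = 8$, $N_r = 1$); group membership
and ranges are configuration, and the exact published bar heights of
any particular figure are outside what defaults this coarse can be
expected to reproduce.

## Scale of the shipped tests

The test suite runs the estimation acceptance at a reduced but
structurally faithful design — one dose level, ten sampling times,
three observables, three restarts — and the full protocol (steady
state, 14-day growth, twice-weekly dosing) for every simulation check;
the complete suite executes in a few minutes on one core. The
command-line defaults (20 restarts, all five dose levels) match the
published estimation protocol.

## Known limitations

- Normal tissue is a single muscle-like compartment; other organs'
  secretion and uptake are absorbed into its parameters.
- Only VEGF120/121 and VEGF164/165 are modelled; VEGF188/189, the
  anti-angiogenic xxxb splice forms, other VEGF-family ligands, and
  platelet VEGF are out of scope, as are drug effects on tumor growth
  and vascular permeability (the tumor keeps growing under treatment).
- Tumor composition fractions are frozen as the tumor grows.
- Kinetic rates and receptor densities are prior-model defaults keyed
  by interaction class; with them, the simulated host-VEGF drug complex
  does not dominate the tumor-VEGF complex at late times the way
  published xenograft measurements suggest it should — users fitting
  real data should expect to re-estimate secretion, clearance and
  affinity rather than rely on these defaults.
- The enumeration convention behind the 53/126/79 split (endothelial
  trafficking pools in blood; NRP-coupling classes active on tumor and
  luminal surfaces only) is one reconstruction of a published audit;
  the manifest makes it inspectable rather than canonical.
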