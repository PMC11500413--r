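---
title: "Methods: a generic PBK model for organophosphate pesticides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a generic PBK model for organophosphate pesticides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science of `pbkop`: the model structure and its
assumptions, where every parameter comes from, the numerical choices, what
the synthetic data generator does and does not emulate, and the design
decisions taken where the design was genuinely open. It states no empirical
result that the test-suite or `scripts/acceptance.R` does not itself
compute.

## 1. Model structure

The simulator targets organophosphate (OP) pesticides after a single oral
or intravenous dose in rat or human. A *compound family* consists of up to
three simulated chemical species — the parent organothiophosphate (OTP) or
oxon-type parent, the bioactive oxon (OPO), and one lumped urinary
metabolite — connected by Michaelis–Menten reactions.

**Gut.** Oral dosing uses a compartmentalized stomach–intestine chain:
stomach (first-order gastric emptying, rate GER), seven equal
small-intestine segments in series (per-segment transit rate $k_{t\text{-}SI}$),
colon and feces. OPs are lipophilic and assumed to be absorbed only where
bile acids are active, i.e. from the small intestine: each segment loses
drug at the first-order absorption rate $k_a$, and all absorbed material
enters the liver directly. Competition between absorption and transit gives
the closed-form absorbed fraction

$$f_a \;=\; 1 - \left(1 + \frac{k_a}{k_{t\text{-}SI}}\right)^{-7},$$

which the gut ODEs reproduce exactly (an acceptance oracle). Note the
convention: $k_{t\text{-}SI}$ is the *per-segment* rate, so the mean
small-intestinal residence time is $7/k_{t\text{-}SI}$. The same result is
often written $1-(1+k_a/(7k_t^*))^{-7}$ with $k_t^*$ the whole-intestine
rate; both are identical under $k_t^* = k_{t\text{-}SI}/7$.

**Distribution.** Each chemical species distributes over six
perfusion-limited tissues (liver, kidney, brain, fat, slowly perfused =
muscle/skin/bone, rapidly perfused = remaining viscera) connected by a
single blood compartment:
$\mathrm{d}A_T/\mathrm{d}t = Q_T\,(C_b - C_T/(K_{p,T}/\mathrm{BPR}))$.
Blood-flow limitation is the conventional assumption for small lipophilic
molecules; brain and fat are separated because the brain is the toxicity
target and fat is the depot for lipophilic OPs. Blood vs plasma
concentrations are related by the blood:plasma ratio (BPR).

**Metabolism.** The OTP undergoes hepatic CYP450 oxidative desulfuration
(to the OPO) and oxidative cleavage (to the urinary metabolite); the OPO
undergoes hepatic cleavage plus PON1-mediated hydrolysis in liver and
plasma; PON1 action on OTPs is not modeled (reported negligible), and
urinary metabolites undergo no further metabolism. Every reaction is
$v = V_{max} C/(K_m + C)$ with 1:1 molar stoichiometry: the flux leaves the
substrate's liver (or blood, for plasma PON1) compartment and enters the
product's liver (or blood) compartment. Products that are not themselves
simulated (e.g. PON1 hydrolysis products) flow into explicit terminal mass
sinks.

**Excretion.** Passive renal clearance is glomerular filtration of unbound
plasma drug, $GFR \cdot f_{up} \cdot C_{plasma}$, taken from the blood
compartment's plasma. Conjugated phenolic metabolites are actively
secreted; this is encoded by a GFR multiplication factor (below).

## 2. Parameterization

**Physiology.** Species templates carry body-weight-relative quantities:
tissue volumes as fractions of BW (density 1 kg/L), flows as fractions of
cardiac output (normalized to sum to 1), cardiac output
$= a\,BW^{0.74}$ (exponent configurable; 14.1 and 15.0 L/h/kg^0.74 for rat
and human), GFR linear in BW (0.62 / 0.103 L/h/kg), gastric emptying 2.77/h
(≈15 min half-life), small-intestine segment transit 4.76/h (rat, ≈1.5 h
total) and 2.11/h (human, ≈3.3 h), colon emptying 0.25 / 0.055 per h, and
protein scaling factors (32 mg microsomal, 80.7 mg cytosolic protein per g
liver; plasma fraction of blood 0.54 / 0.55). These are standard
adult-reference values assembled from the usual physiology compilations and
are deliberately *editable defaults*: the source publication's own
parameter tables are supplementary material that is not reproduced here.
Rat defaults skew male and human defaults skew Caucasian; a single template
per species is provided (no sex-specific physiology), matching the
assumption of minimal interindividual variability.

**Fraction unbound (fup).** Modeled as a logistic function of the pH 7.4
distribution coefficient with charge-class-specific coefficients,
$f_{up} = (1 + 10^{a + b\,\log D_{7.4}})^{-1}$ — the class-specific
lipophilicity-regression structure of the published plasma-protein-binding
QSPR family used for this kind of model. The original coefficients are not
reprinted in the source and were not retrievable offline, so the defaults
($a,b$: neutral −0.51, 0.50; acid 0.06, 0.43; base −0.40, 0.42) were chosen
once to reproduce typical binding magnitudes (e.g. ≈4% unbound at
log P 3.8 neutral) and are exposed in `fup_qspr_coefficients()`. Tests pin
the implemented formula by hand-evaluation oracles, its monotonicity in
log P, and its unit limit at vanishing lipophilicity — deliberately *not*
paper values, so the formula cannot silently drift.

**BPR.** 1 for neutral and basic compounds, 0.55 for acids (acids are
largely excluded from erythrocytes), measured overrides pass through.

**Partition coefficients.** Two tissue-composition QSPRs:

* *Lipid-partitioning (Berezhkovskiy-type), used for OTPs and OPOs*:
  $K_p = \dfrac{P(V_{nl,t}+0.3V_{ph,t}) + (V_{w,t}+0.7V_{ph,t})/f_{ut}}
               {P(V_{nl,p}+0.3V_{ph,p}) + (V_{w,p}+0.7V_{ph,p})/f_{up}}$
  with $P = 10^{\log D_{7.4}}$, $f_{ut} = (1+\tfrac{(1-f_{up})/f_{up}}{2})^{-1}$
  for non-adipose tissues and $f_{ut}=1$ for fat (no protein binding in the
  depot). The unbound fractions divide the aqueous terms only — the
  corrected form of the lipid-composition equation.
* *Charge-aware (Rodgers–Rowland-type), used for the urinary metabolites*:
  the unbound tissue:plasma ratio is assembled from extracellular and
  intracellular water (with Henderson–Hasselbalch ionization between
  intracellular pH 7.0 and plasma pH 7.4), neutral-species lipid
  partitioning, and extracellular protein binding inferred from $f_{up}$
  and scaled by tissue:plasma albumin ratios; $K_p = Kpu \cdot f_{up}$.
  Strong bases are handled by the same weak-base equation without an
  acidic-phospholipid association term — a documented limitation that is
  immaterial here because OP urinary metabolites are acids, and the method
  is anyway only used below log P ≈ 3 where its predictive power holds.

All tissue-composition constants and albumin ratios are standard rodent
reference values shipped as editable tables
(`tissue_composition_bere()`, `tissue_composition_rr()`).

**Conjugate lumping.** A urinary metabolite circulating as unconjugated,
glucuronide and sulfate forms is simulated as one species whose fup, BPR,
$k_a$ and per-tissue $K_p$ are fraction-weighted averages over the forms
(every effective parameter is a convex combination, which the tests assert).
Renal secretion of conjugates is encoded by per-form GFR factors
(unconjugated 1, glucuronide 1.6, sulfate 5.5 — cross-species values for
phenol conjugates), weighted the same way; e.g. 50/50
glucuronide/sulfate gives a multiplier of 3.55.

**Metabolic parameters.** QSPRs for metabolism are deliberately *not*
provided (none are reliable for OPs); $V_{max}$/$K_m$ come from in vitro
incubations, fitted here by untransformed nonlinear least squares (no
Lineweaver–Burk), with a direct SSR fallback optimizer for noisy small-n
designs and residual-based standard errors from the model Jacobian. In
vitro→in vivo scaling: hepatic $V_{max}$ [nmol/min/mg] × protein content
[mg/g liver] × liver mass [g] × 0.06 → µmol/h; plasma PON1 rates per mL ×
plasma volume. $K_m$ is assumed equal in vitro and in vivo.

**Absorption rate.** $k_a$ is supplied per compound: rat values are inputs
(predicted or measured elsewhere); the human default is the fitted generic
value 0.1/h, reflecting that calculated human $k_a$ values overpredict
internal concentrations.

## 3. Numerical implementation

Units are µmol, L, h, µmol/L throughout; dose conversion
(mg/kg → µmol = dose·BW/MW·1000) happens only at the boundary.

The RHS is constructed so that total molar amount over the mass-carrying
states (gut, tissues, blood, urine, feces, terminal sinks) is a *linear
invariant*: every flux appears exactly once positive and once negative.
Cumulative reaction-extent states are auxiliary (their moles are already
counted in the product compartments) and are excluded from the mass sum.

Integration uses an adaptive Dormand–Prince 5(4) pair (compiled, FSAL,
steps clamped to the requested output grid so no interpolation error enters
reported values) at rtol 1e-10 / atol 1e-12 by default. Explicit
Runge–Kutta methods conserve linear invariants to round-off; to keep the
*accumulated* round-off at the representation limit over ~10⁴ steps the
state update uses Kahan-compensated summation. Measured mass-balance errors
(recomputed by `scripts/acceptance.R`) are 0–3e-13 µmol for 0.001–100 mg/kg
oral doses in both species, i.e. at or below the 1e-12 µmol order, and the
1e-9 µmol order for the lowest dose trivially. The fastest model
eigenvalues (kidney of a low-$K_p$ metabolite, ≈500/h) are mild, so a
stiff implicit method is unnecessary; the explicit pair was chosen
precisely because implicit solves would destroy the exact linear-invariant
property that the mass-balance criterion measures.

The driving concentration of hepatic Michaelis–Menten rates is the unbound
liver concentration expressed in plasma-equivalent terms,
$C_{drv} = f_{up}\,C_{liver}/K_{p,liver}$ (plasma PON1: unbound plasma).
Unbound is the default because incubations are effectively free-drug
systems and $K_m$ is carried over unchanged; a `total` switch exists
because the choice is a genuine modelling decision, not something the
source material pins down. Other open points resolved here: absorbed flux
enters the liver directly (no explicit portal blood compartment); renal
filtration draws on the blood compartment's plasma; urinary metabolites
undergo no further metabolism; oral dosing with an absorption delay is
implemented by placing the stomach bolus at $t =$ delay (states are
identically zero before it, and the trajectory is the undelayed one
translated in time — asserted in tests).

Degenerate inputs: doses of zero are legal (all-zero trajectories);
families with a parent only reduce to distribution + renal excretion;
Michaelis–Menten fits reject all-zero rates and fewer than four points;
fold evaluation excludes (and counts) observed zeros and
predicted-zero points; within-$k$-fold bounds are inclusive (a ratio of
exactly 5 counts as within 5-fold — the conservative reading).

## 4. Sensitivity analysis

Local sensitivity coefficients are
$SC = \dfrac{\Delta C/C}{\Delta P/P}$ with a 1% forward perturbation by
default (central difference available for verification), where $C$ is the
maximum over time of the *free oxon blood concentration*, operationalized
as $f_{up}/\mathrm{BPR} \times C_{blood}$ of the OPO species — the metric
tied to acetylcholinesterase inhibition. The reference analysis uses a
1 mg/kg single oral dose, below all $K_m$ (linear regime), where
$SC(\text{dose}) = +1$ and parameters with no pathway to the oxon have
$SC = 0$ — both asserted. Every evaluation rebuilds physiology and model
from the perturbed inputs, so perturbing e.g. body weight or a volume
fraction propagates through allometry, flow normalization and $V_{max}$
scaling.

## 5. Synthetic data: what it does and does not establish

`generate_fixtures()` writes everything the package needs to run
end-to-end: species templates, the chlorfenvinphos family carrying the
measured incubation kinetics (rat $V_{max}$ 0.46 nmol/min/mg, $K_m$
5.91 µM; human 0.57, 6.36), a generic OTP→OPO→metabolite triad with
round-number parameters, and two *synthetic* data sets (labelled as such in
their filenames): an observed-series table generated from the model's own
predictions with seeded multiplicative lognormal noise, and incubation
rates from the measured Michaelis–Menten curve with 3% noise.

The synthetic observed series exercises the fold-evaluation machinery with
a *known* answer: in the acceptance test the noise sdlog is
$\log 5 / z_{0.925} \approx 1.118$, so ~15% of points exceed 5-fold *by
construction*, and the evaluation must recover the constructed within-fold
percentages exactly. A green test therefore establishes that the
interpolation, ratio and counting logic is correct — it does **not**
establish predictive accuracy against real in vivo data. The published
evaluation percentages for this model class (85%/55% within 5-/2-fold in
rat, 91%/43% in human) rest on digitized literature concentration–time
data and supplementary parameter tables that are not reproducible at desk
scale; no attempt is made to restate them as package results.

Likewise, the catalytic-efficiency check: from the rounded printed inputs
(0.46, 5.91) the quotient is 77.8 µL/min/mg at three significant digits;
the reported 78.0 (and human 88.9 vs recomputed 89.6) evidently derive from
unrounded fit estimates. The tests assert the computable quantity and its
0.5% agreement with the reported one.

## 6. Known limitations

* No enterohepatic recirculation, biliary excretion, lymphatic/chylomicron
  transport, or gut-wall metabolism; no dermal/inhalation routes; no
  AChE-inhibition pharmacodynamics.
* Glutathione-transferase-mediated O-dealkylation is not part of the
  metabolic scheme.
* One lumped urinary metabolite per family; conjugate ratios are treated as
  species- and dose-independent, and all derivatives are formed in the
  liver — an acknowledged simplification that makes metabolite
  concentrations estimates rather than mechanistic predictions.
* QSPR-derived fup/BPR/$K_p$ inherit the uncertainty of their default
  coefficient tables; every constant is exposed in configuration so users
  can substitute measured or preferred published values.
* Physiology templates are single adult defaults; no pediatric, pregnancy
  or population-variability support.
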