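---
title: "Models and methods: quantifying bivalent isomerase-CTD binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying bivalent isomerase-CTD binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdbind)
```

## The scientific problem

The carboxy-terminal domain (CTD) of RNA polymerase II's largest subunit is
a tandem array of Y~1~S~2~P~3~T~4~S~5~P~6~S~7~ heptad repeats (26 in budding
yeast). Phosphorylation of Ser2 or Ser5 creates pSer-Pro motifs that are
bound and isomerized by parvulin-class prolyl isomerases (yeast Ess1, human
Pin1). Both of the isomerase's modules -- the WW domain and the catalytic
PPIase domain -- recognise pSer-Pro, so a long CTD substrate carrying two
motifs can in principle be engaged *bivalently*, with one motif anchored at
the WW domain while the other is isomerized in the active site.

`ctdbind` implements the quantitative solution-binding analyses by which
such bivalency is established for Ser5-phosphorylated CTD peptides of one to
five repeats, together with seeded synthetic-data generators so that every
fitting stage can be validated by parameter-recovery simulation. Four
orthogonal observables are covered:

1. **SV-AUC sw isotherms** -- the signal-weighted average sedimentation
   coefficient of a fluorescent two-motif peptide as the isomerase is
   titrated in, fitted with a two-site equilibrium model (`fit_sw_isotherm`).
2. **NMR CSP titrations** -- per-residue amide chemical-shift perturbations
   fitted to a single-site fast-exchange model with ligand depletion, then
   aggregated over responsive residues (`fit_residue_kd`, `aggregate_kd`).
3. **Competition fluorescence anisotropy** -- IC50s from a four-parameter
   logistic fit to probe-displacement curves (`fit_fourpl`).
4. **SAXS Guinier analysis** -- radius of gyration from the linearised
   low-angle scattering fit with the qR~g~ < 1.3 window rule, extrapolated
   to infinite dilution (`guinier_fit`,
   `extrapolate_rg_infinite_dilution`).

A small grammar for the peptide panel itself (parenthesised heptad units,
`pS` phospho flags, label tokens) provides the bookkeeping: motif positions,
inter-motif spacing, and sequence-determined extinction coefficients.

## The two-site sedimentation observable

Free peptide sediments slowly; every isomerase bound to it adds mass and
drag. With the two-motif peptide as the receptor `E` and the isomerase as
titrant `S`, the species are `E`, `SE` (site 1 occupied), `ES` (site 2
occupied) and `SES` (both), and the observable is

$$\theta = a + b\,\frac{[ES] + [SE] + 2[SES]}{[E] + [ES] + [SE] + [SES]}$$

where `a` is the minimum s~w~ value (free peptide) and `b` the maximum s~w~
value range per occupied site; `theta` runs from `a` to `a + 2b` at double
occupancy. Species come from mass action with microscopic per-site
constants,

$$[SE] = \frac{[E][S]}{K_{d1}},\qquad
  [ES] = \frac{[E][S]}{K_{d2}},\qquad
  [SES] = \frac{[E][S]^2}{K_{d1}K_{d2}},$$

i.e. the thermodynamic cycle is closed by site independence (cycle product
1, no cooperativity term) -- the simplest energy-conserving closure with
only two fitted constants. No statistical factors are applied; the
constants are reported as microscopic values. The equilibrium reduces to a
single scalar root in free titrant on `[0, S_total]`, where the conservation
function is strictly monotone; we solve it with a bracketed root finder at
an absolute conservation tolerance of 1e-12 uM.

Three modelling points deserve emphasis:

* **Species naming.** The published description of the equivalent model
  calls `E` "the enzyme", but the titrations add enzyme (0.5--1000 uM) to
  fixed peptide (50 uM) while observing the *peptide* signal. The algebra is
  identical either way; we adopt the two-site-receptor/titrant reading
  because it makes the observable well-defined and saturable.
* **Site-label symmetry.** `theta` is invariant under exchanging the site
  labels, so (K~d1~, K~d2~) are identifiable only as an unordered pair.
  Fits report the convention K~d1~ <= K~d2~ (site 1 = high-affinity site).
* **Equilibrium Kd parameterization.** Kinetic simulators fit these data by
  fixing association rates at 1 and floating dissociation rates, giving
  K~d~ = k~off~/k~on~. At equilibrium this is algebraically identical to
  fitting K~d~ directly, which is what we do (log~10~-K~d~ space, bounds
  1e-3 to 1e6 uM), avoiding an ODE engine with no observable consequence.

### Fitting protocol and the floated-b branch

The default analysis fixes `a = 0.61` S and `b = 1.48` S (values determined
from the five-repeat titration) and fits only the two constants, from a
deterministic grid of eight log-spaced starts (best residual sum of squares
wins; ties go to the smaller K~d1~).

For the four-repeat peptide the bound complex is hydrodynamically distinct
and `b` must float. The joint (K~d1~, K~d2~, b) least-squares surface is
**bimodal** at realistic noise: a spurious minimum near b ~ 0.6 S with
compensating K~d~s sits within one noise standard deviation of the true
mode, and a global multistart lands on either branch depending on the noise
draw. We therefore implement floating exactly as the experimental protocol
describes it -- fit first with `b` fixed, then *release* the constraint and
refine locally from the constrained optimum. The continuation keeps the fit
on the physically continuous branch; in simulation at noise sd 0.01 S it
recovers a generative b of 1.04 S with a spread of about 7% (the residual
spread is sampling variance of a 12-point isotherm, not an optimizer
artifact).

K~d~s that run to the search bound are flagged and rendered as `"> bound"`
strings rather than point estimates, matching how such limits are reported
in practice.

### From c(s) distributions to s~w~

`integrate_sw` computes the signal-weighted average
$s_w = \int s\,c(s)\,ds / \int c(s)\,ds$ over the standard 0.5--4 S window
by trapezoidal quadrature with linear interpolation at the window edges. A
window containing no signal returns `NA` with a warning instead of a
number. Computing c(s) itself from raw boundary scans (a Lamm-equation
inversion) is out of scope; distributions are consumed as tabulated input.

## NMR CSP titrations

For each backbone amide, the chemical shift perturbation against the apo
reference is

$$\mathrm{CSP} = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N/5)^2}$$

with the ^15^N scaling fixed at 5 (no per-residue weighting). In fast
exchange the observed CSP is a population-weighted average of free and
bound states,

$$\mathrm{CSP}(L) = \Delta\delta_{bound}\,\frac{[PL]}{P_{total}},\qquad
  [PL] = \tfrac{1}{2}\left(P_t + L_t + K_d -
  \sqrt{(P_t + L_t + K_d)^2 - 4P_tL_t}\right),$$

the exact single-site solution with ligand depletion (essential here:
protein is at 100 uM, comparable to the K~d~s of interest). Each residue is
fitted for (K~d~, delta_bound) by bounded Levenberg-Marquardt
(K~d~ in [1e-2, 1e5] uM, start at the titration midpoint; delta_bound >= 0,
start at the endpoint CSP). We float delta_bound per residue rather than
pinning it at the endpoint, since titrations that do not saturate would
otherwise bias K~d~ downward.

The aggregate constant is the unweighted mean of per-residue K~d~s over
residues whose endpoint CSP exceeds 0.03 ppm, with the *population*
standard deviation (the reference analysis states only "standard deviation
of residue-specific Kd values"; with n ~ 20 the distinction is cosmetic).
Residues broadened beyond detection are excluded from fitting and
aggregation: intermediate exchange violates the fast-exchange averaging
assumption. Every exclusion is itemized with its reason. No global
shared-K~d~ fit is performed -- the headline number is defined as the
average of per-residue fits.

For structure mapping, endpoint CSPs classify as strong (> 0.1 ppm),
moderate (> 0.03 ppm) or none, with broadening dominating; both
inequalities are strict.

## Competition anisotropy

Displacement of a fluorescent single-repeat probe by unlabelled peptides is
summarised by the four-parameter logistic

$$f_1 = \min + \frac{\max - \min}{1 + (x/\mathrm{IC}_{50})^{-\mathrm{Hillslope}}}$$

written with the exponent in exactly this sign convention, under which a
descending competition curve has a negative Hillslope. Fits are
unconstrained in min/max (the observed plateaus are not pinned), run from a
small deterministic set of slope starts, and flag a curve as degenerate when
the fitted amplitude is below three residual standard deviations --
returning no IC50 rather than a meaningless one. IC50s are reported as-is;
no Cheng-Prusoff conversion is applied, since at 50 uM protein and 1 uM
probe the conversion would dominate the headline number with assay-geometry
assumptions.

The synthetic generator offers both the 4PL forward model and an
exact-equilibrium mode (three-component competition solved by a bracketed
root in free protein, mapped to anisotropy linearly in bound-probe
fraction); with a trace probe the two agree to within 2% of the response
range, which is itself one of the test-suite's checks.

## Guinier analysis

In the Guinier region, $\ln I(q) = \ln I_0 - q^2R_g^2/3$. The window is
chosen iteratively: an initial R~g~ from the first ten points, then repeated
restriction to $q \le 1.3/R_g$ and refitting until R~g~ changes by < 0.1%.
Fits are error-weighted (weights $(I/\sigma_I)^2$, the delta-method variance
of ln I) when uncertainties are supplied. A non-decaying profile raises an
invalid-Guinier error, and a window that collapses below five points raises
an insufficient-data error -- both are hard failures, not silent numbers.
R~g~ values over a concentration series are extrapolated to infinite
dilution by ordinary least squares on R~g~(c).

## Synthetic data: what it emulates and what it does not

Generator defaults mirror the published experimental designs: 12 log-spaced
titrant concentrations from 0.5 to 1000 uM into 50 uM peptide for the sw
isotherms; 100 uM protein with ligand:protein ratios 0--3 (long peptides) or
0--6 (single repeat) for the HSQC titrations, with per-residue saturation
CSPs drawn uniformly from 0.05--0.4 ppm; 10 competitor concentrations from 0
to 350 uM for anisotropy; and scattering at 1.57/3.19/4.78 mg/mL over
q = 0.01--0.12 1/Angstrom (the beamline's exact q-range is not published;
this covers the Guinier window for a ~20 Angstrom particle with margin).

Noise defaults are Gaussian and deliberately simple: 0.01 S on s~w~, 0.002
ppm on ^1^H shifts (x5 on ^15^N so CSP-space noise is isotropic), 1% of the
response range on anisotropy, 0.5% multiplicative on scattering intensity.
The experimental records report no noise magnitudes, so these are chosen
once as plausible instrument-level values and flagged as such; they are
*conditions of the simulation study*, not estimates of the original data
quality. Every generator is a deterministic function of (parameters, seed),
with one substream per residue/profile so enlarging a dataset never
perturbs existing draws, and the caller's RNG state is always restored.

What the generators do **not** emulate -- and hence what passing recovery
tests cannot certify about real data: baseline drift and systematic
(non-Gaussian) instrument error; exchange broadening and peak overlap in
crowded spectra (broadening is modelled only as a per-point exclusion
flag); interparticle structure factors, aggregation and radiation damage in
scattering; and any kinetic (non-equilibrium) effects during sedimentation.

## Problem sizes and reproducibility

The packaged recovery experiments use the published designs at desk scale:
12-point isotherms, 20-residue titration sets, 10-point competition curves,
three 60-point scattering profiles. The full test-suite, including the
200-instance solver-vs-oracle comparison and all recovery round trips, runs
in about a minute on one core. `scripts/acceptance.R` reruns every recovery
from scratch under a caller-supplied seed and writes the recovered values as
JSON; identical seeds give bit-identical results.

## Known limitations

* The two-site model assumes independent sites. Genuine binding
  cooperativity would be absorbed into the effective K~d~s; the data types
  handled here cannot separate a cooperativity factor from the pair
  (K~d1~, K~d2~) without additional constraints.
* The CSP model is strictly two-state and fast-exchange per residue;
  residues tracking a secondary event (e.g. a binding-coupled
  conformational change) will fit poorly and inflate the aggregate SD
  rather than being detected as multi-state.
* IC50s from the 4PL are assay-conditional summaries, not binding
  constants, and depend on probe and protein concentrations.
* With the 12-point isotherm design, K~d2~ values in the mM range are
  determined only to within a factor of ~2 and may run to the search bound;
  they are reported as bounds when they do.
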