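# ctdbind

Fitting and simulation tools for the solution-binding assays used to
quantify how parvulin-class prolyl isomerases (yeast Ess1, human Pin1)
engage phosphorylated heptad-repeat peptides from the RNA polymerase II
carboxy-terminal domain (CTD). The package is aimed at structural
biologists and biophysicists analysing multivalent protein-peptide
equilibria from sedimentation-velocity AUC, NMR titrations, fluorescence
anisotropy, or SAXS -- and at anyone who wants to validate such analyses by
seeded parameter-recovery simulation.

## What it computes

**Two-site sw isotherms (SV-AUC).** A two-motif CTD peptide (receptor `E`)
binds titrant `S` at two independent sites with microscopic constants
K<sub>d1</sub>, K<sub>d2</sub> (species `SE`, `ES`, `SES`; thermodynamic
cycle closed by site independence). The signal-weighted sedimentation
coefficient is

    theta = a + b * ([ES] + [SE] + 2[SES]) / ([E] + [ES] + [SE] + [SES])

with `a` the minimum s<sub>w</sub> value and `b` the maximum s<sub>w</sub>
range. `fit_sw_isotherm()` fits (K<sub>d1</sub>, K<sub>d2</sub>) in
log-space with a deterministic multistart, optionally releasing `b` from
the constrained optimum; `integrate_sw()` turns c(s) distributions into
s<sub>w</sub> over the standard 0.5-4 S window.

**NMR CSP titrations.** Per-residue chemical-shift perturbations,
CSP = sqrt(&Delta;&delta;<sub>H</sub>&sup2; +
(&Delta;&delta;<sub>N</sub>/5)&sup2;), follow the fast-exchange model
CSP(L) = &Delta;&delta;<sub>bound</sub> [PL]/P<sub>total</sub> with [PL]
from the exact single-site ligand-depletion quadratic. `fit_residue_kd()`
fits each residue; `aggregate_kd()` averages residues whose endpoint CSP
exceeds 0.03 ppm and reports mean +/- SD.

**Competition anisotropy.** `fit_fourpl()` fits the four-parameter
logistic `f1 = min + (max-min)/(1 + (x/IC50)^(-Hillslope))` to
probe-displacement curves and reports IC50 with its standard error.

**Guinier analysis (SAXS).** `guinier_fit()` performs the iterative linear
fit of ln I vs q&sup2; under the qR<sub>g</sub> &lt; 1.3 window rule;
`extrapolate_rg_infinite_dilution()` extrapolates R<sub>g</sub>(c) to zero
concentration.

**Peptide grammar.** `parse_peptide_spec()` reads the heptad-repeat
notation used for synthetic CTD substrates
(`"AS(YSPTpSPS)(YSPTSPS)...YS"`), locating pSer-Pro motifs, inter-motif
spacing, and Tyr-based extinction coefficients.

**Synthetic data.** `gen_sw_isotherm()`, `gen_hsqc_titration()`,
`gen_competition_curve()`, `gen_guinier_profiles()` and
`gen_cs_distribution()` are seeded, deterministic generators whose sd = 0
output is exactly the corresponding forward model.

## Worked example

```r
library(ctdbind)

# The five-repeat peptide, phosphorylated on the Ser5 of its outer repeats
p <- parse_peptide_spec(ctd_peptide_specs()[["NMR-5R"]], name = "NMR-5R")
p
#> <ctd_peptide> NMR-5R
#>   spec:      AS(YSPTpSPS)(YSPTSPS)(YSPTSPS)(YSPTSPS)(YSPTpSPS)YS
#>   residues:  39, repeats: 5
#>   phospho:   7, 35
#>   caps:      N free / C free
motif_spacing(p)
#> [1] 28

# Simulate a 12-point sw isotherm at the 5R constants and refit it
iso <- gen_sw_isotherm(0.61, 1.48, two_site_params(21.5, 5990),
                       noise = noise_spec(0.01, 42))
fit_sw_isotherm(iso)
#> <sw_isotherm_fit>
#>   a = 0.610 S (fixed), b = 1.480 S (fixed)
#>   Kd1 = 20.79 uM (se 0.43), Kd2 = 5361 uM (se 209)
#>   RSS = 0.0006912 over 12 points (8 starts)

# CSP titration pipeline: 20 simulated residues at Kd = 9.1 uM
r <- recover_nmr_aggregate(9.1, max_ratio = 3, seed = 7)
r$aggregate
#> <aggregate_kd>
#>   mean Kd = 9.955 uM, SD = 2.275 uM over 20 residues
#>   threshold: endpoint CSP > 0.03 ppm; 0 excluded
```

The isotherm fit recovers the generative constants (20.8 vs 21.5 uM for the
high-affinity site, with the weak second site at ~5.4 vs 6.0 mM), and the
residue-averaged NMR K<sub>d</sub> lands within 10% of its generative 9.1
uM -- the same round trips the test-suite runs at fixed tolerances.

A thin command-line wrapper over the same functions ships in
`inst/scripts/ctdbind.R`:

```sh
Rscript inst/scripts/ctdbind.R peptide --spec "AS(YSPTpSPS)(YSPTSPS)(YSPTSPS)(YSPTSPS)(YSPTpSPS)YS"
Rscript inst/scripts/ctdbind.R simulate --what sw_isotherm --kd1 21.5 --kd2 5990 --seed 42 --out-dir out/
Rscript inst/scripts/ctdbind.R fit-auc --input out/isotherm.csv --peptide-total 50
```

## Layout

- `R/` -- peptide grammar, equilibrium solvers, the four fitters, seeded
  generators, pipeline orchestration
- `tests/testthat/` -- unit, property and recovery tests, including
  independent grid-scan/bisection oracles for every solver
- `vignettes/bivalent-ctd-binding.Rmd` -- models, assumptions, numerical
  choices, and what the simulations do and do not emulate
- `scripts/acceptance.R` -- end-to-end recovery report
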