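# qsarpipe

An R toolkit for building and validating 2D- and 3D-QSAR
(quantitative structure–activity relationship) models of small-molecule
inhibitor series, written for computational medicinal chemists who need
the full workflow — activity transformation, descriptor selection,
symbolic regression, molecular-field modelling and external validation —
as tested, scriptable functions rather than a GUI suite.

## What it computes

**Activity scale.** IC50 values in nM are modelled on the pIC50 scale,
`-log10(IC50[nM]) + 9`, so 1 nM maps to 9 and a ten-fold potency gain is
one unit.

**Heuristic descriptor selection (2D).** Stepwise multiple linear
regression in the CODESSA style: single-descriptor screening, exhaustive
pair ranking by R², then beam-search growth scored by the composite
fitness

```
w = R² · F · n / (N · s²)
```

with collinearity control (pairwise |r| < 0.8) and leave-one-out R²cv on
every retained model.

**Gene expression programming (2D, non-linear).** Symbolic regression
over fixed-length Karva genomes (head/tail structure over the function
set `{+, −, ×, ÷, cos}`), decoded breadth-first into expression trees
and evolved by elitist roulette selection with mutation, IS/RIS/gene
transposition and one-point/two-point/gene recombination. Fitness is
`1000/(1 + RMSE)`; division by (near-)zero is lethal.

**CoMSIA-style field analysis (3D).** Gaussian similarity fields
`A(q) = −Σ_atoms w_atom · exp(−α r²)` for steric (r³ weight),
electrostatic (partial charge), hydrophobic, H-bond donor and acceptor
properties on a lattice around pre-aligned molecules, followed by
block scaling, low-variance column filtering, NIPALS PLS with
leave-one-out q² component selection, field-contribution fractions and
STDEV×COEFF contour maps.

**Validation.** `R²ext = 1 − Σ(y−ŷ)²/Σ(y−ȳ_train)²` with the
strict `> 0.5` robustness gate, plus RMSE/MAE/r² summaries and
y-scrambling support.

Two published reference 2D-QSAR models for a 37-compound quinazoline
FGFR4-inhibitor series ship as functions (`ref_linear_model()`,
`ref_gep_model()`), together with the series' IC50 table
(`quinazoline_ic50()`). Because the original descriptor matrices and 3D
structures are not deposited anywhere, model *recovery* is demonstrated
on seeded synthetic generators that plant known linear, symbolic and
spatial-field signals (`gen_descriptor_set()`, `gen_symbolic_set()`,
`gen_aligned_molecules()`, `gen_mo_coefficients()`).

## Worked example

```r
library(qsarpipe)

tab <- quinazoline_ic50()
head(as.data.frame(tab), 3)
#>   id ic50_nM activity      split test_set_3d
#> 1 5a     986 6.006123 unassigned        TRUE
#> 2 5b    4011 5.396747 unassigned        TRUE
#> 3 5c      91 7.040959 unassigned        TRUE

# 2D: select descriptors for a planted-signal synthetic series
sim <- gen_descriptor_set(n_compounds = 40, n_descriptors = 103,
                          noise_sd = 0.1, seed = 7)
res <- hm_search(sim$descriptors, sim$activity,
                 hm_config(max_descriptors = 3,
                           one_param_r2_floor = 0, t_floor = 0))
res
#> size 1: best R2 = 0.6422 (D1)
#> size 2: best R2 = 0.9357 (D1, D2)
#> size 3: best R2 = 0.9995 (D1, D2, D3)

# non-linear follow-up on the selected descriptors
sym <- gen_symbolic_set("2*x + cos(z)", n = 200, seed = 7)
cfg <- gep_config(terminals = c("x", "z"), population_size = 100,
                  max_generations = 500, target_r2 = 0.99, seed = 7)
gep_evolve(sym$X, sym$y, cfg)
#> GEP model: x + x + cos(z)
#>   fitness = 1000.000  RMSE = 0  R2 = 1.0000  (23 generations)

# 3D: CoMSIA fields + PLS on an aligned synthetic series
am <- gen_aligned_molecules(seed = 7)
fit_comsia(am$molecules, am$activity, max_components = 8)
#> PLS field model: ONC = 2  q2 = 0.946  r2 = 0.979  SEE = 0.0449  F = 391.52
#> field contributions:
#> electrostatic           hba           hbd   hydrophobic        steric
#>         0.781         0.042         0.016         0.007         0.155
```

The heuristic search finds exactly the three planted descriptors; the
GEP run rediscovers `2x + cos(z)` as `x + x + cos(z)`; the field model
passes the q² > 0.5 robustness gate and correctly attributes most of the
signal to the electrostatic field, where the activity was planted.

`run_pipeline()` (or `inst/scripts/qsarpipe.R` from a shell) chains
simulate → split → HM → GEP → validate, writing models, validation
reports and a checksummed manifest; the descriptors selected by the HM
stage become the GEP terminal set, mirroring how a 2D-QSAR study hands
its best descriptors to the non-linear modelling step.

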