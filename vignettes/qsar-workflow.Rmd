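---
title: "Methods: the qsarpipe 2D/3D-QSAR workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the qsarpipe 2D/3D-QSAR workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarpipe)
```

qsarpipe implements the complete modelling chain of a classical
QSAR study of enzyme inhibitors: a 2D branch (descriptor-based linear
and symbolic-regression models) and a 3D branch (molecular similarity
fields with PLS), joined by shared validation statistics. This vignette
records the models, their assumptions, every tunable that matters, and
the design decisions taken where conventions diverge.

## Activity scale and data bookkeeping

Potencies arrive as IC50 in nanomolar and are modelled as
`-log10(IC50) + 9`, i.e. pIC50 with the concentration read in molar.
The log transform stabilises a quantity that spans five orders of
magnitude in the packaged quinazoline series (0.55 nM to 4011 nM);
the `+9` offset makes 1 nM map to 9. The base is 10 — the standard
pIC50 convention, and the only base under which the `+9` offset is
exact for nanomolar units.

`split_table()` draws a seeded 4:1 train/test split with
`floor(ratio × n)` training compounds, clamped so both sides are
non-empty. For the 37-compound table this gives 29/8, matching the
published partition of the series. The original study seeded its split
from system time, so the historical 2D membership is unrecoverable; the
8 compounds of the 3D external test set are recorded in the fixture
(`test_set_3d`) as published, and all fresh splits require an explicit
seed.

## Heuristic descriptor selection

`hm_search()` is a CODESSA-style stepwise multiple linear regression:

1. **One-parameter screen.** Each descriptor is regressed alone;
   descriptors below an R² floor or a |t| floor are discarded, as are
   near-constant columns (relative SD below 1e-10) and columns with
   missing values.
2. **Pairs.** All surviving pairs with pairwise |r| below the
   collinearity threshold (default 0.8) are fitted and ranked by R².
3. **Beam growth.** The best `beam_width` models (default 10, the
   conventional "top ten correlations" display) are extended one
   descriptor at a time. Candidate additions that correlate at or
   above the threshold with an included descriptor are skipped; the
   rest are ranked by the composite fitness `w = R²·F·n/(N·s²)`, where
   `n` is the sample count, `N` the surviving-descriptor count and
   `s²` the squared standard error. `s²` (not `s`) is used in the
   denominator, as the formula is printed; the choice only rescales
   scores monotonically for model ranking at fixed size.
4. Every retained model is annotated with leave-one-out R²cv computed
   through the hat-matrix identity `e₍ᵢ₎ = eᵢ/(1−hᵢᵢ)`, which the test
   suite verifies against n explicit refits to 1e-8.

**On the screening floors.** The defaults
(`one_param_r2_floor = 0.01`, `t_floor = 1.5`) are a permissive
pre-screen that cheaply removes noise columns from very large
descriptor catalogues. They are, however, a power trade-off: a real
descriptor contributing ~7% of activity variance at n = 40 has a
marginal correlation of roughly 0.26 ± 0.16, so *any* nonzero floor
rejects it in a nontrivial fraction of samples. The package's own
recovery experiments (planted three-descriptor signal among 100
decoys) therefore run with both floors at zero; users hunting weak but
genuine descriptors should do the same and let the collinearity check
and fitness ranking do the work. Regression always runs on raw
descriptor values — published model coefficients are raw-scale, and
standardisation would change none of the rankings.

The published linear model for the quinazoline series is built in:

```{r}
ref_linear_model(0, 0, 0)   # the intercept
```

Its positive Min-NRO coefficient (+2.5642e4) encodes the series'
oxygen design rule: lowering the minimum nucleophilic reactivity index
of the molecule's oxygen atoms (fewer, or higher-valence, oxygens)
lowers predicted log IC50 and so raises potency.
`nucleophilic_reactivity_index()` computes the underlying Fukui index
`N_A = Σ_{i∈A} (Cᵢ^HOMO)²` from per-atom HOMO coefficients; both the
per-atom index and the minimum over an element are exposed, since the
atom-set granularity of the sum is a modelling choice. The indices are
treated as dimensionless.

## Gene expression programming

`gep_evolve()` is a from-scratch GEP engine. A chromosome is
`n_genes` fixed-length genes; each gene has a head of `h` symbols
(functions or terminals) and a tail of `h·(a−1)+1` terminals, `a` being
the maximum function arity. This head/tail arithmetic guarantees every
random or recombined genome decodes, breadth-first (Karva order), into
a valid expression tree — the property the test suite stresses over
10⁴ random operator applications.

Defaults follow the canonical GEP literature: head 8, 3 genes linked
by `+`, population 50, per-symbol mutation 0.044, IS/RIS/gene
transposition 0.1 each, one-point/two-point/gene recombination
0.3/0.3/0.1, elitism 1. The function set is `{+, −, ×, ÷, cos}` — the
operator table of the reference study. The fitness function is not
specified in that study; `1000/(1+RMSE)` is used (bounded, strictly
decreasing in error, 1000 at a perfect fit), and any chromosome whose
evaluation divides by a denominator within 1e-12 of zero receives
fitness 0. This "lethal" protected division deliberately avoids the
classical silent-large-value protection, which rewards expressions
that are singular on the data. Ephemeral random constants are off by
default — integer literals can enter the terminal set explicitly, and
the reference equation needs none beyond them.

Termination is `max_generations` or an optional training-R² target.
With elitism ≥ 1 the best fitness is monotone non-decreasing, and runs
are bit-reproducible for a fixed seed.

The published non-linear equation is exposed as `ref_gep_model()`.
Machine-generated C code associates division chains left to right, so
`cos(x)·x/y/z` is read `((cos(x)·x)/y)/z`. The one genuinely ambiguous
token, the compact `y/3x`, is read `y/(3x)` by default (implicit
multiplication binding first); `variant = "strict_ltr"` gives the
`(y/3)·x` reading. Both variants are pure functions, raise on zero
denominators, and the default agrees to 1e-12 with an independently
parsed evaluation of the formula.

## CoMSIA-style field analysis

`fit_comsia()` assumes its input molecules are **already aligned** on a
common template (a Kabsch rigid-body utility, `align_to_template()`, is
provided; pharmacophore searching is out of scope). The lattice uses
2 Å spacing with a 4 Å margin around the union of atoms — the
conventional region settings. At each point the similarity index of
property k is

`A_k(q) = − Σ_atoms w_probe · w_atom,k · exp(−α r²)`

with a unit probe, attenuation α = 0.3 Å⁻² (the standard CoMSIA
value; configurable), and property weights radius³ (steric —
volume-proportional), partial charge (electrostatic), atomic
hydrophobicity, and 0/1 donor/acceptor flags. The Gaussian form needs
no cut-off and is smooth near atoms. Note the global minus sign: the
similarity indices are *negative-sensed*, so a grid point whose
underlying atomic property increases activity acquires a negative PLS
coefficient. Contour maps inherit this: in the STDEV×COEFF percentile
maps (defaults 80/20), a site where *more* positive charge means
*more* activity appears in the lower tail. Favorable/unfavorable sets
are disjoint by construction (strict inequalities against distinct
percentiles).

Before PLS, each property block is scaled to equal total variance
(CoMFA-style block scaling) — otherwise the per-field contribution
fractions only reflect raw field magnitudes — and columns with SD
below 0.05 (after scaling) are dropped. PLS is univariate NIPALS; for
every component count up to `max_components` the leave-one-out
`q²(c) = 1 − PRESS(c)/TSS` is computed from n full refits, and the
optimum component number (ONC) maximises q². The final non-validated
model reports r², `SEE = sqrt(RSS/(n−ONC−1))` (SYBYL's degrees of
freedom), F, and contribution fractions `Σ|coef·SD|` per property.
Fitting is invariant (to 1e-8) under a common rigid motion of
molecules and lattice, verified in the tests.

## Validation

`r2_ext()` implements
`R²ext = 1 − Σ(yᵢ−ŷᵢ)² / Σ(yᵢ−ȳ_train)²` with the strict `> 0.5`
robustness gate. The statistic is affine-invariant, at most 1, and
unbounded below; it errors (rather than silently returning 0) when all
test activities equal the training mean. `error_summary()` reports
RMSE, MAE and squared Pearson correlation; "average error" in QSAR
reporting is ambiguous between MAE and RMSE, so both are always
reported, with MAE the likelier conventional meaning. y-scrambling —
refitting on permuted activities and expecting q² to collapse — is
exercised in the acceptance tests as the standard guard against chance
correlation.

## Synthetic data: what it does and does not show

No descriptor matrices or 3D structures are publicly deposited for the
packaged quinazoline series, so recovery is demonstrated on seeded
generators whose planted truth is recorded alongside the data:

- `gen_descriptor_set()`: independent N(0,1) (optionally lognormal)
  descriptor columns, activity linear in three of them (3, −2, 1) plus
  Gaussian noise. The default noise SD of 1.25 places the planted
  model near R² ≈ 0.9, the quality regime of a realistic well-fitting
  2D-QSAR; recovery experiments use noise 0.1 so that failure isolates
  selection errors rather than noise.
- `gen_symbolic_set()`: uniform inputs through any expression over the
  GEP alphabet.
- `gen_aligned_molecules()`: a rigid 8-atom scaffold (jitter ≤ 0.02 Å)
  with one variable O site at (4,0,0); the site's charge is uniform on
  (−0.5, 0.5) e and drives the activity with unit effect plus 0.05
  activity-units of noise; site hydrophobicity and flags vary but
  carry no signal.
- `gen_mo_coefficients()`: per-atom coefficient vectors scaled to hit
  prescribed sums of squares exactly.

These fixtures have independent descriptors, a single pharmacophore
site, and no conformational flexibility, tautomers, alignment error
beyond jitter, or correlated descriptor blocks. Passing tests
therefore demonstrate that the *algorithms* recover what they are
specified to recover; they say nothing about descriptor quality or
alignment choices on real chemistry.

## Numerical choices and problem sizes

Rank-deficient designs and constant responses raise errors naming the
offending columns; exact fits report s² = 0 and infinite fitness with
a warning. Correlation is Pearson throughout. Ties in beam ranking are
broken by order of enumeration; duplicate descriptor sets reached via
different beam parents are deduplicated. The test and acceptance runs
use: 20 seeds × (40 compounds × 103 descriptors) for selection
recovery; 10 seeds × (population 100, ≤ 500 generations, n = 200) for
GEP recovery; 20 molecules × ~1000 raw field columns with 20
y-permutations for the field model — sizes chosen so each experiment
carries clear statistical signal while a full run stays in the
tens-of-seconds range on one core.

## Known limitations

- Descriptor *calculation* for real molecules is delegated to external
  calculators or CSV input; the package treats descriptors as named
  columns.
- The CoMSIA probe is fixed at unit weights; SYBYL's exact probe
  parameterisation is not published in detail.
- The SDF/MOL2 readers recover coordinates, elements and (MOL2)
  partial charges; hydrophobicity and H-bond flags must come from the
  CSV atom-table format.
- The reference models are reproduced as printed equations; their
  original training descriptor values are not available, so their
  statistics cannot be recomputed.
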