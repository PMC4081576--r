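---
title: "Methods: QSAR modelling of kinase inhibitor potency with qsarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR modelling of kinase inhibitor potency with qsarkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`qsarkit` implements a ligand-based QSAR workflow for kinase-inhibitor
potency: molecular descriptors are computed from structures, reduced by
a three-stage selection procedure, and regressed against pIC50 with an
epsilon support vector machine; optional docking-energy terms can be
fused into the feature set ("hybrid" ligand + structure models). This
vignette records the modelling choices, their defaults, and the
reasoning behind decisions the method description leaves open.

## Activity scale

Potency is modelled as pIC50 = −log10(IC50 in molar). Inputs give IC50
in nanomolar, so `pic50 = 9 − log10(ic50_nM)`; a raw
`−log10(IC50_nM)` variant is available through the `convention`
argument of `ic50_to_pic50()`. The molar convention is the standard
medicinal-chemistry scale and places typical kinase-inhibitor data in
the 5–10 range; the choice affects only the intercept of any model,
not correlations.

## Descriptors

Six families are generated from SMILES via OpenBabel
(ChemmineR/ChemmineOB), with column names prefixed by family so
provenance survives any amount of column slicing:

| prefix    | family            | content                                             |
|-----------|-------------------|-----------------------------------------------------|
| `phys_`   | physicochemical   | MW, logP, TPSA, H-bond acceptor/donor counts, molar refractivity, fluorine count |
| `const_`  | constitutional    | heavy-atom, bond, element and ring counts           |
| `topo_`   | topological       | Wiener index, diameter/radius, Petitjean shape, Zagreb indices, branching, mean topological distance |
| `subfp_`  | substructure keys | 22 curated SMARTS patterns (halogens, polar groups, alkyl branches, heteroaromatic cores) |
| `pathfp_` | path fingerprint  | 1024 hashed linear-path bits (OpenBabel FP2)        |
| `maccs_`  | MACCS-like keys   | 256 fixed substructure keys                         |

Descriptor names are engine-specific: a different engine would produce
differently named (and differently many) columns, so descriptor
*counts* from other toolkits are not comparable, and models only
transfer together with the engine that produced their features.
Docking energies are never computed here — they are ingested from a
CSV of the seven standard per-compound terms (kcal/mol) and appended
as `dock_` columns; `screen_energy_descriptors()` reports their 7×7
correlation table and drops, from every pair above the cutoff (default
0.8), the member with the larger mean absolute correlation to the
remaining terms — a deterministic tie-break that removes the more
redundant column.

## Feature selection

Selection runs on the training split only, in the narrative order of
the classical pipeline, and is a pure function of (matrix, activity,
configuration, seed):

1. **Degenerate columns** — all-zero and zero-variance columns are
   removed; they carry no information and make correlations undefined.
2. **Correlation pruning** — while any feature pair has |r| above the
   cutoff (default 0.9, the conventional collinearity threshold), the
   pair member with the smaller |correlation to activity| is removed;
   ties remove the lexicographically later name, making the scan
   deterministic.
3. **CFS subset selection** — subsets are scored by merit
   `k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)`. The search is exhaustive up to
   15 features and best-first above that (start from the best single
   feature, expand the best open node by single-feature additions,
   stop after 5 consecutive non-improving expansions or 200
   expansions). With duplicated features the merit of a pair collapses
   to the singleton merit exactly (`r̄_ff = 1`), and ties resolve to
   the smaller subset. The subset size is capped at the feature
   budget.
4. **Remove-one backward elimination** — each cycle scores the current
   set and every leave-one-out subset by k-fold cross-validated
   Pearson R of the SVR itself (all subsets see identical folds, fixed
   by the seed, so comparisons are paired); the feature whose removal
   gives the largest R *not below* the current R is removed
   permanently; the loop stops when every removal would decrease R.
   The published description of this step is self-contradictory (it
   says a descriptor is removed when removal *decreases* the
   correlation, which would delete useful descriptors and contradicts
   the stated stopping rule); we implement the reading consistent with
   the stopping rule, which guarantees a monotonically non-decreasing
   CV-R trajectory. Scoring by cross-validated rather than training R
   avoids trivially monotone overfitting.
5. **Feature budget** — at most `floor(n/4)` features survive (ranked
   by |correlation to activity| if the cap binds), the usual guard
   against over-optimisation in small-n QSAR.

## Model

The regressor is epsilon-SVR (libsvm through e1071) with configurable
kernel. Defaults: RBF kernel, `C = 10`, `epsilon = 0.1` log units,
`gamma = 1/n_features`, 5-fold CV; the original studies do not report
their SVM settings, so these are ordinary textbook defaults, and
`tune_svr()` offers a small CV grid search over `C` and `gamma` when
wanted. Features are standardised before fitting (SVR is
scale-sensitive; centres and scales are stored in the model).
Prediction uses an explicitly coded kernel decision function over the
stored support vectors, so a model serialised to JSON
(`write_qsar_model()`) reproduces in-memory predictions to 1e-9 by
construction; a test verifies the decision function against the
reference engine's own `predict` at 1e-9 for all three kernels.

`run_protocol()` mirrors the conventional reporting triple: in-sample
fit of a model trained on the whole (class-filtered) set, pooled
k-fold CV on the 80% training split, and validation on the held-out
20% (validation size `floor(0.2·n)`; literature splits that follow no
single rounding rule can be reproduced via `explicit_counts`).
Whole-set rows are training fits, CV rows are out-of-fold — both are
reported and labelled because conventions differ across the
literature.

## Evaluation statistics

`pearson_r`, `r_squared` (`1 − SSE/SST`), `mae` and `rmse` use their
universal definitions. Note `r_squared` is not the square of
`pearson_r` for biased predictors; it equals it exactly only when the
predictions are the least-squares line of observed on predicted (a
property the test suite checks). RMSE ≥ MAE always (Jensen).

## Fragment enrichment

For a binary fragment column, the class frequency is implemented as
the enrichment ratio

frequency = (N_fragment_class / N_class) / (N_fragment_total / N_total),

class prevalence normalised by overall prevalence: 1 means the
fragment occurs at the background rate, 0 means absent from the class,
and a fragment exclusive to a class scores `N_total/N_class` there.
The source's formula image is not legible; this is the only
dimensionless combination of its four defined count variables that
makes "more frequent in class X" interpretable, and it satisfies the
conservation identity Σ_class (N_class/N_total)·frequency = 1 for
every fragment present anywhere — asserted on randomised instances in
the tests. Fragment presence is counted per molecule (multiple
occurrences in one molecule count once). Strict class-exclusive
fragments are present in all molecules of one class and absent from
all of the other; a relaxed list (default prevalence ≥ 0.9 in, ≤ 0.1
out) tolerates single outliers.

## Synthetic data generator

The generator exists so that every pipeline stage is exercisable
end-to-end without external data, under conditions shaped like the
motivating EGFR problem: a "wild"-labelled 4-anilinoquinazoline series
and a "mutant"-labelled N-alkyl 4-anilino-pyrazolo[3,4-d]pyrimidine
series. Variants are enumerated by substituting 3 scaffold positions
from small substituent libraries (6–7 options per position), and true
activity is linear in substituent presence:

pIC50 = intercept + Σ_g w_g · present_g + N(0, noise_sigma)

with defaults intercept 6.5, noise_sigma 0.3 log units, and effects
Cl +1.0, OMe +0.9, NH2 −0.8, CF3 −0.9 (quinazoline class) — an
activity span of roughly 3.5 log units, typical of a congeneric
optimisation series. Three design choices matter and were made
deliberately:

* **One occurrence per substituent.** Combinations repeating a non-H
  substituent are excluded, so presence equals count and descriptor
  columns that count atoms are exact (not merely approximate)
  surrogates of the planted indicators.
* **Sign-alternating effects within co-counted atom classes.** Cl (+)
  and CF3 (−) share halogen counts; OMe (+) and NH2 (−) share
  H-bond-acceptor and polar-surface counts. Real SAR contains both
  potency-raising and potency-lowering groups; here the alternation
  additionally ensures no single aggregate property (MW, nHal, HBA,
  TPSA) is a sufficient statistic for activity, so "which substituent
  drives potency" remains a well-posed recovery question.
* **Effect sizes of 0.8–1.0 log units** against 0.3 log units of
  noise, so each planted effect is individually resolvable at n ≈ 100
  — the regime the pipeline is designed for.

Docking energies are simulated, not computed: `E_FreeBind` is mixed to
a target correlation with true activity (`energy_signal`, default
−0.3: weakly favourable binding energy for more potent compounds,
echoing the weak predictivity of docking scores), the other six terms
are independent Gaussians with realistic kcal/mol locations. The
two-regime constructor pairs the two scaffold classes with deliberately
different (partly sign-flipped) effect maps, which is what makes
cross-class prediction degrade while within-class models succeed.

What the generator does *not* emulate: conformation-dependent (3D)
descriptors, activity cliffs, nonlinear substituent interactions,
inter-laboratory IC50 noise, and any real binding physics in the
energy terms. Passing tests therefore demonstrate that the pipeline
machinery is correct and that it recovers planted additive structure
under realistic noise — not that any particular real series will give
comparable statistics.

**Feature recovery** is scored by correlation, not by name: a planted
indicator counts as recovered if some selected column has |r| ≥ 0.9
with it, and a selected column is spurious if its best |r| against all
planted indicators is below 0.9. Fingerprint engines "name" a
substituent through whatever key happens to match it (a MACCS halogen
key, an oxygen count), so name-matching would be meaningless; the 0.9
bar accepts exact and near-exact surrogates while rejecting the hashed
path-fingerprint OR-composites that carry only partial information.

## Numerical and reproducibility choices

* All tie-breaks (pruning, CFS, elimination, budget ranking) are
  lexicographic on column name, so every stage is deterministic.
* All randomness (enumeration sampling, noise, splits, CV folds)
  derives from integer seeds through a fixed stream-derivation
  function; identical configuration and seed give bit-identical
  outputs, which the acceptance tests assert.
* Degenerate inputs fail loudly: non-positive IC50s, constant
  activity, zero-variance features at training, folds with fewer than
  two compounds, missing energy columns and unparseable structures are
  all hard errors naming the offender, except where a documented
  opt-in policy (skip-with-warning, inner-join, drop-row) exists.
* Problem sizes in the test suite follow the motivating study's shape
  (128-compound wild series over 10 seeds; 64 + 64 for the two-regime
  experiment); unit tests use 16–60-compound toys.

## Known limitations

* Descriptor identities are OpenBabel-specific; models are not
  portable across descriptor engines.
* The CFS merit intrinsically favours small subsets and can discard
  weakly informative features whose univariate correlation is low;
  backward elimination can only remove, never restore, a feature the
  CFS stage dropped.
* Best-first CFS above 15 features is a bounded heuristic; only the
  ≤ 15-feature regime is guaranteed to match exhaustive enumeration.
* SDF input is supported for structures, but 3D information in it is
  ignored — all descriptors here are 2D.
* The command-line wrapper is intentionally thin; anything beyond its
  four subcommands is meant to be scripted against the R API.
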