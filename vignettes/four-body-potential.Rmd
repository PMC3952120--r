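---
title: "Methods: the four-body potential and topological binding-energy model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-body potential and topological binding-energy model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourbody)
```

## The model in brief

`fourbody` predicts protein–ligand binding free energy from topology
alone. The Delaunay tessellation of a structure's heavy-atom coordinates
partitions its convex hull into tetrahedra whose vertices are, by the
empty-circumsphere property, objective nearest neighbours. Each
tetrahedron is an observation of an unordered quadruplet of atom classes
over the alphabet {C, N, O, S, M, X} (M = any metal, X = any other
non-metal; 126 distinct quadruplet classes). A knowledge-based potential
assigns each class the base-10 log-odds score

$$s_{ijkl} = \log_{10}\frac{f_{ijkl}}{p_{ijkl}},$$

with $f$ the observed tetrahedron fraction over a derivation corpus and
$p$ the multinomial background

$$p_{ijkl} = \frac{4!}{\prod_n t_n!}\prod_n a_n^{t_n},$$

where $a_n$ is the corpus-wide relative frequency of class $n$ and $t_n$
its multiplicity in the quadruplet. Structures are scored by the mean
tetrahedron score $Q = N^{-1}\sum s_{ijkl}$, a complex by the difference
$\Delta Q = Q_\mathrm{complex} - Q_\mathrm{protein}$ between its full and
ligand-stripped tessellations, and binding energy by the fixed empirical
line $\Delta G_\mathrm{calc} = \Delta Q / 0.0003 - 10.49$ kcal/mol.

The main modelling assumptions, inherited with the method:

* an element-class alphabet suffices (no hybridization, charge or
  aromaticity);
* ligands are small enough that interface tetrahedra dominate
  ligand-internal ones, so $Q_\mathrm{complex}$ keeps every tetrahedron;
* a single linear map from $\Delta Q$ to kcal/mol transfers across
  complexes.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| edge cutoff | 8.0 | Å | tetrahedra with any longer edge are not physical contacts; the retained count is the $N$ that normalizes $Q$ |
| log base | 10 | — | the bundled reference table is only reproduced with $\log_{10}$ (e.g. $\log_{10}(0.116386/0.160748) \approx -0.1402$), so "log" is implemented as base 10 throughout |
| $RT$ coefficient | 0.592 | kcal/mol | used verbatim in $\Delta G = 0.592\,\ln k$; recomputing $1.986\times10^{-3}\times298 = 0.591828$ would change printed reference values in their last digits |
| model coefficients | $1/0.0003$, $-10.49$ | — | fixed constants of the published linear model; refitting is available in `fit_regression()` but never applied silently |
| `missing_policy` | `"zero"` | — | how tetrahedra whose quadruplet was never observed in the corpus enter $Q$ (below) |

## Numerical and design choices

**Edge-filter semantics.** "Eliminating edges longer than 8 Å" is
implemented as discarding any tetrahedron with at least one edge strictly
longer than the cutoff: a tetrahedron minus an edge is no longer a
simplex, and whole-tetrahedron removal keeps $N$ well defined. A
tetrahedron at exactly 8.0 Å is retained; the comparison is done in double
precision without tolerance. $N$ counts tetrahedra *after* filtering — the
filter is applied immediately upon tessellation, so the retained set is
the tessellation being scored.

**Tessellation.** The 3D Delaunay tessellation is computed by incremental
insertion (Bowyer–Watson) in compiled code, with cached circumspheres and
double-precision insphere tests. Crystallographic coordinates are printed
at 3 decimal places and can be exactly cospherical or coplanar; when the
insertion detects an inconsistent cavity or a degenerate simplex it
retries on deterministically jittered coordinates (amplitude ≤ 1e-6 Å,
derived from a fixed counter-based stream, with a warning). Degeneracy of
a candidate simplex is judged by a scale-invariant measure,
$|\det| < 10^{-12}\,\lVert e_1\rVert\lVert e_2\rVert\lVert e_3\rVert$, so
well-shaped simplices between distant atom groups are not misflagged.
Exactly coplanar inputs and duplicate points are rejected up front with a
named error. Correctness is enforced in the test suite by an exhaustive
empty-circumsphere oracle and by cross-checking the simplex set against an
independent Delaunay implementation on a seeded cloud.

**Retained-simplex ordering.** `filter_tetrahedra()` returns simplices in
lexicographic vertex order. Scoring then sums contributions in a canonical
order, so two tessellations with identical retained sets (e.g. a complex
whose ligand lies beyond the cutoff from everything) give bit-identical
$Q$ and exactly $\Delta Q = 0$.

**Undefined scores.** Eleven of the 126 reference quadruplets were never
observed ($f = 0$) and carry no score; a corpus can also make $p = 0$ for
classes absent from its composition. Scores are stored as `NA` — never 0
or $-\infty$. At scoring time the default `"zero"` policy lets such
tetrahedra contribute 0 to the numerator while still counting in $N$
(keeping $N$'s meaning as "tetrahedra in the tessellation") with a warning
and a reported count; `"skip"` removes them from both numerator and
denominator; `"error"` aborts naming the key. The choice is conservative:
it biases $Q$ toward 0 rather than inventing an extreme score for an
unseen quadruplet.

**Atom filtering.** Hydrogens (H, D, T) and water residues (HOH, WAT,
DOD) are removed before classification. Multi-model files contribute only
their first model (a single deterministic conformer). Alternate locations
collapse to the highest-occupancy copy, ties broken by the alphabetically
first altloc identifier; the altloc and multi-model policies are this
package's documented choices, as is the explicit metal list (metalloids —
B, Si, Ge, As, Sb, Se, Te — class as X). The metal list is data, not code:
`classify_atom(..., metals = )` accepts an override.

**Composition precision.** Class frequencies $a_n$ are kept unrounded;
displayed 6-decimal values are presentation only. This matters at the
extremes — the expected rate of the all-metal quadruplet,
$a_M^4 \approx 3.86\times10^{-14}$, is reproduced only from unrounded
$a_M$.

**Evaluation statistics.** The prediction standard error uses the
$(n-2)$-denominator regression form
$\sqrt{(1-r^2)\sum(y_i-\bar y)^2/(n-2)}$; both printed algebraic forms are
implemented and tested to agree to 1e-9. The regression line is ordinary
least squares of predicted on experimental values; because the published
scatter for the training set is reported as a through-origin line
($y = 1.18x$) while the head-to-head comparison uses a free intercept,
`fit_regression()` exposes both modes rather than guessing which was
intended. Pearson's $r$ is unchanged by the affine constant-to-energy
conversion, which is what makes correlations quoted on the $pk_d$ scale
comparable with those on the $\Delta G$ scale.

**Proportionality constant.** The log-odds score is proportional to an
interaction energy with an unspecified constant; the package does not
introduce one — the empirical $1/0.0003$ scale in the binding-energy model
absorbs it.

## The bundled reference potential

`load_reference_potential()` returns the published 126-entry table (counts
from 1417 high-resolution, low-sequence-identity crystal structures;
34,504,737 retained tetrahedra) together with the corpus composition
(5,705,981 atoms). Values are stored at printed precision and validated by
checksum at load; the composition's relative frequencies are recomputed
unrounded from the counts. One misprint is known: the published X-class
proportion reads 0.000754 while the published counts give 0.000753(4);
the package keeps the counts. Deriving the table from scratch requires the
full corpus of coordinate files and is supported by `derive_potential()`
but not reproduced here.

## What the synthetic fixtures do and do not show

`random_structure()` and `toy_complex()` generate seeded, rejection-sampled
point clouds (uniform in a box, minimum pairwise separation, classes drawn
from a target composition) emitted as valid fixed-column PDB text, plus an
exhaustive `empty_circumsphere_check()` oracle. They are pure functions of
seed and spec, and they deliberately model *geometry and bookkeeping only*:
no bond lengths, sterics, secondary structure or realistic packing
density. Tests passing on them demonstrate that parsing, filtering,
tessellation, counting, scoring and the statistics are implemented
correctly — not that the potential's empirical accuracy on real complexes
is reproduced, which would require the corpus and affinity datasets.

Default study conditions used by the test and acceptance suites: point
clouds of 50–300 atoms in 16–40 Å boxes at 1.5 Å minimum separation
(composition either simple C/N/O mixtures or the reference corpus
proportions), toy complexes of 60–80 protein atoms with 5–14 ligand atoms.
These sizes give tessellations of a few hundred simplices — large enough
to exercise every code path, small enough that brute-force oracles
(exhaustive circumsphere scans, per-simplex recounts) remain exact
companions.

```{r example}
s <- random_structure(fixture_spec(60, composition = c(C = 0.7, N = 0.15,
                                                       O = 0.15),
                                   box = 18, seed = 3))
tess <- tessellate_structure(s)
tess
topological_score(tess, classify_atom(s$element),
                  load_reference_potential())
```

## Known limitations

* No chemistry-aware typing; two chemically different carbons are
  indistinguishable.
* The binding-energy map is a fixed two-parameter line; systematic errors
  for very large or very small ligands pass through unchanged.
* No solvation, entropy or pose-sampling terms; the method scores a given
  crystallographic pose.
* Near-degenerate coordinate sets are resolved by seeded jitter rather
  than exact arithmetic predicates; the jitter is deterministic and
  warned about, but simplex sets on exactly cospherical inputs are a
  documented arbitrary choice among valid triangulations.
* Periodic boundaries, symmetry expansion and multi-conformer averaging
  are out of scope.
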