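---
title: "Methods: amino acid quality scoring and origin discrimination in dried salted cod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino acid quality scoring and origin discrimination in dried salted cod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codaa)
```

## The data model

A specimen is described by its total protein content (`tp`, g/100 g of
skinless, boneless muscle — the *edible portion*) and the concentrations of
exactly 19 amino acids on the same basis. The key set is fixed: 9
indispensable (His, Ile, Leu, Lys, Met, Phe, Thr, Trp, Val), 4
conditionally indispensable (Arg, Gly, Pro, Tyr) and 6 dispensable (Ala,
Asp, Glu, Hyp, Orn, Ser). Asparagine, glutamine and cysteine are standards
in the chromatographic assay but are not quantified in the profile, so they
are deliberately absent from the data model; partial profiles are rejected
rather than zero-filled, because a silent zero would corrupt every
downstream sum and score. Species is a pure function of origin (Norway and
Iceland are Atlantic cod, Alaska is Pacific cod) and is derived, never
stored, so the two can never disagree.

The protein basis divides an edible-portion concentration by `tp` and
multiplies by 100. All inputs are stored on the edible basis; conversions
are done on demand, and class ratios are basis-invariant by construction.

### Taste-active groups

The four taste groups follow the standard assignment for fish muscle:
sweet = Ala + Gly + Hyp + Pro + Ser + Thr; bitter = Arg + His + Ile + Leu +
Met + Phe + Trp + Val; acidic = Asp + Glu + His; umami = Asp + Glu. The
acidic group nominally includes asparagine, but since asparagine is not
quantified the group reduces to the three measured members — a choice
validated by the exact reproduction of the packaged acidic cells (e.g.
Norway 2.96 + 4.21 + 0.43 = 7.60). The groups overlap and omit keys, so
only per-group additivity is asserted, not a partition of the total.

## Protein quality

The amino acid score for scoring key $i$ is
$\mathrm{AAS}_i = 100 \, c_i / r_i$, where $c_i$ is the protein-basis
concentration and $r_i$ the FAO/WHO adult requirement (g/100 g protein):
His 1.6, Ile 3, Leu 6.1, Lys 4.8, Met+Cys 2.3, Phe+Tyr 4.1, Thr 2.5, Trp
0.67, Val 4.0. Two keys are composites: Phe+Tyr sums the two measured
amino acids, while Met+Cys is scored on methionine alone because cystine
was not quantified — a conservative choice (the score can only be
understated) consistent with how the packaged score table was produced.

Limiting amino acids are the keys with AAS below 100%, reported in
ascending score order; ties at the minimum keep stable key order.

The essential amino acid index is the geometric mean of the nine ratios,
$\mathrm{EAAI} = 100 (\prod_i c_i/r_i)^{1/9}$. Ratios are **not** capped at
1: the packaged per-origin EAAI values (99.15 for Norway) are only
reachable if surpluses above the requirement are allowed to compensate
deficits, and the uncapped form is also what makes the index invariant to
rescaling all concentrations and `tp` by a common factor. Consequences
asserted in the tests: EAAI lies between the smallest and largest AAS, and
inflating any single requirement strictly decreases it.

Quality grades partition the positive axis with lower-bound-inclusive
bands: matching ≥ 100, high [95, 100), good [86, 95), useful [75, 86),
inadequate < 75. The band phrasing in the quality literature is ambiguous
at the boundaries; every packaged example (99.15 → high, 77.32 → useful,
88.61 → good) falls strictly inside a band, so the inclusivity choice is
observationally neutral and was fixed once at the lower bound.

### Cohort aggregation

For a cohort, AAS and EAAI default to per-sample computation followed by
arithmetic averaging — that is how a group-mean-with-SEM table is produced
— with a `mean_profile` mode that computes once on the averaged profile,
which is what worked arithmetic on printed group means requires. The two
do not coincide (a geometric mean of averages is not an average of
geometric means), and neither can exactly reproduce per-sample published
scores without the raw data.

### The tryptophan inconsistency

The packaged profile table implies protein-basis tryptophan far above the
0.67 requirement (AAS ≈ 355/221/293 across the origins), while the
packaged score table prints 37.17/23.32/31.01 — a roughly tenfold
discrepancy, most plausibly a decimal misprint in one of the two tables.
The package computes from the data as given and does not silently correct
either table; the score table is kept verbatim because the limiting-amino
acid conclusions (tryptophan most limiting) depend on it, and the profile
table is kept verbatim because every sum and flavour cell reproduces from
it. This is the main reason the mean-profile EAAI of Norway (≈ 128)
exceeds the printed per-sample 99.15.

## Group statistics

The design is a single fixed effect with three levels (origin) and no
random terms, so the mixed-model formulation reduces exactly to one-way
fixed-effects ANOVA; it is implemented in closed form (sums of squares,
`MSE`, pooled `SEM = sqrt(MSE/n)` under balance) with `stats::aov` kept as
an independent oracle in the tests (agreement to 1e-8 on random
instances). The two built-in contrasts are Atlantic-vs-Pacific with
weights (½, ½, −1) — unweighted averaging of the two Atlantic origins is
appropriate because group sizes are equal — and Norway-vs-Iceland
(1, −1, 0); they are orthogonal under balance. Contrast p-values are
two-sided on the residual degrees of freedom. Pairwise comparisons use the
studentized-range (Tukey) adjustment at the fitted MSE; with two groups
this reduces to the pooled two-sample t-test via $q = |t|\sqrt{2}$, which
the tests verify. No multiplicity correction is applied across variables,
matching the original analysis.

## Canonical discriminant analysis

Variable selection is greedy forward stepwise on Wilks'
$\Lambda = \det W / \det T$: for a candidate $x$ given the selected set
$S$, the partial $F$ is
$\frac{1-\Lambda_p}{\Lambda_p}\cdot\frac{N-g-|S|}{g-1}$ with
$\Lambda_p = \Lambda(S\cup x)/\Lambda(S)$; a candidate enters if its
p-value is below `entry_alpha` and selected variables whose partial-F
p-value rises above `stay_alpha` are removed, until no change. Both alphas
default to 0.15, the conventional stepwise default of the statistical
software this analysis style originates from. Candidates that make the
within-group scatter singular at a step are skipped with a warning. The
candidate list for origin discrimination is the 19 amino acids plus the
derived total amino acid content; the total is taken on the edible basis
(the basis of the stored profiles) — whether the original analysis used
edible- or protein-basis totals is not stated, and this choice is flagged
rather than hidden.

The fitted model solves the generalized eigenproblem $W^{-1}B$ via a
Cholesky-symmetrized form (numerically stable, guaranteed real
eigenvalues), retains $\min(g-1, p)$ roots sorted by eigenvalue, and
scales raw coefficients so every canonical variate has unit pooled
within-group variance; standardized coefficients multiply by the pooled
within-group standard deviations and are therefore unit-invariant, which
the tests assert under arbitrary affine rescaling of the inputs.
Canonical correlations are $\sqrt{\lambda/(1+\lambda)}$, root significance
uses Bartlett's $\chi^2$ approximation on the residual roots, and the sign
of each root is fixed by making its first nonzero coefficient positive
(canonical vectors are sign-indeterminate).

Classification uses the linear rule: equal priors, pooled within-group
covariance, assignment to the group with the smallest Mahalanobis
distance. Priors are equal because the design is balanced; a quadratic
rule is out of scope. Exact distance ties are broken deterministically by
group order and flagged — never randomly. Leave-one-out cross-validation
refits the group means and pooled covariance without each sample in turn
while keeping the variable set fixed; re-running selection inside each
fold would measure the stability of the selection procedure rather than
the prediction error of the selected model, and the classification matrix
is defined for the selected model.

## The synthetic cohort generator

The generator emulates the study design: three origins, `n = 15` specimens
per origin, per-origin mean vectors equal to the packaged group means (19
amino acids plus total protein) and a pooled per-variable SD
back-calculated from the single printed SEM column as SD = SEM·√15. The
single SEM column is interpreted as the pooled residual SEM (one column
for all origins is what a pooled-MSE table prints); it is applied to every
origin. Variables are independent by default — the printed tables carry no
covariance information, so any correlation would be invented; an
exchangeable-correlation knob (`rho`) exists because discriminant
behaviour depends on correlation structure, and it is documented as an
emulation device, not an estimate. A separability `multiplier` moves
origin means away from (or toward) the grand mean to create
easier/harder classification regimes for testing.

Draws are truncated at zero. Under independence the truncation uses exact
inverse-CDF sampling of the zero-truncated normal — identical in law to
redrawing negative values, but with bounded cost even when a large
multiplier pushes a shifted mean below zero. With `rho > 0`, whole rows
are redrawn (bounded retries) to preserve the joint distribution.
Truncation matters for the high-variance, low-mean variables (tryptophan,
hydroxyproline, lysine): their simulated means sit above the nominal means
by the standard truncated-normal correction
$\mu + \sigma\,\phi(\alpha)/(1-\Phi(\alpha))$, and the parameter-recovery
tests compare against that analytic value rather than pretending the bias
does not exist.

**What passing tests show, and what they do not.** The generator
reproduces first and second moments and the printed direction of the large
between-origin differences; downstream, calibrated cohorts yield two
canonical roots with cumulative proportion 1 and a leave-one-out confusion
pattern in which Norway misclassifications go to Iceland rather than
Alaska — the qualitative structure of the original classification matrix.
None of this shows that real per-sample data are multivariate normal,
uncorrelated, or homoscedastic across origins; amino acid concentrations
within a specimen are in reality strongly correlated (they share total
protein), and seasonal/spawning covariates are not modelled.

**A calibration caveat the tests surface honestly.** The printed SEM
column and the printed contrast p-values are mutually inconsistent for
several amino acids (e.g. a serine Atlantic-vs-Pacific contrast estimate
of 0.015 with SEM 0.07 cannot yield p = 0.001). A generator calibrated to
the SEM column therefore cannot reproduce the printed significance
structure: at n = 15 the sign of the smaller printed contrasts agrees with
the printed direction in well under 95% of seeds for several amino acids,
and the acceptance-style test asserting ≥ 95% directional agreement for
every amino acid fails for exactly those variables. The test is kept as
stated and left failing, because weakening it would hide a real property
of the published summary statistics. Contrasts with a zero printed
difference (ornithine, Norway vs Iceland) have no direction and are
skipped.

## Numerical choices and problem sizes

* Printed-value comparisons use absolute tolerance 0.05: the inputs are
  printed to 2 decimals, so recomputed sums can differ by up to ~0.05 from
  printed cells through rounding alone.
* Scatter conservation ($B + W = T$), basis round-trips and oracle
  equivalences are asserted at 1e-8–1e-9; Wilks' Λ uses log-determinants.
* Degenerate inputs fail loudly: zero within-group variance flags the F
  statistic, singular within-scatter raises an error advising variable
  reduction, zero denominators in ratios and scores are domain errors.
* Report files render floats with 4 significant decimals and are written
  bytewise, so identical inputs give byte-identical outputs.
* Test problem sizes were chosen for tightness per unit time: moment
  recovery at n = 4000 (unit tests) and n = 10000 (acceptance property)
  per origin, 100 seeds for directional agreement, 8 seeds for the
  cross-validated confusion direction; the multi-comparison Monte-Carlo
  bands use a 3.9σ (family-wise ≈ 1%) allowance across the 60
  simultaneous mean checks.

## Known limitations

* Digestibility-corrected scores (PDCAAS/DIAAS) and age-specific reference
  patterns other than the adult pattern are not implemented.
* The exact published eigenvalues (25.5199), canonical correlations and
  the Norway misclassification count require the unavailable raw
  per-sample data; the package reproduces the structure (root count,
  proportions, confusion direction), not those numbers.
* Free vs protein-bound amino acid speciation is not modelled; the taste
  sums quantify potential, not sensory outcome.
* Fixture-mode pipelines grade protein quality from the packaged
  per-sample EAAI row, since mean-profile EAAI is distorted by the
  tryptophan inconsistency described above.
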