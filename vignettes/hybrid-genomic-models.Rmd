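---
title: "Origin-specific genomic models for single-cross hybrids: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Origin-specific genomic models for single-cross hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridGP)
```

# The genetic model

`hybridGP` analyses single-cross hybrids of fully inbred lines drawn
from two heterotic groups.  Because each parent is homozygous, it
transmits one fixed gamete to every hybrid, so the classical partition
into general (GCA) and specific (SCA) combining abilities has a precise
marker-level counterpart: GCA collects within-group additive
substitution effects and within-group additive×additive (and higher)
epistatic deviations; SCA collects dominance deviations, across-group
additive×additive epistasis, and dominance-involving interactions.

## Single locus

For a biallelic locus with group-1 alleles B₁/b₁ at frequency p₁ and
group-2 alleles B₂/b₂ at p₂, genotypic values are G(B₁B₂) = a₁ + a₂,
G(B₁b₂) = a₁ + d, G(b₁B₂) = a₂ + d, G(b₁b₂) = 0.  Enumerating an ideal
hybrid population (class frequencies p₁p₂, p₁q₂, q₁p₂, q₁q₂) gives the
population mean E(G) = p₁a₁ + p₂a₂ + (p₁q₂ + q₁p₂)d, the substitution
effects α₁ = a₁ + (q₂ − p₂)d and α₂ = a₂ + (q₁ − p₁)d — each involving
the *other* group's frequencies — gamete codes z₁ ∈ {q₁, −p₁},
z₂ ∈ {q₂, −p₂}, and dominance deviations g_D = w·d with w = −2 z₁ z₂.
The three statistical components have zero weighted means, zero pairwise
weighted cross-products, and variances p₁q₁α₁², p₂q₂α₂² and
4p₁q₁p₂q₂d² that add exactly to the total genotypic variance.

`decompose_locus()` implements these closed forms;
`dominance_deviation_by_subtraction()` re-derives the dominance
deviations along the independent route G − E(G) − g_A1 − g_A2, and
`verify_substitution_definition()` checks the three printed routes to
α₁.  These mutual checks are the package's core self-validation: the
matrix pipeline is trusted because it agrees with exhaustive
enumeration on every random parameter draw the test suite throws at it.
One printed intermediate in the source derivation (the average allele
effect of B₁) is typeset ambiguously in the literature this follows;
the package uses the algebraically exact form α_B1 = q₁α₁, which the
enumeration oracle confirms.

## Relationship matrices

With M₁, M₂ the 0/1 homozygote-indicator panels and p the observed
column frequencies, Z = M − 1p′ and the matrices are

* `G_A(1) = Z₁Z₁′/Σp₁q₁`, `G_A(2)` analogously (line level);
* `D = WW′/Σ4p₁q₁p₂q₂` with W[h,·] = −2·z₁(parent1)·z₂(parent2)
  (hybrid level);
* Hadamard-product epistatic matrices, each rescaled to mean diagonal 1
  by its trace over n: `G_AA(1,1)`, `G_AA(2,2)` within groups and
  `G_AA(1,2) = (T₁G_A(1)T₁′) ⊙ (T₂G_A(2)T₂′)/(tr/n)` across groups,
  where T₁, T₂ map hybrids to parents.  The Kronecker pair coding
  satisfies Z₁₁Z₁₁′ = (Z₁Z₁′) ⊙ (Z₁Z₁′) exactly, which is asserted
  explicitly at small size in the tests;
* dominance-involving matrices `G_A(1)D`, `G_A(2)D`, `G_DD`
  (constructible; excluded from stock model codes because their
  variance components are practically inestimable);
* the hybrid-level NOIA matrices `G_AH`, `D_H`, `G_AAH` of the G-model,
  built from the Ha/Hd codings without assuming Hardy–Weinberg
  equilibrium in the hybrid set.

The Σpq-type denominators for `G_A` and `D` and the tr/n denominators
for every epistatic and G-model matrix are used exactly as derived; no
blending, weighting or diagonal inflation is applied to stored
matrices.  With observed frequencies, `G_A` has mean diagonal exactly 1
and mean entry exactly 0, and `D` has mean diagonal exactly 1 under a
complete factorial — these identities are the package's acceptance
anchors, at tolerance 1e−10.

A within-group epistatic scaling note: the trace-based denominator
tr(G_A ⊙ G_A)/n is used, not the analytic (Σpq)² alternative that also
appears in the literature; the two differ by a factor that approaches 1
as panels grow.

## The evaluation models

The GCA-model, in its fullest stock form, is

y = 1μ + T₁g_A1 + T₂g_A2 + g_D + T₁g_AA(1,1) + T₂g_AA(2,2) + g_AA(1,2)
    + T₁r(1) + T₂r(2) + e

with each random term normal with its relationship matrix and variance.
The "residual genetic" r terms are i.i.d. line effects, estimable
because lines repeat across hybrids; they absorb higher-order
within-group epistasis not explicitly modelled and keep the additive
estimates stable across model complexity.  The G-model,
y = 1μ + g_AH + g_DH + g_AAH + e, defines effects uniquely at the
hybrid level; r terms are not estimable there because entry-mean data
carry one record per hybrid.  `hybrid_model()` exposes the nine stock
codes; the dominance-involving epistatic terms can be added explicitly.

# Inference

## Eigen-designs

Each term's hybrid-level covariance TKT′ is eigendecomposed once and
replaced by the design B = UΓ^½ over the retained spectrum, so the term
becomes a Bayesian ridge regression whose coefficient variance is the
term's variance component on the kinship scale.  Eigenvalues below
1e−10 of the largest are dropped (numerically null or negative
directions; the dropped mass is recorded on the design).  A ridge of
1e−8 stabilizes the retained eigenvalues inside this step only.
Because B has orthogonal columns, the Gibbs update for a term's
coefficients is a single joint draw with diagonal precision — exact,
fast, and free of the slow coordinate-wise scans that plague
high-dimensional samplers.  When a fit subsets training rows (as in
cross-validation), the subset design is re-diagonalized once per fit
through the eigendecomposition of its cross-product, keeping the block
update exact.

## Gibbs sampler and priors

The sampler uses standard conjugate updates: flat prior on μ, one
multivariate-normal block per term, scaled inverse-chi-square draws for
every variance (df₀ = 5).  Prior scales follow the common
Bayesian-ridge default: a fraction R² = 0.5 of var(y) is split equally
across the genetic terms (prior mode R²·var(y)/n_terms each) and the
residual prior mode is (1 − R²)·var(y).  Both df₀ and R², and per-term
scales, are exposed in `chain_config()`.  Chain defaults are 60,000
iterations, 30,000 burn-in, thinning 10; runs are bit-reproducible for
a fixed seed.  A `fix_variances` argument clamps any subset of
variances, turning the sampler into a draw from the effect posteriors
at known variances; in that regime the posterior-mean genetic values
match generalized-least-squares BLUP computed from the total
phenotypic covariance (correlation > 0.999 in the test suite's
300-hybrid check).

## Summaries

`summarize_fit()` reports posterior means and SDs of all variances, the
genomic broad-sense heritability, DIC, and the aggregates
σ²GCA(1) = σ²A(1) + σ²AA(1,1) + σ²r(1) (and analogously for group 2)
and σ²SCA = σ²D + σ²AA(1,2) (+ dominance-involving terms when fit).
Two conventions are deliberately pinned down because the source
material leaves them open:

* **H²** is computed per posterior sample as the sum of *all* fitted
  genetic-term variances, r terms included, over that sum plus σ²e.
  Which terms enter the numerator is not uniquely defined in the
  literature; including every fitted genetic term is the choice here
  and is stated in the summary's metadata note.
* **DIC** uses the conditional Gaussian deviance given the sampled
  effects (D̄ + pD with pD = D̄ − D at posterior means), the practical
  convention of Bayesian ridge software.  DIC variants differ; the
  convention is recorded in the summary rather than assumed comparable
  across software.

# Cross-validation

`make_cv_split()` samples nD group-1 and nF group-2 lines, draws the
training set uniformly from hybrids whose two parents are both sampled
(resampling lines up to a cap if the pool is short — the uniform rule
is the package's choice; the protocol it follows does not specify how
training hybrids are drawn from the sampled lines), and labels the
remaining hybrids T2/T1/T0 by how many of their parents occur among the
training hybrids' parents.  Defaults are 300 training hybrids from
90 × 53 lines and 100 replicates.  `run_cv()` derives all per-replicate
seeds from one master seed, so different model codes evaluated at the
same seed see identical splits (paired comparison).

Predictive ability divides the predicted–observed correlation by H²
taken from a full-data fit of the most complete GCA-model.  The printed
protocol this mirrors says "divided by H2", which may denote √H²
typeset as a root; both modes (and no division) are implemented, the
default is the literal `h2`, and the mode used is recorded in the
result.

# The synthetic-data generator

`sim_config()` defaults emulate the structure of the published
Dent × Flint maize study the models were demonstrated on: 123 × 86
inbred lines, an incomplete factorial of 1,254 hybrids with every line
represented, two Beta(2, 2) founder-frequency laws truncated to
[0.05, 0.95], intercept 100 (a realistic grain-yield entry mean in
q/ha, chosen by the package since the study does not print its mean),
and variance components equal to that study's fullest-model estimates
(19.06, 10.61, 2.3, 5.41, 5.57, 3.24, 3.8, 4.56, 13.67).  The default
marker panel is 5,000 LE loci, a desk-scale stand-in for a 35k chip:
under linkage equilibrium every quantity the theory uses is governed by
Σpq-type sums that the generator's rescaling fixes exactly at any panel
size.

Marker effects are drawn i.i.d. normal per class and rescaled once so
the realized analytic variance — Σp₁q₁α₁², Σ4p₁q₁p₂q₂d², and the pair
sums for 500 sparse epistatic pairs per class — equals its target
exactly; residual genetic and residual effects are drawn at their
target variances without rescaling.  A functional mode draws a₁, a₂, d
per locus and derives the statistical effects through the single-locus
theory before the same rescaling, exercising the enumeration module
end to end.

**What the generator does not emulate.**  Founders are unrelated and
loci are in linkage equilibrium, whereas real heterotic groups carry
strong within-group LD and pedigree structure.  Two consequences matter
for interpreting green tests.  First, with LE and unrelated founders
the line relationship matrices are close to identity, so the additive
and residual-genetic variances of a group — and likewise σ²D versus
σ²e, since entry means carry one record per hybrid — are only weakly
separated by the likelihood; their *sums* (the GCA totals, and the
non-parental variance) are estimated sharply, the splits with wide
posteriors.  The parameter-recovery test therefore accepts a component
through either a 25 % relative-error criterion on the posterior mean or
coverage by the pooled central 95 % interval.  On real, LD-structured
panels the matrices are far from identity and the splits are better
identified.  Second, monomorphic-in-one-group markers are retained, as
in the real study; their pq = 0 terms contribute nothing to any
scaling.  Markers monomorphic in *both* groups are also kept and
contribute zero columns — dropping them would silently change panel
alignment.

# Numerical and degenerate-input policy

* Genotype calls are strictly {0, 1}; missing calls fail loudly unless
  per-marker major-allele imputation is explicitly requested (silent
  imputation would distort the Σpq scalings).
* Marker panels of the two groups must match exactly;
  intersect-and-reorder is an explicit flag.
* All-fixed panels (Σpq = 0) and no-marker-segregating-in-both-groups
  studies (Σ4p₁q₁p₂q₂ = 0) are hard errors.
* The NOIA Hd coding's denominator p_BB + p_bb − (p_BB − p_bb)² can be
  zero (e.g. every hybrid heterozygous at a marker); such columns are
  zeroed rather than dropped, contributing no covariance while
  preserving panel alignment.  In a hybrid set that happens to be in
  HWE, Hd reduces exactly to the classical {−2q², 2pq, −2p²} coding.
* Boundary allele frequencies in the locus oracle return zero-variance
  components, matching the monomorphic-marker policy.
* Kinship files are written with 17 significant digits so both text
  formats round-trip bit-exactly.

# Problem sizes in the test suite

The suite validates the analytic identities at 30–50 lines × 120–500
markers (they are exact at any size), the Kronecker/Hadamard identity
at ≤ 5 lines × ≤ 4 markers where the pair coding is explicit, BLUP
equivalence at 300 hybrids, parameter recovery at 100 × 80 lines,
1,000 hybrids and 2,000 markers over three seeds with 6,000-iteration
chains, and the cross-validation ordering (T2 > T1 > T0 on
additive-only data) at 20 × 16 lines with 5 replicates.  These sizes
are the package's own trade-off between resolution and a test suite
that runs in minutes; every identity-based check is size-independent.

# Known limitations

* Two heterotic groups only; the algebra extends to more groups but the
  containers and model codes do not.
* Third- and higher-order epistatic matrices are not emitted (the same
  Hadamard pattern would build them).
* No multi-environment or multi-trait modelling; fixed effects beyond
  the intercept are not exposed.
* REML is not provided; inference is Gibbs sampling only.
* LE-only simulation, as discussed above.
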