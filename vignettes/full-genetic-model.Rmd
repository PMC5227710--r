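---
title: "The full genetic model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The full genetic model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullgem)
```

## The model

`fullgem` fits a quantitative trait measured in a multi-ethnic cohort with a
*full genetic model*: for record $k$ of an individual in ethnic group $h$,

$$
y_{hk} = \mu + s_k
  + \sum_i x^A_{ik} a_i + \sum_i x^D_{ik} d_i
  + \sum_{i<j} \left( x^{AA}_{ijk} aa_{ij} + x^{AD}_{ijk} ad_{ij}
      + x^{DA}_{ijk} da_{ij} + x^{DD}_{ijk} dd_{ij} \right)
  + e_h + \sum_i x^A_{ik}\, ae_{ih} + \sum_i x^D_{ik}\, de_{ih}
  + \cdots + \varepsilon_{hk},
$$

where $s_k$ is the sex block (0 female, 1 male), $a_i$ and $d_i$ are the
additive and dominance effects of locus $i$, the four digenic epistasis
effects are products of the single-locus codings, and $e_h$ and the
locus-by-ethnicity terms ($ae$, $de$, and the epistasis-by-ethnicity classes
$aae \ldots dde$) are random effects with zero-mean normal distributions and
one variance per class. The codings are fixed by allele orientation, with
"Q" the **major** allele:

* additive: $x^A = 1$ for QQ, $0$ for Qq, $-1$ for qq;
* dominance: $x^D = 1$ for Qq, $0$ for both homozygotes;
* epistasis: products of the two loci's codings
  ($x^{AA} = x^A_i x^A_j$, etc.), which reproduce the enumerated
  coefficient tables (e.g. $x^{AA} = 1$ for QQ$\times$QQ and qq$\times$qq,
  $-1$ for QQ$\times$qq and qq$\times$QQ, 0 otherwise).

A reported additive effect is therefore the effect of the major-allele
homozygote relative to the homozygote midpoint, and a dominance effect is
the heterozygote's deviation from that midpoint. The reduced *multi-locus
additive model* keeps only $\mu$, sex, the $a_i$ terms and the $e$/$ae$
random classes. The ethnic groups are coded 1 = European-American,
2 = Chinese-American, 3 = African-American, 4 = Hispanic-American.

Repeated examinations (two per individual by default) enter as stacked
replicate records. The printed model carries no replicate term, so records
are conditionally independent given the genetic value; we considered an
optional random individual effect to absorb repeat correlation and did not
implement it — under the generator below, replicates share their entire
genetic value and the residual is exchangeable, which is exactly the
stacked-records assumption. With real repeat data whose correlation exceeds
the modeled genetic share, experiment-wise calibration still holds (the
permutation unit is the individual) but effective sample size is
overstated; this is a known limitation.

## Estimation and testing

**Henderson method III.** All variance components are estimated from
differences of least-squares reductions, treating every effect as fixed.
For random class $v$, the observed reduction
$R(\text{all}) - R(\text{all} \setminus v)$ is equated to its expectation —
a linear combination of the class variances (trace terms) plus the added
rank times $\sigma^2_\varepsilon$ — and the resulting linear system is
solved; negative solutions are truncated at zero and flagged. Because every
reduced model retains all fixed columns, fixed effects cancel from each
class equation. On balanced designs this reproduces the classical ANOVA
moment estimators exactly (the test suite checks one-way and two-way
cases).

**Term-wise F statistics.** Each term's F is its reduction in residual sum
of squares divided by its added degrees of freedom and the residual mean
square of the all-columns fit. The interaction coefficient columns of one
locus sum over the four groups to the main-effect column, so a naive
type-III conditioning set makes mains and levels mutually aliased. We use
marginality-respecting conditioning:

* a main effect is tested *without* its own interaction levels in the
  conditioning set;
* an interaction **level** is tested given the main term but without the
  other levels of its family — the tested direction is the level's
  deviation orthogonal to the main effect, the identifiable per-level
  contrast;
* the joint interaction class adds rank 3 given the main term.

The exact quadratic forms used by the original software are not published;
whatever the choice, the permutation calibration below keeps the
experiment-wise test valid, and the per-level convention above gives
interaction tests their deviation semantics (a purely additive locus does
not light up its own interaction levels).

All reductions are computed in the coordinates of one orthonormal basis of
the full design's column space, with a small precomputed contrast basis per
term. The design is decomposed once; each additional response vector (a
permutation, a simulation replicate) costs a single matrix-vector product.
This is what makes permutation nulls and repeated-simulation studies
affordable at $n \approx 10^4$ records.

**Experiment-wise thresholds.** The null of the maximum F over all tested
terms is built from `n_perm` permutations (2000 by default). The
permutation unit is the individual — replicate records move together — and
non-genetic structure is preserved Freedman–Lane style: residuals from the
intercept + sex + ethnicity fit are permuted and the fitted values added
back. (Relabelling raw records against genotype rows would force a fresh
decomposition per permutation, since the interaction columns mix genotype
and ethnicity; permuting nuisance residuals keeps the design fixed and is
at least as faithful under the null.) The critical value is the empirical
$(1-\alpha_{EW})$ quantile. P values within resolution use the add-one
empirical tail; beyond $1/(n_{perm}+1)$ a generalized Pareto distribution
fitted to the top 10% of max-F samples extrapolates the tail, and such
values are flagged. Extrapolated tails are order-of-magnitude statements,
not exact probabilities.

**Gibbs estimation.** Effects are estimated by a standard Bayesian linear
mixed-model sweep (20000 iterations by default, 2000 burn-in, thinning 1):
flat priors on fixed effects, one IG(0.001, 0.001) variance per random
class and for the residual. Conditionals are computed from precomputed
cross-products, so chain cost is dimension-bound, not record-bound.
Posterior means and SDs are reported per fixed term and per interaction
level.

A consequence worth knowing: with one variance per interaction class and
many levels that are truly zero, strong levels are shrunk toward zero by
the factor $\sigma^2_v / (\sigma^2_v + \mathrm{SE}^2)$. For levels observed
in the smaller ethnic groups this bias is visible even at
$n \approx 5{,}000$ individuals. The simulation study shows the same
signature the original analysis prints for such levels (mean estimates
noticeably below large interaction truths). Fixed main-effect and epistasis
estimates are unbiased in our checks.

**Heritability.** Each term's contribution is the sample variance across
records of its predicted component (coefficient column times estimate),
with a locus's four interaction levels pooled into one contribution.
Contributions are divided by the phenotypic variance and summed into six
classes (additive, dominance, epistasis, and their ethnicity interactions);
the total is the exact sum of the class shares — an identity the tests
assert. The published heritability formulas are schematic component sums;
realized coefficient variance is our concrete reading of "contributed by
sum of individual locus".

## The analysis pipeline

1. **QC**: drop SNPs with MAF $< 0.05$ or call rate $< 0.90$ (strict
   inequalities — a SNP exactly at a boundary is retained). No
   Hardy–Weinberg filter: in a pooled multi-ethnic sample HWE fails by
   construction.
2. **Screening** (`screen_candidates`): a 1D per-SNP joint F test of the
   additive and dominance codings (sex and ethnic means adjusted), then a
   2D epistasis F test over pairs of the top SNPs. This replaces the
   GPU-based multifactor-dimensionality screening of the original
   pipeline, whose internals are separate prior software; a 3D scan is
   omitted because no three-way interactions are reported.
3. **Model building** (`stepwise_build`): forward selection by largest
   conditional F with a nominal entry gate, aliased candidates (e.g. a
   duplicate SNP in complete LD) barred, ties broken by genome order, then
   backward elimination keeping loci/pairs with at least one
   experiment-wise significant term. The search used by the original
   analysis is not published; forward-with-backward is the conventional
   choice.
4. **Fitting** (`fit_full_model` / `fit_additive_model`): F tests,
   permutation calibration, Henderson III components, Gibbs estimates,
   heritability partition; outliers can be removed once by standardized
   residuals ($|z| > 3$) and the model refit.
5. **Single-locus baseline** (`single_locus_scan`): per-SNP least-squares
   regression on minor-allele dosage with sex and top-10 PC covariates,
   one exam at a time; genomic control $\lambda_{GC}$ from the median
   association $\chi^2$; LD pruning (window 50, step 5, $r^2 > 0.75$,
   lower-MAF member dropped) to count approximately independent tests for
   the Bonferroni threshold $-\log_{10}(0.05/m)$. The mixed-model
   single-locus arm of the original comparison (leave-one-chromosome-out
   GRM) is intentionally not re-implemented; its published simulations
   behave like or worse than the plain scan.

## The synthetic cohort

The real study data are access-controlled, so `fullgem` ships a generator
that emulates their statistical structure:

* four ethnic groups at the recruitment shares 38% E-A, 12% C-A, 28% A-A,
  22% H-A of $n = 5{,}277$ individuals;
* per-group allele frequencies from the Balding–Nichols model around an
  ancestral MAF (default 0.30 at model loci — not printed in the original
  study; 0.30 keeps every coding class populated in each group), with
  FST = 0.05 — enough differentiation to exercise stratification control
  without overwhelming the interaction effects;
* Hardy–Weinberg genotypes within group; optional LD blocks through a
  Gaussian copula on the haplotype draws, with `ld_rho` on the
  interpretable allele-correlation scale (genotype $r^2 \approx
  \rho^2$) and one drift draw shared per block (independent drift would
  dilute within-block $r^2$ well below the 0.85 LD-representative
  threshold);
* two phenotype records per individual; trait
  $y = \mu + \text{sex effect} + \text{genetic value} + \varepsilon$, with
  $\mu = 200$ and a sex difference of 5 trait units (a total-cholesterol
  scale in mg/dL; the sex effect is a scale-setting choice, absorbed by
  the sex block);
* residual SD calibrated (`calibrate_residual`) so either the total
  genetic share or one anchor effect's share matches a target — the
  default anchors the largest additive effect (the CELSR2-analog locus,
  $a = 4.94$) at its published 1.46% of phenotypic variance, since the
  error variance itself is not printed.

Scenario I uses the full-model truth set (52 effects at 17 loci and 4
epistasis pairs, the published simulation parameter column); scenario II
the additive-model truth (13 additive effects, with additive-by-ethnicity
effects zero unless supplied, their published values being in unavailable
supplementary material).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: real haplotype structure and genome-wide LD
(blocks are exchangeable-copula constructs), within-group admixture
(genotypes are in exact HWE within each labeled group, while self-reported
ethnicity hides a continuum of ancestry), genotyping batch effects, and
trait non-normality. The within-group HWE assumption has one analytically
provable consequence: a linked partner's additive dosage is orthogonal to a
truth locus's dominance coding given the truth dosage, so the additive
model cannot accumulate the LD-neighbor false positives the original
simulation reports (its published 15.5% vs 3.7% FDR gap rides on real
genotype structure). Our evaluation therefore reproduces the gap's
companion observations — dominance-only loci invisible to the additive
model, similar FDR under an additive truth, LD-adjusted FDR collapsing
toward zero — while the raw-FDR ordering itself is left as an asserted,
documented expectation that desk-scale synthetic cohorts do not reliably
reproduce.

## Numerical choices

* Rank decisions use QR with column pivoting at R's default tolerance;
  aliased tested terms raise errors (zero added rank) rather than silently
  returning 0.
* Negative Henderson III solutions truncate to zero (flagged); the
  residual variance is kept strictly positive.
* The permutation quantile is the order-statistic upper quantile, so
  `alpha_ew = 1` returns the null minimum, and the add-one correction
  keeps P values in $(0, 1]$.
* Stepwise ties break by (chromosome, position); duplicated candidates can
  never both enter (the second is aliased).
* Gibbs chains abort with the iteration index on any non-finite draw; a
  zero-variance response is rejected up front.
* Problem sizes in the shipped tests: the anchor-power study runs 50
  simulations at the full cohort size with 500 permutations each (the
  fixed-design engine makes this a matter of one to two minutes); property
  suites use cohorts of 100–2,000 individuals and the recovery study 50
  Gibbs fits at $n = 2{,}000$.

## Known limitations

* Interaction-level shrinkage, as discussed above: strong per-level
  estimates in small groups are biased toward zero under the class-variance
  prior.
* Tail P values beyond the permutation resolution are generalized-Pareto
  extrapolations; treat $-\log_{10} P_{EW}$ values far above the
  resolution (about 2.7 for 500 permutations, 3.3 for 2000) as order
  statements.
* The screening stage is a plain F-test filter, not a reimplementation of
  the multifactor-dimensionality software it stands in for; candidate sets
  on real data would differ.
* X-chromosome dosage, imputation, phasing and multi-allelic sites are out
  of scope.
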