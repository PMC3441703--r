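---
title: "Genomic BLUP with additive, dominance and epistatic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic BLUP with additive, dominance and epistatic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nagblup)
```

## The model

`nagblup` fits the linear mixed model

$$
\mathbf{y} = \mathbf{1}\mu + \mathbf{a} + \mathbf{i} + \mathbf{d} +
             \mathbf{Z}_l\,\mathbf{l} + \mathbf{e},
$$

where $\mathbf{y}$ is a vector of phenotypes already corrected for
non-genetic fixed effects, $\mathbf{a}$, $\mathbf{i}$ and $\mathbf{d}$
are additive, additive-by-additive epistatic and dominance genetic
values, $\mathbf{l}$ is an iid litter (common-environment) effect and
$\mathbf{e}$ the residual.  The genetic terms are multivariate normal
with covariances proportional to marker-derived relationship matrices:

$$
\mathbf{a} \sim N(0, \mathbf{G}\sigma^2_a), \quad
\mathbf{i} \sim N(0, (\mathbf{G\#G})\,\sigma^2_{aa}), \quad
\mathbf{d} \sim N(0, \mathbf{D}\sigma^2_d),
$$

with $\#$ the Hadamard (elementwise) product.  Dropping terms gives the
four standard nested models compared by `fit_model_family()`: `MA`
(additive + litter), `MAE` (+ epistasis), `MAD` (+ dominance), `MAED`
(all three).

## Relationship matrices

**Additive.** With allele-2 frequency $p_i$ at locus $i$, the centred
additive coding takes the values $-2p_i$, $1-2p_i$, $2-2p_i$ for the
three genotypes (VanRaden's coding), and

$$\mathbf{G} = \frac{\mathbf{M}\mathbf{M}'}{2\sum_i p_i q_i}.$$

**Dominance.** The dominance value of a genotype loads on its
heterozygosity.  Centring the 0/1 heterozygosity indicator by its
Hardy–Weinberg expectation $2p_iq_i$ gives the coding $-2p_iq_i$
(either homozygote) and $1-2p_iq_i$ (heterozygote), and

$$\mathbf{D} = \frac{\mathbf{H}\mathbf{H}'}{\sum_i 2p_iq_i(1-2p_iq_i)}.$$

The denominator is the unique constant for which, in a Hardy–Weinberg
population, a non-inbred individual has expected diagonal 1 and two
unrelated individuals have expected off-diagonal 0 — the same
normalization logic as for $\mathbf{G}$.  Both expectations are checked
by Monte Carlo in the test suite.

**Epistasis.** Following Henderson's covariance argument, the
additive-by-additive relationship matrix is approximated by
$\mathbf{G}\#\mathbf{G}$ (ignoring inbreeding), and higher orders by
further Hadamard products (`grm_epistatic(G, G, D)` gives
additive-by-additive-by-dominance, and so on).  No rescaling is applied
after the product: the expectation properties of the factors carry
through approximately, and rescaling would change the variance-component
scale without improving the approximation.

**Numerical conventions.** Allele frequencies are computed from the
analysed sample after quality control (an external base-population
frequency table can be supplied).  A missing genotype contributes its
expectation — exactly 0 on either centred scale — while the scale
denominators always sum over all retained loci.  Fixed loci are
rejected; quality control removes them first.  Positive semidefiniteness
is enforced only where a factorization is actually needed (REML,
simulation draws), by escalating diagonal jitter $0 \to 10^{-10} \to
10^{-8} \to 10^{-6}$, never at construction.

## Quality control

`qc_filter()` applies the standard chip-editing rules in a fixed,
documented order: loci with minor allele frequency not strictly above
0.05, then loci with call rate not strictly above 0.95 (both computed on
the input), then individuals with call rate not strictly above 0.95 over
the retained loci.  All thresholds are strict inequalities.  Frequencies
used downstream are recomputed on the filtered matrix.  Per-genotype
quality masking (e.g. clustering-score filters from a genotyping
platform) is expected to have been applied upstream by setting entries
missing; the package only handles the missing mask.

## REML estimation

Variance components are estimated by restricted maximum likelihood with
average-information (AI) updates.  The criterion is the standard

$$-2\ell_R(\theta) = \log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}|
  + \mathbf{y}'\mathbf{P}\mathbf{y},$$

omitting the additive constant.  Each iteration takes a full AI step;
if the proposal leaves the feasible region or increases the criterion,
the step is halved up to 10 times, and if that fails a single EM-REML
step is taken instead, which cannot decrease the restricted likelihood.
This AI-with-EM-fallback scheme follows the practice of the established
REML packages of animal breeding (DMU/ASReml lineage) while keeping the
update rules explicit and testable.  Details that are the package's own
choices, since the cited lineage does not fix them:

* **Lower bound** $10^{-6}\,\mathrm{var}(y)$ per component.  Components
  that land there are *pinned*: reported, flagged, and excluded from the
  AI matrix when standard errors are computed (their SE is `NA`).
* **Convergence** requires both a relative change in $-2\ell_R$ below
  `tol` (default $10^{-8}$) and a maximum relative parameter change
  below $10^{-6}$.
* **Starting values**: residual $= 0.5\,\mathrm{var}(y)$, each other
  term $0.5\,\mathrm{var}(y)/(\text{number of random terms})$.
* **Dense algebra** throughout; the target scale is a few thousand
  genotyped individuals, where explicit $\mathbf{V}^{-1}$ via Cholesky
  is both fastest and simplest.

Standard errors come from the inverse AI matrix at the optimum.  The
test suite cross-checks the criterion against an independent
error-contrast evaluation, the optimum against a derivative-free
optimizer and against `lme4` on overlapping model classes, and the
closed-form residual-only case.

## Prediction

At the converged variance components the BLUP solutions follow from the
mixed-model equations.  Relationship matrices span reference *and* test
individuals; test individuals simply carry no phenotype record, so their
solutions are the covariance projection of the reference solutions
($\hat{u}_{test} = \mathbf{K}_{tr}\mathbf{K}_{rr}^{-1}\hat{u}_{ref}$ —
the equality of the two routes is a test).  `predict()` returns per-term
solutions, the genomic breeding value (`gbv`, the additive solution) and
the total genetic value (`gtv`, the sum of all genetic-term solutions,
excluding litter).  For a purely additive model, GBLUP is algebraically
identical to ridge-regression SNP-BLUP with shrinkage
$\lambda = \sigma^2_e / (\sigma^2_a / 2\sum p_iq_i)$; the test suite
verifies agreement to $10^{-6}$.

## Evaluation statistics

* **Likelihood-ratio tests** compare nested fits on identical records;
  the reference distribution is the plain central $\chi^2$ with degrees
  of freedom equal to the number of added variance components.  The
  50:50 boundary-mixture correction (appropriate because a variance is
  tested on the boundary) is available via `boundary_mixture = TRUE` but
  is *not* the default: the plain-$\chi^2$ convention is the one used in
  the applied genetic-evaluation literature this package mirrors, and it
  is conservative.
* **Reliability** of predicted breeding values validated against a
  corrected phenotype is $r^2/h^2$, with $h^2$ defaulting to the
  narrow-sense estimate of the fullest fitted model.
* **Unbiasedness** is the OLS slope of the validation phenotype on the
  prediction, with slope 1 as the unbiased reference.
* **Hotelling–Williams test** for dependent correlations uses Williams'
  $t$ (the form recommended by Steiger), since the two model accuracies
  being compared share the same validation phenotypes.  A Monte-Carlo
  null oracle in the test suite confirms its p-values.
* Correlations are Pearson throughout.

## The simulator

`simulate_genotypes()` creates founders in Hardy–Weinberg equilibrium at
allele frequencies drawn uniformly from $[0.05, 0.95]$, then breeds a
reference generation by Mendelian gamete sampling from randomly mated
founder pairs, grouped into full-sib litters, and a test generation from
reference-generation parents.  This gives genuine genomic relatedness
(full sibs average additive relationship 0.5), a litter structure for
the common-environment effect, and a by-generation reference/test split
that mirrors how genomic predictions are validated on the youngest
animals in practice.  Defaults — founder pool 80, litter size 8 — are
chosen to resemble a closed pig nucleus population; litter size 8 is a
typical rearing-group size and the founder pool keeps average
relatedness at realistic within-breed levels.

`simulate_phenotypes()` adds the five phenotype components.  Two modes:

* **`mvn`** draws each genetic component multivariate normal with
  covariance proportional to the *realized* relationship matrix.  This
  matches the GBLUP model assumptions exactly and is what the
  parameter-recovery tests use.
* **`locus`** draws iid per-locus additive effects, dominance values,
  and pairwise additive-by-additive effects, scaled so expected
  component variances hit the targets.  It provides genotype-anchored
  realism (effects attached to markers rather than to the covariance
  structure) for robustness checks.

The default true variances $(\sigma^2_a, \sigma^2_{aa}, \sigma^2_d,
\sigma^2_l, \sigma^2_e) = (2000, 500, 300, 500, 2200)$ are the
magnitudes, in (g/day)$^2$, typical of average daily gain in pig
breeding populations: narrow-sense heritability near 0.4, dominance and
epistatic fractions of 5–10%, and a litter fraction near 10%.

What the simulator does *not* emulate: linkage disequilibrium from
recombination maps (loci segregate independently within gametes),
selection across generations, genotyping error, and crossbreeding.
Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness
to ascertainment or LD structure in real chip data.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_gblup_data(n_ref = 1000, n_test = 200, m = 2000, seed = 1)
g   <- qc_filter(sim$genotypes)$genotypes
G   <- grm_additive(g)
fam <- fit_model_family(sim$pheno, G, grm_dominance(g))
glance(fam)
tidy(fam$MAED)
validate_predictions(fam, dplyr::filter(sim$pheno, test))
```

## Problem sizes and reproducibility

The shipped tests and the acceptance script regenerate every dataset
from code under fixed seeds.  Monte-Carlo matrix expectations use 500
individuals by 5,000 loci; variance-component recovery uses 10–20
replicates of 1,000–1,200 individuals by 1,500–2,000 loci; the
directional model-comparison property uses 50 replicates of 350 + 80
individuals by 600 loci.  These sizes were chosen so each property's
Monte-Carlo error is comfortably below the tolerance it is tested at on
a single desktop core.

## Known limitations

* Dense $O(n^3)$ algebra bounds practical use at roughly $10^4$
  individuals.
* The Hadamard-product epistatic matrix is an approximation that
  ignores inbreeding and linkage; it targets total epistatic variance
  capture, not interaction mapping.
* The models assume one record per individual and an
  already-corrected phenotype; repeated records, fixed-effect
  estimation beyond an intercept, and multi-trait extensions are out of
  scope.
* Variance components pinned at the lower bound make likelihood-ratio
  tests of those components conservative, and their standard errors are
  not reported.
* Separating additive-by-additive variance from the residual and
  common-litter variance needs dispersed relatedness.  In compact
  full-sib designs $\mathbf{G}\#\mathbf{G}$ is nearly collinear with
  the identity plus the litter blocks, so $\hat\sigma^2_{aa}$ is weakly
  identified: its standard error is of the order of the estimate, and
  when the true value is zero roughly half of its sampling mass sits at
  the boundary while the positive half can stray far.  The test suite
  measures both behaviours.
* At moderate reference sizes, the gain in breeding-value accuracy from
  adding non-additive terms is small enough to be offset by the extra
  estimation noise; expect clear gains only with large, diverse
  reference sets.
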