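---
title: "Determining a cost-effective training set size for genomic prediction"
author: "ssdGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining a cost-effective training set size for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdGP)
```

## The problem

Genomic prediction trains a statistical model on a phenotyped *training set*
and uses it to predict genomic estimated breeding values (GEBVs) for
unphenotyped selection candidates. Genotyping is cheap; phenotyping is not.
Given a genotyped *candidate set* of n_c individuals, how many of them should
actually be phenotyped? ssdGP answers this from genotypes alone:

1. **Profile**: for each size n_t on a grid, optimize training sets under the
   r-score criterion and record the achieved criterion values.
2. **Fit**: model the (size, r-score) profile with an S-shaped growth curve.
3. **Invert**: form the operating curve RErs(n_t) — the fitted r-score at
   n_t relative to the fitted r-score of the whole candidate set — and read
   off the smallest n_t* whose RErs meets a user target such as 0.95 or
   0.99.

Once phenotypes exist for the recommended set, the relative prediction
ability REpa = r(n_t\*) / r(n_c) of GBLUP predictions on a test set acts as a
point estimate of RErs(n_t\*) and validates the recommendation.

## Marker processing

SNP scores are coded -1 / 0 / +1 for minor-allele homozygote, heterozygote
and major-allele homozygote. Quality control applies, in order, a marker
call-rate filter (default minimum 0.9), an individual missing-rate filter
(default maximum 0.1) and a minor-allele-frequency filter (default 0, i.e.
off); each published panel's filtering rule is expressible with these three
knobs. MAF is computed on observed calls only, before imputation, so imputed
fractions never influence the allele counts. Missing calls are then replaced
by the marker mean, and the matrix is column-standardized with the n-1
denominator; zero-variance markers cannot be standardized and are dropped
with a warning (subsets of candidate sets routinely fix alleles, so this is
not an error).

All downstream computation uses the principal-component score matrix
L = M Q from the spectral decomposition of M'M, with as many components as
individuals. Components with eigenvalue below 1e-10 times the leading one
are truncated as numerically null — the floating-point proxy for "positive
eigenvalue". Since L L' = M M', every quantity the criterion and the
kinship need is preserved while the column dimension drops from the number
of markers to (at most) the number of individuals.

## The r-score criterion

For a training set with PC scores X_t and a reference set X_0 (the test set
for the *targeted* method, the candidate set itself for the *untargeted*
one), the criterion is r = q12 / sqrt(q1 q2), built from the ridge hat
matrix A = X_t' (X_t X_t' + lambda I)^-1 and the centered reference Gram
matrix Theta = X_0' (I - Jbar) X_0:

* q12 = Tr[Theta A X_t],
* q1 = (n_0 - 1) + Tr[Theta] (reference-only, precomputed once),
* q2 = Tr[A' Theta A] + Tr[X_t' A' Theta A X_t].

It approximates the expected Pearson correlation between GEBVs and
phenotypes of the reference set, computable before any phenotyping. The
shrinkage parameter lambda is fixed at 1 throughout the procedure; a
dedicated robustness check (below) confirms the final size recommendation
does not depend on that choice. In the untargeted method the reference is
the full candidate set including the training individuals themselves — the
criterion is "between S_c and S_t", with no exclusion of selected rows.

Internally the traces are reduced to training-set-sized identities
q12 = Tr[B G^-1] and q2 = q12 + (1 - lambda) Tr[B G^-2], with
B = X_t Theta X_t' and G = X_t X_t' + lambda I solved by symmetric
positive-definite factorization. The unit tests pin this reduction against a
naive dense implementation of the defining formulas to 1e-10, and q2 below
1e-14 q1 raises an explicit degenerate-criterion error rather than returning
a silent 0 (the criterion is 0/0 for null training scores).

## Optimizing a training set of a given size

Training-set optimization is a subset-selection problem. The package solves
it as follows:

* **Tiny pools** (at most 3000 admissible subsets): exact enumeration. At
  this scale enumeration is faster than any heuristic and removes all doubt
  about optimality.
* **Everything else**: an exchange (Fedorov-type) search. Sweep over the
  selected positions; for each position, screen every admissible incoming
  candidate and apply the best strictly improving single swap; stop when a
  full sweep finds no improvement (a fixed point has no improving single
  swap) or after `maxSweeps` sweeps. The search restarts from several
  starts — a deterministic greedy forward-selection start first (for target
  sizes up to 50, where the criterion landscape is most rugged), then
  seeded stratified-random starts — and returns the best.

Candidate swaps inside a sweep are screened with rank-2 Woodbury updates of
G^-1 (and G^-2), which makes a sweep cost a few matrix-vector products per
candidate instead of a fresh factorization. Every accepted move is then
re-scored exactly from a fresh Cholesky factorization, so the reported
criterion values are exact and the update algebra can only influence which
swap is proposed, never the reported score. Ties among equal-scoring swaps
resolve to the lowest candidate index; identical inputs and seed give
byte-identical results.

Local search has real limits worth knowing: on small, low-dimensional
instances, and especially at extreme shrinkage values (lambda of order 100
and beyond), the criterion landscape can contain optima whose basin of
attraction under single swaps is essentially just themselves. Exact
enumeration below the cutoff absorbs the practical cases; above it, the
tests verify the heuristic against enumeration on instances just beyond the
cutoff.

**Structured populations.** When cluster labels are supplied, per-cluster
quotas are apportioned by the largest-remainder rule, proportional to the
cluster shares of the test set (targeted) or the candidate set (untargeted),
capped at per-cluster availability with the shortfall redistributed by the
remaining remainders. Initialization respects the quotas and swaps stay
within a cluster, so every visited subset is quota-compliant.

## The growth curves and the operating curve

The profile of optimal r-scores against size is fitted by nonlinear least
squares (Levenberg-Marquardt, convergence when the relative change of the
residual sum of squares or the step falls below 1e-10) to the logistic
growth curve

y = alpha / (1 + exp(beta - gamma x)),

with alpha the asymptote, beta setting the intercept and gamma the growth
rate. Default initialization: alpha_0 = 1.02 max(y), gamma_0 from the
log-odds slope between the first and last profile points, beta_0 from the
first point; if that fails, a coarse grid of gamma_0 values is retried
before reporting failure.

The logistic family occasionally underfits near the profile maximum. When
the residual SS per point exceeds a threshold (default 5e-4, roughly a 0.02
root-mean-square misfit on r-scores of magnitude one), `runSSD()` refits the
four-parameter Weibull-type curve

y = alpha - beta exp(-gamma x^theta),

initialized by a multi-start over a (gamma_0, theta_0) grid that includes
the sign-flipped branch, seeded with the logistic asymptote, and keeps it if
it converges with a smaller residual SS.

The operating curve for the logistic family is the closed form

RErs(n_t) = (1 + exp(beta - gamma n_c)) / (1 + exp(beta - gamma n_t)),

and for the Weibull-type family the generic ratio fitted(n_t) / fitted(n_c),
which reduces to the same expression in the logistic case. Inversion at a
target is closed-form for the logistic family and monotone bisection for the
Weibull-type one. The integer recommendation is the **ceiling** of the
continuous solution, clamped to [n_min, n_c]: the target is then always met,
at the cost of at most one genotype of conservatism. (Published mean sizes
are means of per-repetition inversions, so fractional values are meaningful
there; a single run needs an integer.) Targets below RErs(n_min) are
refused with the attainable range printed — the grid does not support
extrapolating below its smallest size.

## Validation with GBLUP

Phenotype-based validation fits the GBLUP model y_t = mu 1 + g_t + e_t with
g_t ~ N(0, sigma2_g K_t) and kinship K_t = (1/n) L_t L_t', where n is the
total dataset size (configurable for sensitivity checks). The solve uses
the generalized-least-squares form of Henderson's mixed-model equations —
mu_hat = (1'V^-1 1)^-1 1'V^-1 y and g_hat = K (K + r I)^-1 (y - mu_hat 1)
with r = sigma2_e / sigma2_g — which gives the identical BLUE/BLUP without
inverting K. This deterministic solver replaces MCMC-based fitting of the
same model: the estimand (the conditional mean) is unchanged and
repeatability is exact. The intercept is re-estimated inside every fit.

With `varianceRatio = "reml"`, r is estimated by maximizing the restricted
likelihood over a log-spaced grid (1e-4 to 1e4, 41 points) refined by
golden-section search; one eigendecomposition of K makes each likelihood
evaluation O(n). Test-set GEBVs come from the Henderson projection
g0_hat = K_0 K_t^-1 g_t_hat (with a logged ridge jitter of 1e-8 tr(K_t)/n_t
if K_t is numerically singular) plus mu_hat. REpa is reported unclamped —
values above 1 are meaningful and occur when the optimized subset
out-predicts the full candidate set.

## The synthetic data generator

`simulateGenotypes()` emulates the structured diversity panels the procedure
targets: ancestral minor-allele frequencies uniform on `mafRange`,
per-cluster frequencies from a Balding-Nichols draw
Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `divergence`, diploid genotype
sampling, -1/0/1 coding and completely-at-random missingness.
`simulatePhenotypes()` draws `nQtl` standard-normal marker effects and adds
Gaussian noise scaled so the realized heritability matches `h2`; the causal
effects are returned for recovery tests. The hierarchical frequency model
was chosen over coalescent simulation because the method consumes only the
marker matrix: it reproduces what matters here (population structure,
allele-frequency spectra, missingness, heritable polygenic signal) with
closed-form control. It does **not** emulate linkage disequilibrium decay,
pedigree relatedness, selection or drift dynamics — so passing tests say
nothing about, e.g., how LD pruning would interact with the recommendation
on real data.

Default conditions (300 individuals, 1000 markers, 3 clusters,
divergence 0.15, 2% missing calls, h2 = 0.5, 100 QTL) mirror the published
panels' order of magnitude: hundreds of individuals, 10^3-10^4 markers, a
handful of subpopulations.

## Study conditions used by the test suite

The heavier checks run at deliberately desk-scale sizes, chosen once as
realistic smaller analogues of the published study designs:

* **lambda robustness**: a 300 x 1000 panel, untargeted method, fixed
  candidate set (n_c = 250, n_0 = 50), grid 25..225 by 25 with m = 10
  repeats per size — the published grid — at lambda in {0.001, 1, 1000};
  the recommendation at targets 0.95/0.99 may move by at most one grid step.
* **validation recovery**: a 400 x 800 panel with h2 = 0.5, targeted method,
  fixed candidate set (n_c = 250, n_0 = 100), grid 25..200 by 25 with
  m = 5, ten scenario repetitions at target 0.95; the median REpa must land
  within 0.15 of 0.95.

A full profile at these sizes takes seconds to tens of seconds on one CPU,
so the whole suite stays comfortably inside an ordinary CI budget.

## Numerical choices, in one place

* Exchange acceptance tolerance 1e-10 on the criterion; Woodbury screening
  guarded by a 2x2 determinant check with exact re-scoring before any
  acceptance.
* Eigenvalue truncation at 1e-10 relative; criterion degeneracy at 1e-14
  relative to q1; curve-fit convergence at 1e-10 relative.
* Seeds: a single master seed; per-(size, repetition) child seeds derived by
  a counter scheme, so changing m or the grid does not reshuffle unrelated
  runs; all child seeds stay below 2^31.
* Matrices are individual-major; index sets are 1-based in every exported
  interface and report.

## Known limitations

* The exchange search guarantees a single-swap local optimum, not a global
  one, above the enumeration cutoff; restarts plus the greedy start make
  misses rare at lambda = 1 but adversarial landscapes exist (see above).
* The operating curve inherits any lack of fit of the growth curve;
  the Weibull-type escalation mitigates but does not eliminate this, and
  its four parameters are harder to initialize (hence the multi-start).
* The untargeted fixed-candidate scenario yields one operating curve per
  candidate set, so repetition variability there reflects optimizer
  stochasticity only.
* One run covers one scenario draw. Repeating the whole procedure over many
  scenario draws (as the validation tests do) is left to the caller; every
  run is reproducible from its master seed, so a loop over seeds suffices.
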