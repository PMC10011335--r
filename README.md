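# ssdGP — training set sample size determination for genomic prediction

Genomic prediction trains a model on a phenotyped *training set* and
predicts genomic estimated breeding values (GEBVs) for the rest of a
breeding population. Genotyping is cheap, phenotyping is not — so before a
single plot is grown or a single animal is measured, a breeder has to decide
**how many genotypes to phenotype**. ssdGP makes that decision from
genotypes alone, for plant and animal breeders and quantitative geneticists
designing selective-phenotyping experiments.

## The method

For a candidate set S_c (size n_c) the package:

1. **Profiles** optimal training sets under the *r-score* criterion across a
   size grid n_min, n_min + δ, …, n_max (m optimized sets per size). The
   r-score approximates the expected Pearson correlation between GEBVs and
   phenotypes of a reference set:

       r-score = q12 / sqrt(q1 · q2),   A = X_t' (X_t X_t' + λ I)⁻¹
       q12 = Tr[Θ A X_t],  q1 = (n_0 − 1) + Tr[Θ],
       q2  = Tr[A' Θ A] + Tr[X_t' A' Θ A X_t],   Θ = X_0' (I − J̄) X_0

   with X_t, X_0 the principal-component scores of the training and
   reference sets (test set for the *targeted* method, candidate set for
   the *untargeted* one) and λ = 1.
2. **Fits** the logistic growth curve y = α / (1 + exp(β − γx)) to the
   (size, r-score) profile (with a four-parameter Weibull-type fallback
   y = α − β·exp(−γxᶿ) when the logistic underfits).
3. **Inverts** the operating curve

       RErs(n_t) = (1 + exp(β̂ − γ̂ n_c)) / (1 + exp(β̂ − γ̂ n_t))

   at user targets (e.g. 0.95, 0.99) to get the cost-effective size n_t\*
   and the corresponding optimal training set S_t\*.

Once phenotypes exist, GBLUP via Henderson's mixed-model equations and the
relative prediction ability REpa(n_t\*) = r(n_t\*) / r(n_c) validate the
recommendation. A synthetic-data module generates structured genotype
panels and heritable phenotypes so the whole procedure is testable without
any external dataset.

## Worked example

```r
library(ssdGP)
set.seed(1)
# simulate a structured panel: 300 individuals, 1000 SNPs, 3 subpopulations
sim <- simulateGenotypes(simConfig(nIndividuals = 300, nMarkers = 1000,
                                   nClusters = 3, divergence = 0.15,
                                   missingRate = 0.02, seed = 11))
geno <- imputeMean(filterQC(sim$genotypes))
pc   <- pcScores(standardizeMarkers(geno))

# fixed candidate set of 250, test set of 50, untargeted optimization
scen <- buildScenario(nrow(scoreMatrix(pc)), "fixed-candidate", "untargeted",
                      nC = 250, n0 = 50, seed = 7)
report <- runSSD(pc, scen, searchGrid(25, 225, 25, m = 5),
                 targets = c(0.95, 0.99), seed = 42)
report
#> SSDReport (logistic family, lambda = 1)
#> Scenario: fixed-candidate, untargeted; n_c = 250, n_0 = 50
#>   profile: 46 points over sizes 25..250
#>   SampleSizeDecision: target RErs 0.950 -> n_t* = 197 (continuous 196.04, achieved 0.9512, n_c = 250)
#>   SampleSizeDecision: target RErs 0.990 -> n_t* = 237 (continuous 236.13, achieved 0.9907, n_c = 250)
report@fits[[report@family]]
#> GrowthCurveFit [logistic]: alpha = 1.0322, beta = 0.41908, gamma = 0.013554; RSS 0.003505 over 46 points
```

Reading: phenotyping the 197 candidates in
`selectedIndices(report@finalSets[["0.95"]])` is expected to retain 95% of
the criterion value of phenotyping all 250; retaining 99% requires 237.
`plotSSD(report)` draws the fitted growth curve and the operating curve with
the decision points; `writeReportJson()` / `writeProfileTsv()` serialize the
run. With phenotypes in hand, `assessPrediction()` returns r(n_t\*), r(n_c)
and REpa.

A thin command-line front end over the same functions lives in
`inst/scripts/ssd.R` (subcommands `run`, `profile`, `optimize`, `validate`,
`simulate`; see `--help`).

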