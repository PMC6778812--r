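Package: bmors
Title: Bayesian Multi-Output Regressor Stacking for Multi-Trait
    Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage Bayesian multi-output regressor stacking (BMORS) for
    genomic selection with multiple traits measured across multiple
    environments.  Stage one fits, per trait, a univariate Bayesian GBLUP
    with genotype-by-environment interaction by Gibbs sampling, using a
    genomic relationship matrix built from biallelic marker dosages.  Stage
    two regresses each trait on the scaled stage-one predictions of all
    traits with a Bayesian ridge meta-model, so that information is borrowed
    across correlated traits at a fraction of the cost of a full
    multivariate model.  Includes marker quality control, the random
    cross-validation scheme used for incomplete field trials, average
    Pearson correlation (APC) and mean arctangent absolute percentage error
    (MAAPE) accuracy summaries, and a matrix-variate simulator of
    multi-trait multi-environment phenotypes with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
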