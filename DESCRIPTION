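Package: tripleQTL
Title: Three-Way (Additive x Additive x Additive) Epistasis Estimation for
    Doubled-Haploid Line Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators of three-way additive epistasis (aaa) for fully
    homozygous (doubled-haploid) line populations: a phenotypic estimator of
    the total aaa effect with an extreme-line contrast F test and a Wright-type
    effective-factor count; genotype-based estimation of individual and total
    QTL x QTL x QTL interaction effects by unweighted and weighted multiple
    linear regression with per-line variance weights; two-stage (per linkage
    group, then pooled) stepwise-AIC marker selection with a
    Bonferroni-corrected significance filter and a final interaction-model
    selection stage; flanking-marker imputation of missing genotypes under
    Haldane or Kosambi map functions; and a doubled-haploid population
    simulator with heteroscedastic replicate noise for Monte-Carlo validation
    of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml, optparse
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
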