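Package: gmanova
Title: Genetic Variance Components for Unphased Genotypes via the
    General Multi-Allelic Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: ANOVA-type analysis of genetic markers with unphased
    genotypes. Implements the general multi-allelic (GMA) model with
    mean-corrected genotype codings, the classical dummy-variable general
    linear model (GLM) coding, exact conversions among the GLM, GMA and
    constrained Fisher parameterizations, closed-form least-squares
    estimates from genotypic group means, Hardy-Weinberg disequilibrium
    coefficients, additive/dominance/epistatic variance-component
    estimation at one and two loci, a genotype/phenotype simulator, and a
    forward stepwise model-selection study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, vcfR, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
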