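Package: abtseq
Title: Cardiac Thermal Limits and Heat-Stress Transcriptomics in Selectively
    Bred Abalone
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing upper thermal limits of cardiac performance
    in marine ectotherms and for contrasting heat-stress transcriptomes of
    heat-tolerant and heat-sensitive selective lines. Estimates the Arrhenius
    breakpoint temperature (ABT) of heart rate from temperature-ramp traces by
    exhaustive broken-stick regression, compares lines by one-way ANOVA with
    Duncan's multiple range test and compact letter displays, implements
    negative-binomial differential expression (median-of-ratios normalization,
    moment dispersion estimation with a fitted mean-dispersion trend, Wald
    tests) with the strict p/fold-change filter and four standard line-by-
    condition contrasts, and tests category enrichment with the Wallenius
    non-central hypergeometric distribution using a length-bias probability
    weighting function. Includes seed-reproducible simulators for two-phase
    Arrhenius heart-rate ramps, raw pulse traces, and negative-binomial count
    matrices with spiked fold changes, plus packaged summary-table fixtures
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cardiac.R'
    'diffexpr.R'
    'enrichment.R'
    'fixtures.R'
    'phenotype.R'
    'pipeline.R'
    'simulate.R'
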