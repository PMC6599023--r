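Package: quasimendel
Title: Exact Case-Control Statistics and Threshold-Penetrance Simulation
    for Quasi-Mendelian Retinal Disease Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for studying alleles that behave as
    Mendelian recessive mutations in some genotype contexts and as
    oligogenic risk factors in others, as observed for frequent nonsense
    and structural alleles of the retinal ciliopathy genes RP1 and EYS.
    Provides exact conditional inference on 2x2 allele-count tables
    (point-probability Fisher test, conditional maximum-likelihood odds
    ratio, exact confidence intervals), an exact Hardy-Weinberg
    equilibrium test with a one-sided heterozygote-excess tail, a
    six-step genotype/site quality-control cascade for exome calls,
    method-of-moments IBD/PI_HAT relatedness screening, carrier tallies
    and prevalence arithmetic, a carrier-conditioned rare-variant
    association scan over a curated gene panel with Bonferroni calling
    and Q-Q diagnostics, and a synthetic-cohort generator implementing a
    mutational-load threshold (quasi-Mendelian) penetrance model so the
    entire pipeline runs on simulated data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
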