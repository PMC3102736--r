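Package: admixfine
Title: Fine-Mapping and Cumulative Risk Modeling of GWAS Loci in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ancestry-adjusted association testing, tag-SNP-derived two-tier
    significance thresholds, stepwise regional fine-mapping, an unweighted
    risk-allele score, and a closed-form decomposition of the fraction of
    familial relative risk explained by known risk alleles, for case-control
    studies in admixed populations. Includes a synthetic admixed-cohort
    generator (founder-haplotype LD blocks, local-ancestry tracts, imputed
    dosages with quality metrics, injected relative pairs) so the full
    pipeline is testable without external genotype data, plus sample and
    variant quality control with method-of-moments identity-by-descent
    relatedness inference and principal-component global-ancestry estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
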