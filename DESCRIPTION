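Package: hapmc
Title: Pedigree-Informed Haplotype Phasing and Monte Carlo Haplotype
    Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Haplotype association analysis for study resources of mixed
    structure: independent case-control samples, nuclear families, large
    pedigrees, and combinations thereof.  Implements a pedigree-informed
    haplotype phasing algorithm for tightly linked (zero-recombination)
    SNP markers, combining rule-based preprocessing of phase ambiguity
    and missing data, enumeration of Mendelian-consistent pedigree
    haplotype configurations with integrated genotype elimination, and
    EM estimation of population haplotype frequencies under the
    Elston-Stewart pedigree likelihood, with an optional
    partition-ligation strategy for longer marker sets.  Association of
    full-length haplotypes, sub-haplotypes, and single SNPs is assessed
    with Cochran-Armitage trend, chi-square, odds-ratio, and TDT
    statistics using explicit or pseudo controls, and significance is
    obtained from a gene-dropping Monte Carlo null that re-phases every
    simulated data set exactly as the observed data, yielding valid
    empirical p-values despite the use of maximum-likelihood haplotype
    estimates.  A simulation module generates case-control, trio,
    affected-sib-pair, and large-pedigree resources under multiplicative
    disease models for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
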