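Package: svjoint
Title: Population-Scale Structural Variant Joint Genotyping and Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building population structural variant (SV) call sets
    from per-sample deletion, duplication and inversion calls. Merges
    per-sample calls into candidate sites by breakpoint-proximity clustering,
    jointly genotypes every site across the cohort by fitting Gaussian
    mixture models to pileup-summary evidence (alignment support counts and
    GC-corrected normalized read depth), handles chromosome X with inferred
    sex and male depth compensation, flags low-confidence duplications with
    rule-based and SVM-based filters, and evaluates call sets with pedigree
    statistics (Mendelian error, de novo rate, allelic balance), Hudson FST,
    SV-SNP linkage disequilibrium, and hotspot/desert window scans. A
    synthetic-cohort generator reproduces the statistical structure the
    genotyper assumes so the full pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
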