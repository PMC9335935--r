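Package: sdrscan
Title: Sex-Determining Region Scans and Gametolog Tree-Sharing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising sex chromosome differentiation and the
    history of sex-determining regions (SDRs) from multi-sample variant calls.
    Implements sliding-window male/female divergence statistics (read-depth
    ratio, Weir-Cockerham FST between the sexes, SNP density ratio, SDR-like
    and female-specific SNP densities) with empirical autosomal envelopes;
    per-site classification of putatively Y-linked and female-specific SNPs
    from heterozygosity patterns; inference of fixed X/Y gametolog alleles
    per species, outgroup polarisation, and classification of topologically
    informative SNPs into the ten possible gametolog tree topologies to
    discriminate homologous, independent, and turnover SDR histories; and a
    scenario simulator that generates VCF genotypes, read-depth tables, and
    per-site truth tables under explicit sex-chromosome histories, including
    the hemizygote-imputation artifact of diploid variant callers and
    male-biased mutation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
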