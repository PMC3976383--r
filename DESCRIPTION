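Package: sinemap
Title: Homozygosity Mapping and SINE Insertion Discovery for Recessive
    Canine Retinal Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the discovery pipeline that maps a
    recessive progressive retinal atrophy locus to an intronic SINE
    retrotransposon insertion: stratification-corrected case-control
    association (IBS clustering, Cochran-Mantel-Haenszel, max(T)
    permutation, genomic inflation), homozygosity mapping of a shared-case
    critical region, segregation- and exon-proximity-filtered variant
    screening, mobile-element insertion detection from soft-clipped short
    reads with target-site-duplication inference and read-support
    genotyping, structural decomposition of the inserted SINE (body,
    dinucleotide linker, interrupted poly(A) tract), branch-point
    displacement and splice-acceptor impact assessment, exon-skip
    transcript consequence prediction with in-silico RT-PCR, and
    concordance/penetrance statistics for genotyped screening panels.
    Seeded generators provide synthetic cohorts, reads, inserts, pedigrees
    and a toy gene model with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
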