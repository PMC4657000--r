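Package: melomap
Title: Mapping-by-Sequencing of a Recessive Pigmentation Locus from Pooled Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing a Mendelian recessive locus by bulked-segregant
    mapping and for characterizing a causal retrotransposon insertion. Implements
    the variant filter cascade used with four pooled-cross samples (heterozygous
    parent, homozygous mutant parent, and phenotype-sorted offspring pools):
    quality and coverage exclusion, per-sample allelic-state classification with a
    one-read tolerance, segregation-pattern filtering, and contig co-segregation
    verdicts. Adds comparative-synteny hit clustering to delineate a candidate
    chromosome interval, two-point linkage LOD scoring with flanking-recombinant
    interval refinement, and insertion detection with cryptic-exon (GT..AG) splice
    reconstruction and open-reading-frame truncation reporting. A synthetic-data
    generator emulates the pedigree, pooled sequencing, synteny hits, and gene
    structure so the whole pipeline is testable without external data.
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
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
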