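Package: senomob
Title: Detection of Somatic SVA Insertions and De Novo Numts in
    Senescent Versus Proliferating Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for two readouts of somatic genome
    instability in a senescent-versus-proliferating two-sample design:
    (i) de novo SVA retrotransposon insertion flanks recovered from
    subtractive (RDA) amplicon sequencing, and (ii) de novo nuclear
    insertions of mitochondrial DNA (numts) recovered from reads
    chimeric for mtDNA and unique nuclear flanks in WGS and inter-Alu
    (AluScan) amplicon data. Includes a deterministic exact/near-exact
    read aligner with circular mtDNA support, PSL scoring and
    filtering, target-site feature annotation with fixed precedence,
    tiled RPM/fold-change abundance profiling, and a synthetic-genome
    spike-in simulator with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
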