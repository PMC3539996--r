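Package: ptgr
Title: In Silico Restriction Cloning with the pTGR Plasmid Standard
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for designing and virtually executing restriction/ligation
    cloning under the pTGR eight-slot plasmid standard for Corynebacterium
    glutamicum engineering: a double-stranded DNA model with sticky ends,
    complete-digestion and circular-ligation simulation with isocaudomer scar
    arithmetic (XbaI/SpeI/NheI/AvrII), a part-grammar validator with the
    platform's promoter/RBS/replicon strength metadata, recursive operon and
    gene-cluster assembly planning and virtual execution, codon recoding with
    forbidden-site removal, and GenBank/FASTA input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
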