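Package: aamap
Title: Amino Acid Resolution Functional Maps from CRISPR Tiling
    Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of CRISPR tiling mutagenesis screens that read out
    fragmented cDNA of a target gene before and after a positive selection.
    Enumerates tiling sgRNAs (NGG/NAG PAMs) over a coding sequence, extracts
    nucleotide variants from aligned ~250 bp fragments, translates in-frame
    changes into amino-acid-level effects (deletion, combo, substitution),
    quantifies effect frequencies against coverage denominators, and computes
    a per-residue essential score from deletion/combo fold changes and a
    qualitative substitution cutoff. Includes a synthetic screen simulator
    with allele-level genotype-to-phenotype rules for recessive and dominant
    selection models, so the whole pipeline can be exercised end to end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
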