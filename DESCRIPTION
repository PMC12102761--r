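Package: mitocodon
Title: Codon Usage Bias and Divergence Analysis of Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of annotated mitochondrial genomes:
    parsing and validation of protein-coding genes under the vertebrate
    mitochondrial genetic code, base-composition and strand-skew summaries,
    the full codon-usage-bias index battery (RSCU, ENC, GC3s, CAI, CBI, FOP,
    GRAVY, aromaticity) with neutrality, ENC-GC3s and PR2 diagnostics and
    optimal-codon classification, per-gene divergence statistics (nucleotide
    diversity, Kimura two-parameter distances, Nei-Gojobori Ka/Ks), and
    concatenated supermatrix construction with codon-position partitions.
    Includes a codon-level simulator of homologous gene families with
    controlled composition, transition bias and selection intensity, so that
    every stage can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'genetic-code.R'
    'AllClasses.R'
    'bias.R'
    'cds.R'
    'codon-metrics.R'
    'composition.R'
    'divergence.R'
    'genbank.R'
    'gene-names.R'
    'mitocodon-package.R'
    'pipeline.R'
    'simulate.R'
    'supermatrix.R'
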