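Package: spacerTracer
Title: Quantifying CRISPR Spacer Acquisition from Amplicon Deep Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for measuring CRISPR adaptation (spacer
    acquisition) in Streptococcus thermophilus type II-A CR1 arrays from
    paired-end amplicon sequencing. Merges read pairs, parses repeat/spacer
    array structure with mismatch-tolerant repeat anchoring, extracts newly
    acquired leader-proximal spacers, maps them to plasmid, anti-CRISPR gene
    and host-genome references, and infers the protospacer-adjacent motif
    (PAM) as a position frequency matrix with an IUPAC consensus. Also
    implements six-frame ORF calling with alternative start codons, a
    truncated anti-CRISPR homolog screen based on local protein alignment,
    and plasmid-loss / phage-titer assay statistics (Wilson intervals,
    efficiency of plaquing, log reduction). A synthetic-data module
    generates complete cohorts (references, arrays, read pairs, colony
    screens) with known ground truth so that parameter recovery by the
    pipeline is directly testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
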