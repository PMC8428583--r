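Package: ribodeplete
Title: Experiment-Specific rRNA Depletion Oligo Design for Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs and scores antisense biotinylated oligos that deplete the
    most abundant rRNA fragments observed in pilot ribosome-profiling (Ribo-seq)
    libraries. Candidate oligos tiling user-supplied rRNA references are scored
    by a depleting potential: the fraction of a pilot sample's primary-aligned
    rRNA fragments that fall, under coverage and overhang rules, inside the
    oligo's near-perfectly complementary depletion regions. The package also
    optimizes pre-existing oligo sets for a new organism's rRNAs, screens
    designs for off-target complementarity against protein-coding transcripts,
    scores duplexes with published nearest-neighbor RNA/RNA free energies at
    37 degrees C, predicts oligo self-folding, selects non-redundant final oligo
    sets, and simulates hotspot-concentrated pilot data for testing. Results are
    written as FASTA, CSV, BED and GFF3.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
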