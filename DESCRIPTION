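Package: acylstoich
Title: Site-Specific Lysine Acylation Stoichiometry from SWATH Acquisitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies site-specific lysine acetylation and succinylation
    stoichiometry from data-independent acquisition (SWATH) mass spectrometry
    of light (endogenous) versus heavy (isotope-labelled, chemically
    installed) acyl peptide pairs. Computes light/heavy peptide and fragment
    ion masses for Glu-C digests, verifies co-isolation of precursor pairs in
    SWATH windows, extracts fragment-level ion chromatograms from mzML runs
    at ppm tolerance, and reports per-site occupancy as L/(L+H) with median
    and rank-1 fragment summaries, including resolution of peptides carrying
    two or three modified lysines via differentiating b- and y-ions. A
    synthetic SWATH run generator with known ground-truth occupancies makes
    the full pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    Biostrings,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
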