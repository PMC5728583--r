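Package: chaetokey
Title: Chaetotaxy Formulas, Diagnostic Character Matrices and
    Pitfall-Trap Community Summaries for Orchesella Springtails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for morphological taxonomy and shallow-subterranean
    community ecology of Orchesella springtails (Collembola,
    Entomobryidae). Parses and serializes the compact "simplified Mc
    formula" notation for dorsal macrochaetotaxy, houses a 22-character
    diagnostic matrix with per-character count ranges, computes pairwise
    unshared-character dissimilarity with an audit against published
    values, scores partial observations against reference species, and
    exports standard NEXUS morphological matrices. Includes the
    pitfall-trap community summaries used for Mesovoid Shallow
    Substratum (MSS) surveys (species totals, altitude-band abundance
    profiles, compass resultant vectors) and a synthetic-data generator
    with controlled dissimilarity, altitude and orientation structure
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
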