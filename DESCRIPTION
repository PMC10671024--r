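Package: gpcrdimer
Title: Topology Filtering and Interface Triage of GPCR Dimer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combinatorial triage of G protein-coupled receptor (GPCR)
    dimer and truncated-isoform complex models. Reads two-chain complex
    coordinates with transmembrane (TM) segment annotations, fits a
    membrane frame per protomer, applies topology-compliance rules to
    docked poses, characterises dimer interfaces at helix resolution with
    extracellular/middle/intracellular qualifiers, selects the most stable
    models from binding free energy tables, issues competitive-dimerization
    and isoform-blocking verdicts from interface overlap and energy
    comparison, and assembles clash-checked higher-order oligomers. A
    deterministic generator of idealized seven-TM (and truncated) helix
    bundles with designed dimer poses, topology decoys and seeded
    per-residue energy tables provides fully synthetic test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
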