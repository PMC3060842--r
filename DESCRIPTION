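Package: protutils
Title: Utilities for Computational Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A support library for building proteomics software: monoisotopic
    and average peptide mass computation with fixed-mass modifications,
    in-silico enzymatic digestion, theoretical fragment-ion generation and
    tandem mass spectrum annotation, spectrum and chromatogram models with
    MGF input/output, deterministic SVG/PNG rendering and linked zooming,
    FASTA reading and writing with automatic header-dialect detection
    (UniProt, NCBI gi, IPI, generic), an engine-agnostic peptide-spectrum
    match model with auto-detecting adapters for three search-engine result
    dialects, and a data-access-code generator that introspects relational
    tables and emits CRUD accessor classes with all SQL hidden behind four
    persistence operations. A deterministic fixture generator produces all
    test inputs, and a command-line interface exposes the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    xml2
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
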