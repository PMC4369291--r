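Package: elnote
Title: Machine-First 2D Chemical Structures, Datasheets and Depiction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A machine-first chemical data stack built around a minimalist,
    extensible 2D molecule format with virtual-hydrogen and zero-order-bond
    semantics and recursive inline abbreviations. Provides deterministic
    molecular-formula inference with strict and legacy implicit-hydrogen
    decision tables, a strongly typed datasheet container with tolerant
    "aspects" (Solvent, SARTable, Reaction, Experiment), lossy-but-honest
    MDL Molfile V2000 and SDfile interoperability with a machine-readable
    loss ledger, a validation gate that rejects ambiguous entries while
    leaving the chemist the final arbiter, Markush-style template
    enumeration, and deterministic vector (SVG) depiction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    stringr,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
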