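Package: migrantscreen
Title: Untargeted LC-HRMS Screening of Plastic Packaging Migrants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for untargeted screening of non-volatile migrants
    from food-contact plastics by liquid chromatography high-resolution
    mass spectrometry. Provides elemental-formula arithmetic, adduct m/z
    computation, isotope-pattern simulation and formula enumeration from
    accurate mass; parsing, cleaning, harmonization, deduplication and
    merging of MSP-format MS/MS spectral libraries with pseudo-MRM
    transition export; feature-table cleaning (blank, QC and RSD filters),
    correlation-based adduct and in-source-fragment clustering and
    positive/negative polarity merging; multi-evidence compound
    identification combining spectral-library matching with weighted
    structure-database search; and pseudo-MRM presence screening on
    data-independent-acquisition chromatograms. Seeded synthetic-data
    generators make the full pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'elements.R'
    'formula.R'
    'adducts.R'
    'isotopes.R'
    'enumerate.R'
    'msp.R'
    'speclib.R'
    'features.R'
    'cluster.R'
    'identify.R'
    'pseudomrm.R'
    'synthdata.R'
    'cli.R'
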