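Package: saponinscreen
Title: Rule-Based LC-QTOF-MS Dereplication of Steroidal Saponins and
    Cholinesterase Inhibition Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale bioactivity-oriented screening toolkit for
    steroidal saponins. Implements exact monoisotopic mass and adduct m/z
    arithmetic for elemental formulas, a compositional candidate library of
    furostanol and spirostanol glycosides, in-silico ESI-MS/MS fragmentation
    (sequential hexose neutral losses, E-ring cleavage, dehydration) with
    tolerance-based peak matching, and a rule cascade that annotates QTOF
    peak tables with formula assignments, ppm mass errors, skeleton and
    hydroxylation calls and retention-time-based C25 epimer disambiguation.
    The assay half analyses Ellman-type microplate cholinesterase inhibition
    screens: percent inhibition from optical densities, replicate summaries,
    one-way ANOVA with Fisher's LSD post hoc comparisons, and agent ranking.
    Seeded generators simulate QTOF spectra of glycosides and 96-well plate
    readings so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
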