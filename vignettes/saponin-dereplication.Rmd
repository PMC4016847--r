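---
title: "Dereplicating steroidal saponins and scoring cholinesterase inhibition"
author: "saponinscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating steroidal saponins and scoring cholinesterase inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saponinscreen)
```

## The problem

Crude plant extracts that inhibit cholinesterases are interesting leads for
symptomatic Alzheimer's treatment, but a fraction that scores well in an
Ellman assay is still a mixture of dozens of constituents.  `saponinscreen`
implements the desk half of a bioactivity-oriented screening platform for
the steroidal saponins of *Anemarrhena asphodeloides* rhizome: it ranks
extracts and fractions by their percent inhibition of acetyl- and
butyrylcholinesterase (AChE, BuChE), and it dereplicates the active
fraction's LC-QTOF-MS peaks -- assigning an elemental formula, a skeleton
class, a sugar count and ultimately a named saponin to each
chromatographic peak, without isolating anything.

## Mass arithmetic

Everything downstream rests on exact monoisotopic arithmetic.  A formula is
a bag of element counts; its mass is the sum of count times monoisotopic
atomic mass (C exactly 12, H 1.0078250, O 15.9949146, Na 22.9897693).  A
singly charged positive ion's m/z is

$$ m/z = M + m(\text{added}) - m(\text{removed}) - m_e $$

with the electron mass $m_e = 0.00054858$ Da subtracted.  The subtraction
is not cosmetic: for a C~45~ glycoside the sodiated adduct moves from
943.4878 to 943.4873, i.e. the fourth decimal -- about 0.6 ppm -- so
skipping it would misstate every theoretical mass at the precision an
accurate-mass table reports.  Mass accuracy is scored as

$$ \mathrm{ppm} = \frac{m/z_\text{theo} - m/z_\text{exp}}{m/z_\text{theo}} \times 10^6, $$

computed against the *display-rounded* (4 dp) theoretical mass, because
that is the number the error is reported next to.

## The candidate model and its fragmentation rules

A saponin candidate is compositional, not structural: an aglycone formula,
a count of glycosidic hexose residues (C~6~H~10~O~5~, 162.0528 Da each --
glucose and galactose are isobaric, so their identity is metadata only),
and four features the spectra can see:

* **skeleton**: furostanols carrying the reactive C22 hydroxyl dehydrate
  in-source, so they show `[M+Na]+` and `[M+H-H2O]+` but no `[M+H]+`;
  spirostanol-type compounds show `[M+H]+`.
* **sugar count**: each glycosidic bond cleaves as a neutral loss of
  162.0528 Da, giving a descending ladder from the protonated-series root.
* **one optional extra aglycone hydroxyl**, which shifts the
  deglycosylated ion series by +15.9949 Da (the diagnostic nominal series
  becomes 433/415/271/253 instead of 417/273/255).
* **E-ring cleavage** of the C20--C22 and C17--C20 bonds, losing
  C~8~H~16~O~2~ (144.115 Da) from saturated side chains and
  C~8~H~14~O~2~ (142.099 Da) from 25(27)-unsaturated ones, followed by a
  final water loss.

`predict_fragments()` turns a candidate into a tree whose every edge is
one of these neutral losses, and `nominal_ladder()` renders the reported
ions as the integer ladder conventionally printed.  The library entries
carry explicit fragmentation descriptors (ladder root, optional head ion,
post-deglycosylation dehydration, E-ring loss formula) because compounds
sharing a molecular formula demonstrably fragment differently -- four
C~39~H~64~O~14~ isomers in the packaged library produce four distinct
ladders -- and those differences are observational facts about each
compound, not derivable from composition alone.  One library entry uses a
C~8~H~18~O~2~ (146.131 Da) E-ring loss, following the loss label reported
for that compound even though its published accurate fragment masses are
internally inconsistent at the 10 mDa level; the nominal ladder is what
the engine reproduces and matches.

## The annotation cascade

For each spectrum, `annotate_spectra()`:

1. keeps the candidates whose sodiated adduct lies within the precursor
   ppm window of the observed precursor (default 5 ppm; the largest error
   in the packaged reference data is 2.8 ppm);
2. requires *full* coverage of the candidate's predicted ladder by the
   observed fragments (greedy nearest matching, each observed peak used
   once; default window 0.5 Da for nominal ladders, since integer ladders
   sit up to ~0.49 Da from their accurate values);
3. vetoes candidates contradicted by the skeleton call (from the
   precursor species) or the hydroxylation-state call (from the
   diagnostic 417/273/255 vs 433/415 series);
4. resolves epimers within an isomer group by elution order: on a C18
   column the 25R epimer elutes later than 25S, so the later-eluting peak
   of a pair receives the 25R candidate;
5. grades confidence: `standard-confirmed` when an authentic standard
   exists for the assignment, `tentative` otherwise, `class-only` when
   retention time cannot separate the remaining isomer possibilities.

Two numerical choices deserve a note.  First, hexose counting stops at
m/z 350: below the aglycone-ion region the only steroid fragments are
E-ring products, and the spacing between the aglycone ion and its final
E-ring/water product (144.115 + 18.011 = 162.126 Da) is indistinguishable
from a hexose loss at unit resolution, so a naive chain count would
overcount by one on every saturated ladder.  Second, when several isomer
candidates fit and retention time cannot separate them, the engine assigns
library order and marks the record `class-only` rather than guessing.

## Synthetic data: what it emulates and what it does not

`simulate_spectrum()` draws the precursor with multiplicative Gaussian ppm
error (default sigma 1.4 ppm, putting ~95% of draws inside the +/- 2.8 ppm
band a calibrated QTOF achieves), the predicted ladder with additive
Gaussian error (default sigma 0.15 Da), and uniform decoy peaks excluded
from +/- 1 Da around true ions so ground truth stays well defined.
`simulate_plate()` draws control and sample wells around their Ellman
means with a common OD noise (default sigma 0.02 OD at a control of 1.0).
Everything is a pure function of (parameters, seed).

The generators do *not* emulate chromatographic peak shape, isotope
envelopes, intensity patterns, ion suppression or plate-position effects.
A recovery experiment passing on these simulations therefore shows that
the rule cascade and the assay arithmetic are correct under calibrated
noise -- not that the platform would be robust to matrix effects in real
extracts.

In the stress-test recovery experiment (5 ppm precursor noise, 0.3 Da
fragment noise, 3 decoys) the matching windows are set to three times the
noise scale (15 ppm, 0.9 Da), the usual matched-window rule; with the
default windows a 5 ppm-sigma precursor would fall outside a 5 ppm window
a third of the time by construction.  The suite runs 200 seeded spectra
for that experiment and 100 seeded plates for inhibition recovery; the
fragment windows stay safe because no predicted ladder contains two ions
closer than 2 Da.

## Assay analytics

Percent inhibition is the blank-corrected OD ratio
$(1 - (S - B)/(C - B)) \times 100$; whether the instrument's export is
already blank-corrected varies between laboratories, so a `raw-ratio`
variant is a configuration switch.  Replicates (n >= 3) are summarised as
mean +/- SEM.  Group comparison is one-way ANOVA (via `stats::aov`)
followed by Fisher's LSD -- pairwise t tests on the pooled within-group
mean square -- at alpha 0.05, matching the screening study's design.
Ranking is by mean inhibition, ties broken by SEM; "not detected" entries
are excluded rather than treated as zero, because screening tables
distinguish a blank entry from a measured 0.1%.

The fraction-level screen (water through 95% ethanol fractions) is only
reported graphically in the underlying study, so the packaged
`screen_effects_preset("fractions")` values are synthetic, package-chosen
truths with the 60% ethanol fraction dominant; they exercise the
pipeline, they are not measurements.

## Known limitations

* The candidate model has no connectivity: it cannot distinguish sugar
  attachment sites or anomeric configuration, and positional isomers
  sharing composition *and* fragmentation descriptors are separable only
  by retention time.
* Only singly charged positive-mode ions are modelled; negative mode,
  multimers and isotope patterns are out of scope.
* The annotation requires full ladder coverage; heavily suppressed
  spectra with missing rungs will come back `unassigned` rather than
  partially scored.
* LSD comparisons are unprotected against the family-wise error rate by
  design (that is what the LSD test is); treat the flags accordingly.
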