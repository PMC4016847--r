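# saponinscreen

Rule-based LC-QTOF-MS dereplication of steroidal saponins, coupled to
Ellman cholinesterase-inhibition screening analytics.

Bioassay-guided fractionation of medicinal plants produces two kinds of
desk work: deciding **which extract or fraction is active** (percent
inhibition of AChE/BuChE from 412 nm microplate optical densities,
replicate statistics, ANOVA + Fisher's LSD, ranking) and deciding **what
is in the active fraction** without isolating anything (accurate-mass
formula assignment, in-silico fragmentation of glycoside candidates,
diagnostic ion-series rules, retention-time epimer calls).
`saponinscreen` implements both halves for the steroidal saponins of
*Anemarrhena asphodeloides* rhizome, together with seeded simulators of
QTOF spectra and assay plates so every stage is testable without
instrument data.

## The core model

A saponin candidate is an aglycone formula plus `n` glycosidic hexose
residues (C6H10O5, 162.0528 Da).  Ion m/z is exact monoisotopic
arithmetic with electron-mass correction,

    m/z = M + m(added) − m(removed) − m_e,

and mass accuracy is `(theo − exp)/theo × 1e6` ppm.  Fragmentation is a
tree of neutral losses: in-source dehydration for C22-hydroxy
furostanols (they show [M+Na]+ and [M+H−H2O]+ but no [M+H]+), successive
162.0528 Da hexose losses down to the aglycone ion, an optional further
dehydration (+OH aglycones shift the diagnostic nominal series from
417/273/255 to 433/415/271/253), E-ring cleavage (−C8H16O2 saturated,
−C8H14O2 for 25(27)-ene) and a final water loss.  The annotation cascade
keeps candidates matching the precursor within a ppm window, demands full
fragment-ladder coverage, vetoes rule contradictions, and resolves 25R/25S
epimers by elution order (25R later on C18).

## Worked example

Annotate the packaged peak table of the active (60% ethanol) fraction:

```r
library(saponinscreen)
peaks <- read_peak_table(system.file("extdata", "table2_peaks.tsv",
                                     package = "saponinscreen"))
ann <- annotate_spectra(peaks, saponin_library())
ann
#> <annotation> 15 peak(s), 15 assigned
#>  peak_id rt_min   formula selected_ion theoretical_mz experimental_mz error_ppm
#>        1   29.8 C45H76O20      [M+Na]+       959.4822        959.4833      -1.1
#>        2   31.7 C45H74O19      [M+Na]+       941.4717        941.4726      -1.0
#>        3   37.6 C45H76O19      [M+Na]+       943.4873        943.4886      -1.4
#>        4   38.5 C45H76O19      [M+Na]+       943.4873        943.4882      -1.0
#>  ...
```

All fifteen peaks are assigned (timosaponins N, M, BII and its 25R
epimer, BIII, G, AIII/AIV, AI, *Anemarrhena* saponin I, ...); six carry
`standard-confirmed` confidence because an authentic standard exists.
The `error_ppm` column is the accuracy of each formula assignment --
everything here is within ±2.8 ppm.

Predicted fragmentation of one standard:

```r
predict_fragments(saponin_library()[["Timosaponin BII"]])
#> <fragmentation tree> Timosaponin BII
#>                         label     formula       mz step ...
#>                       [M+Na]+ C45H76NaO19 943.4873    0
#>                    [M+H-H2O]+   C45H75O18 903.4948    0
#>                [M+H-H2O-162]+   C39H65O13 741.4420    1
#>              [M+H-H2O-2x162]+    C33H55O8 579.3891    2
#>              [M+H-H2O-3x162]+    C27H45O3 417.3363    3
#>      [M+H-H2O-3x162-C8H16O2]+     C19H29O 273.2213    4
#>  [M+H-H2O-3x162-C8H16O2-H2O]+      C19H27 255.2107    5
```

i.e. the nominal ladder 903, 741, 579, 417, 273, 255: dehydration, three
hexose losses, E-ring cleavage, water loss.

Rank the isolated compounds by BuChE inhibition:

```r
tab <- read_screen_table(system.file("extdata", "compound_screen.tsv",
                                     package = "saponinscreen"))
rank_agents(tab[tab$role == "compound" & tab$enzyme == "BuChE", ])
#> <ranking> BuChE inhibition, top agent: 3 (75.8%)
```

Compound 3 (75.8 ± 0.7 %) leads; "not detected" entries are excluded
rather than counted as zero.

A command-line wrapper installs under `exec/` with one verb per stage
(`mass`, `predict`, `annotate`, `assay`, `screen-rank`, `simulate`).

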