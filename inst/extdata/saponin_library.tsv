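# Compositional library of steroidal saponin candidates (furostanol /
# spirostanol glycosides of Anemarrhena rhizome).  Sugars are counted as
# isobaric dehydrated hexoses (C6H10O5); glucose/galactose labels are
# informational only.  The fragmentation descriptor columns (ladder_root,
# head_ion, post_deglyc_h2o, ering_loss) encode each compound's observed
# protonated-series behaviour: which ion heads the ladder, whether an extra
# dehydration follows deglycosylation, and which E-ring neutral loss applies.
name	rt_min	skeleton	c22_hydroxyl	extra_aglycone_oh	ene_25_27	n_hexose	sugar_labels	c25_config	aglycone_formula	ladder_root	head_ion	post_deglyc_h2o	ering_loss	is_standard
Timosaponin N	29.8	furostanol	TRUE	1	FALSE	3	gal;glc;glc	unspecified	C27H46O5	MH-H2O	none	TRUE	C8H16O2	FALSE
Timosaponin M	31.7	furostanol	TRUE	0	TRUE	3	gal;glc;glc	unspecified	C27H44O4	MH-H2O	none	FALSE	C8H14O2	FALSE
Timosaponin BII	37.6	furostanol	TRUE	0	FALSE	3	gal;glc;glc	S	C27H46O4	MH-H2O	none	FALSE	C8H16O2	TRUE
25R-Timosaponin BII	38.5	furostanol	TRUE	0	FALSE	3	gal;glc;glc	R	C27H46O4	MH-H2O	none	FALSE	C8H16O2	FALSE
25S-Officinalisnin-I	39.2	furostanol	TRUE	0	FALSE	3	gal;glc;glc	S	C27H46O4	MH-H2O	none	FALSE	C8H16O2	FALSE
Timosaponin BIII	54.9	spirostanol	FALSE	0	FALSE	3	gal;glc;glc	unspecified	C27H44O3	MH	none	FALSE	C8H16O2	TRUE
Timosaponin G	56.7	furostanol	TRUE	1	TRUE	2	gal;glc	unspecified	C27H44O4	MH	MH-H2O	TRUE	C8H14O2	TRUE
Anemarrhena saponin I	57.6	furostanol	TRUE	0	FALSE	2	gal;glc	unspecified	C27H46O4	MH-H2O	none	TRUE	C8H18O2	TRUE
Isomer of timosaponin G	58.0	furostanol	TRUE	0	TRUE	2	gal;glc	unspecified	C27H44O4	MH-H2O	none	FALSE	C8H14O2	FALSE
25(27)-ene-Anemarrhena saponin I	58.6	furostanol	TRUE	1	TRUE	2	gal;glc	unspecified	C27H44O4	MH	MH-H2O	TRUE	C8H16O2	FALSE
Timosaponin A2	60.4	spirostanol	FALSE	1	FALSE	2	gal;glc	unspecified	C27H44O4	MH	MH	TRUE	C8H16O2	FALSE
Timosaponin AIV	62.2	spirostanol	FALSE	0	FALSE	2	gal;glc	unspecified	C27H44O3	MH	none	FALSE	C8H16O2	TRUE
Timosaponin AIII	63.9	spirostanol	FALSE	0	FALSE	2	gal;glc	S	C27H44O3	MH	none	FALSE	C8H16O2	TRUE
25R-Timosaponin AIII	64.4	spirostanol	FALSE	0	FALSE	2	gal;glc	R	C27H44O3	MH	none	FALSE	C8H16O2	FALSE
Timosaponin AI	75.8	spirostanol	FALSE	0	FALSE	1	gal	unspecified	C27H44O3	MH	none	FALSE	C8H16O2	FALSE
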